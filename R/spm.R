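# Nonparametric 1-D statistical parametric mapping for paired stance-phase
# trajectories: pointwise paired t statistic, sign-flip permutation null,
# family-wise max-|t| thresholding and cluster p-values.

#' Pointwise paired t statistic
#'
#' For an n x T matrix of paired differences, returns
#' `t(j) = mean(d[, j]) / (sd(d[, j]) / sqrt(n))` with the sample (n-1)
#' standard deviation. Where the pointwise sd is zero, t is defined as 0
#' when the mean is also zero and as signed `Inf` otherwise.
#'
#' @param diffs n x T numeric matrix of within-subject differences.
#' @return Length-T numeric vector.
#' @examples
#' pointwise_paired_t(cbind(c(1, 2, 3)))
#' @export
pointwise_paired_t <- function(diffs) {
  d <- as.matrix(diffs)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  m <- colMeans(d)
  s <- sqrt(pmax((colSums(d^2) - n * m^2) / (n - 1), 0))
  t <- numeric(ncol(d))
  zero <- s <= 1e-300
  t[!zero] <- m[!zero] / (s[!zero] / sqrt(n))
  t[zero] <- ifelse(abs(m[zero]) <= 1e-300, 0, sign(m[zero]) * Inf)
  t
}

# t statistics for all sign-flip permutations at once.
# signs: P x n matrix of +/-1; d: n x T. Uses the invariance of sum(d^2)
# under sign flips. Returns P x T matrix.
perm_t_matrix <- function(signs, d) {
  n <- nrow(d)
  M <- (signs %*% d) / n                       # P x T means
  ssq <- matrix(colSums(d^2), nrow(signs), ncol(d), byrow = TRUE)
  v <- (ssq - n * M^2) / (n - 1)
  v[v < 0] <- 0
  # zero-variance columns (up to cancellation error): same sentinel rule
  # as pointwise_paired_t, applied symmetrically to every permutation
  zerov <- v <= 1e-13 * ssq / (n - 1)
  tt <- M / sqrt(v / n)
  tt[zerov] <- sign(M[zerov]) * Inf
  tt[zerov & abs(M) <= 1e-300] <- 0
  tt[is.nan(tt)] <- 0
  tt
}

sign_flip_matrix <- function(n) {
  # all 2^n sign vectors, deterministic order
  m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(m) <- NULL
  m
}

#' Paired nonparametric SPM over stance trajectories
#'
#' Compares two conditions measured on the same subjects at every point of
#' a 1-D (stance) grid. The pointwise paired t statistic is referred to
#' the permutation distribution of the maximum absolute t over the grid,
#' obtained by flipping the sign of each subject's difference curve:
#' exhaustively (all `2^n` flips) when `n <= exhaustive_max`, else by
#' seeded Monte-Carlo. The critical threshold is the `(1 - alpha)`
#' quantile of the max-|t| distribution; maximal contiguous runs with
#' `|t| > threshold` are reported as significant clusters, each with the
#' max-statistic p-value `Pr(max|t*| >= max |t| in cluster)`.
#'
#' @param cond_a,cond_b n_subjects x n_points matrices (same subjects,
#'   same grid).
#' @param alpha Family-wise significance level. Default 0.05.
#' @param n_perm Monte-Carlo permutation count when exhaustive enumeration
#'   is not used. Default 10000.
#' @param exhaustive_max Largest n for exhaustive enumeration. Default 12.
#' @param seed Seed for Monte-Carlo mode (ignored when exhaustive).
#' @param stance_pct Optional grid labels (default `0..100` uniform).
#' @return An `spm_result` list: `t_stat`, `threshold`, `alpha`,
#'   `clusters` (data.frame `start`, `end` (grid units), `max_t`,
#'   `p_value`), `n_perm`, `exhaustive`, `stance_pct`.
#' @examples
#' set.seed(2)
#' a <- matrix(rnorm(9 * 101), 9)
#' b <- a + matrix(rnorm(9 * 101, sd = 0.1), 9)
#' snpm_paired(a, b)
#' @export
snpm_paired <- function(cond_a, cond_b, alpha = 0.05, n_perm = 10000L,
                        exhaustive_max = 12L, seed = NULL,
                        stance_pct = NULL) {
  a <- as.matrix(cond_a); b <- as.matrix(cond_b)
  if (!all(dim(a) == dim(b)))
    stop("cond_a and cond_b must have identical shape", call. = FALSE)
  n <- nrow(a); np <- ncol(a)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("trajectories must be finite", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  d <- a - b
  t_obs <- pointwise_paired_t(d)
  if (is.null(stance_pct)) stance_pct <- seq(0, 100, length.out = np)

  if (all(d == 0)) {
    # identical conditions: zero t everywhere, nothing can be significant
    return(structure(list(
      t_stat = rep(0, np), threshold = Inf, alpha = alpha,
      clusters = data.frame(start = numeric(0), end = numeric(0),
                            max_t = numeric(0), p_value = numeric(0)),
      n_perm = 0L, exhaustive = TRUE, stance_pct = stance_pct),
      class = "spm_result"))
  }

  # Monte-Carlo with a budget covering all 2^n flips enumerates instead
  exhaustive <- n <= exhaustive_max || n_perm >= 2^n
  if (exhaustive) {
    signs <- sign_flip_matrix(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
    signs[1, ] <- 1                       # include the identity
  }
  tt <- perm_t_matrix(signs, d)
  # row 1 is the identity flip: use it as the observed statistic so that
  # the observed max ties its own permutation value exactly
  t_obs <- tt[1L, ]
  max_abs <- apply(abs(tt), 1L, max)
  if (all(max_abs == 0))
    stop("degenerate data: zero variance under all permutations",
         call. = FALSE)
  P <- nrow(signs)
  thr_idx <- ceiling((1 - alpha) * P)
  threshold <- sort(max_abs, partial = thr_idx)[thr_idx]

  sup <- abs(t_obs) > threshold
  clusters <- data.frame(start = numeric(0), end = numeric(0),
                         max_t = numeric(0), p_value = numeric(0))
  if (any(sup)) {
    r <- rle(sup)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      i0 <- starts[i]; i1 <- ends[i]
      mt <- max(abs(t_obs[i0:i1]))
      pv <- if (is.infinite(mt)) mean(is.infinite(max_abs)) else
        mean(max_abs >= mt * (1 - 1e-10))
      clusters <- rbind(clusters, data.frame(
        start = stance_pct[i0], end = stance_pct[i1],
        max_t = mt, p_value = pv))
    }
  }
  structure(list(t_stat = t_obs, threshold = threshold, alpha = alpha,
                 clusters = clusters, n_perm = P, exhaustive = exhaustive,
                 stance_pct = stance_pct),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "Nonparametric SPM (paired): %s, %d permutations, threshold |t| > %.3f (alpha = %g)\n",
    if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm,
    x$threshold, x$alpha))
  if (nrow(x$clusters)) {
    cat("Significant clusters:\n")
    print(x$clusters, row.names = FALSE)
  } else cat("No supra-threshold clusters.\n")
  invisible(x)
}

#' Write an SPM result as JSON
#' @param result An [snpm_paired()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_spm <- function(result, path) {
  stopifnot(inherits(result, "spm_result"))
  jsonlite::write_json(list(
    stance_pct = result$stance_pct, t_stat = result$t_stat,
    threshold = result$threshold, alpha = result$alpha,
    n_perm = result$n_perm, exhaustive = result$exhaustive,
    clusters = result$clusters), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot an SPM t curve with significant intervals shaded
#' @param result An [snpm_paired()] result.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_spm <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(stance_pct = result$stance_pct, t = result$t_stat)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stance_pct, y = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * result$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Stance [%]", y = "paired t")
  if (nrow(result$clusters))
    g <- g + ggplot2::annotate("rect", xmin = result$clusters$start,
                               xmax = result$clusters$end, ymin = -Inf,
                               ymax = Inf, alpha = 0.2)
  g
}
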