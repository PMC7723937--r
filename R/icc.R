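# Intrarater reliability: ICC(2,1) — two-way random effects, absolute
# agreement, single measurement — with the F-based 95% confidence interval
# of McGraw & Wong, plus the Koo-Li qualitative classification and
# threshold counting.

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Computes the single-measurement absolute-agreement intraclass
#' correlation from an n x k table (rows = subjects, columns = repeated
#' trials):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the rows (subjects),
#' columns (trials) and error mean squares of the two-way ANOVA. The
#' confidence interval is the F-based interval with Satterthwaite degrees
#' of freedom:
#' \deqn{\nu = \frac{(a\,MS_C + b\,MS_E)^2}{\frac{(a MS_C)^2}{k-1} +
#'   \frac{(b MS_E)^2}{(n-1)(k-1)}}}
#' with \eqn{a = k\,ICC/(n(1-ICC))} and
#' \eqn{b = 1 + k\,ICC\,(n-1)/(n(1-ICC))};
#' lower bound \eqn{n(MS_R - F_U MS_E) / (F_U (k MS_C + (kn - k - n) MS_E)
#' + n MS_R)} with \eqn{F_U = F_{1-\alpha/2}(n-1, \nu)}, and the symmetric
#' upper bound with \eqn{F_{1-\alpha/2}(\nu, n-1)}.
#'
#' @param values Numeric n x k matrix (or data.frame) of measurements;
#'   n >= 2 subjects, k >= 2 trials, no missing cells.
#' @param conf_level Confidence level. Default 0.95.
#' @return An `icc_result` list: `icc`, `ci_low`, `ci_high`,
#'   `classification`, mean squares `ms`, `n`, `k`.
#' @examples
#' set.seed(1)
#' subj <- rnorm(8, 50, 3)
#' x <- sapply(1:3, function(i) subj + rnorm(8, 0, 1))
#' icc_2way_random_absolute(x)
#' @export
icc_2way_random_absolute <- function(values, conf_level = 0.95) {
  x <- as.matrix(values)
  if (anyNA(x)) stop("no missing cells allowed (complete design)",
                     call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 trials", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((x - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))

  if (ss_t < .Machine$double.eps * max(1, grand^2) * n * k) {
    warning("zero total variance: ICC defined as 1 with degenerate CI",
            call. = FALSE)
    res <- list(icc = 1, ci_low = 1, ci_high = 1,
                classification = "excellent",
                ms = c(rows = ms_r, cols = ms_c, error = ms_e),
                n = n, k = k)
    class(res) <- "icc_result"
    return(res)
  }

  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  icc <- (ms_r - ms_e) / denom

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  if (ms_e > 0 && icc < 1) {
    v <- (a * ms_c + b * ms_e)^2 /
      ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (ms_r - f_l * ms_e) /
      (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
    ci_high <- n * (f_u * ms_r - ms_e) /
      (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
  } else {
    ci_low <- icc; ci_high <- icc
  }
  res <- list(icc = icc, ci_low = min(ci_low, icc),
              ci_high = max(ci_high, icc),
              classification = classify_icc(icc),
              ms = c(rows = ms_r, cols = ms_c, error = ms_e),
              n = n, k = k)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f-%.3f), %s reliability [n = %d, k = %d]\n",
              x$icc, x$ci_low, x$ci_high, x$classification, x$n, x$k))
  invisible(x)
}

#' Classify an ICC value (Koo-Li cutoffs)
#'
#' Below 0.5: poor; 0.5 to 0.75: moderate; above 0.75 up to 0.9: good;
#' above 0.9: excellent. Boundary handling keeps "ICC > 0.75" equivalent
#' to good-or-excellent.
#'
#' @param icc ICC value(s), each <= 1 (may be negative).
#' @return Character vector: `"poor"`, `"moderate"`, `"good"` or
#'   `"excellent"`.
#' @examples
#' classify_icc(c(0.3, 0.731, 0.85, 0.981))
#' @export
classify_icc <- function(icc) {
  if (any(icc > 1 + 1e-12)) stop("ICC cannot exceed 1", call. = FALSE)
  out <- character(length(icc))
  out[icc < 0.5] <- "poor"
  out[icc >= 0.5 & icc <= 0.75] <- "moderate"
  out[icc > 0.75 & icc <= 0.9] <- "good"
  out[icc > 0.9] <- "excellent"
  out
}

#' Count reliable measurements (ICC above a threshold)
#'
#' @param iccs Numeric vector of ICC point estimates.
#' @param threshold Reliability threshold; values strictly greater count.
#'   Default 0.75 (good-or-excellent).
#' @return Integer count.
#' @examples
#' ex <- reported_icc_examples()
#' count_reliable(ex$icc[ex$modality == "CT"])
#' @export
count_reliable <- function(iccs, threshold = 0.75) {
  sum(iccs > threshold)
}

#' Bundled intrarater ICC example table
#'
#' A packaged worked-example dataset of intrarater ICC point estimates
#' (with 95% CIs) for the five femoral dimension measurements (ML, AP
#' medial/lateral, JSW medial/lateral) by four raters on CT and MR images
#' of the same nine knees, as reported in a published reliability study of
#' this measurement protocol. Used to demonstrate [classify_icc()] and
#' [count_reliable()].
#'
#' @return Data frame: `parameter`, `modality`, `rater`, `icc`, `ci_low`,
#'   `ci_high`.
#' @export
reported_icc_examples <- function() {
  path <- system.file("extdata", "icc_examples.csv", package = "cartatlas")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Ratings table utilities
#'
#' `read_ratings` reads a long-format CSV with columns
#' `subject_id,rater,trial,modality,parameter,value_mm`. `ratings_matrix`
#' extracts the n x k subject-by-trial matrix for one
#' (parameter, rater, modality) cell. `icc_table` computes ICC(2,1) for
#' every such cell.
#'
#' @param path CSV path.
#' @return `read_ratings`: a data.frame; `ratings_matrix`: a numeric
#'   matrix; `icc_table`: a data.frame with one row per
#'   (parameter, rater, modality) and columns `icc`, `ci_low`, `ci_high`,
#'   `classification`.
#' @export
read_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "rater", "trial", "modality", "parameter",
            "value_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_ratings
#' @param ratings Long-format ratings data.frame.
#' @param parameter,rater,modality Cell selectors.
#' @export
ratings_matrix <- function(ratings, parameter, rater, modality) {
  sub <- ratings[ratings$parameter == parameter & ratings$rater == rater &
                   ratings$modality == modality, ]
  if (!nrow(sub)) stop("no rows match the selection", call. = FALSE)
  tab <- tapply(sub$value_mm, list(sub$subject_id, sub$trial), mean)
  if (anyNA(tab)) stop("incomplete design for the selection", call. = FALSE)
  unclass(tab)
}

#' @rdname read_ratings
#' @export
icc_table <- function(ratings) {
  cells <- unique(ratings[c("parameter", "rater", "modality")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    m <- ratings_matrix(ratings, cells$parameter[i], cells$rater[i],
                        cells$modality[i])
    r <- icc_2way_random_absolute(m)
    data.frame(cells[i, ], icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, classification = r$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
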