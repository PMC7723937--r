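#' Simulate a scaled template under simplified gait loading
#'
#' Time-marches the tibial cartilage layer of a (scaled) template atlas
#' through the stance phase: the prescribed medial-compartment axial force
#' is applied through force-controlled penalty contact with the rigid
#' femoral condyle surface, whose centre translates anteriorly with knee
#' flexion (femoral rollback). The cartilage bottom is tied to bone (fixed,
#' sealed); the free side faces drain; the contact patch seals.
#'
#' @param atlas A [template_atlas()] (typically from [scale_template()]).
#' @param loading A [build_loading()] profile.
#' @param params An [frpve_params()]; default tibial.
#' @param stance_duration_s Duration of 100% stance (s). Default 0.6.
#' @param penalty Contact penalty (MPa/mm). Default 10.
#' @param rollback_mm_per_deg Anterior translation of the condyle centre per
#'   degree of flexion (mm/deg). Default 0.05.
#' @param verbose Passed to [solve_fe()].
#' @return A `field_history` (see [solve_fe()]) with an added `stance_pct`
#'   element aligned with the loading grid.
#' @export
run_gait <- function(atlas, loading, params = frpve_params("tibial"),
                     stance_duration_s = 0.6, penalty = 10,
                     rollback_mm_per_deg = 0.05, verbose = FALSE) {
  stopifnot(inherits(atlas, "template_atlas"),
            inherits(loading, "loading_profile"))
  mesh <- atlas$mesh
  stance <- loading$stance_pct
  times <- stance / 100 * stance_duration_s
  if (times[1] <= 0) times[1] <- times[2] / 10  # first frame shortly after contact
  bottom <- mesh$node_sets$tibial_bottom
  sides <- unique(c(mesh$node_sets$xmin, mesh$node_sets$xmax,
                    mesh$node_sets$ymin, mesh$node_sets$ymax))
  dirichlet <- list(list(nodes = bottom, dof = 1L, value = 0),
                    list(nodes = bottom, dof = 2L, value = 0),
                    list(nodes = bottom, dof = 3L, value = 0))
  centers <- cbind(
    atlas$condyle$center[1] +
      rollback_mm_per_deg * loading$flexion_deg,
    rep(atlas$condyle$center[2], nrow(loading)),
    rep(atlas$condyle$center[3], nrow(loading)))
  contact <- list(nodes = mesh$node_sets$contact_surface,
                  force = loading$medial_force_n,
                  penalty = penalty,
                  condyle = list(radius = atlas$condyle$radius,
                                 center = centers),
                  seal_contact = TRUE)
  prob <- fe_problem(mesh, params,
                     split_line_field = atlas$split_line_field,
                     dirichlet = dirichlet,
                     drained_nodes = setdiff(sides, bottom),
                     contact = contact, time_grid = times)
  hist <- solve_fe(prob, verbose = verbose)
  hist$stance_pct <- stance
  hist
}
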