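#' Measure geometric observables of a model
#'
#' Computes the axial (end-to-end) length, the maximum pairwise
#' inter-atomic distance, and the interdomain angle between the CC-N and
#' CC-C segments.  The interdomain angle is the interior angle at the
#' zinc-motif junction: the angle between the best-fit principal axis of
#' the CC-N C-alphas oriented towards the N-terminus and that of the
#' CC-C C-alphas oriented towards the C-terminus, so a straight model
#' scores 180 degrees and a kinked model the hinge angle.
#'
#' @param model A `dimer_model` or `tetramer_model`.
#' @return A `geometry_report` list with fields `axial_length_A`,
#'   `max_dimension_A`, `interdomain_angle_deg` and `segment_axes` (unit
#'   vectors of the oriented segment axes).
#' @examples
#' measure_geometry(build_ideal_dimer(31, 136))
#' @export
measure_geometry <- function(model) {
  if (inherits(model, "tetramer_model")) {
    pts <- model_coords(model)
    axis_pts <- do.call(rbind, lapply(model$dimers, dimer_axis_points))
    per_dimer <- measure_geometry(model$dimers[[1]])
    rep <- list(axial_length_A = max_pair_distance(axis_pts),
                max_dimension_A = max_pair_distance(pts),
                interdomain_angle_deg = per_dimer$interdomain_angle_deg,
                segment_axes = per_dimer$segment_axes)
    return(structure(rep, class = "geometry_report"))
  }
  stopifnot(inherits(model, "dimer_model"))
  segs <- model$segments
  if (is.null(segs$CC_N) || is.null(segs$CC_C))
    stop("model lacks CC_N/CC_C segment annotation")
  residues <- chain_residues(model$chains[[1]])
  if (sum(residues >= segs$CC_N[1] & residues <= segs$CC_N[2]) < 3 ||
      sum(residues >= segs$CC_C[1] & residues <= segs$CC_C[2]) < 3)
    stop("each annotated segment needs at least 3 residues")

  ax_n <- segment_axis(model, segs$CC_N, towards = "N")
  ax_c <- segment_axis(model, segs$CC_C, towards = "C")
  ang <- acos(pmin(1, pmax(-1, sum(ax_n * ax_c)))) * 180 / pi

  axis_pts <- dimer_axis_points(model)
  structure(
    list(axial_length_A = max_pair_distance(axis_pts),
         max_dimension_A = max_pair_distance(model_coords(model)),
         interdomain_angle_deg = ang,
         segment_axes = list(CC_N = ax_n, CC_C = ax_c)),
    class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("axial length: %.1f A   max dimension: %.1f A   interdomain angle: %.1f deg\n",
              x$axial_length_A, x$max_dimension_A, x$interdomain_angle_deg))
  invisible(x)
}

dimer_axis_points <- function(dimer) {
  (dimer$chains[[1]]$coords + dimer$chains[[2]]$coords) / 2
}

# Principal axis of the pooled C-alphas of a segment, oriented from the
# junction outwards ("N": towards decreasing residue numbers).
segment_axis <- function(dimer, rng, towards = c("N", "C")) {
  towards <- match.arg(towards)
  residues <- chain_residues(dimer$chains[[1]])
  sel <- residues >= rng[1] & residues <= rng[2]
  pts <- rbind(dimer$chains[[1]]$coords[sel, , drop = FALSE],
               dimer$chains[[2]]$coords[sel, , drop = FALSE])
  v <- stats::prcomp(pts, center = TRUE)$rotation[, 1]
  # orient along increasing residue number, then flip for "N"
  ax <- dimer_axis_points(dimer)[sel, , drop = FALSE]
  chain_dir <- ax[nrow(ax), ] - ax[1, ]
  if (sum(v * chain_dir) < 0) v <- -v
  if (towards == "N") v <- -v
  v / sqrt(sum(v^2))
}

# Largest pairwise distance; exact O(N^2) via stats::dist.
max_pair_distance <- function(pts) {
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}
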