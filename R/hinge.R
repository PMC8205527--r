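#' Insert a rigid-body hinge at the zinc-binding motif
#'
#' Bends a straight dimer model at a pivot residue: every atom C-terminal
#' of the pivot is rotated, identically in both chains, about an axis
#' through the superhelical-axis point at the pivot, so that the
#' interdomain angle between the CC-N and CC-C segment axes equals
#' `angle_deg`.  An angle of 180 degrees is the identity (no bend);
#' smaller angles produce increasingly kinked models, mirroring the
#' angulation imposed by zinc coordination at the C89xxC92 site.
#'
#' @param dimer A straight `dimer_model` (a previously hinged model may
#'   be re-hinged; the rotation composes).
#' @param pivot_residue Residue at which to bend; must be strictly
#'   inside the chain range.  Default 91, the midpoint of C89xxC92.
#' @param angle_deg Target interdomain angle in degrees, in (0, 180].
#' @param bend_direction Unit 3-vector towards which the C-terminal arm
#'   tips; default perpendicular to the plane containing the dimer axis
#'   and the A-to-B inter-chain direction at the pivot.
#' @return A new `dimer_model` with the `hinge` field set.
#' @examples
#' d <- build_ideal_dimer(31, 145)
#' h <- insert_hinge(d, angle_deg = 140)
#' measure_geometry(h)$interdomain_angle_deg
#' @export
insert_hinge <- function(dimer, pivot_residue = 91, angle_deg = 140,
                         bend_direction = NULL) {
  stopifnot(inherits(dimer, "dimer_model"))
  ch <- dimer$chains[[1]]
  pivot_residue <- as.integer(pivot_residue)
  if (pivot_residue <= ch$first_residue || pivot_residue >= ch$last_residue)
    stop("pivot_residue must lie strictly inside the chain range ",
         ch$first_residue, "-", ch$last_residue)
  if (!(angle_deg > 0 && angle_deg <= 180))
    stop("angle_deg must lie in (0, 180]")

  residues <- chain_residues(ch)
  pivot_idx <- match(pivot_residue, residues)
  # point on the superhelical axis at the pivot: chain mean (the two
  # chains are related by a 180 deg rotation about the axis)
  pivot_point <- (dimer$chains[[1]]$coords[pivot_idx, ] +
                  dimer$chains[[2]]$coords[pivot_idx, ]) / 2
  if (is.null(bend_direction)) {
    # perpendicular to the plane spanned by the dimer axis (z at the
    # pivot for straight models) and the inter-chain A->B vector
    axis_dir <- local_axis_direction(dimer, pivot_idx)
    interchain <- dimer$chains[[2]]$coords[pivot_idx, ] -
      dimer$chains[[1]]$coords[pivot_idx, ]
    bend_direction <- cross3(axis_dir, interchain)
    if (sum(bend_direction^2) < 1e-12) bend_direction <- c(1, 0, 0)
  }
  bend_direction <- bend_direction / sqrt(sum(bend_direction^2))
  axis_dir <- local_axis_direction(dimer, pivot_idx)
  rot_axis <- cross3(axis_dir, bend_direction)
  if (sum(rot_axis^2) < 1e-12)
    stop("bend_direction must not be parallel to the dimer axis")
  bend <- (180 - angle_deg) * pi / 180
  R <- rotation_matrix(rot_axis, bend)

  sel <- residues > pivot_residue
  out <- dimer
  out$chains <- lapply(dimer$chains, function(chain) {
    chain$coords[sel, ] <- rotate_about(chain$coords[sel, , drop = FALSE],
                                        R, pivot_point)
    if (!is.null(chain$sidechain))
      chain$sidechain[sel, ] <- rotate_about(
        chain$sidechain[sel, , drop = FALSE], R, pivot_point)
    chain
  })
  out$hinge <- list(pivot_residue = pivot_residue, angle_deg = angle_deg,
                    bend_direction = bend_direction)
  out
}

rotate_about <- function(coords, R, centre) {
  sweep(sweep(coords, 2, centre) %*% t(R), 2, centre, "+")
}

# Direction of the dimer axis in the neighbourhood of residue index i,
# from the axis-point trace (chain means).
local_axis_direction <- function(dimer, idx) {
  axis_pts <- (dimer$chains[[1]]$coords + dimer$chains[[2]]$coords) / 2
  n <- nrow(axis_pts)
  lo <- max(1, idx - 3); hi <- min(n, idx + 3)
  d <- axis_pts[hi, ] - axis_pts[lo, ]
  d / sqrt(sum(d^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Assemble a head-to-head dimer-of-dimers tetramer
#'
#' Places a second copy of a cNTD dimer head-to-head with the first so
#' that the two copies run anti-parallel and their tetramerisation
#' overlap regions (residues 31--52 by default) occupy the same axial
#' window, an idealised stand-in for docking onto the nNTD
#' tetramerisation motif.  For hinged dimers the two CC-C arms bend
#' either to the same side (`cis`) or to opposite sides (`trans`) of the
#' long axis; the `trans` assembly has an exact two-fold (C2) symmetry
#' axis perpendicular to both the long axis and the bend direction.
#'
#' @param dimer A `dimer_model` covering at least the overlap range.
#' @param configuration `"cis"` or `"trans"`.
#' @param overlap_range Residue range shared with the tetramerisation
#'   motif structure, default `c(31, 52)`.
#' @return A `tetramer_model` containing the two placed dimers and the
#'   rigid transform applied to the second copy.
#' @examples
#' d <- insert_hinge(build_ideal_dimer(31, 145), angle_deg = 140)
#' tt <- assemble_tetramer(d, "trans")
#' measure_geometry(tt)$max_dimension_A
#' @export
assemble_tetramer <- function(dimer, configuration = c("cis", "trans"),
                              overlap_range = c(31L, 52L)) {
  configuration <- match.arg(configuration)
  stopifnot(inherits(dimer, "dimer_model"))
  ch <- dimer$chains[[1]]
  if (ch$first_residue > overlap_range[1] || ch$last_residue < overlap_range[2])
    stop("dimer range ", ch$first_residue, "-", ch$last_residue,
         " does not contain the overlap range ",
         overlap_range[1], "-", overlap_range[2])
  residues <- chain_residues(ch)
  axis_pts <- (dimer$chains[[1]]$coords + dimer$chains[[2]]$coords) / 2
  sel <- residues >= overlap_range[1] & residues <= overlap_range[2]
  centre <- colMeans(axis_pts[sel, , drop = FALSE])
  # long axis ~ z for models built here; bend direction (if any) sets x
  flip_axis <- c(1, 0, 0)
  if (!is.null(dimer$hinge)) {
    b <- dimer$hinge$bend_direction
    flip_axis <- switch(configuration,
      # rotate about the bend direction: the copy's arm stays on the
      # same side (cis); rotate about the perpendicular: opposite (trans)
      cis = b,
      trans = cross3(c(0, 0, 1), b))
    if (sum(flip_axis^2) < 1e-12) flip_axis <- c(1, 0, 0)
  }
  R <- rotation_matrix(flip_axis, pi)
  copy <- dimer
  copy$chains <- lapply(dimer$chains, function(chain) {
    chain$coords <- rotate_about(chain$coords, R, centre)
    if (!is.null(chain$sidechain))
      chain$sidechain <- rotate_about(chain$sidechain, R, centre)
    chain
  })
  copy$chains[[1]]$chain_id <- "C"
  copy$chains[[2]]$chain_id <- "D"
  structure(
    list(dimers = list(dimer, copy), configuration = configuration,
         overlap_range = as.integer(overlap_range),
         transform = list(rotation = R, centre = centre)),
    class = "tetramer_model")
}

#' @export
print.tetramer_model <- function(x, ...) {
  cat(sprintf("Dimer-of-dimers tetramer model (%s configuration)\n",
              x$configuration))
  cat(sprintf("  overlap range: %d-%d\n",
              x$overlap_range[1], x$overlap_range[2]))
  print(x$dimers[[1]])
  invisible(x)
}
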