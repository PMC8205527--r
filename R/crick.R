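#' Crick parameters for an ideal parallel coiled-coil dimer
#'
#' Geometric parameters of the Crick parameterisation of a two-stranded
#' coiled coil: each alpha-helix (minor helix) winds about a local axis
#' that itself supercoils around the shared superhelical axis.  Defaults
#' are canonical values for a left-handed parallel dimer, matching the
#' geometry produced by ideal-model builders such as CCBuilder.
#'
#' The superhelical pitch is not independent of the other parameters: a
#' heptad repeat constrains the helix to 3.5 residues per turn in the
#' frame that rotates with the supercoil, so the supercoil must absorb
#' the difference between 3.5 and the lab-frame `residues_per_turn`.
#' When `superhelical_pitch` is `NULL` it is derived from that relation,
#' `P = rise * (3.5 * rpt) / (rpt - 3.5)` (156.8 A at the defaults).
#'
#' @param superhelical_radius Distance from the superhelical axis to each
#'   local helix axis, in Angstrom.
#' @param rise_per_residue Axial rise per residue along the superhelical
#'   axis, in Angstrom.  Must lie in `[1.3, 1.6]`.
#' @param residues_per_turn Lab-frame residues per alpha-helical turn.
#'   Must lie in `[3.5, 3.7]`.
#' @param helix_radius Radius of the C-alpha trace about the local helix
#'   axis, in Angstrom.
#' @param superhelical_pitch Pitch of the supercoil in Angstrom, or
#'   `NULL` to derive it from the heptad constraint (see Details).
#' @param handedness Handedness of the supercoil, `"left"` (canonical)
#'   or `"right"`.
#' @param interface_phase Phase of the minor helix at residue 1, in
#'   degrees; sets the azimuthal orientation of the heptad a/d seam.
#' @return An object of class `crick_parameters`.
#' @examples
#' crick_parameters()
#' @export
crick_parameters <- function(superhelical_radius = 4.9,
                             rise_per_residue = 1.485,
                             residues_per_turn = 3.62,
                             helix_radius = 2.26,
                             superhelical_pitch = NULL,
                             handedness = c("left", "right"),
                             interface_phase = 26) {
  handedness <- match.arg(handedness)
  stopifnot(superhelical_radius > 0, helix_radius > 0)
  if (rise_per_residue < 1.3 || rise_per_residue > 1.6)
    stop("rise_per_residue must lie in [1.3, 1.6] Angstrom")
  if (residues_per_turn < 3.5 || residues_per_turn > 3.7)
    stop("residues_per_turn must lie in [3.5, 3.7]")
  if (is.null(superhelical_pitch)) {
    if (residues_per_turn <= 3.5)
      stop("superhelical_pitch must be given when residues_per_turn <= 3.5")
    superhelical_pitch <- rise_per_residue *
      (3.5 * residues_per_turn) / (residues_per_turn - 3.5)
  }
  stopifnot(superhelical_pitch > 0)
  structure(
    list(superhelical_radius = superhelical_radius,
         superhelical_pitch = superhelical_pitch,
         rise_per_residue = rise_per_residue,
         residues_per_turn = residues_per_turn,
         helix_radius = helix_radius,
         handedness = handedness,
         interface_phase = interface_phase),
    class = "crick_parameters")
}

#' @export
print.crick_parameters <- function(x, ...) {
  cat("Crick parameters (", x$handedness, "-handed supercoil)\n", sep = "")
  cat(sprintf("  superhelical radius: %.2f A   pitch: %.1f A\n",
              x$superhelical_radius, x$superhelical_pitch))
  cat(sprintf("  rise/residue: %.3f A   residues/turn: %.2f   helix radius: %.2f A\n",
              x$rise_per_residue, x$residues_per_turn, x$helix_radius))
  invisible(x)
}

# Default CtIP-cNTD segment annotation (1-based CtIP numbering):
# CC-N and CC-C coiled coils flanking the zinc-binding motif, whose
# helices run parallel without supercoiling.
ctip_segments <- function() {
  list(CC_N = c(35L, 84L), zinc_motif = c(85L, 116L), CC_C = c(117L, 138L))
}

# Supercoil phase per residue (radians, signed by handedness) and the
# minor-helix phase per residue in the rotating frame.
crick_frequencies <- function(params) {
  omega0 <- 2 * pi * params$rise_per_residue / params$superhelical_pitch
  if (params$handedness == "left") omega0 <- -omega0
  # lab-frame helical frequency corrected into the supercoiling frame
  omega1 <- 2 * pi / params$residues_per_turn - omega0
  list(omega0 = omega0, omega1 = omega1)
}

# C-alpha coordinates of one chain of the ideal dimer.  `phase0` is the
# supercoil phase offset of the chain (0 for A, pi for B).  Residues in
# the zinc motif [85, 116] do not supercoil: their local helix axes are
# straight lines parallel to the superhelical axis (the motif's two
# helices run parallel to each other), anchored continuously to the
# flanking coiled-coil segments.
crick_chain_coords <- function(residues, params, phase0 = 0,
                               segments = ctip_segments()) {
  fr <- crick_frequencies(params)
  t_idx <- seq_along(residues) - 1L
  # pitch angle of the supercoil, signed by handedness (negative for a
  # left-handed supercoil, like omega0)
  alpha <- atan2(2 * pi * params$superhelical_radius, params$superhelical_pitch)
  if (params$handedness == "left") alpha <- -alpha
  r0 <- params$superhelical_radius
  r1 <- params$helix_radius
  d <- params$rise_per_residue
  crick_point <- function(t) {
    phi0 <- fr$omega0 * t + phase0
    phi1 <- fr$omega1 * t + params$interface_phase * pi / 180
    cbind(r0 * cos(phi0) +
            r1 * (cos(phi0) * cos(phi1) - cos(alpha) * sin(phi0) * sin(phi1)),
          r0 * sin(phi0) +
            r1 * (sin(phi0) * cos(phi1) + cos(alpha) * cos(phi0) * sin(phi1)),
          d * t - r1 * sin(alpha) * sin(phi1))
  }
  zn <- segments$zinc_motif
  in_motif <- if (is.null(zn)) rep(FALSE, length(residues)) else
    residues >= zn[1] & residues <= zn[2]
  m <- crick_point(t_idx)
  if (any(in_motif)) {
    # anchor residue: last residue before the motif (or the first motif
    # residue when the chain starts inside it)
    ia <- if (in_motif[1]) 1L else max(which(!in_motif & t_idx < max(t_idx[in_motif])))
    ta <- t_idx[ia]
    az <- fr$omega0 * ta + phase0
    phi1a <- fr$omega1 * ta + params$interface_phase * pi / 180
    # minor-helix phase of the anchor point about the frozen vertical axis
    psi_a <- atan2(cos(alpha) * sin(phi1a), cos(phi1a))
    om_lab <- 2 * pi / params$residues_per_turn
    z_a <- m[ia, 3]
    motif_point <- function(t) {
      s <- t - ta
      psi <- psi_a + om_lab * s
      cbind((r0 + r1 * cos(psi)) * cos(az) - r1 * sin(psi) * sin(az),
            (r0 + r1 * cos(psi)) * sin(az) + r1 * sin(psi) * cos(az),
            z_a + d * s)
    }
    m[in_motif, ] <- motif_point(t_idx[in_motif])
    # resume supercoiling after the motif, rigidly re-anchored: rotate
    # the remaining supercoil to the frozen azimuth and translate so the
    # chain is continuous at the last motif residue
    ie <- max(which(in_motif))
    post <- t_idx > t_idx[ie]
    if (any(post)) {
      te <- t_idx[ie]
      rot <- rotation_matrix(c(0, 0, 1), az - (fr$omega0 * te + phase0))
      cc <- crick_point(t_idx[post | t_idx == te]) %*% t(rot)
      shift <- motif_point(te) - cc[1, , drop = FALSE]
      cc <- sweep(cc, 2, -as.vector(shift))
      m[post, ] <- cc[-1, , drop = FALSE]
    }
  }
  colnames(m) <- c("x", "y", "z")
  rownames(m) <- residues
  m
}

new_chain_model <- function(chain_id, first_residue, last_residue, coords,
                            sidechain = NULL) {
  stopifnot(nrow(coords) == last_residue - first_residue + 1)
  structure(
    list(chain_id = chain_id, first_residue = as.integer(first_residue),
         last_residue = as.integer(last_residue), coords = coords,
         sidechain = sidechain),
    class = "chain_model")
}

chain_residues <- function(chain) chain$first_residue:chain$last_residue

#' Build an ideal straight parallel coiled-coil dimer
#'
#' Generates C-alpha coordinates for a two-chain parallel coiled coil in
#' CtIP residue numbering, using the Crick parameterisation.  The two
#' chains are related by a 180 degree rotation about the superhelical
#' axis (the z axis).  Residues falling inside the zinc-binding motif
#' (85--116) are built as straight parallel alpha-helices that do not
#' supercoil, reflecting the interruption of the heptad repeat at the
#' C89xxC92 site.  Optionally a fixed-offset side-chain centroid
#' pseudo-atom is placed 1.5 Angstrom radially outward of each C-alpha.
#'
#' @param first_residue,last_residue 1-based inclusive residue range
#'   (CtIP numbering).
#' @param params A [crick_parameters()] object.
#' @param include_sidechains Add a side-chain centroid pseudo-atom per
#'   residue (default `FALSE`).
#' @param segments Named list of segment ranges; defaults to the
#'   CtIP-cNTD annotation (CC-N 35--84, zinc motif 85--116, CC-C
#'   117--138), intersected with the built range.
#' @return A `dimer_model` with two chains `A` and `B`.
#' @examples
#' d <- build_ideal_dimer(31, 136)
#' measure_geometry(d)
#' @export
build_ideal_dimer <- function(first_residue, last_residue,
                              params = crick_parameters(),
                              include_sidechains = FALSE,
                              segments = ctip_segments()) {
  first_residue <- as.integer(first_residue)
  last_residue <- as.integer(last_residue)
  if (is.na(first_residue) || is.na(last_residue) ||
      last_residue < first_residue)
    stop("invalid residue range: last_residue must be >= first_residue")
  if (!inherits(params, "crick_parameters"))
    stop("params must be a crick_parameters object")
  residues <- first_residue:last_residue
  segs <- clip_segments(segments, first_residue, last_residue)
  ca_a <- crick_chain_coords(residues, params, phase0 = 0, segments = segments)
  rot <- rotation_matrix(c(0, 0, 1), pi)
  ca_b <- ca_a %*% t(rot)
  rownames(ca_b) <- residues
  colnames(ca_b) <- c("x", "y", "z")
  side_a <- side_b <- NULL
  if (include_sidechains) {
    side_a <- sidechain_centroids(ca_a)
    side_b <- side_a %*% t(rot)
    rownames(side_b) <- residues
    colnames(side_b) <- c("x", "y", "z")
  }
  structure(
    list(chains = list(
           new_chain_model("A", first_residue, last_residue, ca_a, side_a),
           new_chain_model("B", first_residue, last_residue, ca_b, side_b)),
         parallel = TRUE, segments = segs, hinge = NULL, params = params),
    class = "dimer_model")
}

# Pseudo side-chain centroid: 1.5 A radially outward from the local
# helix axis, i.e. along the C-alpha's radial direction from the
# superhelical axis (a cheap but adequate stand-in for C-beta mass).
sidechain_centroids <- function(ca) {
  rad <- ca
  rad[, "z"] <- 0
  nrm <- sqrt(rowSums(rad^2))
  nrm[nrm == 0] <- 1
  ca + 1.5 * rad / nrm
}

clip_segments <- function(segments, first, last) {
  out <- lapply(segments, function(rng) {
    lo <- max(rng[1], first); hi <- min(rng[2], last)
    if (lo > hi) NULL else c(as.integer(lo), as.integer(hi))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.dimer_model <- function(x, ...) {
  ch <- x$chains[[1]]
  cat(sprintf("Coiled-coil dimer model, residues %d-%d (%d residues/chain)\n",
              ch$first_residue, ch$last_residue, nrow(ch$coords)))
  segs <- vapply(names(x$segments), function(nm)
    sprintf("%s [%d-%d]", nm, x$segments[[nm]][1], x$segments[[nm]][2]), "")
  cat("  segments:", paste(segs, collapse = ", "), "\n")
  if (is.null(x$hinge)) {
    cat("  hinge: none (straight)\n")
  } else {
    cat(sprintf("  hinge: pivot %d, interdomain angle %.1f deg\n",
                x$hinge$pivot_residue, x$hinge$angle_deg))
  }
  invisible(x)
}

# All scattering points of a model (C-alpha plus any pseudo-atoms),
# as a single matrix; used by geometry and SAXS code.
model_coords <- function(model, include_sidechains = TRUE) {
  chains <- model_chains(model)
  mats <- lapply(chains, function(ch) {
    m <- ch$coords
    if (include_sidechains && !is.null(ch$sidechain)) m <- rbind(m, ch$sidechain)
    m
  })
  do.call(rbind, mats)
}

model_chains <- function(model) {
  if (inherits(model, "dimer_model")) return(model$chains)
  if (inherits(model, "tetramer_model"))
    return(c(model$dimers[[1]]$chains, model$dimers[[2]]$chains))
  if (inherits(model, "pdb_model")) return(model$chains)
  stop("unsupported model class: ", paste(class(model), collapse = "/"))
}

# Rodrigues rotation matrix about unit axis k by angle (radians).
rotation_matrix <- function(k, angle) {
  k <- k / sqrt(sum(k^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
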