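#' Default paired wild-type/mutant scenario
#'
#' The stated world of the synthetic generator, encoding the reported
#' WT/Mut contrasts across the three techniques: a hinged wild type
#' (interdomain angle 130 degrees, midway between the 120 and 140 degree
#' solution estimates) versus a straight mutant (180 degrees) for SAXS;
#' melting temperatures 333.7 K (WT), 317.0 K (Mut) and 323.0 K
#' (EDTA-treated WT) with hysteretic WT refolding for CD; and a larger
#' tilting (theta) diffusivity for WT than Mut with a common twisting
#' (chi) diffusivity for DXT.
#'
#' @param name Scenario name.
#' @param seed Master seed; all sub-simulations derive their seeds from
#'   it.
#' @return A `scenario_spec` list with components `saxs`, `cd`, `dxt`.
#' @export
default_scenario <- function(name = "default", seed = 1L) {
  structure(
    list(name = name, seed = as.integer(seed),
         saxs = list(wt_hinge_angle_deg = 130, mut_hinge_angle_deg = 180,
                     first_residue = 31, last_residue = 145,
                     pivot_residue = 91, noise = c(a = 0.01, b = 0.04)),
         cd = list(tm_wt = 333.7, tm_mut = 317.0, tm_wt_edta = 323.0,
                   dh = 300, noise_sd = 0.4, refold_shift_wt = -6),
         dxt = list(d_theta_wt = 0.02, d_theta_mut = 0.008,
                    d_chi_common = 0.008, static_fraction = 0.2,
                    edge_fraction = 0.05, n_spots = 500)),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s' (seed %d)\n", x$name, x$seed))
  cat(sprintf("  SAXS: WT hinge %g deg, Mut %g deg\n",
              x$saxs$wt_hinge_angle_deg, x$saxs$mut_hinge_angle_deg))
  cat(sprintf("  CD:   Tm WT %.1f K, Mut %.1f K, WT+EDTA %.1f K\n",
              x$cd$tm_wt, x$cd$tm_mut, x$cd$tm_wt_edta))
  cat(sprintf("  DXT:  D_theta WT %g, Mut %g; D_chi %g rad^2/s\n",
              x$dxt$d_theta_wt, x$dxt$d_theta_mut, x$dxt$d_chi_common))
  invisible(x)
}

scenario_subseed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2147483647L

#' Generate a paired WT/Mut fixture bundle
#'
#' Builds the scenario's structural models, simulates all three data
#' types through the analysis modules, and writes them under `out_dir`:
#' `saxs/wt.dat`, `saxs/mut.dat` (3-column text), six CD curves under
#' `cd/` (melt + refold for WT, Mut and WT+EDTA), `dxt/wt.csv`,
#' `dxt/mut.csv`, plus `truth.json` (the ground-truth record) and
#' `manifest.json` (file list with MD5 checksums).  Regeneration from
#' the same spec and seed is bit-identical.  Analysis code never reads
#' `truth.json`; it exists for recovery tests.
#'
#' @param spec A `scenario_spec` (default [default_scenario()]).
#' @param out_dir Output directory (created if needed).
#' @return A `scenario_bundle` list: `dir`, `files`, `checksums`,
#'   `truth`.
#' @export
generate_scenario <- function(spec = default_scenario(), out_dir) {
  stopifnot(inherits(spec, "scenario_spec"))
  for (d in file.path(out_dir, c("saxs", "cd", "dxt")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  # SAXS: hinged WT vs straight Mut, counting-like noise
  sx <- spec$saxs
  straight <- build_ideal_dimer(sx$first_residue, sx$last_residue)
  models <- list(
    wt = if (sx$wt_hinge_angle_deg >= 180) straight else
      insert_hinge(straight, sx$pivot_residue, sx$wt_hinge_angle_deg),
    mut = if (sx$mut_hinge_angle_deg >= 180) straight else
      insert_hinge(straight, sx$pivot_residue, sx$mut_hinge_angle_deg))
  for (k in seq_along(models)) {
    nm <- names(models)[k]
    curve <- debye_scattering(models[[k]])
    noisy <- simulate_saxs_noise(curve, a = sx$noise[["a"]],
                                 b = sx$noise[["b"]],
                                 seed = scenario_subseed(spec$seed, k))
    f <- file.path(out_dir, "saxs", paste0(nm, ".dat"))
    write_saxs(noisy, f)
    files <- c(files, f)
  }

  # CD: melt + refold for WT, Mut, WT+EDTA
  cd <- spec$cd
  cd_sets <- list(wt = list(tm = cd$tm_wt, shift = cd$refold_shift_wt),
                  mut = list(tm = cd$tm_mut, shift = 0),
                  wt_edta = list(tm = cd$tm_wt_edta, shift = 0))
  k <- 10L
  for (nm in names(cd_sets)) {
    p <- two_state_params(cd_sets[[nm]]$tm, cd$dh)
    for (dir in c("melt", "refold")) {
      k <- k + 1L
      curve <- simulate_melt(p, noise_sd = cd$noise_sd,
                             seed = scenario_subseed(spec$seed, k),
                             direction = dir,
                             refold_shift = cd_sets[[nm]]$shift)
      f <- file.path(out_dir, "cd", paste0(nm, "_", dir, ".csv"))
      write_melt(curve, f)
      files <- c(files, f)
    }
  }

  # DXT: theta contrast, common chi
  dx <- spec$dxt
  det <- detector_config(edge_fraction = dx$edge_fraction)
  dxt_sets <- list(
    wt = motion_model(dx$d_theta_wt, dx$d_chi_common, dx$static_fraction),
    mut = motion_model(dx$d_theta_mut, dx$d_chi_common, dx$static_fraction))
  for (k in seq_along(dxt_sets)) {
    nm <- names(dxt_sets)[k]
    tr <- simulate_tracks(dxt_sets[[nm]], det, n_spots = dx$n_spots,
                          seed = scenario_subseed(spec$seed, 20L + k))
    f <- file.path(out_dir, "dxt", paste0(nm, ".csv"))
    write_tracks(tr, f)
    files <- c(files, f)
  }

  truth <- list(name = spec$name, seed = spec$seed, saxs = spec$saxs,
                cd = spec$cd, dxt = spec$dxt)
  truth_file <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  checksums <- as.vector(tools::md5sum(files))
  manifest <- list(files = basename_rel(files, out_dir),
                   md5 = checksums, seed = spec$seed, name = spec$name)
  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE)
  structure(list(dir = out_dir,
                 files = c(files, truth_file, manifest_file),
                 checksums = checksums, truth = truth),
            class = "scenario_bundle")
}

# paths relative to the bundle root (files are built with file.path(root, ...))
basename_rel <- function(files, root) {
  substring(files, nchar(root) + 2L)
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("Scenario bundle '%s' in %s (%d files)\n",
              x$truth$name, x$dir, length(x$files)))
  invisible(x)
}
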