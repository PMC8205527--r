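#' Write a model to a PDB file
#'
#' Serialises the C-alpha trace (and any side-chain centroid
#' pseudo-atoms, written as CB records) of a dimer or tetramer model as
#' fixed-width PDB ATOM records: chains A/B for dimers and A/B/C/D for
#' tetramers, occupancy 1.00, B-factor 0.00, residue name ALA.
#' Coordinates follow the PDB 8.3 fixed-width convention and therefore
#' round-trip to 3 decimal places.
#'
#' @param model A `dimer_model`, `tetramer_model` or `pdb_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pdb()]
#' @export
write_pdb <- function(model, path) {
  chains <- model_chains(model)
  if (length(chains) == 0 || all(vapply(chains, function(ch)
    nrow(ch$coords) == 0, logical(1))))
    stop("cannot write an empty model")
  lines <- character(0)
  serial <- 0L
  for (ch in chains) {
    residues <- chain_residues(ch)
    for (i in seq_along(residues)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, " CA ", ch$chain_id,
                                      residues[i], ch$coords[i, ]))
      if (!is.null(ch$sidechain)) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(serial, " CB ", ch$chain_id,
                                        residues[i], ch$sidechain[i, ]))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      ALA %s%4d",
                              serial + 1L, ch$chain_id,
                              residues[length(residues)]))
    serial <- serial + 1L
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

pdb_atom_line <- function(serial, atom_name, chain_id, resno, xyz) {
  sprintf("ATOM  %5d %4s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, atom_name, chain_id, resno, xyz[1], xyz[2], xyz[3])
}

#' Read a PDB file written by [write_pdb()] (or any CA/CB-trace PDB)
#'
#' Parses ATOM records into a `pdb_model`: a list of chains with
#' per-residue C-alpha coordinates and optional CB pseudo-atom
#' coordinates.  Only `CA` and `CB` atom records are retained.  A
#' malformed ATOM record raises an error naming the offending line.
#'
#' @param path PDB file path.
#' @param segments Segment annotation to attach (default the CtIP-cNTD
#'   ranges clipped to each chain).
#' @return A `pdb_model` (chains usable by the geometry and SAXS code);
#'   two-chain files additionally gain class `dimer_model`.
#' @export
read_pdb <- function(path, segments = ctip_segments()) {
  raw <- readLines(path)
  idx <- which(startsWith(raw, "ATOM  "))
  if (length(idx) == 0) stop("no ATOM records in ", path)
  rec <- lapply(idx, function(i) {
    ln <- raw[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (anyNA(xyz) || is.na(resno))
      stop("malformed ATOM record at line ", i, ": unparseable fields")
    list(atom = trimws(substr(ln, 13, 16)),
         chain = substr(ln, 22, 22), resno = resno, xyz = xyz)
  })
  atoms <- vapply(rec, `[[`, "", "atom")
  keep <- atoms %in% c("CA", "CB")
  rec <- rec[keep]; atoms <- atoms[keep]
  chains_id <- vapply(rec, `[[`, "", "chain")
  out <- lapply(unique(chains_id), function(cid) {
    rc <- rec[chains_id == cid]
    at <- atoms[chains_id == cid]
    resno <- vapply(rc, `[[`, 0L, "resno")
    ca <- rc[at == "CA"]
    ca_res <- resno[at == "CA"]
    o <- order(ca_res)
    coords <- do.call(rbind, lapply(ca[o], `[[`, "xyz"))
    colnames(coords) <- c("x", "y", "z")
    rownames(coords) <- ca_res[o]
    side <- NULL
    if (any(at == "CB")) {
      cb <- rc[at == "CB"]
      cb_res <- resno[at == "CB"]
      o2 <- order(cb_res)
      side <- do.call(rbind, lapply(cb[o2], `[[`, "xyz"))
      colnames(side) <- c("x", "y", "z")
      rownames(side) <- cb_res[o2]
    }
    new_chain_model(cid, min(ca_res), max(ca_res), coords, side)
  })
  model <- structure(list(chains = out), class = "pdb_model")
  if (length(out) == 2 &&
      out[[1]]$first_residue == out[[2]]$first_residue &&
      out[[1]]$last_residue == out[[2]]$last_residue) {
    model$segments <- clip_segments(segments, out[[1]]$first_residue,
                                    out[[1]]$last_residue)
    model$parallel <- TRUE
    model$hinge <- NULL
    class(model) <- c("dimer_model", "pdb_model")
  }
  model
}

#' Write a JSON geometry report
#'
#' @param report A `geometry_report` from [measure_geometry()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(report, path) {
  jsonlite::write_json(
    list(axial_length_A = report$axial_length_A,
         max_dimension_A = report$max_dimension_A,
         interdomain_angle_deg = report$interdomain_angle_deg),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
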