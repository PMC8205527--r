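test_that("ideal dimer geometry matches the Crick construction", {
  d <- build_ideal_dimer(31, 136)
  g <- measure_geometry(d)
  # axial length = (n residues - 1) * rise, to within the helical wobble
  expect_equal(g$axial_length_A, 105 * 1.485, tolerance = 0.005)
  expect_equal(g$interdomain_angle_deg, 180, tolerance = 1)

  # consecutive C-alpha distances in the physical range for ideal helices
  for (ch in d$chains) {
    dd <- sqrt(rowSums(diff(ch$coords)^2))
    expect_true(all(dd >= 3.6 & dd <= 4.1))
  }

  # rise recovery: projecting axis points on z recovers rise/residue to 1%
  axis_z <- (d$chains[[1]]$coords[, 3] + d$chains[[2]]$coords[, 3]) / 2
  rise <- diff(range(axis_z)) / 105
  expect_equal(rise, 1.485, tolerance = 0.01 * 1.485)

  # chains related by a 180 degree rotation about the superhelical axis
  rot <- diag(c(-1, -1, 1))
  expect_equal(unname(d$chains[[2]]$coords),
               unname(d$chains[[1]]$coords %*% rot), tolerance = 1e-12)
})

test_that("local helix axes of the two chains stay 2 * superhelical_radius apart", {
  # pure coiled-coil segment (no zinc motif in range); unwinding the
  # known supercoil rotation, a 7-residue running mean cancels the minor
  # helix exactly (two full turns at 3.5 residues/turn in that frame)
  # and lands on the local helix axis
  d <- build_ideal_dimer(35, 84)
  p <- crick_parameters()
  om0 <- -2 * pi * p$rise_per_residue / p$superhelical_pitch
  unwind <- function(m) {
    t_idx <- seq_len(nrow(m)) - 1
    cbind(cos(-om0 * t_idx) * m[, 1] - sin(-om0 * t_idx) * m[, 2],
          sin(-om0 * t_idx) * m[, 1] + cos(-om0 * t_idx) * m[, 2],
          m[, 3])
  }
  run7 <- function(m) {
    t(vapply(seq_len(nrow(m) - 6),
             function(i) colMeans(m[i:(i + 6), ]), numeric(3)))
  }
  ax_a <- run7(unwind(d$chains[[1]]$coords))
  ax_b <- run7(unwind(d$chains[[2]]$coords))
  sep <- sqrt(rowSums((ax_a - ax_b)^2))
  expect_true(all(abs(sep - 2 * 4.9) < 0.1))
})

test_that("degenerate and invalid ranges are handled", {
  d1 <- build_ideal_dimer(31, 31)
  expect_equal(nrow(d1$chains[[1]]$coords), 1)
  expect_error(build_ideal_dimer(50, 40), "range")
  expect_error(measure_geometry(d1), "segment")
})

test_that("crick parameter invariants are enforced", {
  expect_error(crick_parameters(rise_per_residue = 1.7), "rise_per_residue")
  expect_error(crick_parameters(residues_per_turn = 3.4), "residues_per_turn")
  expect_s3_class(crick_parameters(), "crick_parameters")
})

test_that("hinge insertion is exact: identity at 180, round-trip elsewhere", {
  d <- build_ideal_dimer(31, 145)
  h180 <- insert_hinge(d, 91, 180)
  expect_equal(h180$chains[[1]]$coords, d$chains[[1]]$coords,
               tolerance = 1e-12)

  for (ang in c(170, 140, 120, 110, 95)) {
    h <- insert_hinge(d, 91, ang)
    expect_equal(measure_geometry(h)$interdomain_angle_deg, ang,
                 tolerance = 1)
    # residues up to the pivot untouched
    residues <- 31:145
    sel <- residues <= 91
    expect_equal(h$chains[[2]]$coords[sel, ], d$chains[[2]]$coords[sel, ],
                 tolerance = 1e-12)
  }

  expect_error(insert_hinge(d, 31, 120), "pivot")
  expect_error(insert_hinge(d, 145, 120), "pivot")
  expect_error(insert_hinge(d, 91, 0), "angle_deg")
})

test_that("max dimension is non-increasing as the hinge closes", {
  d <- build_ideal_dimer(31, 145)
  dmax <- vapply(seq(180, 90, by = -10), function(a) {
    m <- if (a == 180) d else insert_hinge(d, 91, a)
    measure_geometry(m)$max_dimension_A
  }, 0)
  expect_true(all(diff(dmax) <= 1e-9))
  expect_lt(dmax[length(dmax)], dmax[1])
})

test_that("tetramer assembly: symmetry, ordering and extension bounds", {
  d <- build_ideal_dimer(31, 145)

  # straight dimer: cis and trans coincide exactly
  s_cis <- assemble_tetramer(d, "cis")
  s_trans <- assemble_tetramer(d, "trans")
  expect_equal(ctipcc:::model_coords(s_cis), ctipcc:::model_coords(s_trans),
               tolerance = 1e-9)

  # extension bound: Dmax(tetramer) within [2L - 2Lov, 2L]
  L <- measure_geometry(d)$max_dimension_A
  Lov <- (52 - 31) * 1.485
  g <- measure_geometry(s_cis)
  expect_gte(g$max_dimension_A, 2 * L - 2 * Lov)
  expect_lte(g$max_dimension_A, 2 * L)

  # hinged: trans extends further than cis, for a sweep of angles
  for (ang in c(170, 140, 110, 90)) {
    h <- insert_hinge(d, 91, ang)
    dm_cis <- measure_geometry(assemble_tetramer(h, "cis"))$max_dimension_A
    dm_trans <- measure_geometry(assemble_tetramer(h, "trans"))$max_dimension_A
    expect_gte(dm_trans, dm_cis)
  }

  # exact C2: the assembly maps onto itself under its own two-fold
  h <- insert_hinge(d, 91, 140)
  tt <- assemble_tetramer(h, "trans")
  pts <- ctipcc:::model_coords(tt)
  img <- ctipcc:::rotate_about(pts, tt$transform$rotation, tt$transform$centre)
  nn <- vapply(seq_len(nrow(img)), function(i)
    min(sqrt(colSums((t(pts) - img[i, ])^2))), 0)
  expect_lt(max(nn), 0.1)

  expect_error(assemble_tetramer(build_ideal_dimer(35, 145)), "overlap")
})

test_that("geometry report handles the two-point case and JSON output", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 25))
  expect_equal(ctipcc:::max_pair_distance(pts), 25)
  g <- measure_geometry(build_ideal_dimer(31, 136))
  f <- tempfile(fileext = ".json")
  write_geometry_json(g, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$axial_length_A, g$axial_length_A)
  expect_equal(back$interdomain_angle_deg, g$interdomain_angle_deg)
})

test_that("PDB round trip preserves coordinates, chains and numbering", {
  d <- insert_hinge(build_ideal_dimer(31, 145), 91, 140)
  f <- tempfile(fileext = ".pdb")
  write_pdb(d, f)
  m <- read_pdb(f)
  expect_equal(length(m$chains), 2)
  expect_equal(vapply(m$chains, function(ch) ch$chain_id, ""), c("A", "B"))
  for (k in 1:2) {
    expect_equal(chain_rng <- c(m$chains[[k]]$first_residue,
                                m$chains[[k]]$last_residue), c(31L, 145L))
    rmsd <- sqrt(mean((m$chains[[k]]$coords - d$chains[[k]]$coords)^2))
    expect_lt(rmsd, 0.001)
  }
  # 230 C-alpha ATOM records for a 2 x 115 residue model
  expect_equal(sum(startsWith(readLines(f), "ATOM ")), 230)

  # with side-chain pseudo-atoms: twice the records, flagged as CB
  ds <- build_ideal_dimer(31, 60, include_sidechains = TRUE)
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(ds, f2)
  lines <- readLines(f2)
  atom_lines <- lines[startsWith(lines, "ATOM ")]
  expect_equal(sum(substr(atom_lines, 13, 16) == " CB "), 60)
  m2 <- read_pdb(f2)
  expect_false(is.null(m2$chains[[1]]$sidechain))

  # errors: empty model, malformed record with line number
  expect_error(write_pdb(structure(list(chains = list()),
                                   class = "pdb_model"), tempfile()), "empty")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A  31      bad coords here"), bad)
  expect_error(read_pdb(bad), "line 1")
})

test_that("read_pdb re-attaches segment annotation usable downstream", {
  d <- build_ideal_dimer(31, 145)
  f <- tempfile(fileext = ".pdb")
  write_pdb(d, f)
  m <- read_pdb(f)
  g <- measure_geometry(m)
  expect_equal(g$interdomain_angle_deg, 180, tolerance = 1)
})
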