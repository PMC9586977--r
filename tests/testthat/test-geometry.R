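test_that("Kabsch superposition: identity, exact recovery, degenerate input", {
  withr::with_seed(1, P <- matrix(rnorm(36), 12, 3))
  sup <- kabsch_superpose(P, P)
  expect_equal(sup$rmsd, 0, tolerance = 1e-12)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)

  R <- random_rotation(5)
  Q <- P %*% t(R)
  Q <- sweep(Q, 2, c(3, -1, 7), `+`)
  sup2 <- kabsch_superpose(P, Q)
  expect_equal(sup2$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_superposition(Q, sup2), P, tolerance = 1e-10)
  # recovered rotation undoes the applied one
  expect_equal(sup2$rotation %*% R, diag(3), tolerance = 1e-8)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("noisy-superposition RMSD matches a numerical minimisation oracle", {
  withr::with_seed(2, {
    P <- matrix(rnorm(30), 10, 3) * 5
    Q <- P %*% t(random_rotation(3)) + matrix(rnorm(30, sd = 0.5), 10, 3)
  })
  sup <- kabsch_superpose(P, Q)
  expect_equal(sup$rmsd, numeric_min_rmsd(P, Q), tolerance = 1e-6)
  # and agrees with an established implementation
  fit <- bio3d::fit.xyz(as.numeric(t(P)), as.numeric(t(Q)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  # bio3d reports RMSD rounded to three decimals
  expect_equal(sup$rmsd, bio3d::rmsd(as.numeric(t(P)), fit), tolerance = 1e-3)
})

test_that("RMSD is symmetric and invariant under joint rigid motion", {
  withr::with_seed(3, {
    P <- matrix(rnorm(45), 15, 3) * 3
    Q <- P + matrix(rnorm(45, sd = 0.8), 15, 3)
    R <- random_rotation(11)
  })
  r1 <- kabsch_superpose(P, Q)$rmsd
  expect_equal(kabsch_superpose(Q, P)$rmsd, r1, tolerance = 1e-10)
  Pm <- sweep(P %*% t(R), 2, c(5, 5, 5), `+`)
  Qm <- sweep(Q %*% t(R), 2, c(5, 5, 5), `+`)
  expect_equal(kabsch_superpose(Pm, Qm)$rmsd, r1, tolerance = 1e-10)
})

test_that("helix axes recover generator truth, equivariantly", {
  h <- sim_ideal_helix(1)
  expect_equal(mean(sqrt(rowSums(diff(h$ca)^2))), 3.8, tolerance = 0.02)
  expect_lt(interhelix_angle(helix_axis(h$ca), c(0, 0, 1)), 1)

  R <- random_rotation(8)
  hr <- sim_ideal_helix(1, rotation = R)
  expect_lt(interhelix_angle(helix_axis(hr$ca), as.numeric(R %*% c(0, 0, 1))), 1)

  # reversing the residue order flips the orientation
  ax <- helix_axis(h$ca)
  ax_rev <- helix_axis(h$ca[nrow(h$ca):1, ])
  expect_equal(ax_rev$direction, -ax$direction, tolerance = 1e-8)

  expect_error(helix_axis(h$ca[1:4, ]), "at least 5")
})

test_that("inter-helix angles: bounds, symmetry, planted-angle recovery", {
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(interhelix_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  # unsigned convention folds antiparallel onto parallel
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, -1), signed = TRUE), 180)
  for (theta in c(10, 26, 42, 60, 85)) {
    hp <- sim_helix_pair(theta, angle = theta)
    got <- interhelix_angle(helix_axis(hp$ca_a), helix_axis(hp$ca_b))
    expect_equal(got, theta, tolerance = 1)
    expect_equal(interhelix_angle(helix_axis(hp$ca_b), helix_axis(hp$ca_a)),
                 got, tolerance = 1e-9)
  }
  # noisy helices of >= 10 residues still recover the angle within 1 degree
  hp <- sim_helix_pair(4, angle = 42, n_res = 12, jitter_sd = 0.05)
  expect_equal(interhelix_angle(helix_axis(hp$ca_a), helix_axis(hp$ca_b)),
               42, tolerance = 1)
})

test_that("superpose_modules on a structure against itself is the identity", {
  helix1 <- sim_ideal_helix(1, n_res = 10)$ca
  helix2 <- sim_ideal_helix(2, n_res = 10, rotation = rot_x_test(60 * pi / 180),
                            translation = c(12, 0, 0))$ca
  atoms <- tibble::tibble(
    chain = "A", resno = 1:20, resid = "ALA", elety = "CA", elesy = "C",
    x = c(helix1[, 1], helix2[, 1]), y = c(helix1[, 2], helix2[, 2]),
    z = c(helix1[, 3], helix2[, 3]), o = 1, b = 0)
  mod <- as_structure_model(atoms)
  res <- superpose_modules(mod, mod,
                           pairing = data.frame(resno_ref = 1:20, resno_mov = 1:20),
                           helix_map = data.frame(ref_start = c(1, 11),
                                                  ref_end = c(10, 20),
                                                  mov_start = c(1, 11),
                                                  mov_end = c(10, 20)))
  expect_equal(res$superposition$rmsd, 0, tolerance = 1e-10)
  expect_equal(res$tilts$tilt_deg, c(0, 0), tolerance = 1e-6)
})

test_that("superpose_modules recovers a planted inter-module tilt", {
  # reference: two helices; mobile: same first helix, second helix tilted 42
  # degrees more, whole structure then rigidly moved
  mk <- function(angle2) {
    h1 <- sim_ideal_helix(1, n_res = 12)$ca
    h2 <- sim_ideal_helix(2, n_res = 12,
                          rotation = rot_x_test(angle2 * pi / 180),
                          translation = c(14, 0, 0))$ca
    rbind(h1, h2)
  }
  ref_ca <- mk(0)
  mov_ca <- mk(42)
  R <- random_rotation(17)
  mov_ca <- sweep(mov_ca %*% t(R), 2, c(4, -7, 2), `+`)
  to_model <- function(ca) as_structure_model(tibble::tibble(
    chain = "A", resno = seq_len(nrow(ca)), resid = "ALA", elety = "CA",
    elesy = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3], o = 1, b = 0))
  res <- superpose_modules(
    to_model(ref_ca), to_model(mov_ca),
    pairing = data.frame(resno_ref = 1:12, resno_mov = 1:12),  # align on helix 1
    helix_map = data.frame(ref_start = 13, ref_end = 24,
                           mov_start = 13, mov_end = 24))
  expect_equal(res$superposition$rmsd, 0, tolerance = 1e-8)
  expect_equal(res$tilts$tilt_deg, 42, tolerance = 1)
})

test_that("missing pairing residues are dropped with a warning", {
  h <- sim_ideal_helix(1, n_res = 10)$ca
  mod <- as_structure_model(tibble::tibble(
    chain = "A", resno = 1:10, resid = "ALA", elety = "CA", elesy = "C",
    x = h[, 1], y = h[, 2], z = h[, 3], o = 1, b = 0))
  expect_warning(
    res <- superpose_modules(mod, mod,
                             pairing = data.frame(resno_ref = c(1:10, 99),
                                                  resno_mov = c(1:10, 99))),
    "dropped")
  expect_equal(res$n_dropped, 1)
  expect_error(
    suppressWarnings(superpose_modules(
      mod, mod, pairing = data.frame(resno_ref = 97:99, resno_mov = 97:99))),
    "fewer than 3")
})

test_that("zinc coordination: planted sites, cutoff behaviour, rigid invariance", {
  site <- sim_zn_site(1)
  zc <- zn_coordination(site$struct)
  expect_equal(nrow(zc), 4)
  expect_equal(sort(zc$resno), 1:4)
  expect_equal(zc$distance, rep(2.3, 4), tolerance = 1e-8)

  # one donor pushed past the cutoff
  far <- sim_zn_site(2, distances = c(2.3, 2.3, 2.3, 3.5))
  expect_equal(nrow(zn_coordination(far$struct)), 3)
  expect_equal(nrow(zn_coordination(far$struct, cutoff = 3.6)), 4)

  # rigid motion leaves the coordination sphere unchanged
  R <- random_rotation(4)
  atoms <- dplyr::bind_rows(site$struct$atoms, site$struct$metals)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + 10; atoms$y <- xyz[, 2] - 3; atoms$z <- xyz[, 3]
  moved <- as_structure_model(atoms)
  zc2 <- zn_coordination(moved)
  expect_equal(sort(zc2$resno), sort(zc$resno))
  expect_equal(sort(zc2$distance), sort(zc$distance), tolerance = 1e-8)

  # a structure without zinc yields an empty table, not an error
  apo <- as_structure_model(site$struct$atoms)
  expect_equal(nrow(zn_coordination(apo)), 0)
})

test_that("small donor jitter never breaks tetrahedral coordination", {
  counts <- vapply(1:100, function(seed) {
    nrow(zn_coordination(sim_zn_site(seed, jitter = 0.05)$struct))
  }, numeric(1))
  expect_true(all(counts == 4))
})

test_that("interface contacts match a brute-force all-pairs scan", {
  withr::with_seed(9, {
    mk_res <- function(resno, center, resid) tibble::tibble(
      chain = "A", resno = resno, resid = resid,
      elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
      x = center[1] + rnorm(3, sd = 0.8), y = center[2] + rnorm(3, sd = 0.8),
      z = center[3] + rnorm(3, sd = 0.8), o = 1, b = 0)
    atoms <- dplyr::bind_rows(
      purrr::map2_dfr(1:6, 1:6, ~ mk_res(.x, c(.y * 2, 0, 0), "LEU")),
      purrr::map2_dfr(11:16, 1:6, ~ mk_res(.x, c(.y * 2, 3.5, 0), "SER")))
  })
  mod <- as_structure_model(atoms)
  got <- interface_contacts(mod, c(1, 6), c(11, 16), cutoff = 4.5)
  want <- brute_force_contacts(mod, c(1, 6), c(11, 16), 4.5)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$resno_a, want$resno_a)
  expect_equal(got$resno_b, want$resno_b)
  expect_equal(got$min_distance, want$min_distance, tolerance = 1e-10)
  expect_true(all(got$hydrophobic_a))   # all LEU
  expect_false(any(got$hydrophobic_b))  # all SER

  # cutoff monotonicity: tighter cutoff gives a subset
  tight <- interface_contacts(mod, c(1, 6), c(11, 16), cutoff = 4.0)
  expect_true(all(paste(tight$resno_a, tight$resno_b) %in%
                    paste(got$resno_a, got$resno_b)))
  expect_error(interface_contacts(mod, c(1, 12), c(11, 16)), "overlap")
})

test_that("modules 30 Angstrom apart make no contacts", {
  h1 <- sim_ideal_helix(1, n_res = 8)$ca
  h2 <- sim_ideal_helix(2, n_res = 8, translation = c(30, 0, 0))$ca
  mod <- as_structure_model(tibble::tibble(
    chain = "A", resno = c(1:8, 21:28), resid = "LEU", elety = "CA",
    elesy = "C", x = c(h1[, 1], h2[, 1]), y = c(h1[, 2], h2[, 2]),
    z = c(h1[, 3], h2[, 3]), o = 1, b = 0))
  expect_equal(nrow(interface_contacts(mod, c(1, 8), c(21, 28))), 0)
})

test_that("structures survive a PDB write/read round trip", {
  site <- sim_zn_site(3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(site$struct, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), 4)
  expect_equal(nrow(back$metals), 1)
  zc <- zn_coordination(back)
  expect_equal(nrow(zc), 4)
  expect_equal(zc$distance, zn_coordination(site$struct)$distance,
               tolerance = 1e-2)  # PDB coordinates carry 3 decimals
  expect_error(read_structure("/nonexistent/file.pdb"), "no such file")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("1", bad)
  expect_error(read_structure(bad), "format")
})
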