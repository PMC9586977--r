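# background alphabets for sequence generation: the default excludes every
# letter that could form a spurious anchor or Zn ligand (C, H, R, G, S, T and
# the aromatics), so planted-truth recovery is exact; the realistic
# background re-enables them for stress tests.
.bg_safe <- c("A", "D", "E", "I", "K", "L", "M", "N", "P", "Q", "V")

#' Generate a module sequence with a planted zinc finger and anchors
#'
#' Builds an amino-acid sequence containing one BIR-like module at known
#' positions: the `Rxx(S/T)W` anchor, the `GW` turn dipeptide, the CCHC
#' zinc finger with requested spacers, and a final aromatic two residues
#' after the last cysteine. Background residues are drawn uniformly from an
#' alphabet that excludes anchor-forming letters, so the scan recovers
#' exactly the planted positions; set `realistic_background = TRUE` to draw
#' from all 20 letters instead.
#'
#' @param seed Integer seed (mandatory).
#' @param family `"zf_C3HC"`, `"Rsm1"` or `"canonical_BIR"`; sets default
#'   spacers and the arginine-to-glycine distance (the Rsm1 module gets the
#'   long inter-anchor insertion).
#' @param spacers Length-3 integer vector `(c1_c2, c2_h, h_c3)`; defaults
#'   per family.
#' @param anchors_present Named logical flags `r`, `st`, `g`, `final`;
#'   absent anchors are replaced by background residues.
#' @param r_to_g Distance from the arginine to the glycine anchor (default
#'   29 for zf-C3HC/canonical, 54 for Rsm1).
#' @param g_to_c1 Distance from the glycine to the first cysteine.
#' @param lead,tail Background padding before the arginine and after the
#'   final aromatic.
#' @param length Optional total sequence length (padded with background;
#'   error if shorter than the planted architecture).
#' @param realistic_background Draw background from all 20 amino acids.
#' @return A list: `sequence` (string) and `truth` (one-row tibble of all
#'   planted indices, the family, and the seed).
#' @export
sim_module_sequence <- function(seed, family = "zf_C3HC", spacers = NULL,
                                anchors_present = list(r = TRUE, st = TRUE,
                                                       g = TRUE, final = TRUE),
                                r_to_g = NULL, g_to_c1 = 16,
                                lead = 10, tail = 10, length = NULL,
                                realistic_background = FALSE) {
  stopifnot(is.numeric(seed), family %in% c("zf_C3HC", "Rsm1", "canonical_BIR"))
  spacers <- spacers %||% switch(family,
    zf_C3HC = c(2L, 34L, 3L), Rsm1 = c(2L, 16L, 3L),
    canonical_BIR = c(2L, 16L, 6L))
  r_to_g <- r_to_g %||% if (family == "Rsm1") 54L else 29L
  if (r_to_g < 5 || g_to_c1 < 2) {
    stop("anchor layout too tight: need r_to_g >= 5 and g_to_c1 >= 2",
         call. = FALSE)
  }
  r_pos <- lead + 1L
  g_pos <- r_pos + as.integer(r_to_g)
  c1 <- g_pos + as.integer(g_to_c1)
  c2 <- c1 + spacers[1] + 1L
  h <- c2 + spacers[2] + 1L
  c3 <- h + spacers[3] + 1L
  omega_f <- c3 + 2L
  total <- omega_f + as.integer(tail)
  if (!is.null(length)) {
    if (length < total) {
      stop("length ", length, " too short for the planted architecture (needs ",
           total, ")", call. = FALSE)
    }
    total <- as.integer(length)
  }
  bg <- if (realistic_background) .aa_alphabet else .bg_safe
  chars <- withr::with_seed(as.integer(seed),
                            sample(bg, total, replace = TRUE))
  put <- function(pos, res) { chars[pos] <<- res; pos }
  ap <- anchors_present
  truth <- tibble::tibble(
    family = family, seed = as.integer(seed),
    r_pos = if (isTRUE(ap$r)) put(r_pos, "R") else NA_integer_,
    st_pos = if (isTRUE(ap$st)) put(r_pos + 3L, "S") else NA_integer_,
    omega_a_pos = if (isTRUE(ap$r)) put(r_pos + 4L, "W") else NA_integer_,
    g_pos = if (isTRUE(ap$g)) put(g_pos, "G") else NA_integer_,
    omega_g_pos = if (isTRUE(ap$g)) put(g_pos + 1L, "W") else NA_integer_,
    c1 = put(c1, "C"), c2 = put(c2, "C"), h = put(h, "H"), c3 = put(c3, "C"),
    final_omega_pos = if (isTRUE(ap$final)) put(omega_f, "W") else NA_integer_
  )
  list(sequence = paste(chars, collapse = ""), truth = truth)
}

#' Generate a tandem zf-C3HC + Rsm1 sequence
#'
#' Concatenates a planted zf-C3HC module, a background linker, and a planted
#' Rsm1 module -- the tandem architecture of the Pml39 fold -- with the
#' combined ground truth.
#'
#' @inheritParams sim_module_sequence
#' @param linker Length of the background linker between the modules.
#' @param order `"zf_rsm1"` (the native order) or `"rsm1_zf"` (reversed
#'   negative control).
#' @return A list: `sequence` and `truth` (two-row tibble, one per module,
#'   indices in whole-sequence coordinates).
#' @export
sim_tandem_sequence <- function(seed, linker = 30, order = c("zf_rsm1", "rsm1_zf"),
                                realistic_background = FALSE) {
  order <- match.arg(order)
  fams <- if (order == "zf_rsm1") c("zf_C3HC", "Rsm1") else c("Rsm1", "zf_C3HC")
  m1 <- sim_module_sequence(seed, fams[1], tail = 2,
                            realistic_background = realistic_background)
  m2 <- sim_module_sequence(seed + 1L, fams[2], lead = 8,
                            realistic_background = realistic_background)
  link <- withr::with_seed(as.integer(seed) + 2L, paste(
    sample(if (realistic_background) .aa_alphabet else .bg_safe,
           linker, replace = TRUE), collapse = ""))
  offset <- nchar(m1$sequence) + nchar(link)
  t2 <- m2$truth
  idx_cols <- c("r_pos", "st_pos", "omega_a_pos", "g_pos", "omega_g_pos",
                "c1", "c2", "h", "c3", "final_omega_pos")
  t2[idx_cols] <- lapply(t2[idx_cols], function(v) v + as.integer(offset))
  list(sequence = paste0(m1$sequence, link, m2$sequence),
       truth = dplyr::bind_rows(m1$truth, t2))
}

#' Generate an ideal alpha-helix C-alpha trace
#'
#' Canonical helical parametrisation (default rise 1.5 Angstrom per residue,
#' radius 2.3 Angstrom, twist 100 degrees per residue) along +z, optionally
#' moved by a rigid frame and perturbed by isotropic Gaussian jitter. The
#' true axis is the frame-rotated z direction.
#'
#' @param seed Integer seed (used for jitter).
#' @param n_res Number of residues (>= 5).
#' @param rise,radius,twist Helical parameters (Angstrom, Angstrom,
#'   degrees/residue).
#' @param rotation 3 x 3 rotation applied to the helix.
#' @param translation Length-3 offset.
#' @param jitter_sd Isotropic coordinate noise, Angstrom.
#' @return A list: `ca` (n x 3 matrix) and `truth` (list with `axis`,
#'   `seed`, the parameters).
#' @export
sim_ideal_helix <- function(seed, n_res = 12, rise = 1.5, radius = 2.3,
                            twist = 100, rotation = diag(3),
                            translation = c(0, 0, 0), jitter_sd = 0) {
  stopifnot(n_res >= 5)
  t <- seq_len(n_res) - 1
  ang <- twist * pi / 180 * t
  ca <- cbind(radius * cos(ang), radius * sin(ang), rise * t)
  if (jitter_sd > 0) {
    ca <- ca + withr::with_seed(as.integer(seed),
                                matrix(stats::rnorm(3 * n_res, sd = jitter_sd),
                                       ncol = 3))
  }
  ca <- sweep(ca %*% t(rotation), 2, translation, `+`)
  list(ca = ca,
       truth = list(axis = as.numeric(rotation %*% c(0, 0, 1)),
                    seed = as.integer(seed), n_res = n_res, rise = rise,
                    radius = radius, twist = twist))
}

#' Generate a pair of helices at a known mutual angle
#'
#' The first helix runs along +z; the second is rotated about the x axis by
#' `angle` degrees and displaced laterally.
#'
#' @inheritParams sim_ideal_helix
#' @param angle Planted inter-axis angle, degrees.
#' @param offset Lateral displacement of the second helix.
#' @return A list: `ca_a`, `ca_b`, `truth` (list with `angle`, axes, seed).
#' @export
sim_helix_pair <- function(seed, angle, n_res = 12, offset = c(15, 0, 0),
                           jitter_sd = 0) {
  rot <- .rot_x(angle * pi / 180)
  a <- sim_ideal_helix(seed, n_res = n_res, jitter_sd = jitter_sd)
  b <- sim_ideal_helix(seed + 1L, n_res = n_res, rotation = rot,
                       translation = offset, jitter_sd = jitter_sd)
  list(ca_a = a$ca, ca_b = b$ca,
       truth = list(angle = angle, axis_a = a$truth$axis, axis_b = b$truth$axis,
                    seed = as.integer(seed)))
}

.rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}

#' A uniformly random proper rotation matrix
#'
#' @param seed Integer seed.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed) {
  M <- withr::with_seed(as.integer(seed), matrix(stats::rnorm(9), 3, 3))
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Generate a synthetic tetrahedral zinc site
#'
#' A Zn atom at the origin with four cysteine S-gamma donors placed on
#' tetrahedral vertices at the requested distances, plus optional Gaussian
#' positional jitter.
#'
#' @param seed Integer seed.
#' @param distances Length-4 vector of Zn-donor distances, Angstrom.
#' @param jitter Isotropic positional noise on the donors, Angstrom.
#' @param center Zn position.
#' @return A list: `struct` (a `structure_model` with 4 Cys S-gamma atoms
#'   and 1 Zn) and `truth` (planted distances, ligand residue numbers 1--4,
#'   seed).
#' @export
sim_zn_site <- function(seed, distances = rep(2.3, 4), jitter = 0,
                        center = c(0, 0, 0)) {
  stopifnot(length(distances) == 4)
  dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3,
                 byrow = TRUE) / sqrt(3)
  xyz <- dirs * distances
  if (jitter > 0) {
    xyz <- xyz + withr::with_seed(as.integer(seed),
                                  matrix(stats::rnorm(12, sd = jitter), 4, 3))
  }
  xyz <- sweep(xyz, 2, center, `+`)
  atoms <- tibble::tibble(
    chain = "A", resno = c(1:4, 101L),
    resid = c(rep("CYS", 4), "ZN"),
    elety = c(rep("SG", 4), "ZN"),
    elesy = c(rep("S", 4), "ZN"),
    x = c(xyz[, 1], center[1]), y = c(xyz[, 2], center[2]),
    z = c(xyz[, 3], center[3]), o = 1, b = 0
  )
  list(struct = as_structure_model(atoms),
       truth = list(distances = distances, ligand_resno = 1:4,
                    seed = as.integer(seed)))
}

#' Generate a synthetic SEC-MALS trace
#'
#' Gaussian elution peaks of species with known molecular weight; the
#' excess Rayleigh ratio of each slice/angle is `K c M` (no angular
#' dependence, appropriate for small proteins) with optional multiplicative
#' Gaussian noise.
#'
#' @param seed Integer seed.
#' @param species List of species, each a list with `mw` (g/mol), `center`
#'   and `width` (s), `cmax` (peak concentration, g/mL).
#' @param angles Detector angles in degrees (default 18 angles from 30 to
#'   150).
#' @param k Optical constant.
#' @param noise Multiplicative noise level on the Rayleigh ratios (fraction).
#' @param dt Slice interval, s.
#' @return A list: `slices` (long tibble for [debye_mw()]), `peaks`
#'   (suggested peak windows, center +/- 2 widths), `truth` (species table
#'   and seed).
#' @export
sim_mals <- function(seed, species, angles = seq(30, 150, length.out = 18),
                     k = 1e-7, noise = 0, dt = 1) {
  stopifnot(length(angles) >= 2, length(species) >= 1)
  sp <- purrr::map_dfr(species, tibble::as_tibble)
  times <- seq(floor(min(sp$center - 3 * sp$width)),
               ceiling(max(sp$center + 3 * sp$width)), by = dt)
  grid <- tidyr::expand_grid(time = times, angle = angles)
  conc_of <- function(tm, s) s$cmax * exp(-(tm - s$center)^2 / (2 * s$width^2))
  conc <- rowSums(sapply(seq_len(nrow(sp)), function(i) conc_of(grid$time, sp[i, ])))
  cm <- rowSums(sapply(seq_len(nrow(sp)),
                       function(i) conc_of(grid$time, sp[i, ]) * sp$mw[i]))
  rtheta <- k * cm
  if (noise > 0) {
    rtheta <- rtheta * (1 + withr::with_seed(
      as.integer(seed), stats::rnorm(length(rtheta), sd = noise)))
  }
  slices <- tibble::tibble(time = grid$time, conc = conc, angle = grid$angle,
                           rtheta = rtheta, k = k)
  peaks <- tibble::tibble(peak = seq_len(nrow(sp)),
                          start = sp$center - 2 * sp$width,
                          end = sp$center + 2 * sp$width)
  list(slices = slices, peaks = peaks,
       truth = list(species = sp, seed = as.integer(seed), noise = noise))
}
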