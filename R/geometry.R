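#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the
#' root-mean-square deviation between two paired coordinate sets, via
#' singular value decomposition of the cross-covariance matrix with the
#' standard reflection correction. The transform maps `Q` onto `P`:
#' `q_aligned = q %*% t(rotation) + translation` (points as rows).
#'
#' @param P,Q Numeric n x 3 matrices of paired coordinates (n >= 3, equal
#'   dimensions, neither set collinear).
#' @return A list of class `superposition`: `rotation` (3 x 3, determinant
#'   +1), `translation` (length 3), `rmsd` (Angstrom), `n_pairs`.
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' kabsch_superpose(P, P)$rmsd  # 0
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3) {
    stop("P and Q must be n x 3 matrices of equal size", call. = FALSE)
  }
  n <- nrow(P)
  if (n < 3) stop("at least 3 point pairs are required", call. = FALSE)
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  if (.collinear(P0) || .collinear(Q0)) {
    stop("degenerate (collinear) coordinate set", call. = FALSE)
  }
  H <- crossprod(Q0, P0)  # sum over i of q_i p_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((P0 - aligned)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(pc - R %*% qc),
                 rmsd = rmsd, n_pairs = n),
            class = "superposition")
}

.collinear <- function(X0, tol = 1e-8) {
  s <- svd(X0, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition of %d atom pairs: RMSD %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param sup A `superposition` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' Helix axis from ordered C-alpha coordinates
#'
#' For each interior residue the bisector
#' `H_i = (P_(i-1) - P_i) + (P_(i+1) - P_i)` points radially toward the
#' helix axis; the cross product of consecutive bisectors is parallel to the
#' axis, exactly so for an ideal helix of any length. The direction is the
#' normalised average of these cross products (falling back to the principal
#' inertial axis for degenerate, nearly straight traces), with its sign
#' chosen so that the axis points from the N- to the C-terminal end
#' (positive projection of last minus first residue). Unlike the raw
#' principal axis of inertia, this estimate is free of the partial-turn bias
#' that tilts the inertia axis of short (5--16 residue) helices by a few
#' degrees.
#'
#' @param ca Ordered n x 3 matrix of consecutive C-alpha coordinates,
#'   n >= 5.
#' @return A list of class `helix_axis`: `direction` (unit 3-vector),
#'   `centroid`, `n_res`.
#' @export
helix_axis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 5) stop("a helix axis needs at least 5 residues", call. = FALSE)
  centroid <- colMeans(ca)
  bis <- ca[1:(n - 2), ] - 2 * ca[2:(n - 1), ] + ca[3:n, ]
  axes <- .cross(bis[1:(nrow(bis) - 1), , drop = FALSE],
                 bis[2:nrow(bis), , drop = FALSE])
  nrm <- sqrt(rowSums(axes^2))
  ok <- nrm > 1e-8
  if (any(ok)) {
    # orient each estimate consistently before averaging
    u <- axes[ok, , drop = FALSE] / nrm[ok]
    ref <- u[1, ]
    flip <- as.numeric(u %*% ref) < 0
    u[flip, ] <- -u[flip, ]
    v <- colMeans(u)
  } else {
    # nearly straight trace: use the principal inertial axis
    v <- svd(sweep(ca, 2, centroid), nu = 0)$v[, 1]
  }
  if (sum(v * (ca[n, ] - ca[1, ])) < 0) v <- -v
  structure(list(direction = v / sqrt(sum(v^2)),
                 centroid = centroid, n_res = n),
            class = "helix_axis")
}

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Angle between two helix axes
#'
#' By default the unsigned inter-helix (tilt) angle
#' `arccos(|a . b|)` in `[0, 90]` degrees; with `signed = TRUE` the oriented
#' angle `arccos(a . b)` in `[0, 180]` degrees, which distinguishes parallel
#' from antiparallel packing.
#'
#' @param a,b `helix_axis` objects (or unit 3-vectors).
#' @param signed Use the oriented convention.
#' @return Angle in degrees.
#' @export
interhelix_angle <- function(a, b, signed = FALSE) {
  va <- if (inherits(a, "helix_axis")) a$direction else a / sqrt(sum(a^2))
  vb <- if (inherits(b, "helix_axis")) b$direction else b / sqrt(sum(b^2))
  d <- sum(va * vb)
  d <- max(-1, min(1, d))
  if (!signed) d <- abs(d)
  acos(d) * 180 / pi
}

#' Superpose one structure onto another and measure helix tilts
#'
#' Superposes structure `mov` onto structure `ref` using an explicit
#' C-alpha residue pairing (the pairing is an input so that alternative
#' structure-guided alignments can be compared), then computes helix axes in
#' the common frame and reports the tilt angle for each requested helix
#' pair. Pairs whose C-alpha is missing in either structure are dropped with
#' a warning.
#'
#' @param ref,mov `structure_model` objects.
#' @param pairing Data frame with columns `resno_ref` and `resno_mov`
#'   (author residue numbers of paired C-alpha atoms).
#' @param helix_map Optional data frame with columns `ref_start`, `ref_end`,
#'   `mov_start`, `mov_end` (one row per helix pair) and optionally `name`.
#' @param chain_ref,chain_mov Chain identifiers (default: first chain).
#' @param signed Tilt-angle convention, see [interhelix_angle()].
#' @return A list: `superposition` (see [kabsch_superpose()]), `tilts` (a
#'   tibble with one row per helix pair: `name`, spans, `tilt_deg`), and
#'   `n_dropped` pairs.
#' @export
superpose_modules <- function(ref, mov, pairing, helix_map = NULL,
                              chain_ref = NULL, chain_mov = NULL,
                              signed = FALSE) {
  stopifnot(all(c("resno_ref", "resno_mov") %in% names(pairing)))
  ca_ref <- ca_coords(ref, chain = chain_ref)
  ca_mov <- ca_coords(mov, chain = chain_mov)
  i <- match(as.character(pairing$resno_ref), rownames(ca_ref))
  j <- match(as.character(pairing$resno_mov), rownames(ca_mov))
  ok <- !is.na(i) & !is.na(j)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(n_dropped, " residue pair(s) dropped: C-alpha missing")
  }
  if (sum(ok) < 3) stop("fewer than 3 surviving C-alpha pairs", call. = FALSE)
  sup <- kabsch_superpose(ca_ref[i[ok], , drop = FALSE],
                          ca_mov[j[ok], , drop = FALSE])

  tilts <- NULL
  if (!is.null(helix_map) && nrow(helix_map) > 0) {
    tilts <- purrr::map_dfr(seq_len(nrow(helix_map)), function(k) {
      hm <- helix_map[k, ]
      ax_ref <- helix_axis(ca_coords(ref, c(hm$ref_start, hm$ref_end), chain_ref))
      mov_ca <- ca_coords(mov, c(hm$mov_start, hm$mov_end), chain_mov)
      ax_mov <- helix_axis(apply_superposition(mov_ca, sup))
      tibble::tibble(
        name = if ("name" %in% names(hm)) hm$name else paste0("helix_", k),
        ref_start = hm$ref_start, ref_end = hm$ref_end,
        mov_start = hm$mov_start, mov_end = hm$mov_end,
        tilt_deg = interhelix_angle(ax_ref, ax_mov, signed = signed)
      )
    })
  }
  list(superposition = sup, tilts = tilts, n_dropped = n_dropped)
}

#' Zinc coordination spheres of a structure
#'
#' For every Zn atom, lists the protein donor atoms (by default cysteine
#' S-gamma and histidine N-delta1/N-epsilon2) within the coordination
#' cutoff, sorted by distance. The ligand count is reported as found, even
#' when it differs from the tetrahedral 4.
#'
#' @param struct A `structure_model`.
#' @param cutoff Coordination distance cutoff in Angstrom (default 2.8, a
#'   typical upper bound for Zn-S/N bonds).
#' @param donor_atoms Atom names accepted as donors.
#' @return A tibble with one row per Zn-ligand pair: `site` (Zn index),
#'   `zn_x`, `zn_y`, `zn_z`, `chain`, `resno`, `resid`, `donor_atom`,
#'   `distance`. Zero rows when the structure has no Zn.
#' @export
zn_coordination <- function(struct, cutoff = 2.8,
                            donor_atoms = c("SG", "ND1", "NE2")) {
  zn <- dplyr::filter(struct$metals, toupper(.data$elesy) == "ZN")
  if (nrow(zn) == 0) return(tibble::tibble(
    site = integer(0), zn_x = numeric(0), zn_y = numeric(0), zn_z = numeric(0),
    chain = character(0), resno = integer(0), resid = character(0),
    donor_atom = character(0), distance = numeric(0)))
  donors <- dplyr::filter(struct$atoms, .data$elety %in% donor_atoms)
  purrr::map_dfr(seq_len(nrow(zn)), function(k) {
    dz <- sqrt((donors$x - zn$x[k])^2 + (donors$y - zn$y[k])^2 +
                 (donors$z - zn$z[k])^2)
    sel <- which(dz <= cutoff)
    sel <- sel[order(dz[sel])]
    tibble::tibble(site = k, zn_x = zn$x[k], zn_y = zn$y[k], zn_z = zn$z[k],
                   chain = donors$chain[sel], resno = donors$resno[sel],
                   resid = donors$resid[sel], donor_atom = donors$elety[sel],
                   distance = dz[sel])
  })
}

.hydrophobic_set <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "TYR", "PRO")

#' Inter-module residue contacts
#'
#' All residue pairs between two disjoint residue spans whose minimum
#' heavy-atom distance is at most `cutoff`, with a hydrophobicity flag per
#' residue (fixed set: A, V, L, I, M, F, W, Y, P).
#'
#' @param struct A `structure_model`.
#' @param span_a,span_b Length-2 inclusive residue-number ranges; must not
#'   overlap.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param chain Chain identifier (default: first chain).
#' @return A tibble: `resno_a`, `resid_a`, `hydrophobic_a`, `resno_b`,
#'   `resid_b`, `hydrophobic_b`, `min_distance`.
#' @export
interface_contacts <- function(struct, span_a, span_b, cutoff = 4.5,
                               chain = NULL) {
  if (span_a[1] <= span_b[2] && span_a[2] >= span_b[1]) {
    stop("spans overlap: contacts require disjoint modules", call. = FALSE)
  }
  a <- struct$atoms
  chain <- chain %||% a$chain[1]
  a <- dplyr::filter(a, .data$chain == !!chain)
  A <- dplyr::filter(a, .data$resno >= span_a[1], .data$resno <= span_a[2])
  B <- dplyr::filter(a, .data$resno >= span_b[1], .data$resno <= span_b[2])
  if (nrow(A) == 0 || nrow(B) == 0) return(.empty_contacts())
  d2 <- outer(A$x, B$x, `-`)^2 + outer(A$y, B$y, `-`)^2 + outer(A$z, B$z, `-`)^2
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(.empty_contacts())
  pairs <- tibble::tibble(
    resno_a = A$resno[hit[, 1]], resid_a = A$resid[hit[, 1]],
    resno_b = B$resno[hit[, 2]], resid_b = B$resid[hit[, 2]],
    distance = sqrt(d2[hit])
  )
  pairs |>
    dplyr::group_by(.data$resno_a, .data$resid_a, .data$resno_b, .data$resid_b) |>
    dplyr::summarise(min_distance = min(.data$distance), .groups = "drop") |>
    dplyr::mutate(hydrophobic_a = .data$resid_a %in% .hydrophobic_set,
                  hydrophobic_b = .data$resid_b %in% .hydrophobic_set) |>
    dplyr::select("resno_a", "resid_a", "hydrophobic_a",
                  "resno_b", "resid_b", "hydrophobic_b", "min_distance") |>
    dplyr::arrange(.data$resno_a, .data$resno_b)
}

.empty_contacts <- function() {
  tibble::tibble(resno_a = integer(0), resid_a = character(0),
                 hydrophobic_a = logical(0), resno_b = integer(0),
                 resid_b = character(0), hydrophobic_b = logical(0),
                 min_distance = numeric(0))
}
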