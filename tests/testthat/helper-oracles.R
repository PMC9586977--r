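# Independent reference implementations used as oracles. These deliberately
# use naive exhaustive or root-finding strategies, not the package's own
# code paths.

# exhaustive enumeration of all CCHC quadruples satisfying a grammar
brute_force_scan <- function(sequence, grammar) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  cpos <- which(chars == "C")
  hpos <- which(chars == "H")
  hits <- list()
  for (c1 in cpos) for (c2 in cpos) for (h in hpos) {
    if (!(c1 < c2 && c2 < h)) next
    c3 <- h + grammar$h_c3 + 1L
    if (c3 > length(chars) || chars[c3] != "C") next
    s1 <- c2 - c1 - 1L; s2 <- h - c2 - 1L
    if (s1 >= grammar$c1_c2_min && s1 <= grammar$c1_c2_max &&
        s2 >= grammar$c2_h_min && s2 <= grammar$c2_h_max) {
      hits[[length(hits) + 1]] <- c(c1, c2, h, c3)
    }
  }
  if (length(hits) == 0) return(matrix(integer(0), ncol = 4))
  m <- do.call(rbind, hits)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# plant letters at given positions in a background of 'A'
planted_sequence <- function(length, positions, letters) {
  chars <- rep("A", length)
  chars[positions] <- letters
  paste(chars, collapse = "")
}

# numeric RMSD minimisation over rotations (Euler angles), translation
# removed by centering: an independent check on the closed-form Kabsch fit
numeric_min_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((P0 - Q0 %*% t(rot(a)))^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, pi / 2),
                     c(pi, pi / 4, -pi / 2), c(-pi / 2, pi / 3, pi))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# 1:1 equilibrium by root-finding on the free-ligand mass balance
oracle_bound <- function(sites, xt, kd) {
  if (xt == 0 || sites == 0) return(0)
  f <- function(xf) xf + sites * xf / (kd + xf) - xt
  xf <- stats::uniroot(f, c(0, xt), tol = 1e-18)$root
  sites * xf / (kd + xf)
}

# per-injection heats using the same displacement bookkeeping but the
# root-finding equilibrium solver
oracle_isotherm <- function(n, kd, dh, protocol) {
  v0 <- protocol$cell_volume
  mt <- protocol$cell_conc; xt <- 0; bound <- 0
  heats <- numeric(length(protocol$injection_volumes))
  for (i in seq_along(protocol$injection_volumes)) {
    v <- protocol$injection_volumes[i]
    xt <- (xt * v0 + protocol$syringe_conc * v) / (v0 + v)
    mt <- mt * v0 / (v0 + v)
    bound_diluted <- bound * v0 / (v0 + v)
    bound <- oracle_bound(n * mt, xt, kd)
    heats[i] <- dh * 1e9 * v0 * (bound - bound_diluted)
  }
  heats
}

# all-pairs residue contact scan over data frames of atoms
brute_force_contacts <- function(struct, span_a, span_b, cutoff) {
  a <- struct$atoms
  A <- a[a$resno >= span_a[1] & a$resno <= span_a[2], ]
  B <- a[a$resno >= span_b[1] & a$resno <= span_b[2], ]
  out <- NULL
  for (ra in unique(A$resno)) for (rb in unique(B$resno)) {
    xa <- A[A$resno == ra, c("x", "y", "z")]
    xb <- B[B$resno == rb, c("x", "y", "z")]
    dmin <- Inf
    for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
      dmin <- min(dmin, sqrt(sum((xa[i, ] - xb[j, ])^2)))
    }
    if (dmin <= cutoff) out <- rbind(out, data.frame(resno_a = ra, resno_b = rb,
                                                     min_distance = dmin))
  }
  out
}

# random amino-acid sequence over the full alphabet
random_sequence <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# rotation about the x axis by theta radians
rot_x_test <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}
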