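#' Molecular weight from multi-angle light scattering (Debye plot)
#'
#' For each elution slice, fits the Debye plot `K c / R(theta)` against
#' `sin^2(theta/2)` by ordinary least squares; in the dilute limit (second
#' virial coefficient neglected) the intercept is `1/M`, so the slice
#' molecular weight is the reciprocal intercept. The peak molecular weight
#' is the concentration-weighted average over the slices in each peak
#' window. Slices with a non-positive intercept are flagged and excluded
#' from the average.
#'
#' @param slices Long-format tibble with columns `time` (s), `conc` (g/mL),
#'   `angle` (degrees), `rtheta` (excess Rayleigh ratio) and `k` (optical
#'   constant, instrument calibration and dn/dc folded in); at least two
#'   distinct angles per slice.
#' @param peaks Optional tibble with columns `peak`, `start`, `end` (time
#'   window per peak). Default: one peak spanning all slices with positive
#'   concentration.
#' @return An object of class `debye_fit`: `slices` (tibble: `time`, `conc`,
#'   `intercept`, `slope`, `mw`, `excluded`), `peaks` (tibble: `peak`,
#'   `start`, `end`, `n_slices`, `mw` in g/mol).
#' @examples
#' s <- sim_mals(seed = 1, species = list(list(mw = 8e4, center = 100,
#'                                             width = 5, cmax = 1e-4)))
#' debye_mw(s$slices)$peaks$mw  # 80000
#' @export
debye_mw <- function(slices, peaks = NULL) {
  stopifnot(all(c("time", "conc", "angle", "rtheta", "k") %in% names(slices)))
  per_slice <- slices |>
    dplyr::filter(.data$conc > 0) |>
    dplyr::group_by(.data$time, .data$conc) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$angle) < 2) {
        stop("each slice needs at least 2 distinct angles", call. = FALSE)
      }
      x <- sin(d$angle * pi / 360)^2  # sin^2(theta / 2)
      y <- d$k * key$conc / d$rtheta
      co <- stats::coef(stats::lm(y ~ x))
      tibble::tibble(intercept = co[1], slope = co[2])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(mw = ifelse(.data$intercept > 0, 1 / .data$intercept, NA_real_),
                  excluded = .data$intercept <= 0)

  if (is.null(peaks)) {
    peaks <- tibble::tibble(peak = 1L, start = min(per_slice$time),
                            end = max(per_slice$time))
  }
  peak_mw <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    w <- dplyr::filter(per_slice, .data$time >= peaks$start[i],
                       .data$time <= peaks$end[i], !.data$excluded)
    tibble::tibble(peak = peaks$peak[i], start = peaks$start[i],
                   end = peaks$end[i], n_slices = nrow(w),
                   mw = sum(w$conc * w$mw) / sum(w$conc))
  })
  structure(list(slices = per_slice, peaks = peak_mw), class = "debye_fit")
}

#' @export
print.debye_fit <- function(x, ...) {
  cat("Debye-plot molecular weights (", nrow(x$slices), " slices):\n", sep = "")
  for (i in seq_len(nrow(x$peaks))) {
    cat(sprintf("  peak %s [%g, %g]: %.1f kDa over %d slices\n",
                x$peaks$peak[i], x$peaks$start[i], x$peaks$end[i],
                x$peaks$mw[i] / 1000, x$peaks$n_slices[i]))
  }
  invisible(x)
}

#' @rdname tidy.itc_fit
#' @method tidy debye_fit
#' @export
tidy.debye_fit <- function(x, ...) x$slices

#' @rdname tidy.itc_fit
#' @method glance debye_fit
#' @export
glance.debye_fit <- function(x, ...) x$peaks

#' Call the oligomeric state from a measured molecular weight
#'
#' Compares a measured (e.g. SEC-MALS) molecular weight with the sequence
#' monomer weight: the call is the nearest integer ratio if the relative
#' deviation is within tolerance, otherwise `NA` (ambiguous). A dimer, for
#' instance, is called when an ~80 kDa species is measured for a 41 kDa
#' monomer.
#'
#' @param measured_mw,monomer_mw Molecular weights, g/mol (both > 0).
#' @param tolerance Maximum relative deviation from an integer ratio
#'   (default 0.15).
#' @return Integer oligomeric state, or `NA` when ambiguous.
#' @examples
#' oligomeric_state(80e3, 41e3)  # 2
#' @export
oligomeric_state <- function(measured_mw, monomer_mw, tolerance = 0.15) {
  stopifnot(measured_mw > 0, monomer_mw > 0)
  ratio <- measured_mw / monomer_mw
  k <- round(ratio)
  if (k >= 1 && abs(ratio - k) / k <= tolerance) as.integer(k) else NA_integer_
}
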