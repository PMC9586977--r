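# gas constant used throughout the thermodynamic identities, cal/(mol K)
.R_GAS <- 1.99

#' Describe an ITC titration protocol
#'
#' Instrument geometry and conditions of an isothermal titration calorimetry
#' experiment. Defaults reproduce a standard auto-iTC200 protocol: 2 uL
#' injections of 1.6 mM titrant into a 350 uL cell containing 70 uM of the
#' binding species, at 4 degrees C (277.15 K). Twenty injections reach a
#' final molar ratio of about 2.6, well past saturation for a low-micromolar
#' dissociation constant.
#'
#' @param cell_conc Cell (binding-site species) concentration, molar.
#' @param syringe_conc Syringe (titrant) concentration, molar.
#' @param cell_volume Active cell volume, litres.
#' @param injection_volumes Vector of injection volumes, litres.
#' @param temperature Kelvin.
#' @return A list of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_conc = 70e-6, syringe_conc = 1.6e-3,
                         cell_volume = 350e-6,
                         injection_volumes = rep(2e-6, 20),
                         temperature = 277.15) {
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0,
            all(injection_volumes > 0), temperature > 0)
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume,
                 injection_volumes = injection_volumes,
                 temperature = temperature),
            class = "itc_protocol")
}

#' Predict single-site ITC injection heats
#'
#' Exact 1:1 mass-action model of a titration in a perfusion-type cell: each
#' injection first displaces an equal volume of the instantaneously mixed
#' cell content (so the active volume stays constant and the displaced
#' aliquot leaves the cell), then the cell re-equilibrates. The bound
#' concentration after each injection is the closed-form root of the binding
#' quadratic with site concentration `n * [cell species]`, and the measured
#' heat of injection i is the enthalpy times the change in moles of complex
#' inside the active volume.
#'
#' @param n Stoichiometry (sites per cell-species molecule).
#' @param kd Dissociation constant, molar.
#' @param dh Binding enthalpy, kcal/mol.
#' @param protocol An [itc_protocol()].
#' @param dilution_heat Constant heat offset per injection, ucal (default 0).
#' @return A tibble with one row per injection: `injection`, `volume` (L),
#'   `molar_ratio` (total titrant over total cell species in the cell),
#'   `xt`, `mt`, `bound` (molar, in-cell totals after the injection),
#'   `displaced_x`, `displaced_m` (cumulative displaced moles), and `heat`
#'   (ucal).
#' @export
predict_isotherm <- function(n, kd, dh, protocol = itc_protocol(),
                             dilution_heat = 0) {
  if (n <= 0 || kd <= 0) stop("n and kd must be positive", call. = FALSE)
  v0 <- protocol$cell_volume
  xs <- protocol$syringe_conc
  mt <- protocol$cell_conc
  xt <- 0
  bound <- 0
  disp_x <- 0; disp_m <- 0
  out <- vector("list", length(protocol$injection_volumes))
  for (i in seq_along(protocol$injection_volumes)) {
    v <- protocol$injection_volumes[i]
    # mix injection into the cell, then remove the displaced volume
    xt_new <- (xt * v0 + xs * v) / (v0 + v)
    mt_new <- mt * v0 / (v0 + v)
    disp_x <- disp_x + xt_new * v
    disp_m <- disp_m + mt_new * v
    bound_diluted <- bound * v0 / (v0 + v)
    bound_new <- .bound_quadratic(n * mt_new, xt_new, kd)
    heat <- dh * 1e9 * v0 * (bound_new - bound_diluted) + dilution_heat
    xt <- xt_new; mt <- mt_new; bound <- bound_new
    out[[i]] <- c(v, xt, mt, bound, disp_x, disp_m, heat)
  }
  m <- do.call(rbind, out)
  tibble::tibble(
    injection = seq_len(nrow(m)), volume = m[, 1],
    molar_ratio = m[, 2] / m[, 3],
    xt = m[, 2], mt = m[, 3], bound = m[, 4],
    displaced_x = m[, 5], displaced_m = m[, 6], heat = m[, 7]
  )
}

# smaller root of B^2 - (S + X + Kd) B + S X = 0, numerically stable form
.bound_quadratic <- function(sites, xt, kd) {
  b <- sites + xt + kd
  disc <- sqrt(pmax(b^2 - 4 * sites * xt, 0))
  2 * sites * xt / (b + disc)
}

#' Simulate an ITC experiment with known parameters
#'
#' Forward-model injection heats plus i.i.d. Gaussian noise. The noise
#' standard deviation is expressed as a fraction of the largest absolute
#' predicted heat, so "2% noise" perturbs every injection by the same
#' absolute amount regardless of where saturation occurs.
#'
#' @inheritParams predict_isotherm
#' @param seed Integer seed (mandatory).
#' @param noise_sd Noise level as a fraction of the maximum absolute heat.
#' @return A list of class `itc_experiment`: the protocol, `heats` (ucal),
#'   the injection table, and `truth` (named list with `n`, `kd`, `dh`,
#'   `noise_sd`, `seed`).
#' @export
sim_itc <- function(seed, n = 1, kd = 13e-6, dh = -10,
                    protocol = itc_protocol(), noise_sd = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  ideal <- predict_isotherm(n, kd, dh, protocol)
  heats <- ideal$heat
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      heats <- heats + stats::rnorm(length(heats),
                                    sd = noise_sd * max(abs(ideal$heat)))
    })
  }
  structure(list(protocol = protocol, heats = heats, injections = ideal,
                 truth = list(n = n, kd = kd, dh = dh, noise_sd = noise_sd,
                              seed = as.integer(seed))),
            class = "itc_experiment")
}

#' Read an ITC experiment from a heats table and a protocol header
#'
#' @param heats_csv CSV with columns `injection`, `volume_ul`, `heat_ucal`.
#' @param protocol_yaml YAML file with fields `cell_conc`, `syringe_conc`,
#'   `cell_volume`, `temperature` (SI units as in [itc_protocol()]).
#' @return An `itc_experiment`.
#' @export
read_itc <- function(heats_csv, protocol_yaml) {
  h <- utils::read.csv(heats_csv)
  stopifnot(all(c("injection", "volume_ul", "heat_ucal") %in% names(h)))
  p <- yaml::read_yaml(protocol_yaml)
  protocol <- itc_protocol(cell_conc = p$cell_conc,
                           syringe_conc = p$syringe_conc,
                           cell_volume = p$cell_volume,
                           injection_volumes = h$volume_ul * 1e-6,
                           temperature = p$temperature %||% 277.15)
  structure(list(protocol = protocol, heats = h$heat_ucal,
                 injections = NULL, truth = NULL),
            class = "itc_experiment")
}

#' Fit the single-site binding model to an ITC experiment
#'
#' Nonlinear least squares of the exact 1:1 isotherm
#' ([predict_isotherm()]) to the observed injection heats, over
#' (n, K_D, dH), parameterised on the log scale for the two positive
#' parameters. Initialisation is multi-start (n in 0.5/1/2, K_D log-spaced
#' over 1e-8 to 1e-3 M, dH estimated from the first-injection heat); the
#' best converged start wins. The free energy and entropic term are then
#' computed from the thermodynamic identities
#' `dG = -RT ln(1/K_D)` and `TdS = dH - dG` with R = 1.99 cal/(mol K) at the
#' experiment temperature -- they are identities, not fitted parameters.
#'
#' @param experiment An `itc_experiment` (from [sim_itc()] or [read_itc()]).
#' @param fit_dilution Also fit a constant per-injection heat offset.
#' @param n_starts_refined Number of best starting points polished with
#'   Levenberg-Marquardt.
#' @return An object of class `itc_fit` with elements `estimates` (named
#'   list: `n`, `kd` (M), `dh`, `dg`, `tds` (kcal/mol)), `std_errors`,
#'   `converged`, `rmse` (ucal), `fitted` (ucal), `experiment`.
#' @export
fit_itc <- function(experiment, fit_dilution = FALSE, n_starts_refined = 3) {
  protocol <- experiment$protocol
  heats <- experiment$heats
  if (length(heats) < 8) {
    stop("at least 8 injections are required for a single-site fit",
         call. = FALSE)
  }
  moles1 <- protocol$injection_volumes[1] * protocol$syringe_conc
  dh0 <- heats[1] * 1e-9 / moles1

  resid_fun <- function(par) {
    pred <- predict_isotherm(exp(par[1]), exp(par[2]), par[3], protocol,
                             dilution_heat = if (fit_dilution) par[4] else 0)
    heats - pred$heat
  }
  starts <- expand.grid(log_n = log(c(0.5, 1, 2)),
                        log_kd = log(10^seq(-8, -3, length.out = 6)),
                        dh = dh0)
  if (fit_dilution) starts$q0 <- 0
  sse <- apply(starts, 1, function(p) sum(resid_fun(as.numeric(p))^2))
  best <- order(sse)[seq_len(min(n_starts_refined, nrow(starts)))]

  fits <- lapply(best, function(k) {
    tryCatch(minpack.lm::nls.lm(par = as.numeric(starts[k, ]), fn = resid_fun,
                                control = minpack.lm::nls.lm.control(maxiter = 200)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  converged <- FALSE
  if (any(ok)) {
    dev <- vapply(fits[ok], function(f) f$deviance, numeric(1))
    fit <- fits[ok][[which.min(dev)]]
    converged <- fit$info %in% 1:4
  } else {
    fit <- NULL
  }
  if (is.null(fit)) {
    warning("single-site fit failed to converge from all starts")
    par <- as.numeric(starts[best[1], ])
    se <- rep(NA_real_, length(par))
  } else {
    if (!converged) warning("single-site fit did not fully converge; ",
                            "parameters reported with caution")
    par <- fit$par
    se <- tryCatch({
      covm <- solve(fit$hessian) * fit$deviance /
        max(1, length(heats) - length(par))
      sqrt(pmax(diag(covm), 0))
    }, error = function(e) rep(NA_real_, length(par)))
  }

  n_hat <- exp(par[1]); kd_hat <- exp(par[2]); dh_hat <- par[3]
  tt <- protocol$temperature
  dg <- -.R_GAS * tt * log(1 / kd_hat) / 1000  # kcal/mol
  tds <- dh_hat - dg
  fitted <- predict_isotherm(n_hat, kd_hat, dh_hat, protocol,
                             dilution_heat = if (fit_dilution) par[4] else 0)$heat
  structure(list(
    estimates = list(n = n_hat, kd = kd_hat, dh = dh_hat, dg = dg, tds = tds,
                     dilution_heat = if (fit_dilution) par[4] else 0),
    std_errors = list(n = n_hat * se[1], kd = kd_hat * se[2], dh = se[3]),
    converged = converged,
    rmse = sqrt(mean((heats - fitted)^2)),
    fitted = fitted,
    experiment = experiment
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf(
    "single-site ITC fit%s:\n  n    = %.3f\n  K_D  = %.2f uM\n  dH   = %.2f kcal/mol\n  dG   = %.2f kcal/mol\n  -TdS = %.2f kcal/mol\n  rmse = %.3f ucal\n",
    if (x$converged) "" else " (NOT converged)",
    e$n, e$kd * 1e6, e$dh, e$dg, -e$tds, x$rmse))
  invisible(x)
}

#' Tidy methods for ITC fits
#'
#' `tidy()` returns one row per fitted parameter with standard errors;
#' `glance()` returns a one-row model summary including the derived
#' thermodynamic decomposition.
#'
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n", "kd", "dh"),
    estimate = c(x$estimates$n, x$estimates$kd, x$estimates$dh),
    std.error = c(x$std_errors$n, x$std_errors$kd, x$std_errors$dh),
    unit = c("", "M", "kcal/mol")
  )
}

#' @rdname tidy.itc_fit
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(
    n = x$estimates$n, kd = x$estimates$kd, kd_uM = x$estimates$kd * 1e6,
    dh = x$estimates$dh, dg = x$estimates$dg, tds = x$estimates$tds,
    rmse = x$rmse, converged = x$converged,
    n_injections = length(x$experiment$heats)
  )
}
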