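#' One-site binding parameters
#'
#' Thermodynamic parameters of the single-site binding model: the
#' stoichiometry `n_stoich` (sites per macromolecule), the association
#' constant `ka` (M^-1) and the molar binding enthalpy `dh`
#' (kcal mol^-1). Either `ka` or the dissociation constant `kd = 1/ka`
#' (in M) may be supplied.
#'
#' @param n_stoich Sites per macromolecule (> 0).
#' @param ka Association constant in M^-1 (> 0).
#' @param kd Dissociation constant in M (alternative to `ka`).
#' @param dh Molar enthalpy in kcal/mol.
#' @return A list of class `itc_params` with fields `n_stoich`, `ka`,
#'   `kd`, `dh`.
#' @examples
#' itc_params(n_stoich = 1, kd = 1.47e-6, dh = -10)
#' @export
itc_params <- function(n_stoich = 1, ka = NULL, kd = NULL, dh) {
  if (is.null(ka) && is.null(kd)) abort("supply ka or kd")
  if (is.null(ka)) ka <- 1 / kd
  if (ka <= 0) abort("ka must be positive")
  if (n_stoich <= 0) abort("n_stoich must be positive")
  structure(list(n_stoich = n_stoich, ka = ka, kd = 1 / ka, dh = dh),
            class = "itc_params")
}

#' @export
print.itc_params <- function(x, ...) {
  cat(sprintf("<itc_params> N = %.3g, Ka = %.4g M^-1 (Kd = %.4g uM), dH = %.3g kcal/mol\n",
              x$n_stoich, x$ka, x$kd * 1e6, x$dh))
  invisible(x)
}

# Equilibrium bound-complex concentration [PL] for total site concentration
# s (= n * Mtot), total ligand x, association constant ka: the physical root
# of ka = PL / ((s - PL)(x - PL)).
bound_complex <- function(s, x, ka) {
  b <- s + x + 1 / ka
  disc <- b^2 - 4 * s * x
  if (any(disc < 0)) abort("negative discriminant: non-physical titration state")
  (b - sqrt(disc)) / 2
}

#' Predict one-site ITC injection heats
#'
#' Implements the single-site binding isotherm with stepwise
#' displacement-dilution accounting: each injection of volume `v` first
#' displaces an equal volume of pre-injection cell solution (scaling both
#' cell concentrations by `1 - v/V0`), then adds ligand, and the bound
#' complex re-equilibrates from the quadratic mass-action equation. The
#' heat of injection i is
#' `dh * V0 * ([PL]_i - [PL]_(i-1) * (1 - v_i/V0))`, expressed per mole of
#' injectant (instrument convention), so plateau heats before saturation
#' approach `dh`.
#'
#' @param params An [itc_params()] object.
#' @param cell_volume Cell volume in L (default 200 uL).
#' @param cell_conc Initial macromolecule concentration in the cell (M).
#' @param syringe_conc Ligand concentration in the syringe (M).
#' @param injection_volumes Injection volumes in L.
#' @return Numeric vector of heats (kcal per mole of injectant), one per
#'   injection.
#' @export
predict_heats <- function(params, cell_volume = 2e-4, cell_conc,
                          syringe_conc, injection_volumes) {
  if (cell_conc <= 0 || syringe_conc <= 0) {
    abort("concentrations must be positive")
  }
  if (cell_volume <= 0 || any(injection_volumes <= 0)) {
    abort("volumes must be positive")
  }
  m <- cell_conc    # macromolecule in cell (M)
  x <- 0            # ligand in cell (M)
  pl_prev <- 0
  heats <- numeric(length(injection_volumes))
  for (i in seq_along(injection_volumes)) {
    f <- injection_volumes[i] / cell_volume
    m <- m * (1 - f)
    x <- x * (1 - f) + syringe_conc * f
    pl_displaced <- pl_prev * (1 - f)
    pl <- bound_complex(params$n_stoich * m, x, params$ka)
    moles_injected <- syringe_conc * injection_volumes[i]
    heats[i] <- params$dh * cell_volume * (pl - pl_displaced) / moles_injected
    pl_prev <- pl
  }
  heats
}

#' Simulate an ITC titration with noise
#'
#' Generates heats from [predict_heats()] plus i.i.d. Gaussian noise, the
#' way an instrument run with a given protocol would be reduced to a
#' per-injection heat table. Defaults mirror a typical protein-peptide
#' protocol: 0.1 mM macromolecule in a 200-uL cell titrated with 19 x 2 uL
#' of 1.2 mM peptide.
#'
#' @param params An [itc_params()] object (the generating truth).
#' @param cell_volume,cell_conc,syringe_conc,injection_volumes Titration
#'   geometry (see [predict_heats()]).
#' @param noise_sd Gaussian noise standard deviation, kcal per mole of
#'   injectant.
#' @param seed Integer seed.
#' @return A tibble of class `itc_titration` (`injection`, `volume`,
#'   `heat`) with the geometry in attributes and the generating
#'   parameters in attribute `truth`.
#' @export
simulate_itc <- function(params, cell_volume = 2e-4, cell_conc = 1e-4,
                         syringe_conc = 1.2e-3,
                         injection_volumes = rep(2e-6, 19),
                         noise_sd = 0, seed = 1L) {
  set.seed(seed)
  mu <- predict_heats(params, cell_volume, cell_conc, syringe_conc,
                      injection_volumes)
  out <- tibble(
    injection = seq_along(injection_volumes),
    volume = injection_volumes,
    heat = mu + rnorm(length(mu), sd = noise_sd)
  )
  attr(out, "cell_volume") <- cell_volume
  attr(out, "cell_conc") <- cell_conc
  attr(out, "syringe_conc") <- syringe_conc
  attr(out, "truth") <- params
  class(out) <- c("itc_titration", class(out))
  out
}

#' Read a titration from CSV
#'
#' Expects columns `injection_volume_uL` and `heat_kcal_per_mol`; the cell
#' geometry is supplied as arguments because exported heat tables do not
#' carry it.
#'
#' @param path CSV path.
#' @param cell_volume,cell_conc,syringe_conc Geometry (L, M, M).
#' @return An `itc_titration` tibble.
#' @export
read_itc_csv <- function(path, cell_volume = 2e-4, cell_conc, syringe_conc) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("injection_volume_uL", "heat_kcal_per_mol")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  out <- tibble(
    injection = seq_len(nrow(x)),
    volume = x$injection_volume_uL * 1e-6,
    heat = x$heat_kcal_per_mol
  )
  attr(out, "cell_volume") <- cell_volume
  attr(out, "cell_conc") <- cell_conc
  attr(out, "syringe_conc") <- syringe_conc
  class(out) <- c("itc_titration", class(out))
  out
}

#' Fit the one-site model to a titration
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the predicted
#' injection heats against the measured heats, over `(n_stoich, log(ka),
#' dh)`; the log parameterization keeps `ka` positive. Standard errors
#' come from the Jacobian at the optimum; the error of `kd` follows by the
#' delta method. A Wiseman c-value (`n * ka * cell_conc`) outside
#' [1, 1000] triggers a warning, as the isotherm shape then constrains
#' `ka` poorly. Non-convergence is reported in the returned object (field
#' `converged`) together with the best parameters found.
#'
#' @param titration An `itc_titration` tibble (or any tibble with
#'   `volume`, `heat` plus geometry arguments).
#' @param start Optional named list `n_stoich`, `ka`, `dh` of starting
#'   values.
#' @param cell_volume,cell_conc,syringe_conc Geometry overrides; default
#'   to the titration's attributes.
#' @param discard_first Drop the first injection before fitting (common
#'   instrument practice; default `FALSE`).
#' @param weights Optional per-injection weights (proportional to inverse
#'   noise variance). Unweighted by default; when the measurement error
#'   scales with the heat amplitude, weighting by `1 / heat^2` makes the
#'   fit the maximum-likelihood estimate and sharpens the Kd estimate
#'   considerably.
#' @return An object of class `itc_fit`: fields `params` ([itc_params()]),
#'   `estimates` (tibble `term`, `estimate`, `std_error`), `kd_uM`,
#'   `c_value`, `converged`, `fitted`, `residuals`, `data`.
#' @export
fit_itc <- function(titration, start = NULL,
                    cell_volume = attr(titration, "cell_volume"),
                    cell_conc = attr(titration, "cell_conc"),
                    syringe_conc = attr(titration, "syringe_conc"),
                    discard_first = FALSE, weights = NULL) {
  if (is.null(cell_volume) || is.null(cell_conc) || is.null(syringe_conc)) {
    abort("titration geometry (cell_volume, cell_conc, syringe_conc) required")
  }
  dat <- as_tibble(titration)
  if (discard_first) dat <- dat[-1, , drop = FALSE]
  if (nrow(dat) < 8) warn("fewer than 8 injections: fit may be unstable")
  heats_model <- function(n_stoich, log_ka, dh) {
    # injections are sequential; heats for a truncated series equal the
    # leading heats of the full series, so refitting after discard is exact
    full <- predict_heats(itc_params(n_stoich = n_stoich, ka = exp(log_ka),
                                     dh = dh),
                          cell_volume, cell_conc, syringe_conc,
                          titration$volume)
    if (discard_first) full[-1] else full
  }
  if (is.null(start)) {
    start <- list(n_stoich = 1,
                  ka = 10 / cell_conc,
                  dh = dat$heat[which.max(abs(dat$heat))])
    if (start$dh == 0) start$dh <- -1
  }
  if (!is.null(weights) && length(weights) != nrow(dat)) {
    abort("weights must have one value per fitted injection")
  }
  dat$.w <- weights %||% rep(1, nrow(dat))
  fit <- minpack.lm::nlsLM(
    heat ~ heats_model(n_stoich, log_ka, dh),
    data = dat,
    start = list(n_stoich = start$n_stoich, log_ka = log(start$ka),
                 dh = start$dh),
    weights = dat$.w,
    lower = c(1e-3, log(1e-2), -1e4),
    upper = c(1e3, log(1e15), 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  dat$.w <- NULL
  converged <- fit$convInfo$isConv
  if (!converged) warn("ITC fit did not converge; best-so-far parameters returned")
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(diag(vc))
  ka_hat <- exp(est[["log_ka"]])
  se_ka <- ka_hat * se[2]          # delta method on log(ka)
  se_kd <- se_ka / ka_hat^2        # kd = 1/ka
  params <- itc_params(n_stoich = est[["n_stoich"]], ka = ka_hat,
                       dh = est[["dh"]])
  c_value <- params$n_stoich * params$ka * cell_conc
  if (is.finite(c_value) && (c_value < 1 || c_value > 1000)) {
    warn(sprintf("Wiseman c-value %.3g outside [1, 1000]: Kd poorly constrained",
                 c_value))
  }
  structure(list(
    params = params,
    estimates = tibble(
      term = c("n_stoich", "ka", "dh", "kd"),
      estimate = c(params$n_stoich, params$ka, params$dh, params$kd),
      std_error = c(se[1], se_ka, se[3], se_kd)
    ),
    kd_uM = params$kd * 1e6,
    c_value = c_value,
    converged = converged,
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(resid(fit)),
    data = dat,
    geometry = list(cell_volume = cell_volume, cell_conc = cell_conc,
                    syringe_conc = syringe_conc)
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("<itc_fit> one-site binding model\n")
  print(x$params)
  cat(sprintf("  Kd = %.3g uM, c = %.3g, converged: %s\n",
              x$kd_uM, x$c_value, x$converged))
  invisible(x)
}

#' @rdname fit_itc
#' @param x An `itc_fit` object.
#' @param ... Unused.
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) x$estimates

#' @rdname fit_itc
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(
    kd_uM = x$kd_uM,
    c_value = x$c_value,
    sigma = sqrt(mean(x$residuals^2)),
    n_injections = nrow(x$data),
    converged = x$converged
  )
}

#' Fold difference between two dissociation constants
#'
#' `kd_a / kd_b`: how many fold weaker interaction A binds than B.
#'
#' @param kd_a,kd_b Dissociation constants (> 0, same units).
#' @return The ratio.
#' @examples
#' kd_fold_ratio(22.9, 1.47)  # ~15.6-fold weaker
#' @export
kd_fold_ratio <- function(kd_a, kd_b) {
  if (any(kd_a <= 0) || any(kd_b <= 0)) abort("Kd values must be positive")
  kd_a / kd_b
}
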