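# Assay mathematics: extinction coefficients, Michaelis-Menten kinetics,
# initial velocities, densitometry, CD signal handling, apparent melting
# temperatures and fold-change summaries.

#' Predicted extinction coefficient from aromatic residue counts
#'
#' `epsilon = 5690 * n_trp + 1280 * n_tyr` (M^-1 cm^-1), the standard
#' denatured-protein prediction from tryptophan and tyrosine counts per
#' monomer; exact integer arithmetic.
#'
#' @param n_trp,n_tyr Non-negative integer counts per monomer.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(n_trp, n_tyr) {
  if (any(n_trp < 0) || any(n_tyr < 0))
    stop("residue counts must be non-negative")
  if (any(n_trp != round(n_trp)) || any(n_tyr != round(n_tyr)))
    stop("residue counts must be integers")
  5690 * n_trp + 1280 * n_tyr
}

#' Michaelis-Menten velocity
#'
#' `v = Vmax * S / (Km + S)`.
#'
#' @param vmax Maximum velocity.
#' @param km Michaelis constant (same units as `S`).
#' @param S Substrate concentration(s), `>= 0`.
#' @return Velocity (same units as `vmax`).
#' @export
mm_velocity <- function(vmax, km, S) {
  if (any(S < 0)) stop("substrate concentrations must be non-negative")
  vmax * S / (km + S)
}

#' Fit the Michaelis-Menten model to initial-velocity data
#'
#' Nonlinear least squares (Levenberg-Marquardt via \pkg{minpack.lm}) of
#' `v = Vmax * S / (Km + S)` with a deterministic start: `Vmax0 = max(v)`
#' and `Km0` the substrate concentration at which the velocity first reaches
#' `Vmax0 / 2` (linearly interpolated).  Parameter standard errors come from
#' the Jacobian.  A warning is raised when fewer than 3 distinct substrate
#' concentrations are supplied or when the data do not span the fitted Km.
#'
#' @param S,v Equal-length numeric vectors of substrate concentration (uM)
#'   and initial velocity.
#' @param enzyme_conc Enzyme concentration (uM) used to derive
#'   `kcat = Vmax / enzyme_conc`.
#' @return Object of class `kinetic_model`: list with `vmax`, `km`,
#'   `enzyme_conc`, `kcat`, `efficiency` (`kcat/km`), `se` (named vector for
#'   Vmax and Km, plus the propagated kcat SE) and `fit` (the underlying
#'   `nls` object).
#' @export
fit_michaelis_menten <- function(S, v, enzyme_conc = 1) {
  S <- as.numeric(S); v <- as.numeric(v)
  if (length(S) != length(v) || length(S) < 2L)
    stop("need matched S and v vectors with at least 2 points")
  if (enzyme_conc <= 0) stop("enzyme_conc must be positive")
  if (all(v == 0) || stats::var(v) == 0)
    stop("non-convergence: velocities carry no signal to fit")
  if (length(unique(S)) < 3L)
    warning("fewer than 3 distinct substrate concentrations; fit is fragile")
  ord <- order(S)
  vmax0 <- max(v)
  half <- vmax0 / 2
  km0 <- NA_real_
  vs <- v[ord]; ss <- S[ord]
  idx <- which(vs >= half)[1]
  if (!is.na(idx) && idx > 1L) {
    km0 <- ss[idx - 1] + (half - vs[idx - 1]) *
      (ss[idx] - ss[idx - 1]) / (vs[idx] - vs[idx - 1])
  } else if (!is.na(idx)) {
    km0 <- ss[idx]
  }
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(ss[ss > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * S / (km + S),
                      data = data.frame(S = S, v = v),
                      start = list(vmax = vmax0, km = km0),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
    error = function(e) stop("non-convergence in Michaelis-Menten fit: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  if (any(est <= 0))
    stop(sprintf("fit produced non-positive parameter(s): Vmax = %.3g, Km = %.3g",
                 est[["vmax"]], est[["km"]]))
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (max(S) < est[["km"]] || min(S[S > 0]) > est[["km"]])
    warning("substrate range does not span the fitted Km; estimates are extrapolated")
  kcat <- est[["vmax"]] / enzyme_conc
  structure(list(vmax = est[["vmax"]], km = est[["km"]],
                 enzyme_conc = enzyme_conc,
                 kcat = kcat,
                 efficiency = kcat / est[["km"]],
                 se = c(vmax = unname(se["vmax"]), km = unname(se["km"]),
                        kcat = unname(se["vmax"]) / enzyme_conc),
                 fit = fit),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic_model: Vmax = %.4g +/- %.2g, Km = %.4g +/- %.2g uM\n",
              x$vmax, x$se["vmax"], x$km, x$se["km"]))
  cat(sprintf("  kcat = %.4g s^-1 ([E] = %g uM), kcat/Km = %.4g s^-1 uM^-1\n",
              x$kcat, x$enzyme_conc, x$efficiency))
  invisible(x)
}

#' Catalytic efficiency from the initial slope
#'
#' Ordinary least-squares slope of `v/[E]` versus `[S]` over the initial,
#' linear region of the saturation curve (where `v/[E] ~ (kcat/Km) * S`).
#' The intercept is left free and reported.
#'
#' @param S Substrate concentrations.
#' @param v_over_e Normalised velocities `v/[E]` (s^-1).
#' @param max_S Upper bound of the linear region; points with `S <= max_S`
#'   are used.  A common choice is `Km/10` from a prior fit; the default uses
#'   the three lowest concentrations.
#' @return List with `efficiency` (the slope, s^-1 uM^-1), `intercept`, `n`
#'   and the `lm` fit.
#' @export
efficiency_from_slope <- function(S, v_over_e, max_S = NULL) {
  S <- as.numeric(S); v_over_e <- as.numeric(v_over_e)
  if (length(S) != length(v_over_e)) stop("S and v/[E] lengths differ")
  keep <- if (is.null(max_S)) {
    S <= sort(unique(S))[min(3L, length(unique(S)))]
  } else S <= max_S
  if (sum(keep) < 2L) stop("fewer than 2 points in the linear region")
  fit <- stats::lm(v_over_e[keep] ~ S[keep])
  list(efficiency = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = sum(keep), fit = fit)
}

#' Initial velocity from the linear portion of a timecourse
#'
#' Least-squares slope of signal versus time over `window`, multiplied by a
#' signal-to-concentration `conversion` factor.  For NADPH-coupled assays
#' monitored by A340 depletion, a negative factor such as
#' `-1 / (6220 * path_cm) * 1e6` converts a negative absorbance slope into a
#' positive product-formation rate in uM/s (6220 M^-1 cm^-1 and the plate
#' path length are user inputs, not constants of the method).
#'
#' @param times,values Equal-length timecourse (times strictly increasing).
#' @param window Length-2 numeric time span; at least 3 points must fall in
#'   it (inclusive).
#' @param conversion Multiplicative signal-to-rate conversion (default 1).
#' @return Rate (units of `values * conversion` per time unit).
#' @export
initial_velocity <- function(times, values, window = range(times),
                             conversion = 1) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 3L) stop("fewer than 3 points in the requested window")
  slope <- unname(stats::coef(stats::lm(values[keep] ~ times[keep]))[2])
  slope * conversion
}

#' Percent band density of a gel lane
#'
#' `band / lane * 100`.
#'
#' @param band Band density (arbitrary units, `0 <= band <= lane`).
#' @param lane Full-lane density (`> 0`).
#' @return Percentage.
#' @export
band_density_percent <- function(band, lane) {
  if (any(lane <= 0)) stop("lane density must be positive")
  if (any(band < 0) || any(band > lane))
    stop("band density must lie between 0 and the lane density")
  band / lane * 100
}

#' Percent change of the iminopyrimidine (IP) CD signal
#'
#' The default convention measures the change relative to the fully formed
#' signal, `((CD313(t) - (CD313(0) + delta)) / delta) * 100`, which reads
#' -100% at t = 0 and 0% once the signal is fully formed.  The alternative
#' `((CD313(t) - CD313(0)) / delta) * 100` (0% at t = 0, +100% fully formed)
#' is available via `convention = "from-start"`; the two differ by exactly
#' 100 for all inputs.
#'
#' @param cd_t CD313 signal at time t (mdeg).
#' @param cd_0 CD313 signal at t = 0 (mdeg).
#' @param delta Total IP signal change (mdeg, nonzero).
#' @param convention `"from-full"` (default) or `"from-start"`.
#' @return Percent change.
#' @export
ip_percent_change <- function(cd_t, cd_0, delta,
                              convention = c("from-full", "from-start")) {
  convention <- match.arg(convention)
  if (any(delta == 0)) stop("delta must be nonzero")
  base <- (cd_t - cd_0) / delta * 100
  if (convention == "from-full") base - 100 else base
}

#' Normalise a phosphonolactyl-ThDP CD timecourse to the AP baseline
#'
#' Pointwise subtraction of the aminopyrimidine (AP) reference signal --
#' typically the mean CD313 of two back-to-back scans recorded before adduct
#' formation -- so variants with shifted AP baselines become comparable.
#'
#' @param values CD313 timecourse values (mdeg).
#' @param ap_reference AP CD313 reference: a scalar, or a vector whose mean
#'   is used.
#' @return Normalised values.
#' @export
normalize_plthdp <- function(values, ap_reference) {
  as.numeric(values) - mean(as.numeric(ap_reference))
}

#' Apparent melting temperature from a CD222 melt curve
#'
#' The apparent Tm is the temperature of the maximum of the first derivative
#' of CD222 versus temperature.  The derivative is taken by central finite
#' differences and the discrete maximum is refined by a quadratic fit
#' through the three surrounding points.  Monotone-linear or flat data (no
#' strict interior derivative peak) raise a "no transition detected" error.
#'
#' @param temperature Strictly increasing temperatures (deg C, `>= 5` points).
#' @param cd222 CD signal at 222 nm (mdeg).
#' @return Apparent Tm in deg C.
#' @export
melting_temperature <- function(temperature, cd222) {
  temperature <- as.numeric(temperature); cd222 <- as.numeric(cd222)
  if (length(temperature) != length(cd222)) stop("input lengths differ")
  n <- length(temperature)
  if (n < 5L) stop("need at least 5 points")
  if (is.unsorted(temperature, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  i <- 2:(n - 1)
  d <- (cd222[i + 1] - cd222[i - 1]) / (temperature[i + 1] - temperature[i - 1])
  tmid <- temperature[i]
  span <- diff(range(d))
  tol <- 1e-9 * max(abs(d), 1)
  pk <- which.max(d)
  if (span <= tol || pk == 1L || pk == length(d) ||
      d[pk] - d[pk - 1] <= tol || d[pk] - d[pk + 1] <= tol)
    stop("no transition detected in the melt curve")
  # quadratic through the three points around the discrete maximum
  t3 <- tmid[(pk - 1):(pk + 1)]
  d3 <- d[(pk - 1):(pk + 1)]
  qc <- stats::coef(stats::lm(d3 ~ t3 + I(t3^2)))
  if (!is.finite(qc[3]) || qc[3] >= 0) return(tmid[pk])
  vertex <- -qc[2] / (2 * qc[3])
  if (vertex < t3[1] || vertex > t3[3]) tmid[pk] else unname(vertex)
}

#' Fold change between a reference and a variant value
#'
#' `mode = "decrease"` reports `reference / variant` (how many fold the
#' variant dropped); `mode = "increase"` reports `variant / reference`.
#' Optional nearest-integer rounding matches narrative usage.
#'
#' @param reference,variant Positive values (e.g. kcat or Km).
#' @param mode `"decrease"` or `"increase"`.
#' @param rounding `"none"` (default) or `"nearest-int"`.
#' @return Fold change.
#' @export
fold_change <- function(reference, variant, mode = c("decrease", "increase"),
                        rounding = c("none", "nearest-int")) {
  mode <- match.arg(mode)
  rounding <- match.arg(rounding)
  if (any(reference <= 0) || any(variant <= 0))
    stop("fold_change requires positive inputs")
  out <- if (mode == "decrease") reference / variant else variant / reference
  if (rounding == "nearest-int") round(out) else out
}
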