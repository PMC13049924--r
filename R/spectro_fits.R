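# Nonlinear spectroscopy fits: Morrison tight-binding titration, Boltzmann
# sigmoidal melt, two-summed-exponential stopped-flow decay, and the kinetic
# isotope effect. All fitters use bounded Levenberg-Marquardt least squares
# (minpack.lm) with a small set of data-driven starts; uncertainties come
# from the Jacobian-based covariance at the optimum. Fits are invariant to
# data-point ordering.

fitBest <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fit error: no start converged; check the data span the transition")
  best
}

#' Fit a tight-binding titration (Morrison quadratic)
#'
#' Least-squares fit of the absorbance change against substrate
#' concentration to the Morrison quadratic tight-binding model
#' (see [morrisonDeltaA()]), the appropriate binding isotherm when the enzyme
#' concentration is comparable to the dissociation constant. In the weak
#' binding limit (E much smaller than Kd) the model reduces to the hyperbola
#' `dAmax * S / (S + Kd)`.
#'
#' @param S substrate concentrations (uM), strictly increasing, >= 4 points
#'   spanning the transition.
#' @param dA observed absorbance changes.
#' @param E enzyme concentration (uM), fixed.
#' @param start optional named list (`Kd`, `dAmax`) overriding the
#'   data-driven starts.
#' @return list of class `"tightBindingFit"`: `Kd`, `dAmax` (estimates), `se`
#'   (named standard errors), `rss` and the underlying `nls` object as `fit`.
#' @export
fitMorrisonKd <- function(S, dA, E, start = NULL) {
  if (length(S) < 4L) stop("at least 4 titration points are required")
  if (E <= 0) stop("enzyme concentration must be positive")
  d <- data.frame(S = S, dA = dA)
  amax0 <- max(dA)
  half <- S[which.min(abs(dA - amax0 / 2))]
  starts <- if (!is.null(start)) list(start) else list(
    list(Kd = max(half, 1e-3), dAmax = amax0),
    list(Kd = max(half / 5, 1e-3), dAmax = amax0 * 1.1),
    list(Kd = max(half * 5, 1e-3), dAmax = amax0 * 0.9))
  best <- fitBest(dA ~ morrisonDeltaA(S, Kd, dAmax, E), d, starts,
                  lower = c(Kd = 1e-9, dAmax = 0),
                  upper = c(Kd = Inf, dAmax = Inf))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  structure(list(Kd = unname(cf["Kd"]), dAmax = unname(cf["dAmax"]),
                 E = E, se = se, rss = best$rss, fit = best$fit),
            class = "tightBindingFit")
}

#' @export
print.tightBindingFit <- function(x, ...) {
  cat(sprintf("Tight-binding fit (Morrison): Kd = %.4g uM, dAmax = %.4g (rss %.3g)\n",
              x$Kd, x$dAmax, x$rss))
  invisible(x)
}

#' Fit a thermal melting curve (Boltzmann sigmoid)
#'
#' Fits ellipticity (or any melt signal) against temperature to the Boltzmann
#' sigmoid (see [boltzmannSignal()]); the melting temperature Tm is the
#' temperature at the middle of the transition. Adding a constant to all
#' signals leaves Tm unchanged.
#'
#' @param temp scan temperatures (degC).
#' @param signal melt signal (e.g. mean residue ellipticity).
#' @param start optional named list (`Tm`, `slope`, `lower`, `upper`).
#' @return list of class `"meltFit"`: `Tm`, `slope`, `lower`, `upper`, `se`,
#'   `rss`, `fit`.
#' @export
fitBoltzmannTm <- function(temp, signal, start = NULL) {
  if (length(temp) < 5L) stop("at least 5 scan points are required")
  lo0 <- min(signal); up0 <- max(signal)
  if (up0 - lo0 <= 0) stop("fit error: no transition in the scanned range")
  mid <- (lo0 + up0) / 2
  tm0 <- temp[which.min(abs(signal - mid))]
  rng <- diff(range(temp))
  d <- data.frame(temp = temp, signal = signal)
  starts <- if (!is.null(start)) list(start) else list(
    list(Tm = tm0, slope = rng / 20, lower = lo0, upper = up0),
    list(Tm = tm0, slope = rng / 50, lower = lo0, upper = up0),
    list(Tm = mean(range(temp)), slope = rng / 10, lower = lo0, upper = up0))
  best <- fitBest(signal ~ boltzmannSignal(temp, Tm, slope, lower, upper), d,
                  starts,
                  lower = c(Tm = min(temp), slope = 1e-6, lower = -Inf, upper = -Inf),
                  upper = c(Tm = max(temp), slope = Inf, lower = Inf, upper = Inf))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(list(Tm = unname(cf["Tm"]), slope = unname(cf["slope"]),
                 lower = unname(cf["lower"]), upper = unname(cf["upper"]),
                 se = se, rss = best$rss, fit = best$fit),
            class = "meltFit")
}

#' @export
print.meltFit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit: Tm = %.2f degC (slope %.3g degC, rss %.3g)\n",
              x$Tm, x$slope, x$rss))
  invisible(x)
}

#' Fit a stopped-flow trace to two summed exponentials
#'
#' Least-squares fit of `A(t) = offset + A1 exp(-k1 t) + A2 exp(-k2 t)` with
#' three data-driven starts (biexponential fits are
#' initialization-sensitive). Rates are reported fast-first
#' (`kFast >= kSlow`). When the two rates collapse within 1% a warning
#' suggests a single-exponential model instead.
#'
#' @param time times (s), >= 10 points spanning at least ~3 slow lifetimes.
#' @param absorbance observed trace.
#' @param start optional named list (`A1`, `k1`, `A2`, `k2`, `offset`).
#' @return list of class `"biExponentialFit"`: `kFast`, `kSlow`, `aFast`,
#'   `aSlow`, `offset`, `se` (on the fast/slow rates), `rss`, `fit`.
#' @export
fitDoubleExponential <- function(time, absorbance, start = NULL) {
  if (length(time) < 10L) stop("at least 10 trace points are required")
  ord <- order(time)
  d <- data.frame(time = time[ord], absorbance = absorbance[ord])
  off0 <- mean(utils::tail(d$absorbance, max(3L, length(time) %/% 20L)))
  amp0 <- d$absorbance[1] - off0
  tspan <- max(d$time[d$time > 0], na.rm = TRUE)
  k0 <- 3 / tspan                      # ~3 lifetimes over the trace
  starts <- if (!is.null(start)) list(start) else list(
    list(A1 = amp0 / 2, k1 = 10 * k0, A2 = amp0 / 2, k2 = k0, offset = off0),
    list(A1 = amp0 * 0.8, k1 = 30 * k0, A2 = amp0 * 0.2, k2 = k0 / 2, offset = off0),
    list(A1 = amp0 / 2, k1 = 3 * k0, A2 = amp0 / 2, k2 = k0 / 3, offset = off0))
  best <- fitBest(absorbance ~ doubleExponential(time, A1, k1, A2, k2, offset),
                  d, starts,
                  lower = c(A1 = -Inf, k1 = 1e-9, A2 = -Inf, k2 = 1e-9, offset = -Inf),
                  upper = c(A1 = Inf, k1 = Inf, A2 = Inf, k2 = Inf, offset = Inf))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 5), names(cf)))
  fastFirst <- cf["k1"] >= cf["k2"]
  kF <- unname(if (fastFirst) cf["k1"] else cf["k2"])
  kS <- unname(if (fastFirst) cf["k2"] else cf["k1"])
  if (kF > 0 && abs(kF - kS) / kF < 0.01)
    warning("rate collapse: the two rates agree within 1%; consider a single-exponential model")
  structure(list(
    kFast = kF, kSlow = kS,
    aFast = unname(if (fastFirst) cf["A1"] else cf["A2"]),
    aSlow = unname(if (fastFirst) cf["A2"] else cf["A1"]),
    offset = unname(cf["offset"]),
    se = c(kFast = unname(if (fastFirst) se["k1"] else se["k2"]),
           kSlow = unname(if (fastFirst) se["k2"] else se["k1"])),
    rss = best$rss, fit = best$fit), class = "biExponentialFit")
}

#' @export
print.biExponentialFit <- function(x, ...) {
  cat(sprintf("Biexponential fit: kFast = %.4g /s, kSlow = %.4g /s (rss %.3g)\n",
              x$kFast, x$kSlow, x$rss))
  invisible(x)
}

#' Kinetic isotope effect
#'
#' Ratio of the rate constants measured with the protonated and the
#' deuterated substrate. A primary KIE well above unity indicates that C-H
#' bond cleavage is rate-limiting.
#'
#' @param kProtonated rate constant with the protonated substrate (1/s).
#' @param kDeuterated rate constant with the deuterated substrate (1/s).
#' @return list with `kie` (the raw ratio) and `rounded` (nearest integer,
#'   the conventional "~n" report).
#' @examples
#' kineticIsotopeEffect(183, 24.1)   # ~8
#' @export
kineticIsotopeEffect <- function(kProtonated, kDeuterated) {
  if (kProtonated <= 0 || kDeuterated <= 0)
    stop("rate constants must be positive")
  ratio <- kProtonated / kDeuterated
  list(kie = ratio, rounded = round(ratio))
}
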