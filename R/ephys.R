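#' Boltzmann conductance-voltage model
#'
#' `G(V) = Gmin + (Gmax - Gmin) / (1 + exp((V50 - V) * s))` with the slope
#' factor `s` in 1/mV (s > 0 gives an activating curve). By construction
#' `G(V50) = (Gmin + Gmax) / 2`.
#'
#' @param v voltage, mV
#' @param gmin,gmax minimal and maximal conductance
#' @param v50 midpoint voltage, mV
#' @param slope slope factor, 1/mV
#' @export
boltzmannModel <- function(v, gmin, gmax, v50, slope) {
  gmin + (gmax - gmin) / (1 + exp((v50 - v) * slope))
}

#' Hill concentration-response model
#'
#' `dEffect([L]) = dEffectMax / (1 + (L50/[L])^|H|)`; the magnitude of the
#' effect grows and saturates with concentration, and the sign of `effectMax`
#' carries the direction. At `[L] = L50` the effect is `effectMax / 2`.
#'
#' @param conc ligand concentration (> 0)
#' @param effectMax maximal effect
#' @param l50 half-maximal concentration
#' @param hill Hill coefficient (absolute value used)
#' @export
hillModel <- function(conc, effectMax, l50, hill = 1) {
  effectMax / (1 + (l50 / conc)^abs(hill))
}

#' Conductance-voltage curve from tail currents
#'
#' Tail-current amplitudes plotted against the preceding activation voltage.
#' Tabulated amplitudes pass through unchanged; when per-step traces are
#' given, the amplitude is the mean current over a measurement window placed
#' immediately after the capacitive-transient blank following the step to the
#' tail voltage.
#'
#' @param records either a data.frame with columns `voltage`, `tail`
#'   (tabulated amplitudes), or a list with elements `voltage` (vector) and
#'   `traces` (list of data.frames with columns `time` (s), `current`, one per
#'   activation voltage, time zero at the step to the tail voltage)
#' @param blank capacitive blank duration, s
#' @param window length of the measurement window after the blank, s
#' @return data.frame of class `GVCurve` with columns `voltage`, `conductance`
#'   sorted by voltage
#' @export
gvFromTails <- function(records, blank = 0.005, window = 0.015) {
  if (is.data.frame(records)) {
    v <- records$voltage; g <- records$tail
  } else {
    v <- records$voltage
    g <- vapply(records$traces, function(tr) {
      sel <- tr$time >= blank & tr$time < blank + window
      if (!any(sel)) stop("measurement window contains no samples")
      mean(tr$current[sel])
    }, 1)
  }
  if (anyDuplicated(v)) stop("duplicate activation voltages")
  out <- data.frame(voltage = v, conductance = g)[order(v), ]
  rownames(out) <- NULL
  class(out) <- c("GVCurve", "data.frame")
  out
}

# heuristic initial guesses for the Boltzmann fit
.boltzmannStart <- function(v, g) {
  gmin <- min(g); gmax <- max(g)
  half <- (gmin + gmax) / 2
  v50 <- v[which.min(abs(g - half))]
  q <- gmin + c(0.25, 0.75) * (gmax - gmin)
  vq <- vapply(q, function(t) v[which.min(abs(g - t))], 1)
  span <- abs(diff(vq))
  s <- if (span > 0) 2 * log(3) / span else 0.05
  if (stats::cor(v, g) < 0) s <- -s
  list(gmin = gmin, gmax = gmax, v50 = v50, s = s)
}

#' Fit the Boltzmann model to a G(V) curve
#'
#' Unweighted Levenberg-Marquardt least squares of
#' `G(V) = Gmin + (Gmax - Gmin)/(1 + exp((V50 - V) s))`. Initial guesses are
#' derived from the half-range crossing (V50) and the 25-75% rise span (s)
#' unless supplied.
#'
#' @param curve data.frame with columns `voltage`, `conductance` (>= 5 points
#'   spanning the transition)
#' @param start optional named list `gmin`, `gmax`, `v50`, `s`
#' @return list of class `BoltzmannFit`: `gmin`, `gmax`, `v50`, `s`,
#'   standard errors (`se`), `residualSd`, `fitted`, and the `nls` object
#' @export
boltzmannFit <- function(curve, start = NULL) {
  v <- curve$voltage; g <- curve$conductance
  if (length(v) < 5) stop("at least 5 points are required for a Boltzmann fit")
  if (stats::sd(g) < .Machine$double.eps^0.5 * max(1, abs(mean(g))))
    stop("degenerate flat data: no voltage dependence to fit")
  if (is.null(start)) start <- .boltzmannStart(v, g)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ gmin + (gmax - gmin) / (1 + exp((v50 - v) * s)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Boltzmann fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(list(gmin = unname(cf["gmin"]), gmax = unname(cf["gmax"]),
                 v50 = unname(cf["v50"]), s = unname(cf["s"]),
                 se = se, residualSd = stats::sigma(fit),
                 fitted = stats::fitted(fit), nls = fit),
            class = "BoltzmannFit")
}

#' Per-cell effect summary from paired Boltzmann fits
#'
#' `dV50 = V50(treated) - V50(control)` (mV) and
#' `dGmax = Gmax(treated)/Gmax(control) - 1`, expressed in percent. Both fits
#' must come from the same cell.
#'
#' @param control,treated `BoltzmannFit` objects for the same cell
#' @return list with `dV50` (mV) and `dGmaxPct` (%)
#' @export
effectSummary <- function(control, treated) {
  list(dV50 = treated$v50 - control$v50,
       dGmaxPct = 100 * (treated$gmax / control$gmax - 1))
}

#' Fit the Hill concentration-response model
#'
#' Unweighted least squares of `dEffect = dEffectMax / (1 + (L50/[L])^|H|)`.
#' The Hill coefficient is constrained to `|H| = hill` (default 1, the
#' customary robustness constraint for sparse dose ranges) and its direction
#' sign is recorded as metadata rather than fitted; `effectMax` may optionally
#' be fixed as well, leaving L50 as the only free parameter.
#'
#' @param data data.frame with columns `conc` (> 0) and `effect`
#' @param hill fixed |H|
#' @param hillSign recorded direction convention (+1 or -1), metadata only
#' @param effectMax optional fixed maximal effect; `NULL` fits it
#' @return list of class `HillFit`: `effectMax`, `l50`, `hill`, `hillSign`,
#'   `constraints`, `se`, `fitted`, `nls`
#' @export
hillFit <- function(data, hill = 1, hillSign = sign(sum(data$effect)),
                    effectMax = NULL) {
  conc <- data$conc; eff <- data$effect
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(conc) < 3) stop("at least 3 concentrations are required")
  if (all(eff == 0)) stop("all-zero effects: nothing to fit")
  h <- abs(hill)
  l50Start <- conc[which.min(abs(abs(eff) - max(abs(eff)) / 2))]
  if (is.null(effectMax)) {
    emaxStart <- eff[which.max(abs(eff))] * 1.2
    fit <- tryCatch(
      minpack.lm::nlsLM(eff ~ emax / (1 + (l50 / conc)^h),
                        start = list(emax = emaxStart, l50 = l50Start),
                        lower = c(emax = -Inf, l50 = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("Hill fit did not converge: ",
                               conditionMessage(e)))
    cf <- stats::coef(fit)
    emax <- unname(cf["emax"]); l50 <- unname(cf["l50"])
    constraints <- sprintf("|H| fixed to %g", h)
  } else {
    emax <- effectMax
    fit <- tryCatch(
      minpack.lm::nlsLM(eff ~ emax / (1 + (l50 / conc)^h),
                        start = list(l50 = l50Start), lower = c(l50 = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("Hill fit did not converge: ",
                               conditionMessage(e)))
    l50 <- unname(stats::coef(fit)["l50"])
    constraints <- sprintf("|H| fixed to %g; effectMax fixed to %g", h, emax)
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(effectMax = emax, l50 = l50, hill = h,
                 hillSign = sign(hillSign), constraints = constraints,
                 se = se, fitted = stats::fitted(fit), nls = fit),
            class = "HillFit")
}

#' Fit a single exponential to a relaxation trace
#'
#' Least squares of `I(t) = A exp(-t/tau) + C` over a window starting after
#' the capacitive blank.
#'
#' @param trace data.frame with columns `time` (s), `current`
#' @param window fit window length, s (default 1, starting after the blank)
#' @param blank capacitive blank duration, s
#' @return list of class `TauFit`: `amplitude`, `tau` (s), `offset`, `window`,
#'   `nls`
#' @export
expTauFit <- function(trace, window = 1, blank = 0) {
  sel <- trace$time >= blank & trace$time <= blank + window
  t <- trace$time[sel]; i <- trace$current[sel]
  if (length(t) < 4) stop("fit window contains too few samples")
  c0 <- min(i) - 0.05 * abs(min(i))
  a0 <- i[1] - c0
  # crude tau from the time to decay to 1/e of the initial span
  target <- c0 + a0 / exp(1)
  tau0 <- t[which.min(abs(i - target))] - t[1]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(i ~ a * exp(-(t - t[1]) / tau) + cc,
                      start = list(a = a0, tau = tau0, cc = c0),
                      lower = c(a = -Inf, tau = 1e-9, cc = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  # report the amplitude referred to t = 0
  structure(list(amplitude = unname(cf["a"]) * exp(t[1] / cf[["tau"]]),
                 tau = unname(cf["tau"]), offset = unname(cf["cc"]),
                 window = c(blank, blank + window), nls = fit),
            class = "TauFit")
}

#' @export
print.BoltzmannFit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: Gmin = %.4g, Gmax = %.4g, V50 = %.4g mV, s = %.4g /mV\n",
              x$gmin, x$gmax, x$v50, x$s))
  invisible(x)
}

#' @export
print.HillFit <- function(x, ...) {
  cat(sprintf("Hill fit: effectMax = %.4g, L50 = %.4g, |H| = %g (sign %+d)\n  constraints: %s\n",
              x$effectMax, x$l50, x$hill, x$hillSign, x$constraints))
  invisible(x)
}

#' @export
print.TauFit <- function(x, ...) {
  cat(sprintf("Exponential fit: tau = %.4g s, amplitude = %.4g, offset = %.4g\n",
              x$tau, x$amplitude, x$offset))
  invisible(x)
}
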