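test_that("G(V) extraction passes tabulated tails through and reads traces", {
  tab <- data.frame(voltage = seq(-80, 60, by = 10), tail = seq_len(15))
  gv <- gvFromTails(tab)
  expect_equal(nrow(gv), 15)
  expect_equal(gv$conductance, seq_len(15))
  expect_error(gvFromTails(data.frame(voltage = c(0, 0), tail = 1:2)),
               "duplicate")
  # traces with known plateau amplitudes after the capacitive blank
  volts <- c(-40, 0, 40)
  amps <- c(0.2, 0.7, 1.1)
  traces <- lapply(amps, function(a) {
    t <- seq(0, 0.05, by = 0.001)
    data.frame(time = t, current = ifelse(t < 0.005, 10, a))
  })
  gv2 <- gvFromTails(list(voltage = volts, traces = traces))
  expect_equal(gv2$conductance, amps)
})

test_that("Boltzmann fit recovers noiseless parameters to 1e-6", {
  truth <- list(gmin = 0, gmax = 1, v50 = -20, s = 0.1)
  gv <- generateGVData(seq(-80, 60, by = 10), truth$gmin, truth$gmax,
                       truth$v50, truth$s)
  fit <- boltzmannFit(gv)
  expect_lt(abs(fit$gmin - truth$gmin), 1e-6)
  expect_lt(abs(fit$gmax - truth$gmax), 1e-6)
  expect_lt(abs(fit$v50 - truth$v50), 1e-6)
  expect_lt(abs(fit$s - truth$s), 1e-6)
  # G at the fitted V50 equals (Gmin + Gmax) / 2 by construction
  expect_equal(boltzmannModel(fit$v50, fit$gmin, fit$gmax, fit$v50, fit$s),
               (fit$gmin + fit$gmax) / 2)
  # recovery also succeeds from perturbed initial guesses (x0.5 to x2)
  for (fac in c(0.5, 2)) {
    f2 <- boltzmannFit(gv, start = list(gmin = 0.01, gmax = truth$gmax * fac,
                                        v50 = truth$v50 * fac,
                                        s = truth$s * fac))
    expect_lt(abs(f2$v50 - truth$v50), 1e-6)
  }
  expect_error(boltzmannFit(data.frame(voltage = 1:6,
                                       conductance = rep(1, 6))),
               "flat")
})

test_that("Boltzmann fit is equivariant under voltage translation", {
  gv <- generateGVData(seq(-80, 60, by = 10), 0.1, 1.2, -25, 0.08,
                       noiseSd = 0.02, seed = 5)
  f0 <- boltzmannFit(gv)
  gvShift <- gv; gvShift$voltage <- gv$voltage + 37
  f1 <- boltzmannFit(gvShift)
  expect_lt(abs((f1$v50 - f0$v50) - 37), 1e-6)
  expect_lt(abs(f1$s - f0$s), 1e-6)
  expect_lt(abs(f1$gmax - f0$gmax), 1e-6)
})

test_that("median V50 error is below 1 mV at 2% noise on a 15-point grid", {
  errs <- vapply(seq_len(100), function(sd) {
    gv <- generateGVData(seq(-80, 60, by = 10), 0, 1, -20, 0.1,
                         noiseSd = 0.02, seed = 1000 + sd)
    abs(boltzmannFit(gv)$v50 - (-20))
  }, 1)
  expect_lt(stats::median(errs), 1)
})

test_that("effect summaries are paired differences of fit parameters", {
  ctrl <- structure(list(gmin = 0, gmax = 1.0, v50 = -20, s = 0.1),
                    class = "BoltzmannFit")
  trt <- structure(list(gmin = 0, gmax = 1.49, v50 = -34.3, s = 0.1),
                   class = "BoltzmannFit")
  es <- effectSummary(ctrl, trt)
  expect_equal(es$dV50, -14.3)
  expect_equal(es$dGmaxPct, 49)
  es0 <- effectSummary(ctrl, ctrl)
  expect_equal(es0$dV50, 0)
  expect_equal(es0$dGmaxPct, 0)
})

test_that("Hill fit recovers noiseless parameters and honours constraints", {
  conc <- c(0.7, 2, 7, 20, 70, 200)
  dr <- generateDoseResponse(conc, effectMax = -25, l50 = 15, hill = 1)
  fit <- hillFit(dr)
  expect_lt(abs(fit$effectMax - (-25)), 1e-6)
  expect_lt(abs(fit$l50 - 15), 1e-6)
  # effect at L50 is half-maximal in the fitted model
  expect_equal(hillModel(fit$l50, fit$effectMax, fit$l50, fit$hill),
               fit$effectMax / 2)
  fitC <- hillFit(dr, effectMax = -25)
  expect_lt(abs(fitC$l50 - 15), 1e-6)
  expect_match(fitC$constraints, "effectMax fixed")
  expect_error(hillFit(data.frame(conc = c(-1, 2, 3), effect = 1:3)),
               "positive")
  expect_error(hillFit(data.frame(conc = c(1, 2, 3), effect = c(0, 0, 0))),
               "all-zero")
})

test_that("constrained Hill fit matches a grid-search oracle over L50", {
  conc <- c(2, 7, 20, 70)
  dr <- generateDoseResponse(conc, effectMax = -25, l50 = 18, hill = 1,
                             noiseSd = 1.5, seed = 9)
  fit <- hillFit(dr, effectMax = -25)
  grid <- seq(1, 100, by = 0.05)
  sse <- vapply(grid, function(l)
    sum((dr$effect - hillModel(conc, -25, l, 1))^2), 1)
  expect_lt(abs(fit$l50 - grid[which.min(sse)]), 0.05)
})

test_that("median relative L50 error stays below 25% under 10% noise", {
  conc <- c(0.7, 2, 7, 20, 35, 70)   # six concentrations up to 70
  errs <- vapply(seq_len(100), function(sd) {
    dr <- generateDoseResponse(conc, effectMax = -25, l50 = 15, hill = 1,
                               noiseSd = 2.5, seed = 2000 + sd)
    abs(hillFit(dr, effectMax = -25)$l50 - 15) / 15
  }, 1)
  expect_lt(stats::median(errs), 0.25)
})

test_that("exponential fit recovers tau and is scale equivariant", {
  t <- seq(0, 1, by = 0.002)
  tr <- generateExpTrace(t, amplitude = 1, tau = 0.3, offset = 0.1)
  fit <- expTauFit(tr, window = 1)
  expect_lt(abs(fit$amplitude - 1), 1e-6)
  expect_lt(abs(fit$tau - 0.3), 1e-6)
  expect_lt(abs(fit$offset - 0.1), 1e-6)
  # rescaling the current rescales the amplitude but not tau
  tr2 <- tr; tr2$current <- 7 * tr$current
  fit2 <- expTauFit(tr2, window = 1)
  expect_lt(abs(fit2$tau - fit$tau), 1e-8)
  expect_lt(abs(fit2$amplitude - 7 * fit$amplitude), 1e-6)
  # median relative tau error < 5% at 5% noise
  errs <- vapply(seq_len(100), function(sd) {
    trn <- generateExpTrace(t, 1, 0.3, 0.1, noiseSd = 0.05, seed = 3000 + sd)
    abs(expTauFit(trn, window = 1)$tau - 0.3) / 0.3
  }, 1)
  expect_lt(stats::median(errs), 0.05)
})
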