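em_fix <- function(tau = 1e-3, c1 = 0, c2 = 1e-4)
  exchange_model(c1 = c1, c2 = c2, tau = tau, D = 4.4e-6)

test_that("exchange model ties tau, t0 and L together consistently", {
  em <- exchange_model(c1 = 0, c2 = 1e-4, L = 0.02, D = 1.96e-5)
  expect_equal(em$tau, 4 * 0.02^2 / (1.96e-5 * pi^2), tolerance = 1e-12)
  expect_equal(em$t0 / em$tau, log(4 / pi), tolerance = 1e-12)
  expect_equal(round(em$t0 / em$tau, 2), 0.24)
  # round trip L -> tau -> L and the quadratic / inverse scaling laws
  expect_equal(length_from_tau(tau_from_geometry(0.01, 4.4e-6), 4.4e-6),
               0.01, tolerance = 1e-12)
  expect_equal(tau_from_geometry(0.01 * sqrt(2), 4.4e-6),
               2 * tau_from_geometry(0.01, 4.4e-6), tolerance = 1e-12)
  expect_equal(tau_from_geometry(0.01, 2 * 4.4e-6),
               tau_from_geometry(0.01, 4.4e-6) / 2, tolerance = 1e-12)
  expect_error(tau_from_geometry(-1, 1e-5), "positive")
})

test_that("series solution honors its limits and truncation bound", {
  em <- em_fix()
  amp <- abs(em$c1 - em$c2)
  expect_identical(series_concentration(em, 0), em$c1)
  expect_lt(abs(series_concentration(em, 10 * em$tau) - em$c2), 1e-4 * amp)
  # delayed exponential approximates the series: < 1% at tau, < 2% beyond tau/2
  tt <- seq(0.5 * em$tau, 8 * em$tau, length.out = 200)
  err <- abs(series_concentration(em, tt) - approx_concentration(em, tt))
  expect_lt(max(err), 0.02 * amp)
  expect_lt(abs(series_concentration(em, em$tau) -
                  approx_concentration(em, em$tau)), 0.01 * amp)
  # the approximation error decays monotonically after the delay
  tt2 <- seq(1.2 * em$t0, 6 * em$tau, length.out = 40)
  err2 <- abs(series_concentration(em, tt2) - approx_concentration(em, tt2))
  expect_true(all(diff(err2) <= 1e-12 * amp))
})

test_that("delayed exponential: delay branch conventions", {
  em <- em_fix(c1 = 2e-5, c2 = 1e-4)
  expect_equal(approx_concentration(em, em$t0), em$c1, tolerance = 1e-12)
  expect_equal(approx_concentration(em, em$t0 / 2), em$c1)
  expect_equal(approx_concentration(em, em$t0 / 2, strict_zero = TRUE), 0)
  em0 <- em_fix(c1 = 0)
  expect_equal(approx_concentration(em0, em0$t0 * 0.9), 0)
  expect_equal(approx_concentration(em, 50 * em$tau), em$c2,
               tolerance = 1e-12)
})

test_that("tau rescaling by diffusion coefficients", {
  # K+ -> cAMP: 1.1 ms * (1.96e-5 / 4.4e-6) = 4.9 ms
  expect_equal(rescale_tau(1.1e-3, 1.96e-5, 4.4e-6),
               1.1e-3 * 1.96 / 0.44, tolerance = 1e-12)
  expect_equal(rescale_tau(1.1e-3, "K", "cAMP"), 4.9e-3, tolerance = 1e-3)
  expect_equal(rescale_tau(2e-3, 5e-6, 5e-6), 2e-3)
  expect_equal(rescale_tau(2e-3, 5e-6, 2.5e-6), 4e-3)
  tab <- diffusion_coefficients()
  expect_setequal(c("K", "cAMP", "cGMP") %in% tab$species, TRUE)
  expect_equal(tab$D_cm2_per_s[tab$species == "K"], 1.96e-5)
})

test_that("exchange time constant is recovered from K+ jump relaxations", {
  make_jump <- function(tau, noise_sd = 0, seed = NULL) {
    em <- exchange_model(c1 = 1, c2 = 0.8, tau = tau)  # normalized current
    tt <- seq(0, 12 * tau, by = tau / 50)
    y <- approx_concentration(em, tt) * 100  # pA scale
    if (noise_sd > 0) {
      if (!is.null(seed)) set.seed(seed)
      y <- y + rnorm(length(y), 0, noise_sd * max(abs(y)))
    }
    channel_trace(tt, current_pA = y)
  }
  fit <- fit_exchange_tau(make_jump(1.1e-3), tau0 = 3e-3)
  expect_true(fit$converged)
  expect_false(fit$low_confidence)
  expect_lt(abs(fit$tau / 1.1e-3 - 1), 1e-3)
  expect_equal(fit$t0, fit$tau * log(4 / pi))
  fit2 <- fit_exchange_tau(make_jump(18.7e-3, noise_sd = 0.01, seed = 11),
                           tau0 = 5e-3)
  expect_lt(abs(fit2$tau / 18.7e-3 - 1), 0.05)
  set.seed(3)
  flat <- channel_trace(seq(0, 0.1, 1e-4),
                        current_pA = rnorm(1001, 50, 0.5))
  expect_true(fit_exchange_tau(flat)$low_confidence)
})

test_that("protocol correction chains delayed-exponential relaxations", {
  # tau -> 0 limit reproduces the nominal rectangular protocol
  prot <- protocol(c(1e-6, 1e-5, 0), c(0.01, 0.01, 0.01))
  rect <- correct_protocol(prot, 0, dt = 1e-3)
  expect_equal(rect$conc_M, rep(c(1e-6, 1e-5, 0), each = 10))
  # one long step ends within 1e-4 of its target
  tau <- 2e-3
  one <- correct_protocol(protocol(1e-4, 10 * tau), tau, dt = 1e-4)
  expect_lt(abs(one$conc_M[nrow(one)] - 1e-4), 1e-4 * 1e-4 * exp(1))
  # single step equals the delayed-exponential evaluated at interval midpoints
  em <- exchange_model(c1 = 0, c2 = 1e-4, tau = tau)
  mids <- one$time_s + 1e-4 / 2
  expect_equal(one$conc_M, approx_concentration(em, mids), tolerance = 1e-12)
  # two opposite fast steps of duration tau: peak = 1 - exp(-(1 - ln(4/pi)))
  updown <- correct_protocol(protocol(c(1e-4, 0), c(tau, tau)), tau,
                             dt = tau / 1000)
  peak_frac <- 1 - exp(-(1 - log(4 / pi)))       # ~0.53 of the amplitude
  expect_equal(max(updown$conc_M) / 1e-4, peak_frac, tolerance = 2e-3)
  expect_equal(round(peak_frac, 2), 0.53)
  # bounded by the nominal levels (with the initial level included)
  expect_true(all(updown$conc_M >= 0 & updown$conc_M <= 1e-4))
  expect_error(correct_protocol(protocol(1e-6, 1e-4), 1e-3, dt = 5e-4),
               "sampling interval")
})
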