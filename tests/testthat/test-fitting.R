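test_that("summed squared residuals objective", {
  tt <- seq(0, 0.1, 1e-3)
  a <- channel_trace(tt, po = rep(0.3, length(tt)))
  expect_equal(objective_ssr(a, a), 0)
  b <- channel_trace(tt, po = rep(0.3 + 0.02, length(tt)))
  expect_equal(objective_ssr(a, b), length(tt) * 0.02^2, tolerance = 1e-12)
  set.seed(1)
  x <- runif(50); y <- runif(50)
  expect_equal(objective_ssr(x, y), objective_ssr(rev(x), rev(y)))
  misaligned <- channel_trace(tt + 0.5, po = rep(0.3, length(tt)))
  expect_error(objective_ssr(a, misaligned), "grid")
})

test_that("correlation matrix from covariance", {
  expect_equal(correlation_matrix(diag(3)), diag(3), ignore_attr = TRUE)
  rho <- correlation_matrix(matrix(c(4, 2, 2, 1), 2))
  expect_equal(rho[1, 2], 1)
  expect_equal(diag(rho), c(1, 1))
  # invariance under positive diagonal rescaling of the parameters
  cov <- matrix(c(4, 1.2, 1.2, 2), 2)
  D <- diag(c(10, 0.2))
  expect_equal(correlation_matrix(D %*% cov %*% D),
               correlation_matrix(cov), tolerance = 1e-12)
  degenerate <- correlation_matrix(matrix(c(1, 0, 0, 0), 2))
  expect_equal(attr(degenerate, "undefined"), 2L)
  expect_true(is.na(degenerate[1, 2]))
})

test_that("reduced SSR arithmetic and underdetermination guard", {
  expect_equal(reduced_ssr(4.4, 23, 1), 0.2)
  expect_equal(reduced_ssr(0, 23, 4), 0)
  s <- vapply(1:21, function(k) reduced_ssr(4.4, 23, k), numeric(1))
  expect_true(all(diff(s) > 0))
  expect_error(reduced_ssr(4.4, 23, 23), "underdetermined")
  expect_error(reduced_ssr(4.4, 4, 6), "underdetermined")
})

test_that("noiseless self-fit recovers the generating parameters", {
  fx <- coop_fixture()
  prot <- staircase_protocol(5e-7, 1e-4, 6, 0.2, direction = "updown")
  conc <- correct_protocol(prot, 1.1e-3)
  data <- simulate_deterministic(fx$model, fx$theta, conc)
  fit <- global_fit(fx$model, conc, data,
                    theta0 = fx$theta * c(4, 0.3, 0.5, 2), protocol = prot)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta_hat / fx$theta - 1)), 0.01)
  expect_lt(fit$S, 1e-10 * fit$n_points)
  expect_equal(fit$sd, sqrt(diag(fit$cov))[fit$free])
  expect_equal(fit$sigma2_bar, fit$S / (fit$n_points - fit$k - 1))
  expect_equal(fit$chi2, fit$S / fit$sigma2_bar)
  expect_equal(fit$n_jumps, count_jumps(prot))
  expect_equal(fit$reduced_ssr, fit$S / (fit$n_jumps - fit$k))
})

test_that("ignoring slow exchange in the forward model degrades the fit", {
  co <- co_fixture()
  tau_s <- 50e-3
  prot <- protocol(c(4e-5, 0), c(0.4, 0.3))
  corrected <- correct_protocol(prot, tau_s)
  rectangular <- correct_protocol(prot, 0)
  data <- simulate_deterministic(co$model, co$theta, corrected)
  f_cor <- global_fit(co$model, corrected, data,
                      theta0 = co$theta * c(2, 0.5))
  f_rect <- global_fit(co$model, rectangular, data,
                       theta0 = co$theta * c(2, 0.5))
  expect_gt(f_rect$S, 100 * f_cor$S)
  expect_lt(max(abs(f_cor$theta_hat / co$theta - 1)), 0.01)
})

test_that("model ranking orders by reduced SSR and segregates underdetermined fits", {
  stub <- function(label, k, S, n_jumps = 23, hash = "h",
                   underdet = FALSE)
    chankin:::new_fit_result(
      model_label = label, k = as.integer(k), S = S,
      n_jumps = as.integer(n_jumps),
      reduced_ssr = if (n_jumps > k) S / (n_jumps - k) else NA_real_,
      converged = TRUE, underdetermined = underdet, data_hash = hash)
  # equal S: the model with more parameters ranks worse
  r <- rank_models(list(stub("a", 2, 1), stub("b", 6, 1)))
  expect_equal(vapply(r$ranked, `[[`, character(1), "model_label"),
               c("a", "b"))
  one <- rank_models(list(stub("solo", 2, 1)))
  expect_length(one$ranked, 1)
  r2 <- rank_models(list(stub("a", 2, 1), stub("u", 8, 0.5,
                                               underdet = TRUE)))
  expect_equal(length(r2$ranked), 1)
  expect_equal(r2$unranked[[1]]$model_label, "u")
  expect_error(rank_models(list(stub("a", 2, 1),
                                stub("b", 2, 1, hash = "other"))),
               "different data")
})

test_that("model recovery: the generating cooperative scheme outranks simpler schemes", {
  fx <- coop_fixture()
  prot <- staircase_protocol(5e-7, 1e-4, 8, 0.15, direction = "updown")
  conc <- correct_protocol(prot, 1.1e-3)
  data <- simulate_stochastic(fx$model, fx$theta, conc, 1000, seed = 21)
  nj <- count_jumps(prot)
  fits <- list(
    global_fit(build_sequential_model(1, TRUE), conc, data,
               theta0 = c(5e6, 500), protocol = prot),
    global_fit(build_sequential_model(2, FALSE), conc, data,
               theta0 = c(5e6, 500), protocol = prot),
    global_fit(fx$model, conc, data, theta0 = fx$theta * c(2, 0.5, 0.5, 2),
               protocol = prot))
  r <- rank_models(fits)
  labels <- vapply(r$ranked, `[[`, character(1), "model_label")
  expect_equal(labels[1], "4s4p")
  expect_equal(labels[length(labels)], "3s2p")
})

test_that("Hill fits recover exact parameters and expose cooperativity", {
  cc <- c(0, 10^seq(-6.5, -4.5, length.out = 9), 1e-4)
  resp <- 80 / (1 + (2e-6 / cc)^2)
  resp[cc == 0] <- 0
  resp[cc == 1e-4] <- 80   # idealized: the saturating point gives Imax
  h <- hill_fit(cc, resp)
  expect_lt(abs(h$ec50 / 2e-6 - 1), 1e-6)
  expect_lt(abs(h$hill_n / 2 - 1), 1e-6)
  expect_equal(1 / (1 + (h$ec50 / h$ec50)^h$hill_n), 0.5)
  expect_error(hill_fit(c(0, 1e-6, 1e-4), c(0, 0.5, 1)), "3 usable")
  # quasi-equilibrium staircase of the cooperative scheme: n > 1
  fx <- coop_fixture()
  prot <- staircase_protocol(2e-7, 1e-4, 10, 2.5)
  conc <- correct_protocol(prot, 1.1e-3, dt = 1e-3)
  tr <- simulate_deterministic(fx$model, fx$theta, conc)
  lr <- late_response(tr, prot, list(last_fraction = 0.05))
  hs <- hill_fit(lr$conc_M, lr$response)
  expect_gt(hs$hill_n, 1)
  expect_lt(abs(log10(hs$ec50 / 5e-6)), 0.5)
})

test_that("underdetermination report flags near-unit correlations", {
  id_fit <- chankin:::new_fit_result(corr = diag(3))
  expect_equal(nrow(underdetermination_report(id_fit)), 0)
  corr <- matrix(c(1, 0.9995, 0.5, 0.9995, 1, 0.2, 0.5, 0.2, 1), 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- chankin:::new_fit_result(corr = corr)
  rep1 <- underdetermination_report(fit, threshold = 0.999)
  expect_equal(nrow(rep1), 1)
  expect_setequal(c(rep1$param_i, rep1$param_j), c("a", "b"))
  expect_equal(nrow(underdetermination_report(fit, threshold = 1.0)), 0)
})
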