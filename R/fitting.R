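# Global least-squares fitting of gating schemes to open-probability traces
# under exchange-corrected concentration protocols, with the uncertainty and
# model-ranking statistics used for kinetic model discrimination:
#   S           summed squared residuals (the minimized quantity, since all
#               point variances are taken as equal),
#   sigma2_bar  S / (n - k - 1), the estimated common variance,
#   chi2        S / sigma2_bar,
#   SD(theta_j) sqrt(cov_jj) with cov = sigma2_bar * (J'J)^-1,
#   rho_ij      cov_ij / (sigma_i sigma_j),
#   reduced SSR S / (n_jumps - k), counting concentration jumps (not the
#               mutually correlated sample points) as degrees of freedom.

#' Summed squared residuals between two aligned traces
#'
#' @param po_measured,po_computed [channel_trace()]s with `po` columns on
#'   identical time grids (plain numeric vectors of equal length are also
#'   accepted).
#' @return Non-negative scalar `S`.
#' @export
objective_ssr <- function(po_measured, po_computed) {
  get_po <- function(x) if (inherits(x, "channel_trace")) x$po else
    as.numeric(x)
  if (inherits(po_measured, "channel_trace") &&
      inherits(po_computed, "channel_trace")) {
    if (nrow(po_measured) != nrow(po_computed) ||
        any(abs(po_measured$time_s - po_computed$time_s) > 1e-9))
      stop("traces are not on the same time grid")
  }
  a <- get_po(po_measured); b <- get_po(po_computed)
  if (length(a) != length(b)) stop("traces have different lengths")
  sum((a - b)^2)
}

fd_jacobian <- function(f, theta, rel_step = 1e-6) {
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- rel_step * abs(theta[j])
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

new_fit_result <- function(...) {
  structure(list(...), class = "kinetic_fit")
}

#' Global fit of a kinetic model to an open-probability trace
#'
#' Minimizes the summed squared residuals between a measured trace and the
#' forward model — [simulate_deterministic()] driven by the (ideally
#' exchange-corrected) concentration trace — over the model's free rate
#' constants. Optimization uses the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm]) on log-parameters, which enforces positivity.
#' Parameter uncertainty is derived from a central-finite-difference
#' Jacobian at the optimum: `cov = sigma2_bar * (J'J)^-1` with
#' `sigma2_bar = S / (n - k - 1)`, standard errors `sqrt(cov_jj)`, and the
#' correlation matrix `rho_ij = cov_ij / (sigma_i sigma_j)`. A nearly rank
#' deficient Jacobian (singular-value ratio below 1e-10) marks the fit
#' underdetermined.
#'
#' @param model a `kinetic_model`.
#' @param conc_trace concentration trace driving the forward model
#'   ([correct_protocol()] output, or a rectangular trace for comparison).
#' @param data measured [channel_trace()] with a `po` column on the same
#'   grid.
#' @param theta0 positive starting values (named or in `model$free_params`
#'   order).
#' @param fixed optional named values for parameters to hold fixed.
#' @param lower,upper optional named bounds on the fitted parameters.
#' @param max_iter Levenberg-Marquardt iteration cap (default 100).
#' @param protocol optional nominal protocol used to count concentration
#'   jumps for the reduced-SSR statistic (or give `n_jumps` directly).
#' @param n_jumps number of concentration jumps (degrees of freedom).
#' @param weights optional per-point weights (reciprocal variances); by
#'   default all variances are taken equal and plain `S` is minimized.
#' @return A `kinetic_fit` with fields `theta_hat`, `sd`, `cov`, `corr`,
#'   `S`, `sigma2_bar`, `chi2`, `n_points`, `k`, `n_jumps`, `reduced_ssr`,
#'   `converged`, `underdetermined`, `n_iter`, `ssr_trace`.
#' @export
global_fit <- function(model, conc_trace, data, theta0, fixed = NULL,
                       lower = NULL, upper = NULL, max_iter = 100,
                       protocol = NULL, n_jumps = NULL, weights = NULL) {
  stopifnot(inherits(data, "channel_trace"), !is.null(data$po))
  if (nrow(conc_trace) != nrow(data) ||
      any(abs(conc_trace$time_s - data$time_s) > 1e-9))
    stop("data and concentration trace are not on the same time grid")
  pars <- model$free_params
  theta0 <- check_theta(model, if (!is.null(names(theta0)))
    theta0[pars] else theta0)
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% pars)) stop("unknown fixed parameter name")
    theta0[names(fixed)] <- fixed
  }
  free <- setdiff(pars, names(fixed))
  if (length(free) == 0) stop("no free parameters left to fit")
  w <- if (is.null(weights)) rep(1, nrow(data)) else {
    if (length(weights) != nrow(data)) stop("weights length mismatch")
    weights
  }
  sw <- sqrt(w)
  po_m <- data$po

  forward <- function(theta) {
    simulate_deterministic(model, theta, conc_trace)$po
  }
  # extreme trial rates can overflow the matrix exponential; a constant
  # penalty residual makes the line search back off instead of aborting
  forward_safe <- function(theta) {
    tryCatch(forward(theta), error = function(e) rep(1e3, nrow(data)))
  }
  assemble <- function(phi) {
    th <- theta0
    th[free] <- exp(phi)
    th
  }
  resid_fn <- function(phi) sw * (forward_safe(assemble(phi)) - po_m)

  lm <- minpack.lm::nls.lm(
    par = setNames(log(theta0[free]), free),
    lower = if (!is.null(lower)) log(lower[free]) else NULL,
    upper = if (!is.null(upper)) log(upper[free]) else NULL,
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-12, ptol = 1e-12))
  theta_hat <- assemble(lm$par)
  r <- forward(theta_hat) - po_m
  S <- sum(w * r^2)
  n <- length(r)
  k <- length(free)
  sigma2_bar <- S / (n - k - 1)
  chi2 <- S / sigma2_bar

  J <- fd_jacobian(function(th_free) {
    th <- theta_hat; th[free] <- th_free
    sw * forward(th)
  }, theta_hat[free])
  sv <- svd(J)
  d <- sv$d
  singular <- any(d < max(d) * 1e-10)
  d_safe <- pmax(d, max(d) * 1e-15)
  cov <- sigma2_bar * sv$v %*% (t(sv$v) / d_safe^2)
  dimnames(cov) <- list(free, free)
  corr <- correlation_matrix(cov)
  sds <- sqrt(pmax(diag(cov), 0))

  if (is.null(n_jumps) && !is.null(protocol)) n_jumps <- count_jumps(protocol)
  converged <- lm$info %in% 1:3
  rssr <- if (!is.null(n_jumps) && n_jumps > k) S / (n_jumps - k) else NA_real_
  new_fit_result(
    model_label = model$label,
    theta_hat = theta_hat, free = free, fixed = fixed,
    sd = setNames(sds, free), cov = cov, corr = corr,
    S = S, sigma2_bar = sigma2_bar, chi2 = chi2,
    n_points = n, k = k,
    n_jumps = if (is.null(n_jumps)) NA_integer_ else as.integer(n_jumps),
    reduced_ssr = rssr,
    converged = converged,
    underdetermined = singular || !converged ||
      (!is.null(n_jumps) && n_jumps <= k),
    n_iter = lm$niter, ssr_trace = as.numeric(lm$rsstrace),
    message = lm$message,
    data_hash = sprintf("%d:%.10e:%.10e", n, sum(po_m), sum(po_m^2))
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Global fit of model %s: S = %.6g on %d points (%d free params)\n",
              x$model_label, x$S, x$n_points, x$k))
  est <- data.frame(estimate = x$theta_hat[x$free], sd = x$sd)
  print(signif(est, 4))
  cat(sprintf("  reduced SSR = %s (n_jumps = %s), %s%s, %d iterations\n",
              format(x$reduced_ssr, digits = 4), format(x$n_jumps),
              if (x$converged) "converged" else "NOT converged",
              if (x$underdetermined) " [underdetermined]" else "",
              x$n_iter))
  invisible(x)
}

#' Correlation matrix from a covariance matrix
#'
#' `rho_ij = cov_ij / (sigma_i sigma_j)` with the diagonal set exactly
#' to 1. Parameters with zero variance yield `NA` rows/columns and are
#' reported in the `undefined` attribute.
#'
#' @param cov symmetric positive semi-definite covariance matrix.
#' @return Correlation matrix with `|rho| <= 1`.
#' @export
correlation_matrix <- function(cov) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || max(abs(cov - t(cov))) >
      1e-8 * max(abs(cov), 1e-300))
    stop("cov must be a symmetric matrix")
  sig <- sqrt(pmax(diag(cov), 0))
  zero <- sig == 0
  sig[zero] <- NA_real_
  rho <- cov / outer(sig, sig)
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- ifelse(zero, NA_real_, 1)
  attr(rho, "undefined") <- which(zero)
  rho
}

#' Reduced summed squared residuals
#'
#' `S / (n_jumps - k)`: the residual sum normalized by the degrees of
#' freedom, counted conservatively as the number of concentration jumps in
#' the protocol (successive relaxation samples are strongly correlated, so
#' the sample count would overstate the information content), minus the
#' number of free parameters. The statistic used to rank competing models.
#'
#' @param S summed squared residuals.
#' @param n_jumps number of concentration jumps.
#' @param k number of free parameters.
#' @return Scalar; errors when `n_jumps <= k` (underdetermined).
#' @export
reduced_ssr <- function(S, n_jumps, k) {
  if (n_jumps <= k)
    stop("underdetermined: n_jumps must exceed the number of free parameters")
  S / (n_jumps - k)
}

#' Rank competing model fits by reduced SSR
#'
#' Fits must be to identical data with the same jump count. Converged,
#' determined fits are ordered by ascending reduced SSR; underdetermined or
#' non-converged fits are listed separately and never ranked.
#'
#' @param fits list of `kinetic_fit` objects.
#' @return List with `ranked` (ordered fits), `unranked`, and a summary
#'   `table` (one row per fit, in input order).
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1)
    stop("fits were made on different data; ranking is not meaningful")
  nj <- vapply(fits, `[[`, integer(1), "n_jumps")
  if (length(unique(nj)) != 1)
    stop("fits disagree on the number of concentration jumps")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model_label"),
    k = vapply(fits, `[[`, integer(1), "k"),
    S = vapply(fits, `[[`, numeric(1), "S"),
    reduced_ssr = vapply(fits, `[[`, numeric(1), "reduced_ssr"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    underdetermined = vapply(fits, `[[`, logical(1), "underdetermined"),
    stringsAsFactors = FALSE
  )
  ok <- !tab$underdetermined & !is.na(tab$reduced_ssr)
  ranked <- fits[which(ok)[order(tab$reduced_ssr[ok])]]
  list(ranked = ranked, unranked = fits[!ok], table = tab)
}

#' Report jointly unidentifiable parameter pairs
#'
#' Lists every off-diagonal parameter pair whose correlation magnitude
#' reaches `threshold`. A coefficient of (essentially) one means the data
#' constrain only a combination — typically the ratio — of the two rates,
#' not their individual values; the classic symptom of fitting with an
#' idealized rectangular protocol when the true exchange is slow.
#'
#' @param fit a `kinetic_fit`.
#' @param threshold flag pairs with `|rho| >= threshold` (default 0.999).
#' @return data.frame with `param_i`, `param_j`, `rho` (possibly 0 rows).
#' @export
underdetermination_report <- function(fit, threshold = 0.999) {
  corr <- fit$corr
  nm <- rownames(corr)
  out <- data.frame(param_i = character(0), param_j = character(0),
                    rho = numeric(0), stringsAsFactors = FALSE)
  if (is.null(corr) || nrow(corr) < 2) return(out)
  for (i in seq_len(nrow(corr) - 1))
    for (j in (i + 1):ncol(corr))
      if (is.finite(corr[i, j]) && abs(corr[i, j]) >= threshold)
        out <- rbind(out, data.frame(param_i = nm[i], param_j = nm[j],
                                     rho = corr[i, j],
                                     stringsAsFactors = FALSE))
  out
}

#' Hill fit of a concentration-activation relationship
#'
#' Fits `I/Imax = 1 / (1 + (EC50 / c)^n)` to per-concentration responses.
#' The zero-concentration response is used for offset correction and the
#' saturating (highest) concentration for normalization; with
#' `exclude_zero_and_sat = TRUE` (the convention) those points are excluded
#' from the fitted set. Requires at least 3 usable points.
#'
#' @param concs concentrations in molar.
#' @param responses raw responses (current or Po), same length.
#' @param exclude_zero_and_sat drop the zero and saturating points from the
#'   fit (default TRUE).
#' @return A `hill_fit`: `ec50`, `hill_n`, `sd_ec50`, `sd_hill_n`,
#'   `residual_norm`, `n_used`, `converged`.
#' @export
hill_fit <- function(concs, responses, exclude_zero_and_sat = TRUE) {
  stopifnot(length(concs) == length(responses))
  cmax <- max(concs)
  i_sat <- max(which(concs == cmax))       # tie-break: latest occurrence
  offset <- if (any(concs == 0)) mean(responses[concs == 0]) else 0
  span <- responses[i_sat] - offset
  if (span == 0) stop("saturating response equals the offset; cannot normalize")
  y <- (responses - offset) / span
  use <- concs > 0
  if (exclude_zero_and_sat) use <- use & concs != cmax
  cc <- concs[use]; yy <- y[use]
  if (length(cc) < 3)
    stop("need at least 3 usable points after exclusion for a Hill fit")
  start <- c(log_ec50 = log(stats::median(cc)), log_n = log(1.5))
  fn <- function(par) 1 / (1 + (exp(par[["log_ec50"]]) / cc)^
                             exp(par[["log_n"]])) - yy
  lm <- minpack.lm::nls.lm(par = start, fn = fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  ec50 <- exp(lm$par[["log_ec50"]]); hn <- exp(lm$par[["log_n"]])
  J <- fd_jacobian(function(th)
    1 / (1 + (th[1] / cc)^th[2]), c(ec50, hn))
  S <- sum(lm$fvec^2)
  dof <- max(length(cc) - 2 - 1, 1)
  cov <- tryCatch(S / dof * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, 2, 2))
  structure(list(ec50 = ec50, hill_n = hn,
                 sd_ec50 = sqrt(abs(cov[1, 1])),
                 sd_hill_n = sqrt(abs(cov[2, 2])),
                 residual_norm = sqrt(S), n_used = length(cc),
                 converged = lm$info %in% 1:3),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: EC50 = %.4g uM (sd %.2g), n = %.3g (sd %.2g), %d points\n",
    1e6 * x$ec50, 1e6 * x$sd_ec50, x$hill_n, x$sd_hill_n, x$n_used))
  invisible(x)
}

#' Serialize a fit result as a JSON report
#'
#' @param fit a `kinetic_fit`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(
    model = fit$model_label,
    theta = as.list(fit$theta_hat),
    sd = as.list(fit$sd),
    corr = fit$corr,
    S = fit$S, sigma2_bar = fit$sigma2_bar, chi2 = fit$chi2,
    n_points = fit$n_points, k = fit$k, n_jumps = fit$n_jumps,
    reduced_ssr = fit$reduced_ssr,
    converged = fit$converged, underdetermined = fit$underdetermined,
    n_iter = fit$n_iter, ssr_trace = fit$ssr_trace
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", matrix = "rowmajor")
  invisible(path)
}
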