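# Diffusion-limited solution exchange at a patch inside the pipette tip.
# The concentration relaxation between pipette tip and membrane follows the
# series solution of the one-dimensional diffusion equation on a cylinder of
# length L (with a mirror cylinder for molecules reflected at the membrane);
# after an initial sigmoid phase it is well approximated by a single
# exponential with time constant tau = 4 L^2 / (D pi^2), delayed by
# t0 = tau * ln(4/pi).

#' Diffusion-limited exchange model for a concentration step
#'
#' Describes the ligand concentration time course at a membrane patch located
#' a distance `L` from the pipette tip when the bath concentration is stepped
#' from `c1` to `c2`. Supply either the geometry (`L` and `D`) or a measured
#' time constant `tau` (with `D` to back-calculate `L`); `tau = 4 L^2 /
#' (D pi^2)` and the delay `t0 = tau * ln(4/pi)` are filled in consistently.
#'
#' @param c1,c2 initial and final concentration (molar).
#' @param tau exchange time constant in seconds (alternative to `L`).
#' @param L tip-to-patch distance in cm (alternative to `tau`).
#' @param D diffusion coefficient in cm^2 s^-1.
#' @return An `exchange_model` with fields `c1, c2, L, D, tau, t0`.
#' @examples
#' exchange_model(c1 = 0, c2 = 1e-4, tau = 1.1e-3, D = 4.4e-6)
#' @export
exchange_model <- function(c1, c2, tau = NULL, L = NULL, D = NULL) {
  if (is.null(tau) && is.null(L))
    stop("supply either tau or L")
  if (is.null(tau)) {
    if (is.null(D)) stop("D is required to derive tau from L")
    tau <- tau_from_geometry(L, D)
  } else if (is.null(L) && !is.null(D)) {
    L <- length_from_tau(tau, D)
  }
  if (tau <= 0) stop("tau must be positive")
  structure(list(c1 = c1, c2 = c2, L = L, D = D,
                 tau = tau, t0 = tau * log(4 / pi)),
            class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat(sprintf(
    "Exchange model: %g -> %g M, tau = %.4g ms, t0 = %.4g ms%s\n",
    x$c1, x$c2, 1e3 * x$tau, 1e3 * x$t0,
    if (!is.null(x$L)) sprintf(", L = %.3g cm", x$L) else ""))
  invisible(x)
}

#' Full series solution of the diffusion-limited concentration step
#'
#' Evaluates the series
#' \deqn{c(t) = c_2 + (c_1 - c_2)\frac{4}{\pi}\sum_{n\ge1}
#'   \frac{-(-1)^n}{2n-1}\exp\left[-(2n-1)^2 t/\tau\right]}
#' truncated when the next term's magnitude drops below
#' `tol * |c1 - c2|`; because the series alternates with decreasing terms
#' this truncation bound is rigorous. At `t = 0` the series sums to 1 only in
#' the limit, so `c1` is returned exactly.
#'
#' @param em an [exchange_model()].
#' @param t time in seconds (vectorized, >= 0).
#' @param tol relative truncation tolerance (default 1e-10 of the step
#'   amplitude; capped at 1e4 terms).
#' @return Concentration(s) in molar.
#' @export
series_concentration <- function(em, t, tol = 1e-10) {
  stopifnot(inherits(em, "exchange_model"), all(t >= 0), tol > 0)
  amp <- em$c1 - em$c2
  vapply(t, function(ti) {
    if (ti == 0 || amp == 0) return(em$c1)
    acc <- 0
    for (n in seq_len(1e4)) {
      q <- 2 * n - 1
      term <- (-(-1)^n / q) * exp(-q^2 * ti / em$tau)
      acc <- acc + term
      if (abs(term) < tol) break
    }
    em$c2 + amp * (4 / pi) * acc
  }, numeric(1))
}

#' Delayed-exponential approximation of the concentration step
#'
#' First-term approximation of the series solution: a single exponential
#' with time constant `tau` delayed by `t0 = tau * ln(4/pi)` (about
#' `0.24 * tau`). Before the delay the default is to hold the starting
#' concentration `c1` (continuous with the exponential branch at `t0`); the
#' `strict_zero` mode instead returns 0 before `t0`, the convenient special
#' case when stepping up from zero ligand.
#'
#' @inheritParams series_concentration
#' @param strict_zero logical; return 0 (not `c1`) for `t < t0`.
#' @return Concentration(s) in molar.
#' @export
approx_concentration <- function(em, t, strict_zero = FALSE) {
  stopifnot(inherits(em, "exchange_model"), all(t >= 0))
  pre <- if (strict_zero) 0 else em$c1
  ifelse(t < em$t0, pre,
         em$c2 + (em$c1 - em$c2) * exp(-(t - em$t0) / em$tau))
}

#' Exchange time constant from geometry, and back
#'
#' `tau_from_geometry` gives the diffusional exchange time constant
#' `tau = 4 L^2 / (D pi^2)` for a tip-to-patch distance `L`;
#' `length_from_tau` inverts it, `L = (pi / 2) sqrt(D tau)`, which estimates
#' the patch position from a measured time constant.
#'
#' @param L distance in cm.
#' @param D diffusion coefficient in cm^2 s^-1.
#' @param tau time constant in s.
#' @return Time constant in s, or distance in cm.
#' @export
tau_from_geometry <- function(L, D) {
  if (any(L <= 0) || any(D <= 0)) stop("L and D must be positive")
  4 * L^2 / (D * pi^2)
}

#' @rdname tau_from_geometry
#' @export
length_from_tau <- function(tau, D) {
  if (any(tau <= 0) || any(D <= 0)) stop("tau and D must be positive")
  (pi / 2) * sqrt(D * tau)
}

#' Rescale an exchange time constant to another diffusing species
#'
#' The geometry (distance L) being fixed, tau scales inversely with the
#' diffusion coefficient: a time constant measured with a K+ jump is
#' converted to the ligand's by `tau_ref * D_ref / D_target`. Diffusion
#' coefficients may be given numerically or by name from
#' [diffusion_coefficients()].
#'
#' @param tau_ref measured time constant (s).
#' @param D_ref,D_target diffusion coefficients (cm^2 s^-1) or species names.
#' @return Rescaled time constant in s.
#' @examples
#' rescale_tau(1.1e-3, "K", "cAMP")   # ~4.9 ms
#' @export
rescale_tau <- function(tau_ref, D_ref, D_target) {
  lookup <- function(x) {
    if (is.character(x)) {
      tab <- diffusion_coefficients()
      if (!x %in% tab$species) stop("unknown species in diffusion table: ", x)
      tab$D_cm2_per_s[tab$species == x]
    } else x
  }
  D_ref <- lookup(D_ref); D_target <- lookup(D_target)
  if (tau_ref <= 0 || D_ref <= 0 || D_target <= 0)
    stop("tau and diffusion coefficients must be positive")
  tau_ref * D_ref / D_target
}

#' Table of diffusion coefficients
#'
#' Reads the editable table shipped with the package (species name,
#' diffusion coefficient in cm^2 s^-1). It is seeded with K+ (1.96e-5) and
#' cAMP (4.4e-6); cGMP is listed with the cAMP value, the structurally
#' closest molecule with a published coefficient.
#'
#' @param path optional path to a user table (tab-separated, columns
#'   `species`, `D_cm2_per_s`).
#' @return A data.frame.
#' @export
diffusion_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "diffusion_coefficients.tsv",
                        package = "chankin")
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Fit the exchange time constant to a K+ jump current
#'
#' Fits the delayed-exponential relaxation `I(t) = I_end + (I_start - I_end)
#' * g(t - t_on)` with `g = 1` before the delay `t0` and `exp(-(t - t_on -
#' t0)/tau)` after, to the current (or open-probability) trace inside
#' `window`. The delay is constrained to `t0 = tau ln(4/pi)` as the diffusion
#' model dictates; set `constrain_delay = FALSE` to let it float as a
#' robustness check. The switch is taken at the start of the window.
#'
#' @param trace a [channel_trace()] containing a `current_pA` (or `po`)
#'   column.
#' @param window numeric length-2 time range in seconds; default the whole
#'   trace.
#' @param tau0 starting value for tau (s).
#' @param constrain_delay keep `t0 = tau ln(4/pi)` (default TRUE).
#' @return List with `tau`, `t0`, `amplitude`, `offset`, `converged`,
#'   `low_confidence` (amplitude not resolved above the residual noise),
#'   `residual_sd` and the underlying `nls.lm` diagnostics.
#' @export
fit_exchange_tau <- function(trace, window = NULL, tau0 = 2e-3,
                             constrain_delay = TRUE) {
  y <- if (!is.null(trace$current_pA)) trace$current_pA else trace$po
  if (is.null(y)) stop("trace has neither a current_pA nor a po column")
  tt <- trace$time_s
  if (is.null(window)) window <- range(tt)
  keep <- tt >= window[1] & tt <= window[2]
  tt <- tt[keep] - window[1]
  y <- y[keep]
  if (length(y) < 5) stop("window contains fewer than 5 samples")

  relax <- function(par) {
    tau <- exp(par[["log_tau"]])
    t0 <- if (constrain_delay) tau * log(4 / pi) else exp(par[["log_t0"]])
    g <- ifelse(tt < t0, 1, exp(-(tt - t0) / tau))
    par[["offset"]] + par[["amplitude"]] * g
  }
  start <- c(log_tau = log(tau0), amplitude = y[1] - y[length(y)],
             offset = y[length(y)])
  if (!constrain_delay) start <- c(start, log_t0 = log(tau0 * log(4 / pi)))
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(par) relax(par) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  tau <- exp(fit$par[["log_tau"]])
  res_sd <- sd(fit$fvec)
  amp <- fit$par[["amplitude"]]
  list(
    tau = tau,
    t0 = if (constrain_delay) tau * log(4 / pi) else exp(fit$par[["log_t0"]]),
    amplitude = amp,
    offset = fit$par[["offset"]],
    converged = fit$info %in% 1:3,
    low_confidence = abs(amp) < 3 * res_sd,
    residual_sd = res_sd,
    n_iter = fit$niter,
    ssr_trace = fit$rsstrace
  )
}

#' Transform a nominal protocol into the effective concentration trace
#'
#' Replaces each rectangular concentration segment by the delayed-exponential
#' relaxation from the current effective concentration toward the segment's
#' nominal level, chaining incomplete relaxations across segment boundaries
#' so the effective concentration is continuous. The output is the
#' piecewise-constant discretization used by the propagator: sample `i`
#' carries the concentration governing the interval `[t_i, t_i + dt)`,
#' evaluated at the interval midpoint.
#'
#' @param protocol a [protocol()] of nominal segments.
#' @param tau_ligand exchange time constant of the ligand (s). `0` gives the
#'   nominal rectangular trace.
#' @param dt sampling interval in seconds (default 0.5 ms).
#' @param c_init effective concentration before the first segment (M).
#' @param strict_zero use the zero-before-delay convention of the
#'   step-from-zero special case instead of holding the pre-switch level.
#' @return A [channel_trace()] with `time_s` and `conc_M`.
#' @export
correct_protocol <- function(protocol, tau_ligand, dt = 5e-4, c_init = 0,
                             strict_zero = FALSE) {
  stopifnot(inherits(protocol, "concentration_protocol"), dt > 0,
            tau_ligand >= 0)
  segs <- protocol$segments
  if (any(segs$duration_s < dt))
    stop("every segment must be at least one sampling interval long")
  n_per <- round(segs$duration_s / dt)
  starts <- cumsum(c(0, segs$duration_s))[seq_len(nrow(segs))]
  t0 <- tau_ligand * log(4 / pi)
  conc <- numeric(sum(n_per))
  a <- c_init  # effective concentration entering the segment
  pos <- 0L
  for (k in seq_len(nrow(segs))) {
    target <- segs$level_M[k]
    tm <- (seq_len(n_per[k]) - 0.5) * dt  # interval midpoints, segment time
    if (tau_ligand == 0) {
      ck <- rep(target, n_per[k])
      a <- target
    } else {
      pre <- if (strict_zero) 0 else a
      ck <- ifelse(tm < t0, pre,
                   target + (a - target) * exp(-(tm - t0) / tau_ligand))
      dur <- segs$duration_s[k]
      a <- if (dur < t0) a else
        target + (a - target) * exp(-(dur - t0) / tau_ligand)
    }
    conc[pos + seq_len(n_per[k])] <- ck
    pos <- pos + n_per[k]
  }
  channel_trace(time_s = (seq_along(conc) - 1) * dt, conc_M = conc,
                meta = list(sampling_rate_hz = 1 / dt,
                            tau_exchange_s = tau_ligand,
                            protocol_label = attr(protocol, "label")))
}
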