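# Forward simulation of gating schemes along a (possibly exchange-corrected)
# concentration trace, plus trace summaries used for concentration-response
# analysis.

model_arrays <- function(model, theta) {
  list(s = model$n_states,
       from = as.integer(model$edges$from - 1L),
       to = as.integer(model$edges$to - 1L),
       coef = as.numeric(edge_coefficients(model, theta)),
       cdep = as.integer(model$edges$conc_dep),
       open = as.integer(model$open_states - 1L))
}

#' Deterministic open-probability time course
#'
#' Propagates the state distribution exactly along a piecewise-constant
#' concentration trace: on each sampling interval the distribution advances
#' by `exp(Q(c_i) * dt)`, the true conditional law of the gating chain, so no
#' sub-stepping is required. The state is carried continuously across all
#' segment boundaries. The initial distribution defaults to the stationary
#' distribution at the first concentration.
#'
#' @param model a [build_sequential_model()] or [build_co_model()] scheme.
#' @param theta positive parameter vector.
#' @param conc_trace a [channel_trace()] with a `conc_M` column on a uniform
#'   grid (sample i governs the interval starting at t_i).
#' @param p0 optional initial state distribution.
#' @return The trace with a `po` column added; the full state trajectory is
#'   attached as attribute `prob` and the final state as `p_final`.
#' @export
simulate_deterministic <- function(model, theta, conc_trace, p0 = NULL) {
  stopifnot(inherits(conc_trace, "channel_trace"),
            !is.null(conc_trace$conc_M))
  dt <- trace_dt(conc_trace)
  if (is.null(p0))
    p0 <- stationary_distribution(model, theta, conc_trace$conc_M[1])
  p0 <- check_distribution(model, p0)
  a <- model_arrays(model, theta)
  res <- tryCatch(
    po_trace_cpp(a$s, a$from, a$to, a$coef, a$cdep, a$open,
                 conc_trace$conc_M, dt, p0),
    error = function(e) stop("propagation failed: ", conditionMessage(e)))
  out <- channel_trace(conc_trace$time_s, conc_M = conc_trace$conc_M,
                       po = pmin(pmax(res$po, 0), 1),
                       meta = c(attr(conc_trace, "meta"),
                                list(model = model$label)))
  attr(out, "prob") <- res$prob
  attr(out, "p_final") <- res$p_final
  out
}

#' Stochastic open-probability time course of a finite channel population
#'
#' Simulates `n_channels` independent channels: per sampling interval the
#' per-state channel counts redistribute by multinomial draws from the exact
#' interval transition matrix `exp(Q * dt)` (no event-by-event simulation is
#' needed since this is the true conditional law at the sampling grid). The
#' initial counts are a multinomial draw from the stationary distribution at
#' the first concentration. The reported `po` is the open-channel fraction.
#'
#' @inheritParams simulate_deterministic
#' @param n_channels channel population size (>= 1).
#' @param seed integer seed; set for reproducibility and recorded in the
#'   trace metadata.
#' @return The trace with a stochastic `po` column; per-state counts are
#'   attached as attribute `counts`.
#' @export
simulate_stochastic <- function(model, theta, conc_trace, n_channels,
                                seed = NULL) {
  stopifnot(inherits(conc_trace, "channel_trace"),
            !is.null(conc_trace$conc_M), n_channels >= 1)
  if (!is.null(seed)) set.seed(seed)
  dt <- trace_dt(conc_trace)
  p0 <- stationary_distribution(model, theta, conc_trace$conc_M[1])
  counts0 <- as.integer(rmultinom(1, n_channels, as.numeric(p0)))
  a <- model_arrays(model, theta)
  res <- stochastic_trace_cpp(a$s, a$from, a$to, a$coef, a$cdep, a$open,
                              conc_trace$conc_M, dt, counts0)
  out <- channel_trace(conc_trace$time_s, conc_M = conc_trace$conc_M,
                       po = res$po,
                       meta = c(attr(conc_trace, "meta"),
                                list(model = model$label,
                                     n_channels = n_channels, seed = seed)))
  attr(out, "counts") <- res$counts
  out
}

#' Scale an open-probability trace to a macroscopic current
#'
#' `I = N * i_single * Po + leak + Gaussian(0, noise_sd)`.
#'
#' @param po_trace trace with a `po` column.
#' @param n_channels channel count N.
#' @param i_single single-channel current amplitude (pA).
#' @param leak constant leak current (pA).
#' @param noise_sd standard deviation of added Gaussian recording noise (pA).
#' @param seed integer seed for the noise.
#' @return The trace with a `current_pA` column added.
#' @export
to_current <- function(po_trace, n_channels, i_single, leak = 0,
                       noise_sd = 0, seed = NULL) {
  stopifnot(inherits(po_trace, "channel_trace"), !is.null(po_trace$po),
            i_single >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) rnorm(nrow(po_trace), 0, noise_sd) else 0
  cur <- n_channels * i_single * po_trace$po + leak + noise
  meta <- c(attr(po_trace, "meta"),
            list(n_channels = n_channels, i_single_pA = i_single,
                 leak_pA = leak, noise_sd_pA = noise_sd))
  if (!is.null(seed)) meta$noise_seed <- seed
  channel_trace(po_trace$time_s, conc_M = po_trace$conc_M, po = po_trace$po,
                current_pA = cur, meta = meta)
}

#' Late-response summary per protocol segment
#'
#' Means of the trace value over the terminal window of every ligand/zero
#' segment — either the last fixed number of milliseconds (`last_ms`) or the
#' last fraction of each segment (`last_fraction`). At quasi-equilibrium
#' this estimates the steady-state response per concentration, the input to
#' Hill fitting.
#'
#' @param trace a [channel_trace()] covering the protocol.
#' @param protocol the nominal `concentration_protocol`.
#' @param rule a one-element named list: `list(last_ms = 0.6)` or
#'   `list(last_fraction = 0.05)`.
#' @param value which trace column to summarize (`"po"` or `"current_pA"`).
#' @return data.frame with `segment`, `conc_M`, `kind`, `response`.
#' @export
late_response <- function(trace, protocol, rule = list(last_fraction = 0.05),
                          value = c("po", "current_pA")) {
  value <- match.arg(value)
  stopifnot(inherits(trace, "channel_trace"), !is.null(trace[[value]]))
  dt <- trace_dt(trace)
  segs <- protocol$segments
  if (max(trace$time_s) + dt < protocol$total_duration_s - 1e-9)
    stop("trace does not cover the protocol")
  ends <- cumsum(segs$duration_s)
  starts <- ends - segs$duration_s
  win <- if (!is.null(rule$last_ms)) rep(rule$last_ms / 1e3, nrow(segs))
         else if (!is.null(rule$last_fraction))
           rule$last_fraction * segs$duration_s
         else stop("rule must specify last_ms or last_fraction")
  if (any(win > segs$duration_s + 1e-12))
    stop("late-response window is longer than a segment")
  keep <- segs$kind != "k_jump"
  resp <- vapply(which(keep), function(k) {
    sel <- trace$time_s >= ends[k] - win[k] - 1e-9 &
      trace$time_s < ends[k] - 1e-9
    if (!any(sel)) sel <- which.min(abs(trace$time_s - (ends[k] - dt)))
    mean(trace[[value]][sel])
  }, numeric(1))
  data.frame(segment = which(keep), conc_M = segs$level_M[keep],
             kind = segs$kind[keep], response = resp,
             stringsAsFactors = FALSE)
}

#' Hysteresis index of paired up/down staircase responses
#'
#' Signed area between the normalized decremental and incremental
#' concentration-response branches on the log10-concentration axis
#' (trapezoidal rule). Both branches are normalized by their joint maximum.
#' Positive values mean the decremental branch lies above (is left-shifted
#' from) the incremental branch — the signature of incomplete equilibration;
#' the index shrinks toward zero as pulse duration grows.
#'
#' @param up_summary,down_summary data.frames with `conc_M` and `response`
#'   (as from [late_response()]) on matching concentration grids.
#' @return Signed scalar index (dimensionless, per log10 concentration unit).
#' @export
hysteresis_index <- function(up_summary, down_summary) {
  up <- up_summary[order(up_summary$conc_M), ]
  dn <- down_summary[order(down_summary$conc_M), ]
  if (nrow(up) != nrow(dn) ||
      any(abs(up$conc_M - dn$conc_M) > 1e-9 * up$conc_M))
    stop("up and down branches are on different concentration grids")
  if (any(up$conc_M <= 0)) stop("hysteresis index requires positive levels")
  top <- max(c(up$response, dn$response))
  if (top <= 0) stop("responses must contain positive values")
  x <- log10(up$conc_M)
  d <- (dn$response - up$response) / top
  sum(diff(x) * (head(d, -1) + tail(d, -1)) / 2)
}
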