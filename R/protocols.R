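# Nominal concentration protocols: ordered segments of (level, duration,
# kind). Kinds: "ligand" (agonist application), "zero" (explicit zero-ligand
# segment), "k_jump" (K+ concentration jump used to calibrate the solution
# exchange, excluded from jump counting and Hill fitting).

#' Construct a concentration protocol
#'
#' @param level_M segment concentration levels in molar (>= 0).
#' @param duration_s segment durations in seconds (> 0).
#' @param kind segment kinds, recycled; one of `"ligand"`, `"zero"`,
#'   `"k_jump"`. Zero levels of kind `"ligand"` are reclassified `"zero"`.
#' @param label protocol label.
#' @return A `concentration_protocol`: list with a `segments` data.frame and
#'   a `total_duration_s` field.
#' @export
protocol <- function(level_M, duration_s, kind = "ligand", label = "protocol") {
  if (length(level_M) == 0) stop("protocol needs at least one segment")
  if (any(duration_s <= 0)) stop("segment durations must be positive")
  if (any(level_M < 0)) stop("segment levels must be non-negative")
  kind <- rep_len(kind, length(level_M))
  if (!all(kind %in% c("ligand", "zero", "k_jump")))
    stop("segment kind must be ligand, zero or k_jump")
  kind[kind == "ligand" & level_M == 0] <- "zero"
  structure(list(
    segments = data.frame(level_M = as.numeric(level_M),
                          duration_s = rep_len(as.numeric(duration_s),
                                               length(level_M)),
                          kind = kind, stringsAsFactors = FALSE),
    total_duration_s = sum(rep_len(duration_s, length(level_M)))
  ), class = "concentration_protocol", label = label)
}

#' @export
print.concentration_protocol <- function(x, ...) {
  s <- x$segments
  cat(sprintf("Protocol '%s': %d segments, %.3g s total, levels %g - %g uM\n",
              attr(x, "label"), nrow(s), x$total_duration_s,
              1e6 * min(s$level_M), 1e6 * max(s$level_M)))
  invisible(x)
}

#' Logarithmically equidistant concentration staircase
#'
#' Builds `n_steps` pulses whose levels are equidistant on a log scale
#' between `c_min` and `c_max`. Direction `"up"` runs incremental,
#' `"down"` decremental, and `"updown"` concatenates the incremental run
#' with its decremental mirror (2 * n_steps segments).
#'
#' @param c_min,c_max lowest and highest level (molar, both > 0; prepend an
#'   explicit zero segment with [protocol()] if needed).
#' @param n_steps number of levels (>= 2).
#' @param duration pulse duration in seconds.
#' @param direction `"up"`, `"down"` or `"updown"`.
#' @return A `concentration_protocol`.
#' @examples
#' staircase_protocol(1e-7, 1e-4, 25, 0.1)  # 25 pulses, 2.5 s in total
#' @export
staircase_protocol <- function(c_min, c_max, n_steps, duration,
                               direction = c("up", "down", "updown")) {
  direction <- match.arg(direction)
  if (!(c_min > 0 && c_max > c_min))
    stop("need 0 < c_min < c_max (log spacing is undefined at zero)")
  if (n_steps < 2) stop("n_steps must be at least 2")
  lv <- 10^seq(log10(c_min), log10(c_max), length.out = n_steps)
  lv <- switch(direction, up = lv, down = rev(lv), updown = c(lv, rev(lv)))
  protocol(lv, duration, label = sprintf("staircase-%s-%d", direction, n_steps))
}

#' Response-equidistant concentration series
#'
#' Levels chosen so that, for a channel obeying a Hill-type
#' concentration-activation relationship with known `ec50` and `hill_n`, the
#' steady-state responses are equally spaced: the i-th level is the Hill
#' inverse of `f_i = i / (n_steps + 1)`, i.e.
#' `c_i = ec50 * (f_i / (1 - f_i))^(1 / hill_n)`.
#'
#' @param ec50 half-activating concentration (molar).
#' @param hill_n Hill coefficient.
#' @param n_steps number of levels (>= 2).
#' @param duration pulse duration (s).
#' @return A `concentration_protocol` with strictly increasing levels.
#' @export
response_equidistant_protocol <- function(ec50, hill_n, n_steps, duration) {
  if (ec50 <= 0 || hill_n <= 0) stop("ec50 and hill_n must be positive")
  if (n_steps < 2) stop("n_steps must be at least 2")
  f <- seq_len(n_steps) / (n_steps + 1)
  lv <- ec50 * (f / (1 - f))^(1 / hill_n)
  protocol(lv, duration, label = sprintf("response-equidistant-%d", n_steps))
}

#' Verbatim complex protocol
#'
#' @param spec data.frame or list with elements/columns `level_M` and
#'   `duration_s` (optionally `kind`).
#' @return A `concentration_protocol`.
#' @export
complex_protocol <- function(spec) {
  spec <- as.data.frame(spec)
  if (nrow(spec) == 0) stop("empty protocol specification")
  protocol(spec$level_M, spec$duration_s,
           kind = if (!is.null(spec$kind)) spec$kind else "ligand",
           label = "complex")
}

#' Reference complex pulse-train protocol
#'
#' A deterministic 23-pulse train of 500-ms segments (11.5 s in total)
#' spanning zero to 100 uM with all consecutive levels distinct, patterned
#' after complex activation protocols for CNGA2 channels: large jumps
#' between high and low levels probe activation and deactivation kinetics
#' across the whole concentration range, and one zero-ligand segment
#' (6.5-7.0 s) probes full deactivation. The exact levels are this package's
#' own stand-in fixture, not a published table.
#'
#' @return A `concentration_protocol` of 23 segments.
#' @export
pulse_train_protocol <- function() {
  levels_uM <- c(1, 10, 0.5, 30, 3, 100, 0.2, 20, 2, 60, 0.1, 6, 100,
                 0, 5, 0.3, 50, 1.5, 15, 0.7, 100, 4, 40)
  protocol(levels_uM * 1e-6, 0.5, label = "pulse-train-23")
}

#' Count concentration jumps in a protocol
#'
#' A jump is a ligand or zero segment whose level differs from the effective
#' level before it (the level preceding the first segment is `c_init`).
#' K+ jump calibration segments are excluded. Used as the degrees of freedom
#' of the reduced-SSR model-ranking statistic, a deliberately conservative
#' alternative to counting correlated sample points.
#'
#' @param protocol a `concentration_protocol`.
#' @param c_init effective level before the protocol starts (M).
#' @return Integer jump count.
#' @export
count_jumps <- function(protocol, c_init = 0) {
  segs <- protocol$segments[protocol$segments$kind != "k_jump", ]
  prev <- c(c_init, segs$level_M[-nrow(segs)])
  sum(segs$level_M != prev)
}
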