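# Sampled traces on a uniform time grid. Columns: time_s, and any of
# conc_M, po, current_pA. Sample i of conc_M is the concentration governing
# the interval [t_i, t_i + dt); po/current are instantaneous values at t_i.

#' Construct a sampled trace
#'
#' @param time_s uniform time grid in seconds.
#' @param conc_M,po,current_pA optional data columns (same length as
#'   `time_s`); `po` must lie in `[0, 1]`.
#' @param meta named list of metadata (sampling rate, channel count,
#'   single-channel amplitude, seed, ...).
#' @return A `channel_trace` (a data.frame with a `meta` attribute).
#' @export
channel_trace <- function(time_s, conc_M = NULL, po = NULL,
                          current_pA = NULL, meta = list()) {
  n <- length(time_s)
  if (n >= 2) {
    dt <- diff(time_s)
    bad <- which(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1e-12))
    if (length(bad))
      stop(sprintf("non-uniform time grid at index %d", bad[1] + 1L))
  }
  cols <- list(time_s = as.numeric(time_s))
  for (nm in c("conc_M", "po", "current_pA")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != n) stop(nm, " must match the length of time_s")
      cols[[nm]] <- as.numeric(v)
    }
  }
  if (!is.null(cols$po) &&
      any(cols$po < -1e-9 | cols$po > 1 + 1e-9, na.rm = TRUE))
    stop("po values must lie in [0, 1]")
  out <- as.data.frame(cols)
  attr(out, "meta") <- meta
  class(out) <- c("channel_trace", "data.frame")
  out
}

#' @export
print.channel_trace <- function(x, ...) {
  dt <- if (nrow(x) >= 2) x$time_s[2] - x$time_s[1] else NA_real_
  cat(sprintf("Trace: %d samples, dt = %.4g s, columns: %s\n",
              nrow(x), dt, paste(names(x), collapse = ", ")))
  m <- attr(x, "meta")
  if (length(m))
    cat("  meta:", paste(sprintf("%s=%s", names(m),
                                 vapply(m, function(v)
                                   paste(format(v), collapse = "/"),
                                   character(1))), collapse = ", "), "\n")
  invisible(x)
}

trace_dt <- function(trace) {
  if (nrow(trace) < 2) stop("trace needs at least two samples")
  trace$time_s[2] - trace$time_s[1]
}

#' Read / write a trace as delimited text
#'
#' Traces are stored as tab-separated text with a header drawn from
#' `time_s`, `conc_M`, `po`, `current_pA` (SI units). Values round-trip at
#' 17 significant digits. Metadata are written as `# key: value` comment
#' lines and restored on read.
#'
#' @param path file path.
#' @param trace a [channel_trace()].
#' @return `read_trace` returns a `channel_trace`; a header-only file gives
#'   a zero-length trace with attribute `empty = TRUE`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trace file: ", path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0) {
      key <- trimws(substr(kv, 1, pos - 1))
      val <- trimws(substr(kv, pos + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop("trace file has no header line: ", path)
  dat <- read.delim(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE)
  if (!"time_s" %in% names(dat))
    stop("trace file is missing the required time_s column")
  known <- intersect(c("time_s", "conc_M", "po", "current_pA"), names(dat))
  dat <- dat[known]
  if (nrow(dat) == 0) {
    out <- channel_trace(numeric(0), meta = meta)
    attr(out, "empty") <- TRUE
    return(out)
  }
  args <- c(as.list(dat), list(meta = meta))
  do.call(channel_trace, args)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "channel_trace"))
  meta <- attr(trace, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key,
                       paste(format(meta[[key]], digits = 17),
                             collapse = " ")), con)
  df <- as.data.frame(lapply(unclass(trace)[names(trace)],
                             function(v) format(v, digits = 17,
                                                scientific = TRUE,
                                                trim = TRUE)))
  names(df) <- names(trace)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
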