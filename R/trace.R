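#' Uniformly sampled membrane-potential trace
#'
#' The package's basic data container: a voltage time series with uniform
#' sampling and annotated stimulus-onset times.
#'
#' @param v Numeric vector of voltage samples (mV).
#' @param dt Sample interval (ms).
#' @param t0 Time of the first sample (ms).
#' @param stim_onsets Stimulus-onset times (ms), possibly empty.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(v, dt, t0 = 0, stim_onsets = numeric(0)) {
  stopifnot(is.numeric(v), length(v) >= 2, dt > 0)
  structure(
    list(v = as.numeric(v), dt = dt, t0 = t0,
         stim_onsets = as.numeric(stim_onsets)),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %d samples, dt = %g ms, t = [%g, %g] ms, %d stimuli\n",
    length(x$v), x$dt, x$t0, trace_end(x), length(x$stim_onsets)))
  invisible(x)
}

#' @export
length.voltage_trace <- function(x) length(x$v)

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$v) - 1) * trace$dt
}

trace_end <- function(trace) trace$t0 + (length(trace$v) - 1) * trace$dt

#' @export
as.data.frame.voltage_trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), voltage_mV = x$v)
}

# linear interpolation of trace voltage at arbitrary times (within support)
trace_interp <- function(trace, t) {
  stats::approx(trace_times(trace), trace$v, xout = t, rule = 1)$y
}

#' Plot a voltage trace
#' @param x A [voltage_trace()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.voltage_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$v, type = "l",
                 xlab = "time (ms)", ylab = "V (mV)", ...)
  if (length(x$stim_onsets))
    graphics::abline(v = x$stim_onsets, col = "grey70", lty = 3)
  invisible(x)
}

#' Extract single beats from a multi-beat trace
#'
#' Splits a paced trace at its stimulus onsets. Each returned beat keeps the
#' pre-onset segment (`pre_ms` before its stimulus) so that the resting
#' potential remains measurable, and is annotated with its own onset.
#'
#' @param trace A [voltage_trace()] with at least one stimulus onset.
#' @param pre_ms Pre-stimulus context retained per beat (ms).
#' @return List of single-beat `voltage_trace` objects.
#' @export
split_beats <- function(trace, pre_ms = 50) {
  ons <- trace$stim_onsets
  if (!length(ons)) stop("trace has no stimulus annotations")
  tt <- trace_times(trace)
  ends <- c(ons[-1], trace_end(trace) + trace$dt)
  lapply(seq_along(ons), function(i) {
    sel <- tt >= ons[i] - pre_ms & tt < ends[i]
    voltage_trace(trace$v[sel], dt = trace$dt, t0 = tt[sel][1],
                  stim_onsets = ons[i])
  })
}

#' Average action potentials aligned at their stimulus onsets
#'
#' Beats are aligned at their (first) stimulus onset and averaged pointwise
#' over the common support, mirroring how averaged experimental APs are
#' formed from ten consecutive recorded beats.
#'
#' @param traces List of [voltage_trace()] objects with equal sample
#'   intervals and at least one stimulus annotation each.
#' @return A `voltage_trace` in onset-aligned time, with its stimulus onset
#'   at the position of the first input's onset.
#' @export
average_aps <- function(traces) {
  stopifnot(length(traces) >= 1)
  dts <- vapply(traces, function(x) x$dt, numeric(1))
  if (length(unique(dts)) != 1) stop("sample intervals differ across traces")
  for (x in traces) if (!length(x$stim_onsets))
    stop("every trace needs a stimulus annotation")
  dt <- dts[1]
  # support relative to each trace's first onset, snapped to the sample grid
  rel <- lapply(traces, function(x) {
    k_on <- round((x$stim_onsets[1] - x$t0) / dt)
    c(-k_on, length(x$v) - 1 - k_on)
  })
  lo <- max(vapply(rel, `[`, numeric(1), 1))
  hi <- min(vapply(rel, `[`, numeric(1), 2))
  if (hi <= lo) stop("traces have no common support around their onsets")
  acc <- rep(0, hi - lo + 1)
  for (x in traces) {
    k_on <- round((x$stim_onsets[1] - x$t0) / dt)
    acc <- acc + x$v[(k_on + lo):(k_on + hi) + 1]
  }
  on1 <- traces[[1]]$stim_onsets[1]
  voltage_trace(acc / length(traces), dt = dt, t0 = on1 + lo * dt,
                stim_onsets = on1)
}

#' Read / write voltage traces as two-column delimited text
#'
#' The format is two tab-separated columns (`time_ms`, `voltage_mV`) under a
#' comment header that carries the sample interval and stimulus onsets, so a
#' round trip preserves the trace exactly.
#'
#' @param trace A [voltage_trace()].
#' @param path File path.
#' @return `read_voltage_trace` returns a `voltage_trace`;
#'   `write_voltage_trace` returns `path` invisibly.
#' @export
write_voltage_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dt_ms=%.17g", trace$dt),
    sprintf("# t0_ms=%.17g", trace$t0),
    paste0("# stim_onsets_ms=",
           paste(sprintf("%.17g", trace$stim_onsets), collapse = ",")),
    "# time_ms\tvoltage_mV"
  ), con)
  utils::write.table(
    data.frame(sprintf("%.17g", trace_times(trace)),
               sprintf("%.17g", trace$v)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  dt_raw <- get("dt_ms")
  dt <- if (is.null(dt_raw)) NA_real_ else as.numeric(dt_raw)
  t0_raw <- get("t0_ms")
  t0 <- if (is.null(t0_raw)) NA_real_ else as.numeric(t0_raw)
  ons_raw <- get("stim_onsets_ms")
  ons <- if (is.null(ons_raw) || !nzchar(ons_raw)) numeric(0)
         else as.numeric(strsplit(ons_raw, ",")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("no data rows in ", path)
  parts <- strsplit(body, "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad))
    stop("malformed row ", bad[1], " in ", path)
  tcol <- as.numeric(vapply(parts, `[`, character(1), 1))
  vcol <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(tcol) || anyNA(vcol))
    stop("non-numeric row ", which(is.na(tcol) | is.na(vcol))[1], " in ", path)
  if (is.na(dt)) dt <- tcol[2] - tcol[1]
  if (length(tcol) > 2) {
    steps <- diff(tcol)
    if (max(abs(steps - dt)) > 1e-6 * dt)
      stop("time column is not uniformly sampled in ", path)
  }
  if (is.na(t0)) t0 <- tcol[1]
  voltage_trace(vcol, dt = dt, t0 = t0, stim_onsets = ons)
}
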