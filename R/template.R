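# Template-based target-canceling model selection: the baseline (pre-GA)
# approach builds nine candidate mouse models with APD80 labels 40..120 ms
# and picks the one closest to the measured cell's APD80.

.template_labels <- seq(40, 120, by = 10)

# APD80 of the mouse model with gss/gKslow scaled by a common factor s,
# measured from a fresh 1 Hz paced beat after re-settling the resting state
.apd80_of_scale <- function(s, settle_ms = 5000) {
  p <- .mouse_baseline_params
  p[["gss"]] <- p[["gss"]] * s
  p[["gKslow"]] <- p[["gKslow"]] * s
  mm <- neonatal_mouse_model(params = p)
  st <- settle_model(mm, settle_ms)
  tr <- simulate_paced(mm, state = st)
  list(apd80 = apd_mouse80(tr), state = st, params = p)
}

#' Calibrate a template member to a target APD80
#'
#' Finds a `(g_ss, g_Kslow)` pair whose 1 Hz paced APD80 matches the target.
#' The search follows a one-dimensional path: both conductances are scaled
#' from baseline by a common factor `s`, along which APD80 is monotone
#' decreasing (verified at run time), and `s` is bisected.
#'
#' @param target_apd80 Target APD80 (ms), mouse definition.
#' @param tol Acceptable |measured - target| (ms).
#' @return Named vector `c(gss=, gKslow=)` with attributes `scale`,
#'   `apd80_verified` and `resting_state` (the member's own settled rest).
#' @export
calibrate_template <- function(target_apd80, tol = 1) {
  key <- sprintf("template_%.6g_%.3g", target_apd80, tol)
  if (!is.null(.ctcfit_cache[[key]])) return(.ctcfit_cache[[key]])
  s_lo <- 0.06; s_hi <- 12   # below ~0.05 the model fails to repolarize
  a_lo <- .apd80_of_scale(s_lo)$apd80  # longest APD on the path
  a_hi <- .apd80_of_scale(s_hi)$apd80  # shortest
  if (a_lo <= a_hi)
    stop("APD80 is not decreasing along the calibration path")
  if (target_apd80 > a_lo || target_apd80 < a_hi)
    stop(sprintf(
      "target APD80 %.1f ms outside achievable range [%.1f, %.1f] ms",
      target_apd80, a_hi, a_lo))
  lo <- s_lo; hi <- s_hi
  for (i in 1:60) {
    mid <- sqrt(lo * hi)   # bisect in log-scale (APD-s relation is log-like)
    res <- .apd80_of_scale(mid)
    if (abs(res$apd80 - target_apd80) <= 0.5 * tol) break
    if (res$apd80 > target_apd80) lo <- mid else hi <- mid
  }
  out <- c(gss = unname(res$params[["gss"]]),
           gKslow = unname(res$params[["gKslow"]]))
  attr(out, "scale") <- mid
  attr(out, "apd80_verified") <- res$apd80
  attr(out, "resting_state") <- res$state
  .ctcfit_cache[[key]] <- out
  out
}

#' Build the nine-member template suite
#'
#' Calibrates mouse models with APD80 labels 40 to 120 ms in 10 ms steps by
#' varying `g_ss` and `g_Kslow`, verifying each label by a fresh paced
#' simulation.
#'
#' @param tol Calibration tolerance per member (ms).
#' @return A `template_suite` data frame with columns `label_ms`, `gss`,
#'   `gKslow`, `scale`, `apd80_verified`.
#' @export
build_suite <- function(tol = 1) {
  if (!is.null(.ctcfit_cache[["suite"]])) return(.ctcfit_cache[["suite"]])
  rows <- lapply(.template_labels, function(lab) {
    cal <- calibrate_template(lab, tol)
    data.frame(label_ms = lab, gss = cal[["gss"]], gKslow = cal[["gKslow"]],
               scale = attr(cal, "scale"),
               apd80_verified = attr(cal, "apd80_verified"))
  })
  suite <- do.call(rbind, rows)
  class(suite) <- c("template_suite", "data.frame")
  .ctcfit_cache[["suite"]] <- suite
  suite
}

#' Select the template member closest to a measured APD80
#'
#' Picks the member whose label is nearest the measured value; an exact tie
#' between two labels goes to the shorter-APD member.
#'
#' @param suite A [build_suite()] result.
#' @param measured_apd80 Measured APD80 (ms); must be finite.
#' @return The selected suite row (single-row data frame).
#' @export
select_template <- function(suite, measured_apd80) {
  stopifnot(is.finite(measured_apd80))
  d <- abs(suite$label_ms - measured_apd80)
  suite[which.min(d), , drop = FALSE]   # which.min takes the first == shorter
}

#' Mouse model for a template suite member
#'
#' @param label_ms Template label (ms), one of 40, 50, ..., 120.
#' @return A `cell_model` with the member's calibrated conductances and its
#'   own settled resting state.
#' @export
template_model <- function(label_ms) {
  neonatal_mouse_model(apd80 = label_ms)
}
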