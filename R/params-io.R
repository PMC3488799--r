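# JSON serialization of model parameter sets, with explicit units.

.param_units <- function(kind) {
  if (kind == "mouse") c(
    gNa = "uS", gCaL = "uS", gt = "uS", gKslow = "uS", gss = "uS",
    gK1 = "uS", gf = "uS", gBNa = "uS", gBCa = "uS", gBK = "uS",
    iNaKmax = "nA", kNaCa = "nA", iCaPmax = "nA",
    Ko = "mM", Nao = "mM", Cao = "mM", Nai = "mM", Ki = "mM", Cai = "mM",
    Cm = "pF"
  ) else c(
    gNa = "nS/pF", gCaL = "cm^3/(uF*s)", gto = "nS/pF", gKr = "nS/pF",
    gKs = "nS/pF", gK1 = "nS/pF", kNaCa = "pA/pF", pNaK = "pA/pF",
    gpCa = "pA/pF", gpK = "nS/pF", gbNa = "nS/pF", gbCa = "nS/pF",
    Ko = "mM", Nao = "mM", Cao = "mM", Nai = "mM", Ki = "mM", Cai = "mM",
    Cm = "pF", CaLdrive = "mM"
  )
}

#' Write / read a model parameter set as JSON
#'
#' The file carries the model kind and, for every parameter, its value and
#' unit, so a parameter set round-trips exactly and remains self-describing.
#'
#' @param model A [`cell_model`][neonatal_mouse_model].
#' @param path JSON file path.
#' @return `write_parameter_set` returns `path` invisibly;
#'   `read_parameter_set` returns a named parameter vector with a `kind`
#'   attribute, suitable for `neonatal_mouse_model(params = )` when the kind
#'   is `"mouse"`.
#' @export
write_parameter_set <- function(model, path) {
  units <- .param_units(model$kind)
  stopifnot(identical(names(model$params), names(units)))
  jsonlite::write_json(
    list(kind = model$kind,
         parameters = mapply(function(v, u) list(value = v, unit = u),
                             model$params, units, SIMPLIFY = FALSE)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$kind) || !obj$kind %in% c("mouse", "human"))
    stop("not a parameter-set file: ", path)
  units <- .param_units(obj$kind)
  if (!setequal(names(obj$parameters), names(units)))
    stop("parameter names do not match the '", obj$kind, "' model")
  p <- vapply(obj$parameters[names(units)],
              function(x) as.numeric(x$value), numeric(1))
  structure(p, kind = obj$kind)
}
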