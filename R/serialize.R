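#' Save a fitted model to a self-describing JSON container
#'
#' Progression-space and subtype models are written as versioned JSON with
#' full double precision, so `load_model(save_model(m))` reproduces every
#' numeric field bit-identically and the files stay diffable and
#' language-portable.
#'
#' @param model A `progression_space_model` or `subtype_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  type <- class(model)[1]
  if (!type %in% c("progression_space_model", "subtype_model"))
    stop("unsupported model type: ", type)
  payload <- list(schema_version = 1L, type = type,
                  fields = lapply(unclass(model), encode_field))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return The restored model, same class and numeric content as saved.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e)
                        stop("cannot parse model file ", path, ": ",
                             conditionMessage(e)))
  if (is.null(payload$schema_version) || is.null(payload$type))
    stop("cannot parse model file ", path, ": not a model container")
  if (payload$schema_version != 1L)
    stop("model schema version mismatch: file has ", payload$schema_version,
         ", this build reads 1")
  model <- lapply(payload$fields, decode_field)
  class(model) <- payload$type
  model
}

# tagged encoding: matrices/arrays keep dim + dimnames exactly; data.frames
# keep column types; lmer/glm fits are not serialized
encode_field <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x) || is.array(x)) {
    list(.kind = "array", dim = dim(x), dimnames = dimnames(x),
         data = as.vector(x))
  } else if (is.data.frame(x)) {
    list(.kind = "data.frame", columns = lapply(as.list(x), encode_field))
  } else if (is.factor(x)) {
    list(.kind = "factor", levels = levels(x), codes = as.integer(x))
  } else if (is.list(x)) {
    list(.kind = "list", items = lapply(x, encode_field))
  } else {
    list(.kind = typeof(x), names = names(x), data = x)
  }
}

decode_field <- function(x) {
  if (is.null(x)) return(NULL)
  kind <- x$.kind
  if (is.null(kind)) stop("cannot parse model file: malformed field")
  if (kind == "array") {
    out <- array(unlist(x$data, use.names = FALSE), dim = unlist(x$dim))
    if (!is.null(x$dimnames))
      dimnames(out) <- lapply(x$dimnames, function(d)
        if (is.null(d)) NULL else unlist(d))
    out
  } else if (kind == "data.frame") {
    as.data.frame(lapply(x$columns, decode_field), stringsAsFactors = FALSE)
  } else if (kind == "factor") {
    lev <- unlist(x$levels)
    factor(lev[unlist(x$codes)], levels = lev)
  } else if (kind == "list") {
    lapply(x$items, decode_field)
  } else {
    out <- unlist(x$data, use.names = FALSE)
    if (kind == "integer") out <- as.integer(out)
    if (kind == "logical") out <- as.logical(out)
    if (!is.null(x$names)) names(out) <- unlist(x$names)
    out
  }
}
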