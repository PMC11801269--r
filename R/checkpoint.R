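# Single-file JSON checkpoints: config, fitted preprocessors and every
# trainable parameter (encoding banks, backbone, fusion, classifier, Meta)
# serialized losslessly (full double precision) and restored bit-for-bit.

pack_tree <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.function(x)) stop_flex("cannot serialize a function")
  if (is.list(x) && !is.data.frame(x)) {
    at <- attributes(x)
    at$names <- NULL
    list(t = "list", nm = names(x) %||% character(0),
         items = lapply(x, pack_tree),
         at = if (length(at)) lapply(at, pack_tree) else NULL)
  } else if (is.numeric(x)) {
    list(t = "num", d = dim(x), v = as.numeric(x), nm = names(x))
  } else if (is.character(x) || is.logical(x) || is.integer(x)) {
    list(t = class(x)[1], v = x, nm = names(x))
  } else stop_flex("cannot serialize object of class %s", class(x)[1])
}

unpack_tree <- function(p) {
  if (identical(p$t, "null") || is.null(p$t)) return(NULL)
  if (p$t == "list") {
    out <- lapply(p$items, unpack_tree)
    if (length(p$nm)) names(out) <- p$nm
    if (!is.null(p$at))
      for (a in names(p$at)) attr(out, a) <- unpack_tree(p$at[[a]])
    out
  } else if (p$t == "num") {
    v <- as.numeric(p$v)
    if (!is.null(p$d) && length(p$d)) dim(v) <- as.integer(p$d)
    if (!is.null(p$nm) && length(p$nm)) names(v) <- p$nm
    v
  } else {
    v <- switch(p$t, character = as.character(p$v),
                logical = as.logical(p$v), integer = as.integer(p$v), p$v)
    if (!is.null(p$nm) && length(p$nm)) names(v) <- p$nm
    v
  }
}

#' Save a trained model to a single JSON checkpoint
#'
#' @param model A \code{flex_model}.
#' @param path Output path (conventionally \code{.json}).
#' @return The path, invisibly.
#' @export
save_flex_model <- function(model, path) {
  payload <- list(
    format = "flexfuse-checkpoint-1",
    config = pack_tree(model$config),
    fcfg = pack_tree(model$fcfg),
    backbone_cfg = pack_tree(model$backbone_cfg),
    mappers = pack_tree(model$mappers),
    scalers = pack_tree(model$scalers),
    params = pack_tree(model$params),
    n_train = model$n_train,
    fit_ids = model$fit_ids,
    history = pack_tree(as.list(model$history)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_flex_model()]
#' @param path Checkpoint path.
#' @return A \code{flex_model}.
#' @export
load_flex_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                           simplifyDataFrame = FALSE)
  assert_that(identical(p$format, "flexfuse-checkpoint-1"),
              "%s is not a flexfuse checkpoint", path)
  model <- structure(list(
    config = unpack_tree(p$config), fcfg = unpack_tree(p$fcfg),
    backbone_cfg = unpack_tree(p$backbone_cfg),
    mappers = unpack_tree(p$mappers), scalers = unpack_tree(p$scalers),
    params = unpack_tree(p$params), n_train = p$n_train,
    fit_ids = unlist(p$fit_ids)), class = "flex_model")
  h <- unpack_tree(p$history)
  if (!is.null(h)) model$history <- as.data.frame(h)
  model
}
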