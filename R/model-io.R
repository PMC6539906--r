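#' Serialize a fitted model to JSON
#'
#' The file stores the color space, the group anchor light levels, the
#' 3 x 3 threshold table, the directions, the chosen combination, the split
#' configuration and the package version, at full double precision so a
#' read-back round trip is lossless.
#'
#' @param model a `fruit_model`.
#' @param path output path (`.json`).
#' @export
write_fruit_model <- function(model, path) {
  obj <- list(
    type = "fruit_model",
    version = as.character(utils::packageVersion("fruitseg")),
    space = model$space,
    hsi_variant = model$hsi_variant,
    group_levels = as.list(model$group_levels),
    thresholds = lapply(seq_len(nrow(model$thresholds)), function(i)
      as.numeric(model$thresholds[i, ])),
    directions = model$directions,
    combination = model$combination,
    interp = model$interp,
    split_config = unclass(model$split_config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path path written by [write_fruit_model()].
#' @return a `fruit_model`.
#' @export
read_fruit_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "fruit_model"))
    stop("not a fruit_model file", call. = FALSE)
  groups <- c("low", "medium", "high")
  th <- obj$thresholds  # stored row-wise; jsonlite may pre-simplify
  if (!is.matrix(th)) th <- matrix(unlist(th), nrow = 3, byrow = TRUE)
  dimnames(th) <- list(groups, NULL)
  structure(list(
    space = obj$space,
    group_levels = unlist(obj$group_levels)[groups],
    thresholds = th,
    directions = as.character(obj$directions),
    combination = obj$combination,
    split_config = do.call(split_config, lapply(obj$split_config, as.numeric)),
    interp = obj$interp,
    hsi_variant = obj$hsi_variant,
    training = list()
  ), class = "fruit_model")
}

#' Serialize tuned parameters to JSON
#'
#' @param tuning a `fruit_tuning` object.
#' @param path output path.
#' @export
write_fruit_tuning <- function(tuning, path) {
  obj <- c(list(type = "fruit_tuning"),
           unclass(tuning)[c("t1", "t2", "t_over", "std_stop", "directions",
                             "space", "min_side", "hsi_variant")],
           list(light_stats = tuning$light_stats))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read tuned parameters from JSON
#'
#' @param path path written by [write_fruit_tuning()].
#' @return a `fruit_tuning` object.
#' @export
read_fruit_tuning <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "fruit_tuning"))
    stop("not a fruit_tuning file", call. = FALSE)
  obj$type <- NULL
  obj$directions <- as.character(obj$directions)
  structure(obj, class = "fruit_tuning")
}
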