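# YAML/JSON run configuration covering model + training + data layout.

#' Read a run configuration file
#'
#' The file (YAML, or JSON — a YAML subset) may hold three sections:
#' `model` (arguments of [model_config()], with nested `psa` and `stages`
#' lists), `train` (arguments of [train_config()]) and `data`
#' (`image_dir`, `mask_dir`, optional `split` fractions and `split_seed`).
#' Missing sections fall back to defaults.
#'
#' @param path configuration file
#' @return list with `model` (`mhanet_config`), `train` (`train_config`)
#'   and `data` (plain list)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  m <- raw$model %||% list()
  if (!is.null(m$psa)) m$psa <- do.call(psa_config, m$psa)
  if (!is.null(m$stages))
    m$stages <- lapply(m$stages, function(s)
      do.call(decoder_stage_config, s))
  if (!is.null(m$input_size)) m$input_size <- unlist(m$input_size)
  model <- do.call(model_config, m)
  tcfg <- do.call(train_config, raw$train %||% list())
  list(model = model, train = tcfg, data = raw$data %||% list())
}

#' Write a run configuration file
#'
#' Round-trips through [read_run_config()].
#'
#' @param model a `mhanet_config`
#' @param train a `train_config`
#' @param data plain list describing the dataset layout
#' @param path output file
#' @return `path`, invisibly
#' @export
write_run_config <- function(model, train = train_config(),
                             data = list(), path) {
  m <- unclass(model)
  m$psa <- unclass(m$psa)
  m$stages <- lapply(m$stages, unclass)
  m$base_width <- NULL   # derived from width_mult
  yaml::write_yaml(list(model = m, train = unclass(train), data = data),
                   path)
  invisible(path)
}
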