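# One YAML file carries the whole configuration: rule-engine parameters
# and the motif set. Schema version 1.

#' Write a configuration file
#'
#' @param path Output YAML path.
#' @param cfg A [code_config()].
#' @param patterns A motif set, see [default_patterns()].
#' @return `path`, invisibly.
#' @export
write_utrcode_config <- function(path, cfg = code_config(),
                                 patterns = default_patterns()) {
  obj <- list(
    config_version = 1L,
    engine = unclass(cfg),
    patterns = lapply(seq_len(nrow(patterns)), function(i)
      as.list(patterns[i, c("name", "element_class", "pattern")]))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a configuration file
#'
#' Missing engine fields fall back to the package defaults, so a config
#' file may override just the windows it cares about.
#'
#' @param path YAML path written by [write_utrcode_config()] (or by
#'   hand, same schema).
#' @return List with elements `cfg` ([code_config()]) and `patterns`.
#' @export
read_utrcode_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(as.integer(obj$config_version %||% 1L), 1L))
    stop("unsupported config_version in ", path, call. = FALSE)
  eng <- obj$engine %||% list()
  cfg <- do.call(code_config, eng[intersect(names(eng),
                                            names(formals(code_config)))])
  patterns <- if (is.null(obj$patterns)) default_patterns()
  else do.call(rbind, lapply(obj$patterns, function(p)
    motif_pattern(p$name, p$element_class, p$pattern)))
  list(cfg = cfg, patterns = patterns)
}
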