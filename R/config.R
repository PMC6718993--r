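# Pipeline configuration: the operational knobs shared across subcommands,
# serialized as JSON.

#' Default pipeline configuration
#'
#' @return a list with the operational settings: `threshold` (degC, weekly
#'   exceedance product), `exposure` (`"sun"`/`"shade"`), `collapse_quantile`
#'   (personal ensemble collapse), `qualifying_days` and `reset_days`
#'   (acclimatization rule), `min_n` and `n_grid` (EQM calibration), `seed`.
#' @export
default_pipeline_config <- function() {
  list(threshold = 27, exposure = "sun", collapse_quantile = 0.5,
       qualifying_days = 5L, reset_days = 30L,
       min_n = 100L, n_grid = 99L, seed = 1L)
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path JSON file of configuration settings.
#' @return a validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(x), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(x)] <- x
  if (!is.finite(cfg$threshold)) stop("threshold must be finite")
  if (cfg$collapse_quantile <= 0 || cfg$collapse_quantile >= 1)
    stop("collapse_quantile must lie in (0, 1)")
  if (!cfg$exposure %in% c("sun", "shade"))
    stop("exposure must be 'sun' or 'shade'")
  cfg$qualifying_days <- as.integer(cfg$qualifying_days)
  cfg$reset_days <- as.integer(cfg$reset_days)
  cfg$min_n <- as.integer(cfg$min_n)
  cfg$n_grid <- as.integer(cfg$n_grid)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a pipeline configuration to JSON
#'
#' @param cfg a configuration list (see [default_pipeline_config()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
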