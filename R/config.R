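# Run configuration: one nested list carrying every threshold, protocol
# setting, sample size and seed, serializable losslessly to JSON (or YAML).

#' Default pipeline configuration
#'
#' All tunable settings of the virtual-cohort pipeline in one list:
#' sampling sizes and seeds, the acceptability thresholds (80 cells/uL
#' recovery, the 1-100 cells/uL stem band, 20\% depletion, the 12x overshoot
#' and 18\% oscillation cutoffs, one order of magnitude for the marginal
#' pools), the chemotherapy window, clustering settings (k pinned to 13 by
#' default), and the cancer screen settings (Table-style bounds multipliers,
#' 625 draws per representative at full scale, the 20\% blast and 3e5
#' cells/uL endpoints, the one-cell seed concentration).
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return A `leuko_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    sampling = list(n_uni = 2000, n_multi = 2000, fold = 5),
    criteria = criteria_thresholds(),
    chemo = list(start = -7, end = 0, infusion = 1),
    clustering = list(k = 13, k_range = 2:15, n_init = 10),
    cancer = list(n_per = 625, source = "monocyte",
                  horizon = 730, diagnosis_window = 365,
                  thresholds = aml_thresholds(),
                  method = "spearman", endpoint = "death_day",
                  mr_upper_absolute = FALSE),
    equilibrium = list(max_horizon = 4000, window = 400)
  ), class = c("leuko_config", "list"))
}

#' Write / read a pipeline configuration
#'
#' JSON by default; YAML when the path ends in `.yml`/`.yaml` (requires the
#' yaml package). Round-trips losslessly.
#'
#' @param config A [default_config()]-style list.
#' @param path File path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # parsers read whole numbers back as integers; normalise numeric types so
  # a round-tripped configuration hashes identically
  to_double <- function(x) {
    if (is.list(x)) lapply(x, to_double)
    else if (is.integer(x)) as.numeric(x)
    else x
  }
  cfg <- to_double(cfg)
  cfg$clustering$k_range <- as.integer(cfg$clustering$k_range)
  structure(cfg, class = c("leuko_config", "list"))
}

#' Stable hash of a configuration
#' @param config Configuration list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  # hash the canonical JSON text: stable across string-encoding flags that
  # differ between in-memory and file-parsed configurations
  rlang::hash(as.character(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA)))
}
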