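#' Default run configuration
#'
#' The documented defaults used across the pipeline: vocabulary cap
#' K = 50000, embedding dimension d = 300 with singular-value exponent
#' p = 0.5, year range 1800-2009, synonym-network edge threshold 0.8,
#' context-network PPMI threshold 3 and minimum co-occurrence rate 200 per
#' 1e10 words, no smoothing, seed 1.
#'
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    corpus = NULL,
    store = NULL,
    norms = NULL,
    vocab_size = 50000L,
    year_range = c(1800L, 2009L),
    dim = 300L,
    factor_exponent = 0.5,
    edge_threshold = 0.8,
    ppmi_threshold = 3.0,
    min_rate = 200,
    per = 1e10,
    smooth = 0L,
    k = 5L,
    seed = 1L,
    log_level = "info"),
    class = "run_config")
}

#' Resolve a run configuration from layered sources
#'
#' Precedence: command-line flags > config file > package defaults. Unknown
#' keys in either source are an error naming them. The resolved configuration
#' should be embedded in every analysis output's metadata for
#' reproducibility.
#'
#' @param defaults base configuration (default [default_run_config()]).
#' @param file optional path to a JSON config file.
#' @param flags named list of overrides (highest precedence).
#' @return a `run_config` list.
#' @export
resolve_config <- function(defaults = default_run_config(), file = NULL,
                           flags = list()) {
  cfg <- unclass(defaults)
  layers <- list()
  if (!is.null(file)) {
    layers$file <- jsonlite::read_json(file, simplifyVector = TRUE)
  }
  layers$flags <- flags
  for (layer in layers) {
    if (length(layer) == 0L) next
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(layer)) {
      if (!is.null(layer[[k]])) cfg[[k]] <- layer[[k]]
    }
  }
  int_keys <- c("vocab_size", "dim", "smooth", "k", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  cfg$year_range <- as.integer(cfg$year_range)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-15s %s\n", k,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# metadata block embedded in analysis outputs
run_metadata <- function(cfg) {
  list(package = "diasem",
       version = as.character(utils::packageVersion("diasem")),
       config = unclass(cfg))
}
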