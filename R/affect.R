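#' Load a word-norms lexicon
#'
#' Reads a ratings table with a `word` column plus any subset of `valence`,
#' `arousal` (scale 1-9) and `concreteness` (scale 1-5). Words are
#' case-folded; duplicate words keep their first occurrence (with a warning);
#' rows with any out-of-bounds rating are rejected (with a warning).
#'
#' @param source a CSV path or a data.frame.
#' @param provenance free-text label recorded on the lexicon.
#' @return an object of class `norm_lexicon`: a data.frame with column `word`
#'   and the available rating columns; attributes `provenance`, `n_duplicates`,
#'   `n_rejected`.
#' @export
load_norms <- function(source, provenance = "unspecified") {
  df <- if (is.character(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE)
  } else as.data.frame(source)
  if (!"word" %in% names(df)) stop("norms table needs a 'word' column")
  dims <- intersect(c("valence", "arousal", "concreteness"), names(df))
  if (length(dims) == 0L) {
    stop("norms table has no recognizable rating columns ",
         "(valence, arousal, concreteness)")
  }
  df <- df[c("word", dims)]
  df$word <- tolower(df$word)
  bounds <- affect_scale_bounds()
  bad <- rep(FALSE, nrow(df))
  for (dim in dims) {
    v <- df[[dim]]
    bad <- bad | (!is.na(v) & (v < bounds[[dim]][1] | v > bounds[[dim]][2]))
  }
  if (any(bad)) {
    warning(sprintf("%d norm rows rejected for out-of-bounds ratings", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df$word)
  if (any(dup)) {
    warning(sprintf("%d duplicate norm words resolved by first occurrence", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance, n_duplicates = sum(dup),
            n_rejected = sum(bad), class = c("norm_lexicon", "data.frame"))
}

affect_scale_bounds <- function() {
  list(valence = c(1, 9), arousal = c(1, 9), concreteness = c(1, 5))
}

#' Contextual affect of a word in a year
#'
#' Scores a word's context by the published norm ratings of the words it
#' co-occurs with that year. Token-weighted (default): the rating of each
#' rated context word, weighted by its co-occurrence count with the target
#' (the diagonal excluded). Type-unweighted: the plain mean over rated
#' context types. Coverage is the proportion of the target's co-occurrence
#' mass carried by rated words, so low-coverage years can be masked
#' downstream.
#'
#' @param word target word (in the tensor vocabulary).
#' @param year integer year present in the tensor.
#' @param tensor a `cooc_tensor`.
#' @param norms a [load_norms()] lexicon.
#' @param dimension one of `"valence"`, `"arousal"`, `"concreteness"`.
#' @param weighting `"token"` (default) or `"type"`.
#' @return a one-row data.frame of class `affect_score` with columns `word`,
#'   `year`, `dimension`, `value`, `n_context_types`, `coverage`.
#' @export
contextual_affect <- function(word, year, tensor, norms,
                              dimension = c("valence", "arousal", "concreteness"),
                              weighting = c("token", "type")) {
  dimension <- match.arg(dimension)
  weighting <- match.arg(weighting)
  if (!dimension %in% names(norms)) {
    stop(sprintf("norms lexicon has no '%s' ratings", dimension))
  }
  vocab <- tensor$vocabulary
  if (!word %in% vocab$words) stop(sprintf("'%s' not in vocabulary", word))
  slice <- tensor_slice(tensor, year)
  row <- slice[word, ]
  row[word] <- 0  # diagonal excluded
  ctx <- row[row > 0]
  total_mass <- sum(ctx)
  ratings <- setNames(norms[[dimension]], norms$word)[names(ctx)]
  rated <- !is.na(ratings)
  coverage <- if (total_mass > 0) sum(ctx[rated]) / total_mass else 0
  if (!any(rated)) {
    cond <- structure(
      class = c("diasem_undefined_affect", "error", "condition"),
      list(message = sprintf(
        "no rated context words for '%s' in %d (coverage 0)", word, year),
        call = sys.call(-1), coverage = 0))
    stop(cond)
  }
  value <- if (weighting == "token") {
    sum(ctx[rated] * ratings[rated]) / sum(ctx[rated])
  } else {
    mean(ratings[rated])
  }
  structure(data.frame(word = word, year = as.integer(year),
                       dimension = dimension, value = value,
                       n_context_types = sum(rated), coverage = coverage,
                       row.names = NULL),
            weighting = weighting,
            class = c("affect_score", "data.frame"))
}

#' Contextual-affect time series
#'
#' One [contextual_affect()] score per available year; years where the score
#' is undefined (no rated context) are emitted as `NA` gaps, never
#' interpolated.
#'
#' @inheritParams contextual_affect
#' @param years integer years (default: all years in the tensor).
#' @return a data.frame with one row per year (columns as in
#'   [contextual_affect()]); `value` is `NA` on gap years.
#' @export
affect_series <- function(word, tensor, norms,
                          dimension = c("valence", "arousal", "concreteness"),
                          weighting = c("token", "type"),
                          years = tensor_years(tensor)) {
  dimension <- match.arg(dimension)
  weighting <- match.arg(weighting)
  rows <- lapply(sort(as.integer(years)), function(y) {
    tryCatch(
      contextual_affect(word, y, tensor, norms, dimension, weighting),
      diasem_undefined_affect = function(e) {
        data.frame(word = word, year = y, dimension = dimension,
                   value = NA_real_, n_context_types = 0L, coverage = 0)
      })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write affect scores as CSV
#' (`word,year,dimension,value,n_context_types,coverage`)
#' @param scores an [affect_series()] (or single-score) data.frame.
#' @param path output CSV path.
#' @export
write_affect_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
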