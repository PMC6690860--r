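#' Normalize raw tokens
#'
#' Applies the package's token policy: case folding plus handling of
#' part-of-speech-tagged tokens from the public Google Books Ngram corpus
#' (e.g. `"burnt_VERB"`, `"_START_"`). Tagged tokens duplicate their untagged
#' counterparts in that corpus, so the default policy drops them outright;
#' the alternative strips the tag suffix instead.
#'
#' @param tokens character vector of raw tokens.
#' @param policy token policy as returned by [token_policy()].
#' @return character vector of the same length; dropped tokens are `NA`.
#' @examples
#' normalize_token(c("Gay", "burnt_VERB", "hong"))
#' @export
normalize_token <- function(tokens, policy = token_policy()) {
  out <- if (policy$lowercase) tolower(tokens) else tokens
  tagged <- grepl("_", out, fixed = TRUE)
  if (any(tagged)) {
    if (policy$tagged == "drop") {
      out[tagged] <- NA_character_
    } else {
      stripped <- sub("_[^_]*$", "", out[tagged])
      # sentinel markers like _START_ have no word part once stripped
      stripped[!nzchar(stripped) | startsWith(stripped, "_")] <- NA_character_
      out[tagged] <- stripped
    }
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Token normalization policy
#'
#' @param lowercase fold tokens to lower case (default `TRUE`).
#' @param tagged what to do with tokens containing the Google POS-tag
#'   separator `"_"`: `"drop"` (default; avoids double counting against the
#'   untagged ngrams) or `"strip"` (remove the `_TAG` suffix).
#' @return a list of class `token_policy`.
#' @export
token_policy <- function(lowercase = TRUE, tagged = c("drop", "strip")) {
  tagged <- match.arg(tagged)
  structure(list(lowercase = lowercase, tagged = tagged),
            class = "token_policy")
}

#' Parse 5-gram TSV lines
#'
#' Parses lines in the Google Books Ngram v2 5-gram dialect
#' (`ngram \t year \t match_count \t volume_count`, ngram space-separated).
#' Malformed lines (fewer than 4 tab fields, a non-integer year or count, or
#' an ngram that is not exactly 5 tokens) are counted and skipped; parsing
#' aborts if their fraction exceeds `max_malformed_frac`.
#'
#' @param lines character vector of raw lines.
#' @param year_range integer length-2 inclusive year filter, or `NULL` for no
#'   filtering. Default `c(1800, 2009)`.
#' @param max_malformed_frac abort threshold on the malformed-line fraction
#'   (default 0.1).
#' @return an object of class `ngram_records`: a list with `tokens` (an
#'   n x 5 character matrix), `year`, `match_count`, `volume_count` (integer
#'   vectors), and counters `n_malformed`, `n_year_filtered`.
#' @examples
#' parse_ngram_lines("cheerful gay colours of the\t1850\t12\t9")
#' @export
parse_ngram_lines <- function(lines, year_range = c(1800L, 2009L),
                              max_malformed_frac = 0.1) {
  lines <- lines[nzchar(lines)]
  n_in <- length(lines)
  if (n_in == 0L) {
    return(new_ngram_records(matrix(character(), 0, 5), integer(), integer(),
                             integer(), n_malformed = 0L, n_year_filtered = 0L))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  ok <- nf >= 4L
  gram <- ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_)
  year <- suppressWarnings(as.integer(ifelse(ok, vapply(parts, `[`, "", 2L), NA)))
  mc   <- suppressWarnings(as.integer(ifelse(ok, vapply(parts, `[`, "", 3L), NA)))
  vc   <- suppressWarnings(as.integer(ifelse(ok, vapply(parts, `[`, "", 4L), NA)))
  toks <- strsplit(gram, " ", fixed = TRUE)
  ok <- ok & !is.na(year) & !is.na(mc) & mc >= 1L & lengths(toks) == 5L
  n_malformed <- sum(!ok)
  if (n_malformed / n_in > max_malformed_frac) {
    stop(sprintf("aborting parse: %d of %d lines malformed (> %.0f%% tolerance)",
                 n_malformed, n_in, 100 * max_malformed_frac))
  }
  keep_year <- rep(TRUE, n_in)
  if (!is.null(year_range)) {
    keep_year <- !is.na(year) & year >= year_range[1] & year <= year_range[2]
  }
  n_year_filtered <- sum(ok & !keep_year)
  keep <- ok & keep_year
  tok_mat <- matrix(unlist(toks[keep], use.names = FALSE),
                    ncol = 5, byrow = TRUE)
  new_ngram_records(tok_mat, year[keep], mc[keep],
                    ifelse(is.na(vc[keep]), 0L, vc[keep]),
                    n_malformed = n_malformed,
                    n_year_filtered = n_year_filtered)
}

new_ngram_records <- function(tokens, year, match_count, volume_count,
                              n_malformed = 0L, n_year_filtered = 0L) {
  structure(list(tokens = tokens, year = as.integer(year),
                 match_count = as.integer(match_count),
                 volume_count = as.integer(volume_count),
                 n_malformed = as.integer(n_malformed),
                 n_year_filtered = as.integer(n_year_filtered)),
            class = "ngram_records")
}

#' @export
print.ngram_records <- function(x, ...) {
  cat(sprintf("<ngram_records> %d records, years %s..%s, %d malformed skipped\n",
              nrow(x$tokens),
              if (length(x$year)) min(x$year) else NA,
              if (length(x$year)) max(x$year) else NA,
              x$n_malformed))
  invisible(x)
}

#' Number of records
#' @param x an `ngram_records` object.
#' @export
n_records <- function(x) nrow(x$tokens)

#' Read a 5-gram corpus from disk
#'
#' Reads one or more 5-gram TSV files (gzip-transparent) or every `*.tsv` /
#' `*.tsv.gz` file in a directory, concatenating the parsed records.
#'
#' @param path file path(s) or a single directory.
#' @inheritParams parse_ngram_lines
#' @return an `ngram_records` object.
#' @export
read_ngram_corpus <- function(path, year_range = c(1800L, 2009L),
                              max_malformed_frac = 0.1) {
  if (length(path) == 1L && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.tsv(\\.gz)?$",
                            full.names = TRUE))
  }
  if (length(path) == 0L) stop("no corpus files found")
  lines <- unlist(lapply(path, function(p) {
    con <- gzfile(p, "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  }), use.names = FALSE)
  parse_ngram_lines(lines, year_range = year_range,
                    max_malformed_frac = max_malformed_frac)
}

#' Serialize records back to the 5-gram TSV dialect
#'
#' @param records an `ngram_records` object.
#' @param path output file (one file; see [generate_corpus()] for the
#'   per-year layout).
#' @return `path`, invisibly.
#' @export
write_ngram_records <- function(records, path) {
  lines <- ngram_record_lines(records)
  writeLines(lines, path)
  invisible(path)
}

ngram_record_lines <- function(records) {
  grams <- apply(records$tokens, 1L, paste, collapse = " ")
  if (length(grams) == 0L) grams <- character()
  sprintf("%s\t%d\t%d\t%d", grams, records$year, records$match_count,
          records$volume_count)
}

#' Apply the token policy to parsed records
#'
#' Lowercases (per policy) and marks dropped tokens as `NA`; records keep
#' their position structure so co-occurrence counting can use the surviving
#' tokens of a partially dropped 5-gram.
#'
#' @param records an `ngram_records` object.
#' @param policy a [token_policy()].
#' @return an `ngram_records` object with normalized tokens.
#' @export
normalize_records <- function(records, policy = token_policy()) {
  records$tokens[] <- normalize_token(as.vector(records$tokens), policy)
  records
}

#' Per-year token counts
#'
#' Aggregates `match_count` over every token slot containing a word, by year.
#' `NA` (dropped) tokens are excluded.
#'
#' @param records normalized `ngram_records`.
#' @return a `data.table` with columns `word`, `year`, `count`.
#' @export
count_tokens <- function(records) {
  n <- n_records(records)
  dt <- data.table::data.table(
    word = as.vector(records$tokens),
    year = rep(records$year, times = 5L),
    count = rep(records$match_count, times = 5L))
  dt <- dt[!is.na(word)]
  out <- dt[, list(count = sum(count)), by = c("word", "year")]
  data.table::setkeyv(out, c("word", "year"))
  out[]
}

#' Per-year total token counts
#'
#' The denominator of relative frequency: the total number of (surviving)
#' tokens in the corpus each year, i.e. `match_count` summed over every
#' non-dropped token slot. For complete 5-gram records this is 5 x
#' `match_count`. Years absent from the corpus are absent from the result.
#'
#' @param records normalized `ngram_records`.
#' @return named numeric vector, names = years.
#' @export
year_totals <- function(records) {
  surviving <- rowSums(!is.na(records$tokens))
  dt <- data.table::data.table(year = records$year,
                               n = surviving * as.numeric(records$match_count))
  agg <- dt[, list(total = sum(n)), by = "year"]
  data.table::setorderv(agg, "year")
  setNames(agg$total, as.character(agg$year))
}

#' Build the analysis vocabulary
#'
#' Ranks words by aggregate token count across all years (ties broken
#' lexicographically) and keeps the top `cap`.
#'
#' @param counts per-year counts from [count_tokens()], or an `ngram_records`
#'   object (counted internally).
#' @param cap maximum vocabulary size K (default 50000, the size used for the
#'   full historical corpus).
#' @return an object of class `vocabulary`: list with `words` (rank order),
#'   `index` (named integer positions), `counts` (aggregate counts in rank
#'   order).
#' @export
build_vocabulary <- function(counts, cap = 50000L) {
  stopifnot(cap >= 1L)
  if (inherits(counts, "ngram_records")) counts <- count_tokens(counts)
  if (nrow(counts) == 0L) {
    warning("empty record stream: returning empty vocabulary")
    return(new_vocabulary(character(), numeric()))
  }
  agg <- counts[, list(count = sum(count)), by = "word"]
  data.table::setorderv(agg, c("count", "word"), order = c(-1L, 1L))
  agg <- utils::head(agg, cap)
  new_vocabulary(agg$word, agg$count)
}

new_vocabulary <- function(words, counts) {
  structure(list(words = words,
                 index = setNames(seq_along(words), words),
                 counts = setNames(as.numeric(counts), words)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d words; top: %s\n", length(x$words),
              paste(utils::head(x$words, 5), collapse = ", ")))
  invisible(x)
}

#' @export
length.vocabulary <- function(x) length(x$words)

#' Relative usage frequency of a word in a year
#'
#' The number of instances of the word in the year divided by the total
#' number of corpus tokens that year.
#'
#' @param word a word (normalized form).
#' @param year integer year.
#' @param counts per-year counts from [count_tokens()].
#' @param totals named totals from [year_totals()].
#' @return a proportion in `[0, 1]`; 0 if the word is unseen that year.
#' @export
relative_frequency <- function(word, year, counts, totals) {
  ykey <- as.character(year)
  if (!ykey %in% names(totals)) {
    stop(sprintf("year %s absent from corpus totals", ykey))
  }
  if (totals[[ykey]] <= 0) stop(sprintf("year %s has zero total tokens", ykey))
  w <- word; y <- as.integer(year)
  hit <- counts[list(w, y), on = c("word", "year"), nomatch = NULL]
  cnt <- if (nrow(hit)) sum(hit$count) else 0
  cnt / totals[[ykey]]
}

#' Relative-frequency time series with optional smoothing
#'
#' One point per requested year; smoothing is a centered moving average with
#' window `2 * smooth + 1` (partial windows at the boundaries, so a constant
#' series is returned unchanged).
#'
#' @param word a word present somewhere in the corpus.
#' @param counts,totals as in [relative_frequency()].
#' @param years integer years to evaluate; default all years in `totals`.
#' @param smooth half-window s >= 0 (default 0 = no smoothing).
#' @return a data.frame of class `frequency_series` with columns `year`,
#'   `frequency` (raw) and `smoothed`.
#' @export
frequency_series <- function(word, counts, totals,
                             years = as.integer(names(totals)), smooth = 0L) {
  if (!word %in% counts$word) stop(sprintf("word '%s' not found in corpus", word))
  years <- sort(as.integer(years))
  if (smooth < 0L) stop("smooth must be >= 0")
  if (2L * smooth + 1L > length(years)) stop("smoothing window exceeds series length")
  freq <- vapply(years, function(y)
    relative_frequency(word, y, counts, totals), numeric(1))
  smoothed <- moving_average(freq, smooth)
  structure(data.frame(year = years, frequency = freq, smoothed = smoothed),
            word = word, smooth = smooth,
            class = c("frequency_series", "data.frame"))
}

moving_average <- function(x, s) {
  if (s == 0L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - s); hi <- min(n, i + s)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Write a frequency series as CSV (`word,year,frequency`)
#' @param series a [frequency_series()] result.
#' @param path output CSV path.
#' @param smoothed write the smoothed column instead of the raw one.
#' @export
write_frequency_csv <- function(series, path, smoothed = FALSE) {
  df <- data.frame(word = attr(series, "word"), year = series$year,
                   frequency = if (smoothed) series$smoothed else series$frequency)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text corpus with year labels
#'
#' One document per file; the year comes from the file name
#' (`<year>.txt`). Documents are whitespace-tokenized and normalized.
#'
#' @param dir directory of `<year>.txt` files.
#' @param policy a [token_policy()].
#' @return a list with `tokens` (list of character vectors) and `year`.
#' @export
read_text_corpus <- function(dir, policy = token_policy()) {
  files <- sort(list.files(dir, pattern = "^[0-9]{3,4}\\.txt$", full.names = TRUE))
  if (length(files) == 0L) stop("no <year>.txt files found in ", dir)
  years <- as.integer(sub("\\.txt$", "", basename(files)))
  toks <- lapply(files, function(f) {
    raw <- scan(f, what = character(), quiet = TRUE)
    tk <- normalize_token(raw, policy)
    tk[!is.na(tk)]
  })
  list(tokens = toks, year = years)
}
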