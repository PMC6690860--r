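#' Accumulate the year-sliced co-occurrence tensor
#'
#' Counts, per year, how often every unordered pair of vocabulary words
#' co-occurs within a 5-gram. Each record contributes `match_count` to every
#' pair of token positions whose both tokens are in the vocabulary (10 pairs
#' for a complete 5-gram); repeated words accumulate on the diagonal. Pair
#' weighting is flat: no distance decay.
#'
#' @param records normalized `ngram_records`.
#' @param vocab a [build_vocabulary()] result.
#' @return an object of class `cooc_tensor`: list with `slices` (named list,
#'   year -> sparse symmetric `Matrix`), `vocabulary`, `mode = "ngram"`.
#' @export
accumulate_cooccurrence <- function(records, vocab) {
  if (length(vocab) == 0L) stop("vocabulary is empty")
  n <- n_records(records)
  idx <- matrix(match(as.vector(records$tokens), vocab$words),
                nrow = n, ncol = 5L)
  pairs <- utils::combn(5L, 2L)
  chunks <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- idx[, pairs[1L, k]]
    b <- idx[, pairs[2L, k]]
    keep <- !is.na(a) & !is.na(b)
    chunks[[k]] <- data.table::data.table(
      year = records$year[keep],
      i = pmin(a[keep], b[keep]),
      j = pmax(a[keep], b[keep]),
      x = as.numeric(records$match_count[keep]))
  }
  events <- data.table::rbindlist(chunks)
  new_cooc_tensor(events, vocab, mode = "ngram")
}

new_cooc_tensor <- function(events, vocab, mode) {
  V <- length(vocab)
  if (nrow(events) == 0L) {
    slices <- list()
  } else {
    agg <- events[, list(x = sum(x)), by = c("year", "i", "j")]
    data.table::setorderv(agg, c("year", "i", "j"))
    slices <- lapply(split(agg, by = "year", keep.by = FALSE), function(d) {
      Matrix::sparseMatrix(i = d$i, j = d$j, x = d$x, dims = c(V, V),
                           dimnames = list(vocab$words, vocab$words),
                           symmetric = TRUE)
    })
    slices <- slices[order(as.integer(names(slices)))]
  }
  structure(list(slices = slices, vocabulary = vocab, mode = mode),
            class = "cooc_tensor")
}

#' @export
print.cooc_tensor <- function(x, ...) {
  cat(sprintf("<cooc_tensor> %d years (%s), %d-word vocabulary, mode=%s\n",
              length(x$slices), paste(range(tensor_years(x)), collapse = ".."),
              length(x$vocabulary), x$mode))
  invisible(x)
}

#' Years present in a tensor
#' @param tensor a `cooc_tensor`.
#' @export
tensor_years <- function(tensor) as.integer(names(tensor$slices))

#' Fetch one year's co-occurrence slice
#' @param tensor a `cooc_tensor`.
#' @param year integer year.
#' @return a sparse symmetric matrix.
#' @export
tensor_slice <- function(tensor, year) {
  key <- as.character(year)
  if (!key %in% names(tensor$slices)) {
    stop(sprintf("year %s not present in co-occurrence tensor", key))
  }
  tensor$slices[[key]]
}

#' Total number of pair events in a slice
#'
#' Off-diagonal unordered pairs counted once plus diagonal events.
#'
#' @param slice a symmetric co-occurrence matrix.
#' @export
pair_total <- function(slice) {
  d <- sum(Matrix::diag(slice))
  (sum(slice) - d) / 2 + d
}

#' Sliding-window pair contributions for plain text
#'
#' Every unordered pair of token positions at distance `< window` contributes
#' one co-occurrence event (flat weighting). Used for plain-text corpora; the
#' 5-gram mode counts within records instead.
#'
#' @param tokens character vector (a tokenized document), `NA` = dropped.
#' @param window window size (default 5): positions i < j pair iff
#'   `j - i < window`.
#' @return a `data.table` with columns `w1`, `w2` (canonical order), `count`.
#' @export
sliding_window_pairs <- function(tokens, window = 5L) {
  stopifnot(window >= 2L)
  n <- length(tokens)
  chunks <- list()
  for (off in seq_len(min(window - 1L, max(n - 1L, 0L)))) {
    a <- tokens[seq_len(n - off)]
    b <- tokens[seq_len(n - off) + off]
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) {
      chunks[[off]] <- data.table::data.table(
        w1 = pmin(a[keep], b[keep]), w2 = pmax(a[keep], b[keep]))
    }
  }
  if (length(chunks) == 0L) {
    return(data.table::data.table(w1 = character(), w2 = character(),
                                  count = numeric()))
  }
  ev <- data.table::rbindlist(chunks)
  out <- ev[, list(count = as.numeric(.N)), by = c("w1", "w2")]
  data.table::setorderv(out, c("w1", "w2"))
  out[]
}

#' Co-occurrence tensor from plain-text documents
#'
#' @param corpus a list as returned by [read_text_corpus()] (fields `tokens`,
#'   `year`).
#' @param vocab a [build_vocabulary()] result.
#' @param window sliding window size (default 5).
#' @return a `cooc_tensor` with `mode = "window"`.
#' @export
accumulate_window_cooccurrence <- function(corpus, vocab, window = 5L) {
  if (length(vocab) == 0L) stop("vocabulary is empty")
  chunks <- mapply(function(toks, yr) {
    p <- sliding_window_pairs(toks, window)
    if (nrow(p) == 0L) return(NULL)
    i <- vocab$index[p$w1]; j <- vocab$index[p$w2]
    keep <- !is.na(i) & !is.na(j)
    data.table::data.table(year = yr, i = pmin(i[keep], j[keep]),
                           j = pmax(i[keep], j[keep]), x = p$count[keep])
  }, corpus$tokens, corpus$year, SIMPLIFY = FALSE)
  events <- data.table::rbindlist(chunks[!vapply(chunks, is.null, TRUE)])
  new_cooc_tensor(events, vocab, mode = "window")
}

#' Sum co-occurrence slices over years
#'
#' @param tensor a `cooc_tensor`.
#' @param years integer years to aggregate (all must be present).
#' @return a sparse symmetric matrix (entrywise sum).
#' @export
aggregate_slices <- function(tensor, years) {
  stopifnot(length(years) > 0L)
  keys <- as.character(years)
  missing <- setdiff(keys, names(tensor$slices))
  if (length(missing)) {
    stop("years missing from tensor: ", paste(missing, collapse = ", "))
  }
  Reduce(`+`, tensor$slices[keys])
}

#' Normalized co-occurrence rate
#'
#' Co-occurrence count of a word pair in a year divided by that year's total
#' token count, scaled by `per` (default 10^10, i.e. events per ten billion
#' words; the network module's minimum-rate threshold of 200 is on this
#' scale).
#'
#' @param w1,w2 vocabulary words.
#' @param year integer year.
#' @param tensor a `cooc_tensor`.
#' @param totals named per-year totals from [year_totals()].
#' @param per normalization constant (default `1e10`).
#' @export
cooccurrence_rate <- function(w1, w2, year, tensor, totals, per = 1e10) {
  vocab <- tensor$vocabulary
  if (!w1 %in% vocab$words) stop(sprintf("'%s' not in vocabulary", w1))
  if (!w2 %in% vocab$words) stop(sprintf("'%s' not in vocabulary", w2))
  ykey <- as.character(year)
  if (!ykey %in% names(totals)) stop(sprintf("year %s absent from totals", ykey))
  slice <- tensor_slice(tensor, year)
  as.numeric(slice[w1, w2]) / totals[[ykey]] * per
}

#' Persist a co-occurrence store
#'
#' One MatrixMarket file per year (`cooc_<year>.mtx`), a vocabulary file
#' (`vocab.txt`, one word per line in rank order) and a JSON metadata sidecar
#' (`meta.json`: years, mode, pair totals, per-year token totals).
#'
#' @param tensor a `cooc_tensor`.
#' @param dir output directory (created if needed).
#' @param totals optional named per-year totals to store alongside.
#' @return `dir`, invisibly.
#' @export
save_cooc_store <- function(tensor, dir, totals = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (y in names(tensor$slices)) {
    Matrix::writeMM(tensor$slices[[y]], file.path(dir, sprintf("cooc_%s.mtx", y)))
  }
  writeLines(tensor$vocabulary$words, file.path(dir, "vocab.txt"))
  meta <- list(
    years = tensor_years(tensor),
    mode = tensor$mode,
    pair_totals = as.list(setNames(vapply(tensor$slices, pair_total,
                                          numeric(1)), names(tensor$slices))),
    vocab_counts = unname(tensor$vocabulary$counts),
    year_totals = if (is.null(totals)) NULL else as.list(totals))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a co-occurrence store written by [save_cooc_store()]
#'
#' @param dir store directory.
#' @return a list with `tensor` (a `cooc_tensor`) and `totals` (named numeric
#'   or `NULL`).
#' @export
load_cooc_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  words <- readLines(file.path(dir, "vocab.txt"))
  counts <- if (!is.null(meta$vocab_counts)) meta$vocab_counts else rep(0, length(words))
  vocab <- new_vocabulary(words, counts)
  slices <- lapply(meta$years, function(y) {
    m <- Matrix::readMM(file.path(dir, sprintf("cooc_%d.mtx", y)))
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(words, words)
    m
  })
  names(slices) <- as.character(meta$years)
  tensor <- structure(list(slices = slices, vocabulary = vocab,
                           mode = meta$mode), class = "cooc_tensor")
  totals <- NULL
  if (!is.null(meta$year_totals)) {
    totals <- unlist(meta$year_totals)
  }
  list(tensor = tensor, totals = totals)
}
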