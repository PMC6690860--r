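#' Positive pointwise mutual information matrix
#'
#' Converts one year's co-occurrence slice into a PPMI matrix:
#' `PPMI(vi, vj) = max(0, log(P(vi, vj) / (P(vi) P(vj))))` with natural log.
#' Probabilities are empirical over ordered co-occurrence events with the
#' diagonal excluded: writing `C` for the full symmetric off-diagonal count
#' matrix and `N = sum(C)`, `P(vi, vj) = C[i, j] / N` and
#' `P(vi) = rowSums(C)[i] / N`. Under this convention a pair co-occurring at
#' exactly its independence rate has PMI 0, so PPMI of an independently
#' sampled corpus converges to 0 entrywise. Pairs that never co-occur stay
#' exactly 0. Relative to raw counts, PPMI penalizes ubiquitous
#' high-frequency words and favours pairs that co-occur selectively.
#'
#' @param slice a symmetric co-occurrence matrix (one tensor slice or an
#'   [aggregate_slices()] result).
#' @param year optional year label carried into the result.
#' @return an object of class `ppmi_matrix`: list with `values` (sparse
#'   symmetric matrix, zero diagonal), `year`, `pair_total`.
#' @export
compute_ppmi <- function(slice, year = NA_integer_) {
  C <- methods::as(methods::as(slice, "generalMatrix"), "CsparseMatrix")
  Matrix::diag(C) <- 0
  C <- Matrix::drop0(C)
  N <- sum(C)
  if (N <= 0) stop("co-occurrence slice has no off-diagonal mass")
  rs <- Matrix::rowSums(C)
  tri <- Matrix::summary(C)
  keep <- tri$i <= tri$j
  i <- tri$i[keep]; j <- tri$j[keep]; x <- tri$x[keep]
  val <- pmax(0, log(x) + log(N) - log(rs[i]) - log(rs[j]))
  nz <- val > 0
  values <- Matrix::sparseMatrix(i = i[nz], j = j[nz], x = val[nz],
                                 dims = dim(C), dimnames = dimnames(C),
                                 symmetric = TRUE)
  structure(list(values = values, year = year, pair_total = N / 2),
            class = "ppmi_matrix")
}

#' @export
print.ppmi_matrix <- function(x, ...) {
  cat(sprintf("<ppmi_matrix> %d x %d, %d positive entries%s\n",
              nrow(x$values), ncol(x$values),
              length(methods::as(x$values, "generalMatrix")@x),
              if (is.na(x$year)) "" else sprintf(", year %d", x$year)))
  invisible(x)
}

#' SVD word embeddings from a PPMI matrix
#'
#' Truncated singular value decomposition `PPMI ~ U_d S_d V_d'`; word i's
#' embedding is row i of `U_d S_d^p`. The default `p = 0.5` (symmetric
#' square-root weighting) is the established choice for PPMI-SVD embeddings.
#' Signs are fixed by forcing the largest-magnitude component of each left
#' singular vector non-negative, so results are fully deterministic (the
#' LAPACK solver used here involves no randomness; `seed` is accepted for
#' interface stability and recorded in the result).
#'
#' @param ppmi a [compute_ppmi()] result.
#' @param d embedding dimension (default 300, capped at the matrix size by
#'   the caller if needed).
#' @param p singular-value exponent in `[0, 1]` (default 0.5).
#' @param seed recorded in the result; unused by the deterministic solver.
#' @param frequency optional named numeric word frequencies used downstream
#'   for tie-breaking in synonym retrieval.
#' @return an object of class `embedding_space`: list with `year`, `dim`,
#'   `vectors` (words x d matrix, rownames = words), `singular_values`,
#'   `factor_exponent`, `seed`, `frequency`.
#' @export
svd_embed <- function(ppmi, d = 300L, p = 0.5, seed = NULL, frequency = NULL) {
  M <- as.matrix(ppmi$values)
  n <- nrow(M)
  if (d < 1L || d > n) stop(sprintf("d = %d out of range 1..%d", d, n))
  s <- svd(M, nu = d, nv = 0L)
  U <- s$u
  for (k in seq_len(d)) {
    m <- which.max(abs(U[, k]))
    if (U[m, k] < 0) U[, k] <- -U[, k]
  }
  sv <- s$d[seq_len(d)]
  vectors <- U %*% diag(sv^p, nrow = d)
  rownames(vectors) <- rownames(M)
  structure(list(year = ppmi$year, dim = d, vectors = vectors,
                 singular_values = sv, factor_exponent = p, seed = seed,
                 frequency = frequency),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> %d words x %d dims (p=%.2f%s)\n",
              nrow(x$vectors), x$dim, x$factor_exponent,
              if (is.na(x$year)) "" else sprintf(", year %d", x$year)))
  invisible(x)
}

#' Cosine similarity between two vectors
#' @param a,b numeric vectors of equal length, both nonzero.
#' @return a real number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Row-normalize a matrix; zero rows stay zero (flagged via attribute).
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  ok <- nrm > 0
  m[ok, ] <- m[ok, , drop = FALSE] / nrm[ok]
  attr(m, "nonzero") <- ok
  m
}

#' Look up a word's embedding vector
#' @param space an `embedding_space`.
#' @param word a word.
#' @export
embedding_vector <- function(space, word) {
  if (!word %in% rownames(space$vectors)) {
    stop(sprintf("word '%s' not in embedding space", word))
  }
  space$vectors[word, ]
}

#' Nearest synonyms by cosine similarity
#'
#' Top-k most similar words to the query in one embedding space ("synonyms"
#' in the distributional sense: nearest neighbours, not dictionary synonyms).
#' The query itself and zero-vector words are excluded; ties are broken by
#' descending corpus frequency, then lexicographically.
#'
#' @param word query word.
#' @param space an `embedding_space`.
#' @param k number of neighbours (default 5).
#' @return a data.frame with columns `word`, `similarity`, sorted descending.
#' @export
nearest_synonyms <- function(word, space, k = 5L) {
  v <- embedding_vector(space, word)
  if (all(v == 0)) stop(sprintf("word '%s' has a zero embedding", word))
  if (k <= 0L) return(data.frame(word = character(), similarity = numeric()))
  m <- normalize_rows(space$vectors)
  ok <- attr(m, "nonzero")
  sims <- as.numeric(m %*% (v / sqrt(sum(v^2))))
  names(sims) <- rownames(space$vectors)
  sims <- sims[ok & names(sims) != word]
  freq <- space$frequency
  if (is.null(freq)) freq <- setNames(rep(0, length(sims)), names(sims))
  fr <- freq[names(sims)]
  fr[is.na(fr)] <- 0
  ord <- order(-sims, -fr, names(sims))
  sel <- utils::head(ord, k)
  data.frame(word = names(sims)[sel], similarity = unname(sims[sel]),
             row.names = NULL)
}

#' Evaluate a multiple-choice synonym test
#'
#' Each question is a probe word plus four choices (one correct). A question
#' is answered iff the probe and at least one choice have nonzero embeddings;
#' the prediction is the in-space choice with maximal cosine similarity to
#' the probe. Questions with out-of-space probes, or none of whose choices
#' are in space, are skipped and counted separately (mirroring the dropping
#' of low-frequency items when the test is run against a finite vocabulary).
#'
#' @param questions a data.frame with columns `probe`, `correct`,
#'   `distractor1`, `distractor2`, `distractor3` (see
#'   [read_synonym_questions()]).
#' @param space an `embedding_space`.
#' @return a list with `accuracy` (proportion correct among answered; `NA` if
#'   none answered), `n_answered`, `n_skipped`, and a per-question `results`
#'   data.frame.
#' @export
evaluate_synonym_test <- function(questions, space) {
  m <- normalize_rows(space$vectors)
  ok <- attr(m, "nonzero")
  in_space <- function(w) w %in% rownames(m) & ok[w]
  res <- lapply(seq_len(nrow(questions)), function(q) {
    probe <- questions$probe[q]
    choices <- c(questions$correct[q], questions$distractor1[q],
                 questions$distractor2[q], questions$distractor3[q])
    avail <- vapply(choices, function(w) isTRUE(in_space(w)), TRUE)
    if (!isTRUE(in_space(probe)) || !any(avail)) {
      return(data.frame(probe = probe, predicted = NA_character_,
                        correct = NA))
    }
    sims <- as.numeric(m[choices[avail], , drop = FALSE] %*% m[probe, ])
    pred <- choices[avail][which.max(sims)]
    data.frame(probe = probe, predicted = pred,
               correct = pred == questions$correct[q])
  })
  results <- do.call(rbind, res)
  answered <- !is.na(results$correct)
  list(accuracy = if (any(answered)) mean(results$correct[answered]) else NA_real_,
       n_answered = sum(answered),
       n_skipped = sum(!answered),
       results = results)
}

#' Read synonym questions from CSV
#'
#' Expected header: `probe,correct,distractor1,distractor2,distractor3`.
#'
#' @param path CSV path.
#' @return a data.frame suitable for [evaluate_synonym_test()].
#' @export
read_synonym_questions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe", "correct", "distractor1", "distractor2", "distractor3")
  if (!all(need %in% names(df))) {
    stop("synonym-question CSV must have columns: ", paste(need, collapse = ","))
  }
  df[need]
}

#' Write synonym questions to CSV
#' @param questions data.frame of questions.
#' @param path output path.
#' @export
write_synonym_questions <- function(questions, path) {
  utils::write.csv(questions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export embeddings in word2vec text format
#'
#' First line `n d`, then one `word v1 ... vd` line per word.
#'
#' @param space an `embedding_space`.
#' @param path output path.
#' @export
write_embeddings_text <- function(space, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(space$vectors), space$dim), con)
  rows <- apply(space$vectors, 1L, function(v)
    paste(formatC(v, format = "g", digits = 8), collapse = " "))
  writeLines(paste(rownames(space$vectors), rows), con)
  invisible(path)
}
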