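# Shared fixtures. The default synthetic study (reference desk-scale
# conditions) is generated once per test run and cached; individual tests
# build their own tiny corpora from TSV lines where hand enumeration matters.

.sim_cache <- new.env(parent = emptyenv())

# embedding dimension used throughout the synthetic suite: the planted
# structure is ~5-dimensional (4 topics + a function-word axis)
SIM_DIM <- 10L

default_sim <- function() {
  if (!is.null(.sim_cache$default)) return(.sim_cache$default)
  cfg <- synthetic_config()  # reference conditions, seed 42
  gen <- generate_corpus(cfg)
  counts <- count_tokens(gen$records)
  totals <- year_totals(gen$records)
  vocab <- build_vocabulary(counts, cap = 1000L)
  tensor <- accumulate_cooccurrence(gen$records, vocab)
  spaces <- lapply(tensor_years(tensor), function(y) {
    svd_embed(compute_ppmi(tensor_slice(tensor, y), y), d = SIM_DIM,
              frequency = vocab$counts)
  })
  names(spaces) <- tensor_years(tensor)
  sim <- list(config = cfg, records = gen$records, manifest = gen$manifest,
              counts = counts, totals = totals, vocab = vocab,
              tensor = tensor, spaces = spaces,
              norms = generate_norms(gen$manifest),
              questions = generate_synonym_questions(gen$manifest, 20L))
  .sim_cache$default <- sim
  sim
}

# parse a character vector of "tok tok tok tok tok<TAB>year<TAB>mc<TAB>vc"
# lines into records with no year filtering
records_from_lines <- function(lines) {
  parse_ngram_lines(lines, year_range = NULL)
}

# tiny corpus: explicit grams as list(c(tokens...), year, match_count)
records_from_grams <- function(grams) {
  lines <- vapply(grams, function(g) {
    sprintf("%s\t%d\t%d\t1", paste(g[[1]], collapse = " "), g[[2]], g[[3]])
  }, "")
  records_from_lines(lines)
}

# naive O(25 n) co-occurrence enumerator: the independent oracle for
# accumulate_cooccurrence
naive_cooc <- function(records, words) {
  V <- length(words)
  out <- list()
  for (y in sort(unique(records$year))) {
    m <- matrix(0, V, V, dimnames = list(words, words))
    idx <- which(records$year == y)
    for (r in idx) {
      toks <- records$tokens[r, ]
      mc <- records$match_count[r]
      for (i in 1:4) for (j in (i + 1):5) {
        a <- toks[i]; b <- toks[j]
        if (!is.na(a) && !is.na(b) && a %in% words && b %in% words) {
          m[a, b] <- m[a, b] + mc
          if (a != b) m[b, a] <- m[b, a] + mc
        }
      }
    }
    out[[as.character(y)]] <- m
  }
  out
}

# scalar-formula PPMI oracle on a dense symmetric count matrix
dense_ppmi <- function(C) {
  diag(C) <- 0
  N <- sum(C)
  r <- rowSums(C)
  P <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  for (i in seq_len(nrow(C))) for (j in seq_len(ncol(C))) {
    if (i != j && C[i, j] > 0) {
      P[i, j] <- max(0, log(C[i, j]) + log(N) - log(r[i]) - log(r[j]))
    }
  }
  P
}

random_orthogonal <- function(d) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
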