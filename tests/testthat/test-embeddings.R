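test_that("PPMI of a 4-word hand slice matches scalar formula evaluation", {
  # c(a,b)=6, c(a,c)=2, c(b,c)=1, c(c,d)=1
  C <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  C["a", "b"] <- C["b", "a"] <- 6
  C["a", "c"] <- C["c", "a"] <- 2
  C["b", "c"] <- C["c", "b"] <- 1
  C["c", "d"] <- C["d", "c"] <- 1
  pp <- compute_ppmi(Matrix::Matrix(C, sparse = TRUE))
  expect_equal(as.matrix(pp$values), dense_ppmi(C), ignore_attr = TRUE)
  # one entry fully by hand: N = 20, r_a = 8, r_b = 7
  expect_equal(as.numeric(pp$values["a", "b"]),
               max(0, log(6) + log(20) - log(8) - log(7)))
  expect_true(Matrix::isSymmetric(pp$values))
  expect_true(all(Matrix::diag(pp$values) == 0))
  expect_true(all(pp$values@x >= 0))
})

test_that("a pair co-occurring at exactly its independence rate has PPMI 0", {
  # c(a,b)=2, all other off-block pairs 3: then P(a,b) = P(a)P(b) exactly
  C <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  C["a", "b"] <- C["b", "a"] <- 2
  C["c", "d"] <- C["d", "c"] <- 2
  for (p in list(c("a", "c"), c("a", "d"), c("b", "c"), c("b", "d"))) {
    C[p[1], p[2]] <- C[p[2], p[1]] <- 3
  }
  pp <- compute_ppmi(Matrix::Matrix(C, sparse = TRUE))
  expect_equal(as.numeric(pp$values["a", "b"]), 0)
  expect_equal(as.numeric(pp$values["c", "d"]), 0)
})

test_that("the single-observed-pair degenerate slice yields the documented log-2 value", {
  C <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  C["a", "b"] <- C["b", "a"] <- 50
  pp <- compute_ppmi(Matrix::Matrix(C, sparse = TRUE))
  expect_equal(as.numeric(pp$values["a", "b"]), log(2))
  expect_error(compute_ppmi(Matrix::Matrix(0, 2, 2)), "mass")
})

test_that("PPMI strictly decreases when one marginal grows at fixed pair count", {
  base <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  base["a", "b"] <- base["b", "a"] <- 5
  base["c", "d"] <- base["d", "c"] <- 100  # background mass dominating N
  vals <- vapply(c(2, 10, 50), function(extra) {
    C <- base
    C["b", "c"] <- C["c", "b"] <- extra  # b gets more frequent, c(a,b) fixed
    as.numeric(compute_ppmi(Matrix::Matrix(C, sparse = TRUE))$values["a", "b"])
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("sparse pipeline agrees with a dense brute-force oracle on a random slice", {
  set.seed(21)
  n <- 150
  words <- sprintf("w%03d", 1:n)
  C <- matrix(0, n, n, dimnames = list(words, words))
  nz <- which(upper.tri(C))
  sel <- sample(nz, 3000)
  C[sel] <- rpois(length(sel), 4) + 1
  C <- C + t(C)
  pp <- compute_ppmi(Matrix::Matrix(C, sparse = TRUE))
  expect_lt(max(abs(as.matrix(pp$values) - dense_ppmi(C))), 1e-12)
  # full-rank embedding with p = 1 reproduces dense PPMI row cosines
  sp <- svd_embed(pp, d = n, p = 1)
  M <- dense_ppmi(C)
  pick <- sample(n, 12)
  for (i in pick[1:6]) for (j in pick[7:12]) {
    expect_equal(cosine_similarity(sp$vectors[i, ], sp$vectors[j, ]),
                 sum(M[i, ] * M[j, ]) / sqrt(sum(M[i, ]^2) * sum(M[j, ]^2)),
                 tolerance = 1e-6)
  }
})

test_that("PPMI of an independence-sampled corpus is near zero entrywise", {
  set.seed(22)
  n_windows <- 1e5
  words <- sprintf("w%02d", 1:50)
  toks <- matrix(sample(words, 5 * n_windows, replace = TRUE), ncol = 5)
  recs <- diasem:::new_ngram_records(toks, rep(1900L, n_windows),
                                     rep(1L, n_windows), rep(1L, n_windows))
  v <- build_vocabulary(recs, cap = 50L)
  pp <- compute_ppmi(tensor_slice(accumulate_cooccurrence(recs, v), 1900))
  dense <- as.matrix(pp$values)
  entries <- dense[upper.tri(dense)]
  expect_lt(median(abs(entries)), 0.05)
})

test_that("rank-1 PPMI is reproduced exactly at d = 1", {
  v <- c(1, 2, 3)
  M <- outer(v, v)
  dimnames(M) <- list(letters[1:3], letters[1:3])
  pp <- structure(list(values = Matrix::Matrix(M, sparse = TRUE),
                       year = NA_integer_, pair_total = sum(M) / 2),
                  class = "ppmi_matrix")
  sp <- svd_embed(pp, d = 1, p = 0.5)
  gram <- sp$vectors %*% t(sp$vectors)
  expect_lt(max(abs(gram - M)) / max(abs(M)), 1e-8)
  expect_error(svd_embed(pp, d = 4), "range")
})

test_that("identical PPMI rows give cosine 1 and mutual nearest neighbours", {
  M <- matrix(c(0, 0, 5, 1,
                0, 0, 5, 1,
                5, 5, 0, 0,
                1, 1, 0, 0), 4, 4, byrow = TRUE,
              dimnames = list(c("x", "y", "u", "z"), c("x", "y", "u", "z")))
  pp <- structure(list(values = Matrix::Matrix(M, sparse = TRUE),
                       year = NA_integer_, pair_total = sum(M) / 2),
                  class = "ppmi_matrix")
  sp <- svd_embed(pp, d = 4, p = 0.5)
  expect_equal(cosine_similarity(sp$vectors["x", ], sp$vectors["y", ]), 1,
               tolerance = 1e-10)
  expect_equal(nearest_synonyms("x", sp, k = 1)$word, "y")
})

test_that("cosine similarity hits its landmark values and rejects zero vectors", {
  a <- c(1, 2, 3)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 2)), 0)
  expect_equal(cosine_similarity(a, -a), -1)
  expect_error(cosine_similarity(a, c(0, 0, 0)), "zero")
})

test_that("embedding cosines are invariant under a global orthogonal transform", {
  sim <- default_sim()
  sp <- sim$spaces[["1900"]]
  set.seed(23)
  for (rep in 1:3) {
    Q <- random_orthogonal(sp$dim)
    rot <- sp$vectors %*% Q
    pick <- sample(nrow(rot), 10)
    for (k in 1:5) {
      i <- pick[k]; j <- pick[k + 5]
      expect_equal(cosine_similarity(rot[i, ], rot[j, ]),
                   cosine_similarity(sp$vectors[i, ], sp$vectors[j, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("nearest synonyms exclude the query, honour k = 0 and break ties by frequency", {
  vecs <- rbind(q = c(1, 0), a = c(1, 0), b = c(1, 0), c = c(0, 1))
  sp <- structure(list(year = NA_integer_, dim = 2L, vectors = vecs,
                       singular_values = c(1, 1), factor_exponent = 0.5,
                       frequency = c(q = 5, a = 1, b = 3, c = 9)),
                  class = "embedding_space")
  expect_equal(nrow(nearest_synonyms("q", sp, k = 0)), 0L)
  top <- nearest_synonyms("q", sp, k = 2)
  expect_equal(top$word, c("b", "a"))  # cosine tie at 1, b more frequent
  expect_false("q" %in% top$word)
  expect_error(nearest_synonyms("missing", sp), "not in")
})

test_that("synonym test scoring answers by max cosine and skips out-of-space items", {
  vecs <- rbind(p = c(1, 0), good = c(0.9, 0.1), bad1 = c(0, 1),
                bad2 = c(-1, 0), bad3 = c(0.2, 0.9), zero = c(0, 0))
  sp <- structure(list(year = NA_integer_, dim = 2L, vectors = vecs,
                       singular_values = c(1, 1), factor_exponent = 0.5,
                       frequency = NULL), class = "embedding_space")
  qs <- data.frame(probe = c("p", "p", "ghost"),
                   correct = c("good", "ghost2", "good"),
                   distractor1 = c("bad1", "ghost3", "bad1"),
                   distractor2 = c("bad2", "ghost4", "bad2"),
                   distractor3 = c("bad3", "ghost5", "bad3"))
  res <- evaluate_synonym_test(qs, sp)
  expect_equal(res$n_answered, 1L)
  expect_equal(res$n_skipped, 2L)
  expect_equal(res$accuracy, 1.0)
  none <- evaluate_synonym_test(qs[3, ], sp)
  expect_true(is.na(none$accuracy))
  expect_equal(none$n_answered, 0L)
})

test_that("synonym questions CSV round-trips", {
  sim <- default_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  write_synonym_questions(sim$questions, path)
  back <- read_synonym_questions(path)
  expect_equal(back, sim$questions, ignore_attr = TRUE)
})
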