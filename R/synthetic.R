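#' Configuration for the synthetic corpus generator
#'
#' Defines a year-stamped 5-gram corpus with planted, recoverable structure:
#' disjoint word topics (words from one topic co-occur with each other and
#' with shared function words), a set of Zipf-weighted function words mixed
#' into every context, designated stable words whose context never changes,
#' drift words whose context interpolates linearly from one topic to another
#' over a scheduled year window, a word whose usage frequency grows linearly,
#' and per-topic affect-rating blocks.
#'
#' The defaults are the package's reference desk-scale conditions: 4 topics of
#' 100 words, 60 function words carrying 8\% of tokens, 100,000 5-grams per
#' year from 1850 to 2000 in 25-year slices, one drift word moving from
#' topic 1 to topic 2 between 1900 and 1950, one stable word per topic, and
#' valence blocks centred at 7 / 3 / 5 / 5 (sd 0.1).
#'
#' @param seed integer RNG seed; the whole corpus and manifest are
#'   deterministic functions of the config including this seed.
#' @param years integer years to emit (default `seq(1850, 2000, 25)`).
#' @param n_topics number of disjoint topics (default 4).
#' @param words_per_topic words per topic (default 100).
#' @param n_function_words shared function words (default 60).
#' @param ngrams_per_year 5-gram records emitted per year (default 1e5).
#' @param function_word_share probability a context token is a function word
#'   (default 0.08).
#' @param concentration probability a topic token stays in its own topic
#'   (default 1: fully disjoint topics).
#' @param drift_specs list of drift specifications, each
#'   `list(word, from_topic, to_topic, onset, completion, rate)` with a
#'   linear schedule; `rate` is the fraction of each year's 5-grams built
#'   around the word.
#' @param stable_word_rate per-word gram fraction for the planted stable
#'   words (one per topic; default 0.01).
#' @param frequency_schedules list of `list(word, topic, rate_start,
#'   rate_end)` linear usage-frequency trends.
#' @param affect_blocks list of `list(topic, dimension, mean, sd)` rating
#'   assignments.
#' @param match_count_lambda Poisson rate of `match_count - 1` (default 1).
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L,
                             years = seq(1850L, 2000L, by = 25L),
                             n_topics = 4L,
                             words_per_topic = 100L,
                             n_function_words = 60L,
                             ngrams_per_year = 100000L,
                             function_word_share = 0.08,
                             concentration = 1.0,
                             drift_specs = list(list(
                               word = "drifter", from_topic = 1L,
                               to_topic = 2L, onset = 1900L,
                               completion = 1950L, rate = 0.02)),
                             stable_word_rate = 0.01,
                             frequency_schedules = list(list(
                               word = "riser", topic = 3L,
                               rate_start = 0.002, rate_end = 0.01)),
                             affect_blocks = list(
                               list(topic = 1L, dimension = "valence", mean = 7, sd = 0.1),
                               list(topic = 2L, dimension = "valence", mean = 3, sd = 0.1),
                               list(topic = 3L, dimension = "valence", mean = 5, sd = 0.1),
                               list(topic = 4L, dimension = "valence", mean = 5, sd = 0.1),
                               list(topic = 1L, dimension = "concreteness", mean = 4, sd = 0.2),
                               list(topic = 2L, dimension = "arousal", mean = 6, sd = 0.2)),
                             match_count_lambda = 1) {
  cfg <- list(seed = as.integer(seed), years = sort(as.integer(years)),
              n_topics = as.integer(n_topics),
              words_per_topic = as.integer(words_per_topic),
              n_function_words = as.integer(n_function_words),
              ngrams_per_year = as.integer(ngrams_per_year),
              function_word_share = function_word_share,
              concentration = concentration,
              drift_specs = drift_specs,
              stable_word_rate = stable_word_rate,
              frequency_schedules = frequency_schedules,
              affect_blocks = affect_blocks,
              match_count_lambda = match_count_lambda)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_topics >= 1L, cfg$words_per_topic >= 1L,
            cfg$n_function_words >= 0L, cfg$ngrams_per_year >= 1L,
            cfg$function_word_share >= 0, cfg$function_word_share < 1,
            cfg$concentration > 0, cfg$concentration <= 1,
            length(cfg$years) >= 1L)
  for (ds in cfg$drift_specs) {
    if (ds$from_topic == ds$to_topic) {
      stop("drift spec must move between two distinct topics")
    }
    if (max(ds$from_topic, ds$to_topic) > cfg$n_topics) {
      stop("drift spec references a topic beyond n_topics")
    }
    if (ds$onset >= ds$completion) stop("drift onset must precede completion")
    if (ds$onset < min(cfg$years) || ds$completion > max(cfg$years)) {
      stop("drift schedule must lie within the configured years")
    }
  }
  for (ab in cfg$affect_blocks) {
    if (ab$topic > cfg$n_topics) stop("affect block references a missing topic")
    if (!ab$dimension %in% c("valence", "arousal", "concreteness")) {
      stop("unknown affect dimension: ", ab$dimension)
    }
  }
  special <- c(vapply(cfg$drift_specs, `[[`, "", "word"),
               vapply(cfg$frequency_schedules, `[[`, "", "word"))
  if (anyDuplicated(special)) stop("special words must be distinct")
  invisible(cfg)
}

synthetic_lexicon <- function(cfg) {
  topic_words <- lapply(seq_len(cfg$n_topics), function(t)
    sprintf("t%dw%03d", t, seq_len(cfg$words_per_topic)))
  function_words <- if (cfg$n_function_words > 0L) {
    sprintf("fw%02d", seq_len(cfg$n_function_words))
  } else character()
  stable_words <- sprintf("stable%d", seq_len(cfg$n_topics))
  list(topic_words = topic_words, function_words = function_words,
       stable_words = stable_words)
}

# linear interpolation of a drift word's probability of sampling its
# destination topic: 0 before onset, 1 after completion
drift_progress <- function(year, onset, completion) {
  pmin(1, pmax(0, (year - onset) / (completion - onset)))
}

#' Generate a synthetic 5-gram corpus with a ground-truth manifest
#'
#' Emits one batch of 5-gram records per configured year. Each record samples
#' a topic, then five tokens from that topic's word set mixed with function
#' words (function words are drawn with Zipf weights, mimicking the heavy
#' head of natural frequency distributions). Grams hosting a special word
#' (drift / stable / frequency-schedule words) place that word at a random
#' position and draw the remaining four tokens from the word's current topic;
#' a drift word's topic is sampled from its linear schedule. The emitted
#' corpus parses under the package's 5-gram reader with zero malformed lines,
#' and the manifest records every planted fact.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; when given, one `<year>.tsv` file
#'   per year plus `manifest.json` are written.
#' @return a list with `records` (an `ngram_records` object over all years)
#'   and `manifest` (class `ground_truth_manifest`).
#' @export
generate_corpus <- function(config, dir = NULL) {
  cfg <- validate_synthetic_config(config)
  lex <- synthetic_lexicon(cfg)
  topic_mat <- do.call(cbind, lex$topic_words)  # words_per_topic x n_topics
  fw <- lex$function_words
  fw_weights <- if (length(fw)) (1 / seq_along(fw)) / sum(1 / seq_along(fw)) else numeric()

  specials <- list()
  for (ds in cfg$drift_specs) {
    specials[[ds$word]] <- list(kind = "drift", spec = ds)
  }
  for (t in seq_len(cfg$n_topics)) {
    specials[[lex$stable_words[t]]] <-
      list(kind = "stable", spec = list(topic = t, rate = cfg$stable_word_rate))
  }
  for (fs in cfg$frequency_schedules) {
    specials[[fs$word]] <- list(kind = "riser", spec = fs)
  }

  set.seed(cfg$seed)
  per_year <- lapply(cfg$years, function(y) {
    N <- cfg$ngrams_per_year
    # per-gram special-word assignment and topic
    host <- character(0); host_topic <- integer(0)
    for (wname in names(specials)) {
      sp <- specials[[wname]]
      n_s <- switch(sp$kind,
        drift = round(sp$spec$rate * N),
        stable = round(sp$spec$rate * N),
        riser = {
          yrs <- range(cfg$years)
          frac <- if (diff(yrs) == 0) 0 else (y - yrs[1]) / diff(yrs)
          round((sp$spec$rate_start +
                   frac * (sp$spec$rate_end - sp$spec$rate_start)) * N)
        })
      if (n_s == 0L) next
      tp <- switch(sp$kind,
        drift = {
          p <- drift_progress(y, sp$spec$onset, sp$spec$completion)
          ifelse(runif(n_s) < p, sp$spec$to_topic, sp$spec$from_topic)
        },
        stable = rep(sp$spec$topic, n_s),
        riser = rep(sp$spec$topic, n_s))
      host <- c(host, rep(wname, n_s))
      host_topic <- c(host_topic, tp)
    }
    n_special <- length(host)
    if (n_special >= N) stop("special-word rates exceed the per-year gram budget")
    n_bg <- N - n_special
    gram_topic <- c(host_topic, sample.int(cfg$n_topics, n_bg, replace = TRUE))

    # draw all 5N tokens: function word vs (possibly leaked) topic word
    M <- 5L * N
    tok_topic <- rep(gram_topic, times = 5L)
    if (cfg$concentration < 1) {
      leak <- runif(M) >= cfg$concentration
      if (any(leak) && cfg$n_topics > 1L) {
        shift <- sample.int(cfg$n_topics - 1L, sum(leak), replace = TRUE)
        tok_topic[leak] <- 1L + (tok_topic[leak] - 1L + shift) %% cfg$n_topics
      }
    }
    is_fun <- runif(M) < cfg$function_word_share & length(fw) > 0L
    widx <- sample.int(cfg$words_per_topic, M, replace = TRUE)
    tokens <- topic_mat[cbind(widx, tok_topic)]
    if (any(is_fun)) {
      tokens[is_fun] <- sample(fw, sum(is_fun), replace = TRUE,
                               prob = fw_weights)
    }
    tok_mat <- matrix(tokens, nrow = N, ncol = 5L)
    if (n_special > 0L) {
      pos <- sample.int(5L, n_special, replace = TRUE)
      tok_mat[cbind(seq_len(n_special), pos)] <- host
    }
    mc <- 1L + stats::rpois(N, cfg$match_count_lambda)
    new_ngram_records(tok_mat, rep(y, N), mc, rep(1L, N))
  })

  records <- new_ngram_records(
    do.call(rbind, lapply(per_year, `[[`, "tokens")),
    unlist(lapply(per_year, `[[`, "year")),
    unlist(lapply(per_year, `[[`, "match_count")),
    unlist(lapply(per_year, `[[`, "volume_count")))

  synonym_pairs <- lapply(seq_len(cfg$n_topics), function(t) {
    w <- lex$topic_words[[t]]
    n_pairs <- min(10L, floor(length(w) / 2))
    lapply(seq_len(n_pairs), function(i) c(w[2 * i - 1], w[2 * i]))
  })

  manifest <- structure(list(
    seed = cfg$seed,
    years = cfg$years,
    config = cfg,
    topic_words = lex$topic_words,
    function_words = lex$function_words,
    stable_words = setNames(seq_len(cfg$n_topics), lex$stable_words),
    topic_of = c(
      setNames(rep(seq_len(cfg$n_topics), each = cfg$words_per_topic),
               unlist(lex$topic_words)),
      setNames(seq_len(cfg$n_topics), lex$stable_words)),
    drift_specs = cfg$drift_specs,
    frequency_schedules = cfg$frequency_schedules,
    synonym_pairs = synonym_pairs,
    affect_blocks = cfg$affect_blocks,
    lexicon = sort(unique(as.vector(records$tokens)))),
    class = "ground_truth_manifest")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(cfg$years)) {
      write_ngram_records(per_year[[i]],
                          file.path(dir, sprintf("%d.tsv", cfg$years[i])))
    }
    write_manifest_json(manifest, file.path(dir, "manifest.json"))
  }
  list(records = records, manifest = manifest)
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat(sprintf("<ground_truth_manifest> %d topics x %d words, %d function words, %d drift spec(s), years %s..%s\n",
              length(x$topic_words), length(x$topic_words[[1]]),
              length(x$function_words), length(x$drift_specs),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Serialize a ground-truth manifest as JSON
#' @param manifest a `ground_truth_manifest`.
#' @param path output JSON path.
#' @export
write_manifest_json <- function(manifest, path) {
  m <- unclass(manifest)
  m$config <- unclass(m$config)
  m$stable_words <- as.list(m$stable_words)
  m$topic_of <- as.list(m$topic_of)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a norms table matching the manifest's affect blocks
#'
#' Every word of a topic named in an affect block receives a rating drawn
#' from `Normal(mean, sd)` truncated to the dimension's scale bounds
#' (valence/arousal 1-9, concreteness 1-5). Words outside all blocks are
#' absent from the table. The returned table is itself the record of the
#' assigned ratings (the generation oracle).
#'
#' @param manifest a [generate_corpus()] manifest.
#' @param seed RNG seed (default: manifest seed + 1).
#' @return a data.frame with columns `word` and the rated dimensions.
#' @export
generate_norms <- function(manifest, seed = manifest$seed + 1L) {
  set.seed(seed)
  bounds <- affect_scale_bounds()
  words <- unlist(manifest$topic_words)
  out <- data.frame(word = words, valence = NA_real_, arousal = NA_real_,
                    concreteness = NA_real_)
  for (ab in manifest$affect_blocks) {
    tw <- manifest$topic_words[[ab$topic]]
    r <- stats::rnorm(length(tw), ab$mean, ab$sd)
    b <- bounds[[ab$dimension]]
    r <- pmin(b[2], pmax(b[1], r))
    out[[ab$dimension]][match(tw, out$word)] <- r
  }
  rated <- !is.na(out$valence) | !is.na(out$arousal) | !is.na(out$concreteness)
  out <- out[rated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate multiple-choice synonym questions from planted pairs
#'
#' Each question takes its probe and correct answer from one planted
#' same-topic pair and its three distractors from three distinct other
#' topics, so topic separation in any faithful embedding identifies the
#' correct choice.
#'
#' @param manifest a [generate_corpus()] manifest.
#' @param n number of questions (default 20).
#' @param seed RNG seed (default: manifest seed + 2).
#' @return a data.frame `probe,correct,distractor1,distractor2,distractor3`.
#' @export
generate_synonym_questions <- function(manifest, n = 20L,
                                       seed = manifest$seed + 2L) {
  n_topics <- length(manifest$topic_words)
  if (n_topics < 4L) {
    stop("insufficient distractor pool: need at least 3 topics besides the probe's")
  }
  if (!any(lengths(manifest$synonym_pairs) > 0L)) {
    stop("manifest has no planted synonym pairs")
  }
  if (n == 0L) {
    return(data.frame(probe = character(), correct = character(),
                      distractor1 = character(), distractor2 = character(),
                      distractor3 = character()))
  }
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    t <- sample(which(lengths(manifest$synonym_pairs) > 0L), 1L)
    pair <- manifest$synonym_pairs[[t]][[
      sample.int(length(manifest$synonym_pairs[[t]]), 1L)]]
    others <- sample(setdiff(seq_len(n_topics), t), 3L)
    distract <- vapply(others, function(o) {
      tw <- manifest$topic_words[[o]]
      tw[sample.int(length(tw), 1L)]
    }, "")
    data.frame(probe = pair[1], correct = pair[2],
               distractor1 = distract[1], distractor2 = distract[2],
               distractor3 = distract[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
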