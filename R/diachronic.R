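#' Orthogonal Procrustes alignment between two embedding spaces
#'
#' Finds the orthogonal matrix `R` minimizing `||A R - B||_F` over the anchor
#' rows (A = source vectors, B = target vectors), by the closed-form solution
#' `R = U V'` from the SVD of `A' B`. No translation and no scaling: a pure
#' rotation/reflection, so all intra-space geometry (cosines, distances) is
#' preserved exactly.
#'
#' @param source,target `embedding_space` objects of equal dimension.
#' @param anchors word list used to fit `R`, or `"auto"` (the intersection of
#'   both spaces' nonzero-vector words, optionally restricted to the `top_m`
#'   most frequent).
#' @param top_m with `anchors = "auto"`, keep only the `top_m` most frequent
#'   shared words (default `Inf` = all shared words).
#' @return an object of class `alignment_map`: list with `rotation` (d x d),
#'   `source_year`, `target_year`, `anchors`, `rank_deficient` flag.
#' @export
procrustes_align <- function(source, target, anchors = "auto", top_m = Inf) {
  d <- source$dim
  if (target$dim != d) stop("embedding spaces have different dimensions")
  if (identical(anchors, "auto")) {
    src_ok <- rownames(source$vectors)[rowSums(source$vectors^2) > 0]
    tgt_ok <- rownames(target$vectors)[rowSums(target$vectors^2) > 0]
    anchors <- intersect(src_ok, tgt_ok)
    if (is.finite(top_m) && !is.null(source$frequency)) {
      fr <- source$frequency[anchors]
      fr[is.na(fr)] <- 0
      anchors <- anchors[order(-fr, anchors)]
      anchors <- utils::head(anchors, top_m)
    }
  }
  missing_src <- setdiff(anchors, rownames(source$vectors))
  missing_tgt <- setdiff(anchors, rownames(target$vectors))
  if (length(missing_src) || length(missing_tgt)) {
    stop("anchor words missing from source/target space: ",
         paste(utils::head(c(missing_src, missing_tgt), 5), collapse = ", "))
  }
  if (length(anchors) < d) {
    stop(sprintf("need at least d = %d anchor words, got %d", d, length(anchors)))
  }
  A <- source$vectors[anchors, , drop = FALSE]
  B <- target$vectors[anchors, , drop = FALSE]
  s <- svd(crossprod(A, B))
  R <- s$u %*% t(s$v)
  rank_def <- sum(s$d > max(s$d) * 1e-12) < d
  if (rank_def) {
    warning("rank-deficient anchor matrix: Procrustes solution is a pseudo-solution")
  }
  orth_err <- max(abs(crossprod(R) - diag(d)))
  if (orth_err > 1e-8) stop("alignment failed orthogonality check")
  structure(list(rotation = R, source_year = source$year,
                 target_year = target$year, anchors = anchors,
                 rank_deficient = rank_def),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> %s -> %s, d=%d, %d anchors%s\n",
              x$source_year, x$target_year, ncol(x$rotation),
              length(x$anchors),
              if (x$rank_deficient) " (pseudo-solution)" else ""))
  invisible(x)
}

#' Apply an alignment to vectors or a whole space
#'
#' @param map an [procrustes_align()] result.
#' @param x a numeric vector, a matrix of row vectors, or an
#'   `embedding_space`.
#' @return the rotated object, same type as `x`.
#' @export
apply_alignment <- function(map, x) {
  if (inherits(x, "embedding_space")) {
    x$vectors <- x$vectors %*% map$rotation
    return(x)
  }
  if (is.matrix(x)) return(x %*% map$rotation)
  as.numeric(x %*% map$rotation)
}

#' Semantic stability of a word between two years
#'
#' `Stability(wi, t) = cos_sim(wi(T), wi(T+t))` after rotating the earlier
#' space onto the later one with orthogonal Procrustes. The raw cosine lies
#' in `[-1, 1]`; the reported default is clipped to `[0, 1]` (negative
#' aligned cosines carry no extra gradation of "changed meaning"), with the
#' raw value always retained.
#'
#' @param word a word present in both spaces.
#' @param space_T,space_Tt `embedding_space` objects for the earlier and
#'   later year.
#' @param map optional precomputed [procrustes_align()] map from `space_T`
#'   onto `space_Tt`; computed automatically when `NULL`.
#' @return a one-row data.frame of class `stability_score` with columns
#'   `word`, `from_year`, `to_year`, `raw`, `clipped`.
#' @export
stability <- function(word, space_T, space_Tt, map = NULL) {
  for (sp in list(space_T, space_Tt)) {
    if (!word %in% rownames(sp$vectors) ||
        sum(sp$vectors[word, ]^2) == 0) {
      stop(sprintf("word '%s' missing from the %s embedding space",
                   word, sp$year))
    }
  }
  if (is.null(map)) map <- procrustes_align(space_T, space_Tt)
  raw <- cosine_similarity(apply_alignment(map, space_T$vectors[word, ]),
                           space_Tt$vectors[word, ])
  structure(data.frame(word = word, from_year = space_T$year,
                       to_year = space_Tt$year, raw = raw,
                       clipped = max(0, raw)),
            class = c("stability_score", "data.frame"))
}

#' Stability of every shared word, ranked
#'
#' Computes the stability of all words present (with nonzero vectors) in
#' both spaces and returns the top `k`, ranked by clipped stability with
#' ties broken by descending frequency then lexicographically. Use
#' `k = Inf` for the complete exportable table.
#'
#' @inheritParams stability
#' @param k number of words to return (default 10).
#' @return a data.frame `word`, `raw`, `clipped`, sorted by rank.
#' @export
most_stable_words <- function(space_T, space_Tt, map = NULL, k = 10L) {
  if (is.null(map)) map <- procrustes_align(space_T, space_Tt)
  shared <- intersect(rownames(space_T$vectors), rownames(space_Tt$vectors))
  A <- normalize_rows(space_T$vectors[shared, , drop = FALSE] %*% map$rotation)
  B <- normalize_rows(space_Tt$vectors[shared, , drop = FALSE])
  ok <- attr(A, "nonzero") & attr(B, "nonzero")
  raw <- rowSums(A * B)[ok]
  words <- shared[ok]
  if (length(words) == 0L) stop("no shared words with nonzero vectors")
  clip <- pmax(0, raw)
  freq <- space_T$frequency
  fr <- if (is.null(freq)) rep(0, length(words)) else {
    f <- freq[words]; f[is.na(f)] <- 0; f
  }
  ord <- order(-clip, -fr, words)
  out <- data.frame(word = words, raw = unname(raw),
                    clipped = unname(clip), row.names = NULL)[ord, ]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Write a stability table as CSV (`word,raw,clipped`)
#' @param table a [most_stable_words()] result.
#' @param path output CSV path.
#' @export
write_stability_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Semantic drift trajectory of a word
#'
#' Charts how a word moved through semantic space between two years. The
#' anchor set is the word's top-`k_anchors` nearest neighbours in the start
#' year plus its top-`k_anchors` in the end year, every anchor represented by
#' its end-year ("modern") vector. Each waypoint year's historical vector of
#' the word is rotated into the end-year space with orthogonal Procrustes. A
#' PCA plane is fitted on the modern anchor vectors plus the word's modern
#' vector, and all points are projected onto its top two components.
#'
#' @param word the target word.
#' @param spaces named list (names = years) of `embedding_space` objects; must
#'   contain every waypoint year.
#' @param start_year,end_year trajectory endpoints (start <= end).
#' @param step interval between waypoints in years (default 50).
#' @param k_anchors neighbours per endpoint used as anchors (default 10).
#' @return an object of class `drift_trajectory`: list with `word`,
#'   `waypoints` (data.frame `year`, `x`, `y`), `anchors` (data.frame `word`,
#'   `x`, `y`, `epoch` in start/end/both), `pca_explained` (length-2
#'   proportions).
#' @export
drift_trajectory <- function(word, spaces, start_year, end_year,
                             step = 50L, k_anchors = 10L) {
  stopifnot(start_year <= end_year)
  wanted <- unique(c(seq(start_year, end_year, by = max(step, 1L)), end_year))
  have <- as.integer(names(spaces))
  missing_years <- setdiff(wanted, have)
  if (length(missing_years)) {
    stop("embedding spaces missing for years: ",
         paste(missing_years, collapse = ", "))
  }
  start_sp <- spaces[[as.character(start_year)]]
  end_sp <- spaces[[as.character(end_year)]]
  syn_start <- nearest_synonyms(word, start_sp, k_anchors)$word
  syn_end <- nearest_synonyms(word, end_sp, k_anchors)$word
  anchors <- union(syn_start, syn_end)
  anchors <- anchors[anchors %in% rownames(end_sp$vectors) &
                       rowSums(end_sp$vectors[anchors, , drop = FALSE]^2) > 0]
  epoch <- ifelse(anchors %in% syn_start & anchors %in% syn_end, "both",
                  ifelse(anchors %in% syn_start, "start", "end"))
  modern <- end_sp$vectors[anchors, , drop = FALSE]
  fit_pts <- rbind(modern, word = end_sp$vectors[word, ])
  pca <- stats::prcomp(fit_pts, center = TRUE, scale. = FALSE, rank. = 2L)
  way <- list()
  for (y in sort(wanted)) {
    sp <- spaces[[as.character(y)]]
    if (!word %in% rownames(sp$vectors) || sum(sp$vectors[word, ]^2) == 0) {
      warning(sprintf("word '%s' missing in %d: waypoint skipped", word, y))
      next
    }
    vec <- if (y == end_year) sp$vectors[word, ] else {
      map <- procrustes_align(sp, end_sp)
      apply_alignment(map, sp$vectors[word, ])
    }
    way[[as.character(y)]] <- vec
  }
  wp_mat <- do.call(rbind, way)
  wp_proj <- stats::predict(pca, wp_mat)[, 1:2, drop = FALSE]
  an_proj <- stats::predict(pca, modern)[, 1:2, drop = FALSE]
  ev <- (pca$sdev^2 / sum(pca$sdev^2))[1:2]
  structure(list(
    word = word,
    waypoints = data.frame(year = as.integer(names(way)),
                           x = wp_proj[, 1], y = wp_proj[, 2],
                           row.names = NULL),
    anchors = data.frame(word = anchors, x = an_proj[, 1], y = an_proj[, 2],
                         epoch = epoch, row.names = NULL),
    pca_explained = ev),
    class = "drift_trajectory")
}

#' @export
print.drift_trajectory <- function(x, ...) {
  cat(sprintf("<drift_trajectory> '%s', %d waypoints (%d..%d), %d anchors, PCA var %.2f/%.2f\n",
              x$word, nrow(x$waypoints), min(x$waypoints$year),
              max(x$waypoints$year), nrow(x$anchors),
              x$pca_explained[1], x$pca_explained[2]))
  invisible(x)
}

#' Export a drift trajectory as JSON
#' @param trajectory a [drift_trajectory()] result.
#' @param path output JSON path.
#' @export
write_trajectory_json <- function(trajectory, path) {
  jsonlite::write_json(list(word = trajectory$word,
                            waypoints = trajectory$waypoints,
                            anchors = trajectory$anchors,
                            pca_explained = trajectory$pca_explained),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
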