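#' Louvain community detection on a semantic network
#'
#' Runs the Louvain modularity-optimization algorithm (Blondel-style
#' multilevel heuristic, via igraph) with a fixed seed and deterministic node
#' ordering. An edgeless graph yields one singleton community per node and
#' modularity 0 by convention.
#'
#' @param graph an igraph graph (edge attribute `weight` used when present).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed fixing tie-breaks (default 1).
#' @return a list with `membership` (named integer vector) and `modularity`.
#' @export
detect_communities <- function(graph, resolution = 1.0, seed = 1L) {
  if (igraph::vcount(graph) == 0L) {
    return(list(membership = setNames(integer(), character()), modularity = 0))
  }
  if (igraph::ecount(graph) == 0L) {
    memb <- setNames(seq_len(igraph::vcount(graph)),
                     igraph::V(graph)$name)
    return(list(membership = memb, modularity = 0))
  }
  w <- igraph::E(graph)$weight
  cl <- withr_seed(seed, igraph::cluster_louvain(graph, weights = w,
                                                 resolution = resolution))
  memb <- igraph::membership(cl)
  list(membership = setNames(as.integer(memb), igraph::V(graph)$name),
       modularity = igraph::modularity(graph, memb, weights = w))
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

new_semantic_network <- function(graph, flavor, year, parameters, seed) {
  comm <- detect_communities(graph, seed = seed)
  structure(list(graph = graph, flavor = flavor, year = year,
                 parameters = parameters, communities = comm$membership,
                 modularity = comm$modularity),
            class = "semantic_network")
}

#' @export
print.semantic_network <- function(x, ...) {
  cat(sprintf("<semantic_network> flavor=%s%s: %d nodes, %d edges, %d communities (Q=%.3f)\n",
              x$flavor, if (is.na(x$year)) "" else sprintf(" year=%d", x$year),
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(unique(x$communities)), x$modularity))
  invisible(x)
}

#' Synonym-similarity network
#'
#' Nodes are the seed words plus the top-`k` nearest synonyms of each seed;
#' edges connect node pairs whose embedding cosine similarity exceeds
#' `edge_threshold`, weighted by that similarity. Communities are labelled by
#' Louvain.
#'
#' @param seeds seed words (all must be in the space).
#' @param space an `embedding_space`.
#' @param k synonyms per seed (default 5).
#' @param edge_threshold minimum cosine for an edge, exclusive (default 0.8).
#' @param seed community-detection seed.
#' @return a `semantic_network` (flavor `"synonym"`).
#' @export
synonym_network <- function(seeds, space, k = 5L, edge_threshold = 0.8,
                            seed = 1L) {
  absent <- setdiff(seeds, rownames(space$vectors))
  if (length(absent)) stop("seed word(s) not in space: ",
                           paste(absent, collapse = ", "))
  syns <- unlist(lapply(seeds, function(s)
    nearest_synonyms(s, space, k)$word), use.names = FALSE)
  nodes <- unique(c(seeds, syns))
  m <- normalize_rows(space$vectors[nodes, , drop = FALSE])
  sims <- m %*% t(m)
  edges <- which(upper.tri(sims) & sims > edge_threshold, arr.ind = TRUE)
  edf <- data.frame(from = nodes[edges[, 1]], to = nodes[edges[, 2]],
                    weight = sims[edges])
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  freq <- space$frequency
  igraph::V(g)$frequency <- if (is.null(freq)) 0 else {
    f <- freq[nodes]; f[is.na(f)] <- 0; unname(f)
  }
  new_semantic_network(g, "synonym", space$year,
                       list(k = k, edge_threshold = edge_threshold,
                            seed = seed), seed)
}

#' Contextual co-occurrence network around a target word
#'
#' Candidate nodes are the words whose PPMI with the target exceeds
#' `ppmi_threshold` AND whose normalized co-occurrence rate with the target
#' is at least `min_rate` (per `per` corpus words). Edges connect candidate
#' pairs (and candidates to the target) whose pairwise PPMI exceeds the same
#' threshold, weighted by PPMI. Node size attribute = the word's relative
#' frequency that year. No surviving candidate yields an empty network, not
#' an error.
#'
#' @param target target word.
#' @param year integer year.
#' @param tensor a `cooc_tensor`.
#' @param totals per-year totals from [year_totals()].
#' @param ppmi optional precomputed [compute_ppmi()] for that year's slice.
#' @param ppmi_threshold minimum PPMI, exclusive (default 3).
#' @param min_rate minimum co-occurrence rate with the target, inclusive
#'   (default 200).
#' @param per rate normalization constant (default `1e10`; the quoted
#'   threshold of 200 is per ten billion words, though a per-billion reading
#'   also circulates — hence the explicit knob).
#' @param counts optional [count_tokens()] table for exact node frequencies;
#'   when absent, frequency falls back to the co-occurrence marginal.
#' @param seed community-detection seed.
#' @return a `semantic_network` (flavor `"context"`).
#' @export
context_network <- function(target, year, tensor, totals, ppmi = NULL,
                            ppmi_threshold = 3.0, min_rate = 200,
                            per = 1e10, counts = NULL, seed = 1L) {
  vocab <- tensor$vocabulary
  if (!target %in% vocab$words) stop(sprintf("'%s' not in vocabulary", target))
  slice <- tensor_slice(tensor, year)
  if (is.null(ppmi)) ppmi <- compute_ppmi(slice, year = as.integer(year))
  P <- ppmi$values
  prow <- P[target, ]
  crow <- slice[target, ]
  ykey <- as.character(year)
  if (!ykey %in% names(totals)) stop(sprintf("year %s absent from totals", ykey))
  rates <- as.numeric(crow) / totals[[ykey]] * per
  cand <- vocab$words[prow > ppmi_threshold & rates >= min_rate &
                        vocab$words != target]
  params <- list(ppmi_threshold = ppmi_threshold, min_rate = min_rate,
                 per = per, seed = seed)
  if (length(cand) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(new_semantic_network(g, "context", as.integer(year), params, seed))
  }
  nodes <- c(target, cand)
  sub <- as.matrix(P[nodes, nodes])
  edges <- which(upper.tri(sub) & sub > ppmi_threshold, arr.ind = TRUE)
  edf <- data.frame(from = nodes[edges[, 1]], to = nodes[edges[, 2]],
                    weight = sub[edges])
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$frequency <- vapply(nodes, function(w) {
    if (!is.null(counts)) relative_frequency(w, year, counts, totals)
    else sum(slice[w, ]) / totals[[ykey]]
  }, numeric(1))
  new_semantic_network(g, "context", as.integer(year), params, seed)
}

#' Largest co-occurrence changes between two years
#'
#' For every word that co-occurs with the target in either year, the change
#' in normalized co-occurrence rate (per `per` words) from `y1` to `y2`.
#' Normalized rates, not raw counts, so corpus growth between the years does
#' not masquerade as contextual change.
#'
#' @param target target word.
#' @param y1,y2 the two years.
#' @param tensor a `cooc_tensor`.
#' @param totals per-year totals.
#' @param top_n rows in each direction (default 15).
#' @param per rate normalization constant (default `1e10`).
#' @return an object of class `change_table`: list with `target`,
#'   `year_pair`, `table` (all rows, sorted by `delta` descending),
#'   `increases` and `decreases` (the top-`top_n` each).
#' @export
cooccurrence_change <- function(target, y1, y2, tensor, totals,
                                top_n = 15L, per = 1e10) {
  for (y in c(y1, y2)) {
    if (!as.character(y) %in% names(tensor$slices)) {
      stop(sprintf("year %d not present in tensor", y))
    }
    if (!as.character(y) %in% names(totals)) {
      stop(sprintf("year %d absent from totals", y))
    }
  }
  if (!target %in% tensor$vocabulary$words) {
    stop(sprintf("'%s' not in vocabulary", target))
  }
  r1 <- tensor_slice(tensor, y1)[target, ] / totals[[as.character(y1)]] * per
  r2 <- tensor_slice(tensor, y2)[target, ] / totals[[as.character(y2)]] * per
  keep <- (r1 > 0 | r2 > 0) & names(r1) != target
  df <- data.frame(word = names(r1)[keep], rate_y1 = as.numeric(r1[keep]),
                   rate_y2 = as.numeric(r2[keep]))
  df$delta <- df$rate_y2 - df$rate_y1
  df <- df[order(-df$delta, df$word), ]
  rownames(df) <- NULL
  structure(list(target = target, year_pair = c(y1, y2), table = df,
                 increases = utils::head(df, top_n),
                 decreases = utils::head(df[order(df$delta, df$word), ], top_n)),
            class = "change_table")
}

#' @export
print.change_table <- function(x, ...) {
  cat(sprintf("<change_table> '%s' %d -> %d; top increase: %s (+%.3g), top decrease: %s (%.3g)\n",
              x$target, x$year_pair[1], x$year_pair[2],
              x$increases$word[1], x$increases$delta[1],
              x$decreases$word[1], x$decreases$delta[1]))
  invisible(x)
}

#' Co-occurrence of a target with a fixed context set, over years
#'
#' For each year, the sum over the context set of the target's co-occurrence
#' counts with each context word, plus the same sum normalized by the year's
#' token total. Context words never co-occurring contribute 0; the set is
#' typically a prior [context_network()]'s nodes or user-chosen words.
#'
#' @param target target word.
#' @param context_words nonempty character vector.
#' @param tensor a `cooc_tensor`.
#' @param totals per-year totals.
#' @param years years to evaluate (default: all tensor years).
#' @param per normalization constant for the rate column (default `1e10`).
#' @return a data.frame `year`, `count`, `rate`.
#' @export
context_set_series <- function(target, context_words, tensor, totals,
                               years = tensor_years(tensor), per = 1e10) {
  stopifnot(length(context_words) > 0L)
  if (!target %in% tensor$vocabulary$words) {
    stop(sprintf("'%s' not in vocabulary", target))
  }
  ctx <- setdiff(intersect(context_words, tensor$vocabulary$words), target)
  years <- sort(as.integer(years))
  counts <- vapply(years, function(y) {
    if (length(ctx) == 0L) return(0)
    sum(tensor_slice(tensor, y)[target, ctx])
  }, numeric(1))
  rate <- counts / unname(totals[as.character(years)]) * per
  data.frame(year = years, count = counts, rate = rate)
}

#' Export a semantic network
#'
#' Writes GraphML plus an edge-list CSV (`source,target,weight`) and a
#' node-attribute CSV (`word,frequency,community`).
#'
#' @param network a `semantic_network`.
#' @param graphml,edges_csv,nodes_csv output paths (`NULL` to skip any).
#' @export
write_network <- function(network, graphml = NULL, edges_csv = NULL,
                          nodes_csv = NULL) {
  g <- network$graph
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edges_csv)) {
    e <- igraph::as_data_frame(g, what = "edges")
    names(e)[1:2] <- c("source", "target")
    utils::write.csv(e, edges_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(nodes_csv)) {
    v <- igraph::as_data_frame(g, what = "vertices")
    out <- data.frame(word = v$name,
                      frequency = if ("frequency" %in% names(v)) v$frequency else 0,
                      community = unname(network$communities[v$name]))
    utils::write.csv(out, nodes_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(network)
}
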