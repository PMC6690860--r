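test_that("Louvain separates two disjoint 4-cliques and handles edgeless graphs", {
  edges <- rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:4), 2)))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  igraph::E(g)$weight <- 1
  res <- detect_communities(g, seed = 1L)
  expect_equal(length(unique(res$membership)), 2L)
  expect_equal(length(unique(res$membership[paste0("a", 1:4)])), 1L)
  expect_equal(length(unique(res$membership[paste0("b", 1:4)])), 1L)
  expect_gt(res$modularity, 0)
  lone <- igraph::make_graph(NULL, n = 1) |> igraph::set_vertex_attr("name", value = "x")
  res1 <- detect_communities(lone)
  expect_equal(unname(res1$membership), 1L)
  expect_equal(res1$modularity, 0)
})

test_that("Louvain exactly recovers a planted 3-block partition and is reproducible", {
  set.seed(51)
  blocks <- rep(1:3, each = 10)
  n <- length(blocks)
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (blocks[i] == blocks[j]) 0.9 else 0.05
    adj[i, j] <- adj[j, i] <- rbinom(1, 1, p)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", 1:n)
  igraph::E(g)$weight <- 1
  res <- detect_communities(g, seed = 7L)
  ari <- igraph::compare(res$membership, blocks, method = "adjusted.rand")
  expect_equal(ari, 1.0)
  res2 <- detect_communities(g, seed = 7L)
  expect_identical(res$membership, res2$membership)
  # modularity of the returned partition beats the singleton partition
  singleton <- seq_len(n)
  expect_gt(res$modularity, igraph::modularity(g, singleton))
})

test_that("synonym networks threshold edges and label planted topics", {
  sim <- default_sim()
  sp <- sim$spaces[["2000"]]
  # impossible threshold: cosine never exceeds 1
  net0 <- synonym_network(c("t1w001", "t2w001"), sp, k = 3,
                          edge_threshold = 1.01)
  expect_equal(igraph::ecount(net0$graph), 0L)
  expect_equal(length(unique(net0$communities)),
               igraph::vcount(net0$graph))
  # seeds from two planted topics split into exactly two communities
  net <- synonym_network(c("t1w001", "t2w001"), sp, k = 5,
                         edge_threshold = 0.8)
  expect_equal(length(unique(net$communities)), 2L)
  topic_of <- sim$manifest$topic_of
  memb_by_topic <- split(net$communities, topic_of[names(net$communities)])
  expect_equal(length(unique(memb_by_topic[["1"]])), 1L)
  expect_equal(length(unique(memb_by_topic[["2"]])), 1L)
  expect_error(synonym_network("absent_word", sp), "absent_word")
})

test_that("raising the edge threshold never adds edges", {
  sim <- default_sim()
  sp <- sim$spaces[["2000"]]
  seeds <- c("t1w001", "t2w001", "t3w001")
  edge_set <- function(th) {
    g <- synonym_network(seeds, sp, k = 5, edge_threshold = th)$graph
    e <- igraph::as_data_frame(g, what = "edges")
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  prev <- edge_set(0.2)
  for (th in c(0.5, 0.8, 0.95)) {
    cur <- edge_set(th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("context networks recover planted context blocks of a mid-drift word", {
  # sharper topic geometry for the PPMI threshold: 20 topics of 10 words
  cfg <- synthetic_config(
    seed = 44L, years = c(1850L, 1875L, 1900L), n_topics = 20L,
    words_per_topic = 10L, ngrams_per_year = 30000L,
    drift_specs = list(list(word = "drifter", from_topic = 1L, to_topic = 2L,
                            onset = 1850L, completion = 1900L, rate = 0.02)),
    frequency_schedules = list(),
    affect_blocks = list(list(topic = 1L, dimension = "valence",
                              mean = 7, sd = 0.1)))
  gen <- generate_corpus(cfg)
  v <- build_vocabulary(count_tokens(gen$records), cap = 500L)
  tensor <- accumulate_cooccurrence(gen$records, v)
  totals <- year_totals(gen$records)
  # mid-drift year: half the drifter's grams in topic 1, half in topic 2
  net <- context_network("drifter", 1875, tensor, totals,
                         ppmi_threshold = 1.2, min_rate = 1e5, per = 1e10)
  nodes <- setdiff(igraph::V(net$graph)$name, "drifter")
  blocks <- c(gen$manifest$topic_words[[1]], gen$manifest$topic_words[[2]])
  expect_setequal(nodes, blocks)
  memb <- net$communities[nodes]
  topic_of <- gen$manifest$topic_of
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[topic_of[nodes] == 1])), 1L)
  expect_equal(length(unique(memb[topic_of[nodes] == 2])), 1L)
  # an impossible rate floor empties the network without erroring
  empty <- context_network("drifter", 1875, tensor, totals,
                           ppmi_threshold = 1.2, min_rate = Inf)
  expect_equal(igraph::vcount(empty$graph), 0L)
  expect_equal(empty$parameters$min_rate, Inf)
})

test_that("change tables are exact deltas, antisymmetric, and date the drift", {
  sim <- default_sim()
  same <- cooccurrence_change("drifter", 1850, 1850, sim$tensor, sim$totals)
  expect_true(all(same$table$delta == 0))
  fwd <- cooccurrence_change("drifter", 1850, 2000, sim$tensor, sim$totals)
  bwd <- cooccurrence_change("drifter", 2000, 1850, sim$tensor, sim$totals)
  m <- merge(fwd$table, bwd$table, by = "word")
  expect_equal(m$delta.x, -m$delta.y)
  expect_equal(fwd$table$delta,
               fwd$table$rate_y2 - fwd$table$rate_y1)
  # increases dominated by destination-topic words, decreases by origin-topic
  topic_of <- sim$manifest$topic_of
  ds <- sim$manifest$drift_specs[[1]]
  inc <- head(fwd$increases$word, 10)
  dec <- head(fwd$decreases$word, 10)
  expect_true(all(topic_of[inc] == ds$to_topic))
  expect_true(all(topic_of[dec] == ds$from_topic))
  expect_error(cooccurrence_change("drifter", 1850, 1840, sim$tensor,
                                   sim$totals), "1840")
})

test_that("context-set series are linear in the set and zero off-support", {
  sim <- default_sim()
  t2 <- sim$manifest$topic_words[[2]]
  # drifter never meets topic-3 words: all-zero series
  zero <- context_set_series("drifter", sim$manifest$topic_words[[3]],
                             sim$tensor, sim$totals)
  expect_true(all(zero$count == 0))
  # additivity over a partition of the context set
  half1 <- t2[1:50]; half2 <- t2[51:100]
  s_all <- context_set_series("drifter", t2, sim$tensor, sim$totals)
  s1 <- context_set_series("drifter", half1, sim$tensor, sim$totals)
  s2 <- context_set_series("drifter", half2, sim$tensor, sim$totals)
  expect_equal(s_all$count, s1$count + s2$count)
})

test_that("old-context decay and new-context rise cross inside the drift window", {
  sim <- default_sim()
  ds <- sim$manifest$drift_specs[[1]]
  old <- context_set_series("drifter", sim$manifest$topic_words[[ds$from_topic]],
                            sim$tensor, sim$totals)
  new <- context_set_series("drifter", sim$manifest$topic_words[[ds$to_topic]],
                            sim$tensor, sim$totals)
  expect_gt(old$rate[1], new$rate[1])
  expect_gt(new$rate[nrow(new)], old$rate[nrow(old)])
  cross <- old$year[which(new$rate > old$rate)[1]]
  expect_gte(cross, ds$onset)
  expect_lte(cross, ds$completion)
  # decay/rise monotone trends across the window
  expect_lt(cor(old$rate, old$year), 0)
  expect_gt(cor(new$rate, new$year), 0)
})

test_that("network export writes GraphML, edges and node attributes", {
  sim <- default_sim()
  net <- synonym_network(c("t1w001", "t2w001"), sim$spaces[["2000"]], k = 3)
  gml <- withr::local_tempfile(fileext = ".graphml")
  ecsv <- withr::local_tempfile(fileext = ".csv")
  ncsv <- withr::local_tempfile(fileext = ".csv")
  write_network(net, graphml = gml, edges_csv = ecsv, nodes_csv = ncsv)
  expect_true(file.exists(gml))
  e <- read.csv(ecsv); nd <- read.csv(ncsv)
  expect_equal(names(e), c("source", "target", "weight"))
  expect_equal(names(nd), c("word", "frequency", "community"))
  expect_setequal(nd$word, igraph::V(net$graph)$name)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
})
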