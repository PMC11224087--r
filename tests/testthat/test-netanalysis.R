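toy_triplets <- function() {
  data.frame(sponge_id = c("lnc_1", "lnc_2"), sponge_class = c("lncRNA", "lncRNA"),
             mirna_id = c("mi_1", "mi_1"), mrna_id = c("m_1", "m_1"),
             stringsAsFactors = FALSE)
}

toy_de <- function() {
  data.frame(feature_id = c("lnc_1", "lnc_2", "mi_1", "m_1"),
             direction = c("up", "up", "down", "up"), stringsAsFactors = FALSE)
}

test_that("network assembly counts nodes and edges with deduplication", {
  one <- assemble_network(toy_triplets()[1, ], toy_de())
  expect_equal(nrow(one$nodes), 3)
  expect_equal(nrow(one$edges), 2)
  # two triplets sharing miRNA and mRNA: 5 nodes would need distinct mRNAs;
  # here the shared pair gives 4 nodes, 3 edges after dedup
  two <- assemble_network(toy_triplets(), toy_de())
  expect_equal(nrow(two$nodes), 4)
  expect_equal(nrow(two$edges), 3)
  tri2 <- toy_triplets(); tri2$mrna_id <- c("m_1", "m_2")
  de2 <- rbind(toy_de(), data.frame(feature_id = "m_2", direction = "up"))
  shared_mi <- assemble_network(tri2, de2)
  expect_equal(nrow(shared_mi$nodes), 5)
  expect_equal(nrow(shared_mi$edges), 4)
  # empty input -> empty network
  empty <- assemble_network(toy_triplets()[0, ], toy_de())
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
  # regulation attached from the DE table
  expect_identical(two$nodes$regulation[two$nodes$id == "mi_1"], "down")
  # bipartite structure: edges connect miRNA to non-miRNA only
  role_of <- setNames(two$nodes$role, two$nodes$id)
  expect_true(all(xor(role_of[two$edges$source] == "miRNA",
                      role_of[two$edges$target] == "miRNA")))
  # unknown direction is an error
  expect_error(assemble_network(toy_triplets(), toy_de()[-1, ]), "lnc_1")
})

test_that("SIF and GraphML exports round-trip the network", {
  net <- assemble_network(toy_triplets(), toy_de())
  d <- withr::local_tempdir()
  sif <- file.path(d, "net.sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(net$edges))
  expect_true(all(grepl("\t(sponges|targets)\t", lines)))
  gml <- file.path(d, "net.graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges[order(back$edges$source, back$edges$target), ],
               net$edges[order(net$edges$source, net$edges$target), ])
  # empty network exports an empty SIF
  export_network(assemble_network(toy_triplets()[0, ], toy_de()), sif, "sif")
  expect_equal(length(readLines(sif)), 0)
})

test_that("PPI reader filters by score and cleans loops and duplicates", {
  d <- withr::local_tempdir()
  p <- file.path(d, "ppi.tsv")
  writeLines(c("node1\tnode2\tcombined_score",
               "A\tB\t900", "B\tC\t500", "C\tD\t100", "A\tB\t800", "D\tD\t999",
               "A\tC\t450"), p)
  expect_message(g <- read_ppi(p, score_threshold = 400), "self-loop")
  expect_equal(igraph::ecount(g), 3)  # AB, BC, AC above threshold, dedup, no loop
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C"))
  writeLines(c("node1\tnode2\tcombined_score", "A\tB"), p)
  expect_error(read_ppi(p), "malformed line 2")
})

test_that("maximal cliques match brute-force enumeration on the worked graphs", {
  # 4-cycle: four edge-cliques
  cyc <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  cyc["a", "b"] <- cyc["b", "c"] <- cyc["c", "d"] <- cyc["d", "a"] <- 1L
  cyc <- cyc + t(cyc)
  got <- maximal_cliques(adj_to_igraph(cyc))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(brute_cliques(pmin(cyc, 1L)), paste, collapse = ","))
  # K4: one clique of size 4
  k4 <- adj_to_igraph(matrix(1L, 4, 4, dimnames = list(letters[1:4], letters[1:4])) -
                      diag(1L, 4))
  expect_equal(maximal_cliques(k4), list(letters[1:4]))
  # edgeless graph: no cliques (singletons excluded by convention)
  e0 <- igraph::make_empty_graph(3, directed = FALSE)
  e0 <- igraph::set_vertex_attr(e0, "name", value = c("x", "y", "z"))
  expect_equal(length(maximal_cliques(e0)), 0)
})

test_that("MCC reproduces the hand-computed scores on canonical graphs", {
  k3 <- adj_to_igraph(matrix(1L, 3, 3, dimnames = list(letters[1:3], letters[1:3])) -
                      diag(1L, 3))
  expect_equal(mcc_scores(k3)$mcc, rep(2, 3))  # (3-1)! per node
  path <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "c"] <- 1L
  path <- path + t(path)
  sc <- mcc_scores(adj_to_igraph(path))
  expect_equal(sc$mcc[sc$node_id == "b"], 2)  # member of {a,b} and {b,c}
  expect_equal(sc$mcc[sc$node_id %in% c("a", "c")], c(1, 1))
  edge <- adj_to_igraph(matrix(c(0L, 1L, 1L, 0L), 2, 2,
                               dimnames = list(c("u", "v"), c("u", "v"))))
  expect_equal(mcc_scores(edge)$mcc, c(1, 1))
  k5 <- adj_to_igraph(matrix(1L, 5, 5, dimnames = list(letters[1:5], letters[1:5])) -
                      diag(1L, 5))
  sck5 <- mcc_scores(k5)
  expect_equal(sck5$mcc, rep(24, 5))  # 4!
  expect_equal(nrow(top_hubs(sck5, 10)), 5)  # underfull
})

test_that("MCC equals the brute-force oracle on random graphs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:9, 1)
    adj <- random_adj(n, runif(1, 0.2, 0.7))
    got <- mcc_scores(adj_to_igraph(adj))
    want <- brute_mcc(adj)
    expect_equal(setNames(got$mcc, got$node_id)[names(want)], want,
                 info = sprintf("graph %d", i))
  }
})

test_that("isolated nodes score zero and ranks are dense with degree tie-break", {
  adj <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  adj["a", "b"] <- 1L; adj <- adj + t(adj)
  sc <- mcc_scores(adj_to_igraph(adj))
  expect_equal(sc$mcc[sc$node_id %in% c("c", "d")], c(0, 0))
  expect_equal(sc$rank, c(1, 1, 2, 2))
  expect_identical(sc$node_id[1:2], c("a", "b"))  # id tie-break within equal mcc
})

test_that("planted clique members occupy the top MCC ranks", {
  g <- generate_ppi(40, edge_prob = 0.05, planted_cliques = 5, rng_seed = 12)
  members <- igraph::graph_attr(g, "planted_cliques")[[1]]
  hubs <- top_hubs(mcc_scores(g), 5)
  expect_setequal(hubs$node_id, members)
})
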