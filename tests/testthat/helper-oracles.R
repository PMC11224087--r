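# Independent brute-force oracles used across the suite.

# All maximal cliques (size >= 2) of a graph given as an adjacency matrix,
# by exhaustive subset enumeration. Feasible for n <= ~12 nodes.
brute_cliques <- function(adj) {
  n <- nrow(adj)
  ids <- rownames(adj)
  cliques <- list()
  is_clique <- function(idx) {
    if (length(idx) < 2) return(FALSE)
    all(adj[idx, idx][upper.tri(diag(length(idx)))] == 1)
  }
  subsets <- unlist(lapply(2:n, function(k) utils::combn(n, k, simplify = FALSE)),
                    recursive = FALSE)
  clq <- Filter(is_clique, subsets)
  # maximal: no clique strictly contains it
  maximal <- Filter(function(s) {
    !any(vapply(clq, function(t) length(t) > length(s) && all(s %in% t), logical(1)))
  }, clq)
  lapply(maximal, function(s) sort(ids[s]))
}

# MCC by the brute-force clique oracle: sum of (|C|-1)! over maximal
# cliques containing the node; isolated nodes score 0.
brute_mcc <- function(adj) {
  ids <- rownames(adj)
  mcc <- stats::setNames(numeric(length(ids)), ids)
  for (cl in brute_cliques(adj)) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  mcc
}

igraph_to_adj <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  a[a > 1] <- 1
  a
}

# Upper-tail hypergeometric P(X >= x) by exhaustive enumeration of all
# C(N, n) draws of the "mRNA" target set from a universe containing K
# "sponge" targets. Feasible for N <= 12.
hyper_enum <- function(x, K, n, N) {
  if (x <= 0) return(1)
  draws <- utils::combn(N, n, simplify = FALSE)
  mean(vapply(draws, function(d) sum(d <= K) >= x, logical(1)))
}

# random simple graph on n named nodes as an adjacency matrix
random_adj <- function(n, p) {
  adj <- matrix(0L, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# run the full screening stages on a generated dataset (shared by several
# test files); returns the screen output plus the inputs
run_screen <- function(cfg) {
  d <- generate_expression(cfg)
  seqs <- generate_sequences(cfg, d$truth)
  cn <- quantile_normalize(d$cerna)
  mn <- quantile_normalize(d$mirna)
  de <- rbind(differential_expression(cn), differential_expression(mn))
  de_ids <- de$feature_id[de$direction != "ns"]
  hits <- scan_targets(seqs$mirna_seqs[intersect(names(seqs$mirna_seqs), de_ids)],
                       seqs$target_seqs[intersect(names(seqs$target_seqs), de_ids)])
  screen <- screen_triplets(de, hits, cn, mn)
  list(data = d, seqs = seqs, de = de, hits = hits, screen = screen,
       cerna_norm = cn, mirna_norm = mn)
}

triplet_key <- function(df) paste(df$sponge_id, df$mirna_id, df$mrna_id)
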