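#' Assemble the tripartite ceRNA network from screened triplets
#'
#' Nodes are the union of triplet members with their DE direction attached;
#' edges are the deduplicated sponge--miRNA ("sponges") and miRNA--mRNA
#' ("targets") pairs. Sponge--mRNA, sponge--sponge, miRNA--miRNA and
#' mRNA--mRNA edges never occur.
#'
#' @param triplets the \code{triplets} data.frame from
#'   \code{\link{screen_triplets}}.
#' @param de DE table supplying each member's direction (up/down).
#' @return An object of class \code{"cerna_network"}: list with
#'   \code{nodes} (id, role, regulation) and \code{edges}
#'   (source, interaction, target).
#' @export
assemble_network <- function(triplets, de) {
  nodes <- data.frame(id = character(0), role = character(0),
                      regulation = character(0), stringsAsFactors = FALSE)
  edges <- data.frame(source = character(0), interaction = character(0),
                      target = character(0), stringsAsFactors = FALSE)
  if (nrow(triplets)) {
    dir_of <- stats::setNames(de$direction, de$feature_id)
    ids <- unique(c(triplets$sponge_id, triplets$mirna_id, triplets$mrna_id))
    missing <- ids[!ids %in% names(dir_of) | dir_of[ids] == "ns"]
    if (length(missing))
      stop("triplet member(s) without a DE direction: ",
           paste(missing, collapse = ", "))
    sponge_role <- stats::setNames(paste0("sponge-", triplets$sponge_class),
                                   triplets$sponge_id)
    nodes <- rbind(
      data.frame(id = unique(triplets$sponge_id),
                 role = unname(sponge_role[unique(triplets$sponge_id)]),
                 stringsAsFactors = FALSE),
      data.frame(id = unique(triplets$mirna_id), role = "miRNA",
                 stringsAsFactors = FALSE),
      data.frame(id = unique(triplets$mrna_id), role = "mRNA",
                 stringsAsFactors = FALSE))
    nodes$regulation <- unname(dir_of[nodes$id])
    nodes <- nodes[order(nodes$id), ]
    rownames(nodes) <- NULL
    edges <- unique(rbind(
      data.frame(source = triplets$sponge_id, interaction = "sponges",
                 target = triplets$mirna_id, stringsAsFactors = FALSE),
      data.frame(source = triplets$mirna_id, interaction = "targets",
                 target = triplets$mrna_id, stringsAsFactors = FALSE)))
    edges <- edges[order(edges$source, edges$target), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  roles <- table(x$nodes$role)
  cat(sprintf("cerna_network: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes))
    cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

#' Export a ceRNA network for Cytoscape-style viewers
#'
#' SIF writes one "source<TAB>interaction<TAB>target" line per edge;
#' GraphML (via igraph) carries role and regulation as node attributes;
#' "tsv" writes a nodes TSV and an edges TSV (paths derived by suffix).
#'
#' @param net a \code{cerna_network}.
#' @param path output file (for "tsv", the edge file; the node file gets a
#'   \code{.nodes.tsv} suffix).
#' @param format one of "sif", "graphml", "tsv".
#' @return Invisibly, the path.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cerna_network"))
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$interaction,
                     net$edges$target)
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- cerna_network_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$nodes, sub("\\.tsv$", ".nodes.tsv", path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

cerna_network_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes$id)
  g <- igraph::set_vertex_attr(g, "role", value = net$nodes$role)
  g <- igraph::set_vertex_attr(g, "regulation", value = net$nodes$regulation)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$source, net$edges$target))
    g <- igraph::set_edge_attr(g, "interaction", value = net$edges$interaction)
  }
  g
}

#' Re-import a GraphML network written by \code{export_network}
#'
#' @param path GraphML file.
#' @return A \code{cerna_network} (round-trips losslessly).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name, role = igraph::V(g)$role,
                      regulation = igraph::V(g)$regulation, stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1],
                      interaction = if (igraph::ecount(g)) igraph::E(g)$interaction else character(0),
                      target = el[, 2], stringsAsFactors = FALSE)
  if (nrow(edges)) {
    # GraphML stores undirected edges; restore the canonical orientation
    # (sponge -> miRNA for "sponges", miRNA -> mRNA for "targets")
    role <- stats::setNames(nodes$role, nodes$id)
    flip <- (edges$interaction == "sponges" & role[edges$source] == "miRNA") |
            (edges$interaction == "targets" & role[edges$target] == "miRNA")
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
  }
  nodes <- nodes[order(nodes$id), ]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$source, edges$target), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' Read a STRING-style PPI edge list
#'
#' Expects a TSV with two id columns (\code{node1}, \code{node2}) and an
#' optional \code{combined_score}. Edges below \code{score_threshold} are
#' dropped; self-loops and duplicate edges are removed with a message
#' reporting the counts.
#'
#' @param path edge-list TSV.
#' @param score_threshold minimum combined score (STRING convention,
#'   0--1000; default 400 = medium confidence). Ignored when the file has
#'   no score column.
#' @return An undirected simple \code{igraph} graph with an edge attribute
#'   \code{score} when available.
#' @export
read_ppi <- function(path, score_threshold = 400) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(igraph::make_empty_graph(0, directed = FALSE))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("PPI file needs at least two id columns")
  has_score <- "combined_score" %in% header
  body <- lines[-1]
  n1 <- character(length(body)); n2 <- character(length(body))
  sc <- numeric(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop(sprintf("malformed line %d in %s: expected %d fields, got %d",
                   i + 1L, path, length(header), length(f)))
    n1[i] <- f[1]; n2[i] <- f[2]
    if (has_score) {
      sc[i] <- suppressWarnings(as.numeric(f[which(header == "combined_score")]))
      if (is.na(sc[i]))
        stop(sprintf("malformed line %d in %s: non-numeric combined_score", i + 1L, path))
    }
  }
  keep <- if (has_score) sc >= score_threshold else rep(TRUE, length(n1))
  n1 <- n1[keep]; n2 <- n2[keep]; sc <- sc[keep]
  loops <- n1 == n2
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  n1 <- n1[!loops]; n2 <- n2[!loops]; sc <- sc[!loops]
  # canonical order for dedup
  a <- pmin(n1, n2); b <- pmax(n1, n2)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) collapsed")
  a <- a[!dup]; b <- b[!dup]; sc <- sc[!dup]
  ids <- sort(unique(c(a, b)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(a, b))
    if (has_score) g <- igraph::set_edge_attr(g, "score", value = sc)
  }
  g
}

#' Enumerate maximal cliques of a simple graph
#'
#' Bron--Kerbosch enumeration (with pivoting, via igraph) of all maximal
#' cliques of size >= 2; singleton "cliques" of isolated nodes are
#' excluded by convention. Output is canonically ordered (members sorted
#' within a clique; cliques sorted by size then members) for determinism.
#' Intended for PPI-scale graphs (up to a few thousand sparse nodes).
#'
#' @param g an undirected \code{igraph} graph with named vertices.
#' @return A list of character vectors, one per maximal clique.
#' @export
maximal_cliques <- function(g) {
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  ord <- order(lengths(cl), vapply(cl, paste, character(1), collapse = "\r"))
  cl[ord]
}

#' Maximal clique centrality (MCC) scores
#'
#' For each node, MCC is the sum over all maximal cliques C containing the
#' node of (|C| - 1)!. Nodes in no clique of size >= 2 (isolated nodes)
#' score 0. Ranks are dense with ties broken by degree (descending) then
#' node id.
#'
#' @param g an undirected \code{igraph} graph with named vertices.
#' @return A data.frame ordered by rank: node_id, mcc, degree, rank.
#' @export
mcc_scores <- function(g) {
  ids <- igraph::V(g)$name
  mcc <- stats::setNames(numeric(length(ids)), ids)
  for (cl in maximal_cliques(g)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  deg <- igraph::degree(g)
  out <- data.frame(node_id = ids, mcc = unname(mcc),
                    degree = unname(deg[ids]), stringsAsFactors = FALSE)
  out <- out[order(-out$mcc, -out$degree, out$node_id), ]
  out$rank <- match(-out$mcc, sort(unique(-out$mcc)))  # dense rank by mcc
  rownames(out) <- NULL
  out
}

#' Top hub genes by MCC
#'
#' @param scores output of \code{\link{mcc_scores}}.
#' @param k number of hubs (default the conventional top 10).
#' @return The first \code{min(k, n)} rows of \code{scores}.
#' @export
top_hubs <- function(scores, k = 10) {
  if (k < 1) stop("k must be >= 1")
  utils::head(scores, k)
}
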