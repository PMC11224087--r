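#' Pipeline configuration
#'
#' Collects the screening thresholds and the simulation block (or input
#' paths) for \code{\link{run_pipeline}}. All thresholds are validated up
#' front so misconfiguration fails before any compute.
#'
#' @param sim a \code{\link{sim_config}} describing the dataset to
#'   generate, or NULL when \code{paths} supplies files on disk.
#' @param paths optional named list with elements cerna_matrix,
#'   cerna_samples, cerna_features, mirna_matrix, mirna_samples,
#'   mirna_features and optionally mirna_fasta, target_fasta, target_table,
#'   ppi, gmt, ct_table.
#' @param fc_threshold,de_alpha differential expression screen.
#' @param r_neg,r_pos,corr_alpha correlation screen.
#' @param pair_alpha hypergeometric pair screen.
#' @param top_k number of top-scoring ceRNA pairs to report.
#' @param hub_k number of MCC hubs to report.
#' @param min_site_type weakest seed-site class the scanner reports.
#' @param seed integer seed for every stochastic stage.
#' @return A validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            fc_threshold = 2.0, de_alpha = 0.05,
                            r_neg = -0.8, r_pos = 0.8, corr_alpha = 0.05,
                            pair_alpha = 0.05, top_k = 100, hub_k = 10,
                            min_site_type = "7mer-m8", seed = 1L) {
  if (is.null(sim) && is.null(paths)) stop("either 'sim' or 'paths' must be given")
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop("'sim' must be a sim_config")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  for (a in c(de_alpha, corr_alpha, pair_alpha))
    if (a <= 0 || a > 1) stop("alpha thresholds must lie in (0, 1]")
  if (r_neg <= -1 || r_neg >= 0) stop("r_neg must lie in (-1, 0)")
  if (r_pos <= 0 || r_pos >= 1) stop("r_pos must lie in (0, 1)")
  if (top_k < 1 || hub_k < 1) stop("top_k and hub_k must be >= 1")
  if (!is.null(paths)) {
    for (p in unlist(paths)) if (!file.exists(p)) stop("input path not found: ", p)
  }
  structure(list(sim = sim, paths = paths, fc_threshold = fc_threshold,
                 de_alpha = de_alpha, r_neg = r_neg, r_pos = r_pos,
                 corr_alpha = corr_alpha, pair_alpha = pair_alpha,
                 top_k = top_k, hub_k = hub_k, min_site_type = min_site_type,
                 seed = as.integer(seed)), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 15)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full ceRNA inference pipeline
#'
#' Simulate (or load) -> quantile-normalize per platform -> differential
#' expression -> seed-scan targeting -> hypergeometric + signed-correlation
#' triplet screen -> network assembly and export -> PPI MCC hubs ->
#' over-representation analysis -> qPCR quantification. Every stage writes
#' a TSV into \code{outdir}; a machine-readable \code{summary.json}
#' records per-stage counts, the thresholds and the seed. Re-running with
#' the same config reproduces every output byte for byte.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  stage <- "simulate"
  summary <- list(seed = config$seed,
                  thresholds = config[c("fc_threshold", "de_alpha", "r_neg", "r_pos",
                                        "corr_alpha", "pair_alpha", "top_k", "hub_k",
                                        "min_site_type")])
  res <- tryCatch({
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$rng_seed <- config$seed
      data <- generate_expression(sim)
      seqs <- generate_sequences(sim, data$truth)
      write_expression(data$cerna, out("cerna_matrix.tsv"), out("cerna_samples.tsv"),
                       out("cerna_features.tsv"))
      write_expression(data$mirna, out("mirna_matrix.tsv"), out("mirna_samples.tsv"),
                       out("mirna_features.tsv"))
      write_fasta(seqs$mirna_seqs, out("mirna.fa"))
      write_fasta(seqs$target_seqs, out("targets.fa"))
      write_truth(data$truth, out("ground_truth.json"))
      cerna <- data$cerna; mirna <- data$mirna
      mirna_seqs <- seqs$mirna_seqs; target_seqs <- seqs$target_seqs
    } else {
      p <- config$paths
      cerna <- read_expression(p$cerna_matrix, p$cerna_samples, p$cerna_features)
      mirna <- read_expression(p$mirna_matrix, p$mirna_samples, p$mirna_features)
      mirna_seqs <- if (!is.null(p$mirna_fasta)) read_fasta(p$mirna_fasta) else NULL
      target_seqs <- if (!is.null(p$target_fasta)) read_fasta(p$target_fasta) else NULL
    }

    stage <- "normalize"
    cerna_n <- quantile_normalize(cerna)
    mirna_n <- quantile_normalize(mirna)

    stage <- "de"
    de_cerna <- differential_expression(cerna_n, config$fc_threshold, config$de_alpha)
    de_mirna <- differential_expression(mirna_n, config$fc_threshold, config$de_alpha)
    de <- rbind(de_cerna, de_mirna)
    write_tsv(de, out("differential_expression.tsv"))
    counts <- classify_counts(de)
    write_tsv(counts, out("de_counts.tsv"))

    stage <- "targets"
    de_ids <- de$feature_id[de$direction != "ns"]
    if (!is.null(config$paths) && !is.null(config$paths$target_table)) {
      hits <- import_target_table(config$paths$target_table,
                                  known_ids = c(rownames(cerna$values),
                                                rownames(mirna$values)))
    } else {
      if (is.null(mirna_seqs) || is.null(target_seqs))
        stop("no sequences and no imported target table available")
      # scan DE mediators against DE transcripts only (the screen's inputs)
      hits <- scan_targets(mirna_seqs[intersect(names(mirna_seqs), de_ids)],
                           target_seqs[intersect(names(target_seqs), de_ids)],
                           min_site_type = config$min_site_type)
    }
    write_hits(hits, out("target_hits.tsv"))

    stage <- "cerna"
    screen <- screen_triplets(de, hits, cerna_n, mirna_n,
                              r_neg = config$r_neg, r_pos = config$r_pos,
                              corr_alpha = config$corr_alpha,
                              pair_alpha = config$pair_alpha)
    write_tsv(screen$triplets, out("triplets.tsv"))
    write_tsv(screen$pairs, out("cerna_pairs.tsv"))
    top_pairs <- top_k_pairs(screen$pairs, config$top_k)
    write_tsv(top_pairs, out("top_pairs.tsv"))

    stage <- "network"
    net <- assemble_network(screen$triplets, de)
    export_network(net, out("cerna_network.sif"), "sif")
    export_network(net, out("cerna_network.graphml"), "graphml")
    export_network(net, out("cerna_network.edges.tsv"), "tsv")

    stage <- "hubs"
    net_mrnas <- net$nodes$id[net$nodes$role == "mRNA"]
    if (!is.null(config$paths) && !is.null(config$paths$ppi)) {
      ppi <- read_ppi(config$paths$ppi)
    } else {
      # stand-in interactome over the network's mRNAs: sparse background
      # plus one planted clique among the first min(5, n) genes
      n_ppi <- length(net_mrnas)
      ppi <- if (n_ppi >= 2)
        generate_ppi(n_ppi, edge_prob = 0.08,
                     planted_cliques = if (n_ppi >= 4) min(5L, n_ppi) else integer(0),
                     rng_seed = config$seed + 2L, node_ids = sort(net_mrnas))
      else igraph::make_empty_graph(0, directed = FALSE)
    }
    hubs <- if (igraph::vcount(ppi) > 0) top_hubs(mcc_scores(ppi), config$hub_k)
            else data.frame(node_id = character(0), mcc = numeric(0),
                            degree = numeric(0), rank = integer(0))
    write_tsv(hubs, out("hub_genes.tsv"))

    stage <- "enrich"
    universe <- rownames(cerna$values)[cerna$features$class == "mRNA"]
    if (!is.null(config$paths) && !is.null(config$paths$gmt)) {
      collection <- read_gmt(config$paths$gmt)
    } else {
      # synthetic gene sets over the measured mRNA universe: one set per
      # contiguous block, so the DE head of the id space is enriched
      set.seed(config$seed + 3L)
      blocks <- split(universe, ceiling(seq_along(universe) / 40))
      collection <- stats::setNames(
        lapply(blocks, function(g) list(description = "synthetic block", genes = g)),
        sprintf("synthetic_set_%02d", seq_along(blocks)))
    }
    enr <- ora(intersect(net_mrnas, universe), collection, universe)
    write_tsv(enr, out("enrichment.tsv"))

    stage <- "qpcr"
    if (!is.null(config$paths) && !is.null(config$paths$ct_table)) {
      ct <- read_ct_table(config$paths$ct_table)
    } else {
      # validation panel emulating array-confirmed genes: 2-fold up and down
      ct <- simulate_ct_table(
        data.frame(gene_id = c("val_mRNA_up", "val_mRNA_down", "val_miR_down"),
                   gene_class = c("mRNA", "mRNA", "miRNA"),
                   delta_dct = c(-1, 1, 1), stringsAsFactors = FALSE),
        rng_seed = config$seed + 4L)
    }
    q <- ddct(ct)
    write_tsv(q$per_gene, out("qpcr_results.tsv"))

    summary$counts <- list(
      features = nrow(cerna$values) + nrow(mirna$values),
      samples = ncol(cerna$values),
      de_per_class = counts,
      n_target_hits = nrow(hits),
      n_pairs = nrow(screen$pairs),
      n_triplets = nrow(screen$triplets),
      network_nodes = nrow(net$nodes),
      network_edges = nrow(net$edges),
      n_hubs = nrow(hubs),
      n_enriched_sets = sum(enr$bh_q < 0.05),
      n_qpcr_genes = nrow(q$per_gene))
    summary
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  jsonlite::write_json(res, out("summary.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(res)
}
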