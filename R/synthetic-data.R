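#' Simulation configuration for the planted-triplet generator
#'
#' Defines a two-group (TULP vs sham) multi-class expression experiment with
#' planted differential expression and planted sponge--miRNA--mRNA triplets.
#' Defaults mirror the study design the package targets: four biological
#' replicates per group, |log2 fold change| = 2 for planted effects, a miRNA
#' group shift of -2 propagated through a latent linear coupling (strength
#' \code{b}) to its sponge and mRNA partners, and log2-scale noise sd 0.25.
#'
#' @param n_features named integer vector: feature counts per class.
#' @param n_per_group samples per group (TULP and sham).
#' @param de_fraction fraction of each class given an independent planted
#'   group effect of size \code{de_log2fc} (random sign), in addition to the
#'   triplet members (which are differentially expressed by construction).
#' @param n_triplets number of planted ceRNA triplets; sponge classes
#'   alternate lncRNA/circRNA unless \code{triplet_sponge_class} is given.
#' @param triplet_sponge_class optional character vector of length
#'   \code{n_triplets} ("lncRNA" or "circRNA").
#' @param aux_per_triplet auxiliary shared miRNAs per triplet: each planted
#'   sponge--mRNA pair additionally carries seed sites for this many
#'   dedicated miRNAs that are differentially expressed but expression-wise
#'   independent of the triplet. Real sponge pairs share several miRNAs,
#'   and the shared-miRNA overlap test is uninformative at a single shared
#'   miRNA (its minimum attainable p is 1/N).
#' @param b latent coupling strength (non-negative): sponge and mRNA log2
#'   values follow \code{mu - b * (m - mu_m)} where \code{m} is the partner
#'   miRNA's log2 value.
#' @param delta_mirna log2 group effect applied to each planted miRNA
#'   (TULP minus sham).
#' @param de_log2fc magnitude of the planted log2 fold change for
#'   non-triplet differential features.
#' @param noise_sd log2-scale Gaussian noise sd (> 0).
#' @param baseline_log2_mean,baseline_log2_sd per-feature baseline log2
#'   intensities are drawn from this normal distribution.
#' @param mirna_length,target_length sequence lengths (nt) for
#'   \code{\link{generate_sequences}}.
#' @param target_alphabet "DNA" or "RNA" alphabet for target sequences.
#' @param rng_seed integer seed; identical configs reproduce outputs
#'   bit for bit.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_features = c(lncRNA = 300, circRNA = 100, miRNA = 300, mRNA = 600),
                       n_per_group = 4,
                       de_fraction = 0.05,
                       n_triplets = 10,
                       triplet_sponge_class = NULL,
                       aux_per_triplet = 2,
                       b = 1,
                       delta_mirna = -2,
                       de_log2fc = 2,
                       noise_sd = 0.25,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       mirna_length = 22,
                       target_length = 500,
                       target_alphabet = c("DNA", "RNA"),
                       rng_seed = 1L) {
  target_alphabet <- match.arg(target_alphabet)
  need <- c("lncRNA", "circRNA", "miRNA", "mRNA")
  if (!all(need %in% names(n_features)))
    stop("n_features must name all of: ", paste(need, collapse = ", "))
  n_features <- n_features[need]
  if (any(n_features < 1)) stop("all class feature counts must be >= 1")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (b < 0) stop("coupling strength b must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (mirna_length < 8) stop("mirna_length must be >= 8 (seed region is positions 2-8)")
  if (target_length < 8) stop("target_length must allow at least one 8mer site")
  if (is.null(triplet_sponge_class)) {
    triplet_sponge_class <- rep(c("lncRNA", "circRNA"), length.out = n_triplets)
  }
  if (length(triplet_sponge_class) != n_triplets)
    stop("triplet_sponge_class must have length n_triplets")
  if (!all(triplet_sponge_class %in% c("lncRNA", "circRNA")))
    stop("triplet sponges must be lncRNA or circRNA")
  if (aux_per_triplet < 0) stop("aux_per_triplet must be non-negative")
  n_sponge_needed <- table(factor(triplet_sponge_class, c("lncRNA", "circRNA")))
  if (n_sponge_needed[["lncRNA"]] > n_features[["lncRNA"]] ||
      n_sponge_needed[["circRNA"]] > n_features[["circRNA"]] ||
      n_triplets * (1 + aux_per_triplet) > n_features[["miRNA"]] ||
      n_triplets > n_features[["mRNA"]])
    stop("planted triplet features exceed class feature counts")
  structure(list(
    n_features = n_features, n_per_group = as.integer(n_per_group),
    de_fraction = de_fraction, n_triplets = as.integer(n_triplets),
    triplet_sponge_class = triplet_sponge_class,
    aux_per_triplet = as.integer(aux_per_triplet),
    b = b, delta_mirna = delta_mirna, de_log2fc = de_log2fc,
    noise_sd = noise_sd,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    mirna_length = as.integer(mirna_length), target_length = as.integer(target_length),
    target_alphabet = target_alphabet,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

feature_ids <- function(class, n) sprintf("%s_%04d", sub("RNA$", "", class), seq_len(n))

#' Generate planted two-group expression data
#'
#' Produces a ceRNA-platform matrix (lncRNA + circRNA + mRNA features), a
#' miRNA-platform matrix over the same samples, and a ground-truth record.
#' For each planted triplet the miRNA carries the group effect
#' (\code{delta_mirna}) and the sponge and mRNA follow the miRNA through a
#' negative linear coupling, inducing negative sponge--miRNA and
#' miRNA--mRNA correlations and a positive sponge--mRNA correlation.
#' All other features are independent Gaussian noise on the log2 scale
#' around their per-feature baseline, with an added group shift for the
#' planted differential fraction. Emitted intensities are linear scale
#' (2^log2, strictly positive).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with \code{cerna} and \code{mirna} (\code{expr_matrix}
#'   objects, matched samples) and \code{truth}: a list with
#'   \code{true_de} (feature_id, class, direction),
#'   \code{true_triplets} (sponge_id, sponge_class, mirna_id, mrna_id) and
#'   \code{true_target_pairs} (mirna_id, target_id, target_class).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  nf <- config$n_features
  npg <- config$n_per_group
  ns <- 2L * npg
  sample_id <- c(sprintf("TULP_%d", seq_len(npg)), sprintf("sham_%d", seq_len(npg)))
  group <- rep(c("TULP", "sham"), each = npg)
  g <- as.numeric(group == "TULP")  # group indicator, sham = 0

  ids <- lapply(names(nf), function(cl) feature_ids(cl, nf[[cl]]))
  names(ids) <- names(nf)

  # planted triplets occupy the head of each class's id space
  tri <- data.frame(
    sponge_id = character(config$n_triplets), sponge_class = config$triplet_sponge_class,
    mirna_id = character(config$n_triplets), mrna_id = character(config$n_triplets),
    stringsAsFactors = FALSE)
  counter <- c(lncRNA = 0L, circRNA = 0L)
  for (i in seq_len(config$n_triplets)) {
    cl <- config$triplet_sponge_class[i]
    counter[cl] <- counter[cl] + 1L
    tri$sponge_id[i] <- ids[[cl]][counter[cl]]
    tri$mirna_id[i] <- ids$miRNA[i]
    tri$mrna_id[i] <- ids$mRNA[i]
  }
  # auxiliary shared miRNAs: targeting-only mediators, allocated after the
  # triplet cores, aux_per_triplet dedicated to each triplet's pair
  n_aux <- config$n_triplets * config$aux_per_triplet
  aux_ids <- if (n_aux) ids$miRNA[config$n_triplets + seq_len(n_aux)] else character(0)
  aux_of <- if (n_aux) split(aux_ids, rep(seq_len(config$n_triplets),
                                          each = config$aux_per_triplet)) else list()

  # planted independent DE features: taken after the triplet block per class
  de_extra <- list()
  used <- c(lncRNA = counter[["lncRNA"]], circRNA = counter[["circRNA"]],
            miRNA = config$n_triplets + n_aux, mRNA = config$n_triplets)
  for (cl in names(nf)) {
    n_de <- round(config$de_fraction * nf[[cl]])
    avail <- ids[[cl]][seq.int(used[[cl]] + 1L, length.out = max(0L, min(n_de, nf[[cl]] - used[[cl]])))]
    de_extra[[cl]] <- avail
  }

  log2_values <- function(cl) {
    n <- nf[[cl]]
    mu <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    v <- matrix(stats::rnorm(n * ns, 0, config$noise_sd), n, ns) + mu
    dimnames(v) <- list(ids[[cl]], sample_id)
    v
  }
  mats <- lapply(names(nf), log2_values)
  names(mats) <- names(nf)

  # independent planted DE (random sign per feature)
  de_dir <- list()
  for (cl in names(nf)) {
    f <- de_extra[[cl]]
    if (length(f)) {
      sign_f <- sample(c(1, -1), length(f), replace = TRUE)
      mats[[cl]][f, ] <- mats[[cl]][f, , drop = FALSE] +
        outer(sign_f * config$de_log2fc, g)
      de_dir[[cl]] <- data.frame(feature_id = f, class = cl,
                                 direction = ifelse(sign_f > 0, "up", "down"),
                                 stringsAsFactors = FALSE)
    }
  }

  # auxiliary miRNAs are ordinary DE features (random sign, independent noise)
  aux_sign <- numeric(0)
  if (n_aux) {
    aux_sign <- sample(c(1, -1), n_aux, replace = TRUE)
    mats$miRNA[aux_ids, ] <- mats$miRNA[aux_ids, , drop = FALSE] +
      outer(aux_sign * config$de_log2fc, g)
  }

  # planted triplets: miRNA carries the group effect, partners follow -b * (m - mu_m)
  for (i in seq_len(config$n_triplets)) {
    m_id <- tri$mirna_id[i]
    mu_m <- stats::rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd)
    m <- mu_m + config$delta_mirna * g + stats::rnorm(ns, 0, config$noise_sd)
    mats$miRNA[m_id, ] <- m
    dev <- m - mu_m
    cl <- tri$sponge_class[i]
    mu_sp <- stats::rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd)
    mats[[cl]][tri$sponge_id[i], ] <- mu_sp - config$b * dev + stats::rnorm(ns, 0, config$noise_sd)
    mu_g <- stats::rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd)
    mats$mRNA[tri$mrna_id[i], ] <- mu_g - config$b * dev + stats::rnorm(ns, 0, config$noise_sd)
  }

  mirna_dir <- if (config$delta_mirna > 0) "up" else if (config$delta_mirna < 0) "down" else "ns"
  partner_dir <- if (config$b * config$delta_mirna < 0) "up"
                 else if (config$b * config$delta_mirna > 0) "down" else "ns"
  tri_de <- if (config$n_triplets > 0) rbind(
    data.frame(feature_id = tri$sponge_id, class = tri$sponge_class,
               direction = partner_dir, stringsAsFactors = FALSE),
    data.frame(feature_id = tri$mirna_id, class = "miRNA",
               direction = mirna_dir, stringsAsFactors = FALSE),
    data.frame(feature_id = tri$mrna_id, class = "mRNA",
               direction = partner_dir, stringsAsFactors = FALSE)) else NULL
  aux_de <- if (n_aux)
    data.frame(feature_id = aux_ids, class = "miRNA",
               direction = ifelse(aux_sign > 0, "up", "down"),
               stringsAsFactors = FALSE) else NULL
  true_de <- rbind(tri_de, aux_de, do.call(rbind, de_dir))
  rownames(true_de) <- NULL

  pairs <- data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), stringsAsFactors = FALSE)
  if (config$n_triplets > 0) pairs <- rbind(
    data.frame(mirna_id = tri$mirna_id, target_id = tri$sponge_id,
               target_class = tri$sponge_class, stringsAsFactors = FALSE),
    data.frame(mirna_id = tri$mirna_id, target_id = tri$mrna_id,
               target_class = "mRNA", stringsAsFactors = FALSE))
  if (n_aux) {
    for (i in seq_len(config$n_triplets)) {
      pairs <- rbind(pairs,
        data.frame(mirna_id = aux_of[[i]], target_id = tri$sponge_id[i],
                   target_class = tri$sponge_class[i], stringsAsFactors = FALSE),
        data.frame(mirna_id = aux_of[[i]], target_id = tri$mrna_id[i],
                   target_class = "mRNA", stringsAsFactors = FALSE))
    }
  }
  rownames(pairs) <- NULL

  cerna_vals <- 2^rbind(mats$lncRNA, mats$circRNA, mats$mRNA)
  cerna <- expression_matrix(
    cerna_vals,
    rep(c("lncRNA", "circRNA", "mRNA"), times = nf[c("lncRNA", "circRNA", "mRNA")]),
    group, scale = "linear")
  mirna <- expression_matrix(2^mats$miRNA, rep("miRNA", nf[["miRNA"]]),
                             group, scale = "linear")
  list(cerna = cerna, mirna = mirna,
       truth = list(true_de = true_de, true_triplets = tri, true_target_pairs = pairs))
}

rand_seq <- function(n, len, alphabet) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

#' Generate miRNA and target sequences carrying the planted target sites
#'
#' Every true miRNA--target pair's target sequence receives, at a recorded
#' 1-based coordinate, an 8mer site: the reverse complement of the miRNA
#' seed (positions 2--8) followed by an A opposite miRNA position 1.
#' Background positions and non-target sequences are uniform random, so
#' additional seed matches occur only by chance.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth the \code{truth} element of \code{\link{generate_expression}}.
#' @return A list: \code{mirna_seqs}, \code{target_seqs} (named character
#'   vectors, RNA alphabet for miRNAs, \code{config$target_alphabet} for
#'   targets) and \code{sites} (data.frame mirna_id, target_id, site_start
#'   of the embedded 8mer on the target sense strand).
#' @export
generate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 1L)
  rna <- c("A", "C", "G", "U")
  tgt_alpha <- if (config$target_alphabet == "RNA") rna else c("A", "C", "G", "T")

  mirna_ids <- feature_ids("miRNA", config$n_features[["miRNA"]])
  mirna_seqs <- rand_seq(length(mirna_ids), config$mirna_length, rna)
  names(mirna_seqs) <- mirna_ids

  target_ids <- c(feature_ids("lncRNA", config$n_features[["lncRNA"]]),
                  feature_ids("circRNA", config$n_features[["circRNA"]]),
                  feature_ids("mRNA", config$n_features[["mRNA"]]))
  target_seqs <- rand_seq(length(target_ids), config$target_length, tgt_alpha)
  names(target_seqs) <- target_ids

  pairs <- truth$true_target_pairs
  sites <- data.frame(mirna_id = character(0), target_id = character(0),
                      site_start = integer(0), stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    u <- if (config$target_alphabet == "RNA") "U" else "T"
    occupied <- list()  # per-target intervals already carrying a planted site
    for (i in seq_len(nrow(pairs))) {
      mir <- mirna_seqs[[pairs$mirna_id[i]]]
      seed <- substr(mir, 2, 8)
      site <- paste0(revcomp_rna(seed, u = u), "A")  # 8mer: seed match + A1
      L <- config$target_length
      tid <- pairs$target_id[i]
      taken <- occupied[[tid]]
      # non-overlapping placement so one planted site never clobbers another
      for (try in 1:200) {
        pos <- sample.int(L - nchar(site) + 1L, 1)
        span <- pos:(pos + nchar(site) - 1L)
        if (!length(intersect(span, taken))) break
        if (try == 200) stop("could not place planted site in target ", tid)
      }
      occupied[[tid]] <- c(taken, span)
      tgt <- target_seqs[[tid]]
      substr(tgt, pos, pos + nchar(site) - 1L) <- site
      target_seqs[[tid]] <- tgt
      sites <- rbind(sites, data.frame(mirna_id = pairs$mirna_id[i],
                                       target_id = tid,
                                       site_start = pos, stringsAsFactors = FALSE))
    }
  }
  list(mirna_seqs = mirna_seqs, target_seqs = target_seqs, sites = sites)
}

# reverse complement of an RNA/DNA seed, output alphabet chosen by `u`
revcomp_rna <- function(x, u = "U") {
  comp <- c(A = u, C = "G", G = "C", U = "A", T = "A")
  chars <- rev(strsplit(x, "")[[1]])
  paste(comp[chars], collapse = "")
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width wrap width (80 columns).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (wrapped or single-line).
#' @return Named character vector of sequences (uppercased).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Generate a protein--protein interaction graph with planted cliques
#'
#' Erdos--Renyi background at \code{edge_prob} with the requested cliques
#' planted as complete subgraphs over disjoint node sets.
#'
#' @param n_nodes number of nodes.
#' @param edge_prob background edge probability in [0, 1].
#' @param planted_cliques integer vector of clique sizes (disjoint members).
#' @param rng_seed integer seed.
#' @param node_ids optional character vector of node labels (defaults to
#'   mRNA-style ids).
#' @return An undirected simple \code{igraph} graph; planted clique
#'   membership is stored in the graph attribute \code{planted_cliques}.
#' @export
generate_ppi <- function(n_nodes, edge_prob, planted_cliques = integer(0),
                         rng_seed = 1L, node_ids = NULL) {
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  if (sum(planted_cliques) > n_nodes)
    stop("planted cliques larger than the number of nodes")
  if (any(planted_cliques < 2)) stop("planted cliques must have size >= 2")
  if (is.null(node_ids)) node_ids <- feature_ids("mRNA", n_nodes)
  if (length(node_ids) != n_nodes) stop("node_ids length must equal n_nodes")
  set.seed(rng_seed)
  pairs <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  members <- list()
  offset <- 0L
  for (k in planted_cliques) {
    idx <- offset + seq_len(k)
    members <- c(members, list(node_ids[idx]))
    keep <- keep | (pairs[1, ] %in% idx & pairs[2, ] %in% idx)
    offset <- offset + k
  }
  edges <- pairs[, keep, drop = FALSE]
  gr <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = node_ids)
  if (ncol(edges) > 0)
    gr <- igraph::add_edges(gr, rbind(node_ids[edges[1, ]], node_ids[edges[2, ]]))
  gr <- igraph::set_graph_attr(gr, "planted_cliques", members)
  gr
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Technical-replicate Ct values for a set of genes plus their reference
#' genes (GAPDH for lncRNA/circRNA/mRNA, U6 for miRNA) in a two-group
#' design. Each gene's true treated-vs-control fold change on the linear
#' scale is \code{2^(-delta_dct)} where \code{delta_dct} is the shift in
#' delta-Ct applied to the treated group.
#'
#' @param genes data.frame with columns gene_id, gene_class, delta_dct
#'   (treated-group shift in delta-Ct cycles; -1 means a 2-fold increase).
#' @param n_per_group biological replicates per group.
#' @param n_tech technical replicates per (sample, gene).
#' @param noise_sd Ct noise sd in cycles.
#' @param rng_seed integer seed.
#' @param control_group,treated_group group labels.
#' @return A data.frame with columns sample_id, group, gene_id, gene_class,
#'   replicate, ct.
#' @export
simulate_ct_table <- function(genes, n_per_group = 4, n_tech = 3, noise_sd = 0.1,
                              rng_seed = 1L, control_group = "sham",
                              treated_group = "TULP") {
  stopifnot(all(c("gene_id", "gene_class", "delta_dct") %in% names(genes)))
  set.seed(rng_seed)
  samples <- data.frame(
    sample_id = c(sprintf("%s_%d", treated_group, seq_len(n_per_group)),
                  sprintf("%s_%d", control_group, seq_len(n_per_group))),
    group = rep(c(treated_group, control_group), each = n_per_group),
    stringsAsFactors = FALSE)
  refs <- data.frame(gene_id = c("GAPDH", "U6"),
                     gene_class = c("reference", "reference"),
                     delta_dct = c(0, 0), stringsAsFactors = FALSE)
  all_genes <- rbind(genes[, c("gene_id", "gene_class", "delta_dct")], refs)
  base_ct <- stats::setNames(stats::runif(nrow(all_genes), 18, 28), all_genes$gene_id)
  rows <- list()
  for (s in seq_len(nrow(samples))) {
    # per-sample global efficiency offset; cancels in delta-Ct
    samp_shift <- stats::rnorm(1, 0, 0.5)
    treated <- samples$group[s] == treated_group
    for (gi in seq_len(nrow(all_genes))) {
      shift <- if (treated) all_genes$delta_dct[gi] else 0
      ct <- base_ct[[all_genes$gene_id[gi]]] + samp_shift + shift +
        stats::rnorm(n_tech, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[s], group = samples$group[s],
        gene_id = all_genes$gene_id[gi], gene_class = all_genes$gene_class[gi],
        replicate = seq_len(n_tech), ct = ct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the ground-truth manifest as JSON
#'
#' @param truth the \code{truth} element of \code{\link{generate_expression}}.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
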