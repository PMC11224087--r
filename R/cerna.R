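#' Pearson correlation with the t-transform p-value
#'
#' Product-moment correlation of two sample vectors with the two-sided
#' p-value from \code{t = r sqrt(n-2) / sqrt(1 - r^2)} on n - 2 degrees of
#' freedom. A perfect correlation (|r| = 1) is reported with p = 0.
#'
#' @param x,y numeric vectors of equal length n >= 3, finite, non-constant.
#' @return A list with \code{r}, \code{p} and \code{n}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired samples")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance input: constant features must be filtered upstream")
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t_stat), df = n - 2), n = n)
}

# upper-tail hypergeometric P(X >= x) via log-space binomial coefficients;
# stable for universes up to ~1e5
hyper_upper_tail <- function(x, K, n, N) {
  if (K > N || n > N) stop("set sizes exceed the universe")
  if (x > min(K, n)) stop("overlap exceeds the smaller set")
  if (x <= 0) return(1)
  t_vals <- x:min(K, n)
  log_terms <- lchoose(K, t_vals) + lchoose(N - K, n - t_vals) - lchoose(N, n)
  mx <- max(log_terms)
  p <- exp(mx) * sum(exp(log_terms - mx))
  min(1, p)
}

#' Hypergeometric ceRNA-pair score for a sponge--mRNA pair
#'
#' Tests whether a sponge (lncRNA/circRNA) and an mRNA share more targeting
#' miRNAs than expected by chance. With K miRNAs targeting the sponge, n
#' targeting the mRNA, x shared, in a universe of N miRNAs, the score is
#' the upper-tail hypergeometric probability
#' \deqn{p = \sum_{t=x}^{\min(K,n)} {K \choose t}{N-K \choose n-t} / {N \choose n}}
#' computed with log-space binomial coefficients, and the ceRNA score is
#' \code{-log10(p)}. An empty overlap gives p = 1 (the pair fails any
#' p < alpha screen).
#'
#' @param sponge_targets character vector (or set) of miRNA ids targeting
#'   the sponge.
#' @param mrna_targets miRNA ids targeting the mRNA.
#' @param universe_size N, the number of miRNAs in the screening universe;
#'   must be >= both set sizes.
#' @return A list with K, n, N, x, shared_mirna_ids, hyper_p and score.
#' @export
cerna_pair_score <- function(sponge_targets, mrna_targets, universe_size) {
  sponge_targets <- unique(sponge_targets)
  mrna_targets <- unique(mrna_targets)
  K <- length(sponge_targets)
  n <- length(mrna_targets)
  if (universe_size < max(K, n))
    stop("universe_size must be at least as large as either target set")
  shared <- sort(intersect(sponge_targets, mrna_targets))
  x <- length(shared)
  p <- hyper_upper_tail(x, K, n, universe_size)
  list(K = K, n = n, N = universe_size, x = x, shared_mirna_ids = shared,
       hyper_p = p, score = -log10(p))
}

#' Screen for ceRNA triplets by targeting, pair score and signed correlation
#'
#' The full ceRNA screen over differentially expressed features:
#' \enumerate{
#'   \item restrict to DE features (direction != "ns"); DE miRNAs are the
#'     mediators and (by default) define the hypergeometric universe N;
#'   \item build per-feature miRNA target sets from the hits table;
#'   \item score every DE sponge (lncRNA or circRNA) against every DE mRNA
#'     with the shared-miRNA hypergeometric test; keep pairs with
#'     hyper_p < \code{pair_alpha};
#'   \item for each shared miRNA of a surviving pair, require the signed
#'     correlation pattern on log2 expression across all samples (both
#'     groups pooled): sponge--miRNA r < \code{r_neg}, miRNA--mRNA r <
#'     \code{r_neg}, sponge--mRNA r > \code{r_pos}, each correlation
#'     p < \code{corr_alpha}.
#' }
#' Emitted triplets therefore satisfy: both targeting relations exist, the
#' pair-level hypergeometric p is below threshold, and the three pooled
#' Pearson correlations carry the sponge-hypothesis sign pattern.
#'
#' @param de DE table from \code{\link{differential_expression}} covering
#'   both platforms (rbind of the two platform tables works).
#' @param hits target hits (scanner or imported).
#' @param cerna_matrix,mirna_matrix linear-scale normalized
#'   \code{expr_matrix} objects over matched samples.
#' @param r_neg,r_pos correlation thresholds (negative and positive arms).
#' @param corr_alpha p threshold for each correlation.
#' @param pair_alpha p threshold for the hypergeometric pair score.
#' @param universe "de" (N = number of DE miRNAs entering the screen) or
#'   "all" (N = all measured miRNAs).
#' @return A list with \code{triplets} (data.frame ordered by pair score
#'   desc then ids: sponge_id, sponge_class, mirna_id, mrna_id, the three
#'   correlations and their p-values, pair x/K/n/N, pair_hyper_p,
#'   pair_score) and \code{pairs} (all scored sponge--mRNA pairs with
#'   x >= 1, before the correlation screen).
#' @export
screen_triplets <- function(de, hits, cerna_matrix, mirna_matrix,
                            r_neg = -0.8, r_pos = 0.8,
                            corr_alpha = 0.05, pair_alpha = 0.05,
                            universe = c("de", "all")) {
  universe <- match.arg(universe)
  stopifnot(inherits(cerna_matrix, "expr_matrix"), inherits(mirna_matrix, "expr_matrix"))
  s1 <- cerna_matrix$samples$sample_id
  s2 <- mirna_matrix$samples$sample_id
  if (!setequal(s1, s2)) {
    miss <- c(setdiff(s1, s2), setdiff(s2, s1))
    stop("platforms measured on different samples; unmatched: ",
         paste(miss, collapse = ", "))
  }
  samples <- s1
  lc <- log2(cerna_matrix$values[, samples, drop = FALSE])
  lm <- log2(mirna_matrix$values[, samples, drop = FALSE])

  de_ids <- de$feature_id[de$direction != "ns"]
  de_mirna <- sort(intersect(de_ids, rownames(lm)))
  sponge_cls <- cerna_matrix$features$class
  names(sponge_cls) <- cerna_matrix$features$feature_id
  de_sponge <- sort(intersect(de_ids, names(sponge_cls)[sponge_cls %in% c("lncRNA", "circRNA")]))
  de_mrna <- sort(intersect(de_ids, names(sponge_cls)[sponge_cls == "mRNA"]))

  empty_triplets <- data.frame(
    sponge_id = character(0), sponge_class = character(0),
    mirna_id = character(0), mrna_id = character(0),
    r_sponge_mirna = numeric(0), p_sponge_mirna = numeric(0),
    r_mirna_mrna = numeric(0), p_mirna_mrna = numeric(0),
    r_sponge_mrna = numeric(0), p_sponge_mrna = numeric(0),
    x = integer(0), K = integer(0), n = integer(0), N = integer(0),
    pair_hyper_p = numeric(0), pair_score = numeric(0), stringsAsFactors = FALSE)
  empty_pairs <- data.frame(
    sponge_id = character(0), sponge_class = character(0), mrna_id = character(0),
    x = integer(0), K = integer(0), n = integer(0), N = integer(0),
    shared_mirna_ids = character(0), hyper_p = numeric(0), score = numeric(0),
    stringsAsFactors = FALSE)
  if (!length(de_mirna) || !length(de_sponge) || !length(de_mrna))
    return(list(triplets = empty_triplets, pairs = empty_pairs))

  # target sets restricted to DE mediators
  keep <- hits$mirna_id %in% de_mirna
  sets <- target_sets(hits[keep, , drop = FALSE])
  N <- if (universe == "de") length(de_mirna) else nrow(lm)

  mirnas_of <- function(id) {
    v <- sets$by_target[[id]]
    if (is.null(v)) character(0) else intersect(v, de_mirna)
  }

  n_sample <- length(samples)
  cor_p <- function(r) {
    p <- 2 * stats::pt(-abs(r) * sqrt(n_sample - 2) / sqrt(pmax(1 - r^2, 0)),
                       df = n_sample - 2)
    p[abs(r) >= 1] <- 0
    p
  }
  # pooled-sample correlation blocks between the three feature groups
  r_sp_mi <- stats::cor(t(lc[de_sponge, , drop = FALSE]), t(lm[de_mirna, , drop = FALSE]))
  r_mi_mr <- stats::cor(t(lm[de_mirna, , drop = FALSE]), t(lc[de_mrna, , drop = FALSE]))
  r_sp_mr <- stats::cor(t(lc[de_sponge, , drop = FALSE]), t(lc[de_mrna, , drop = FALSE]))

  pair_rows <- list()
  trip_rows <- list()
  for (sp in de_sponge) {
    sp_set <- mirnas_of(sp)
    if (!length(sp_set)) next
    for (mr in de_mrna) {
      mr_set <- mirnas_of(mr)
      if (!length(mr_set)) next
      ps <- cerna_pair_score(sp_set, mr_set, N)
      if (ps$x == 0) next
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        sponge_id = sp, sponge_class = unname(sponge_cls[[sp]]), mrna_id = mr,
        x = ps$x, K = ps$K, n = ps$n, N = ps$N,
        shared_mirna_ids = paste(ps$shared_mirna_ids, collapse = ","),
        hyper_p = ps$hyper_p, score = ps$score, stringsAsFactors = FALSE)
      if (ps$hyper_p >= pair_alpha) next
      r3 <- r_sp_mr[sp, mr]
      if (!(r3 > r_pos && cor_p(r3) < corr_alpha)) next
      for (mi in ps$shared_mirna_ids) {
        r1 <- r_sp_mi[sp, mi]
        r2 <- r_mi_mr[mi, mr]
        if (r1 < r_neg && cor_p(r1) < corr_alpha &&
            r2 < r_neg && cor_p(r2) < corr_alpha) {
          trip_rows[[length(trip_rows) + 1L]] <- data.frame(
            sponge_id = sp, sponge_class = unname(sponge_cls[[sp]]),
            mirna_id = mi, mrna_id = mr,
            r_sponge_mirna = r1, p_sponge_mirna = cor_p(r1),
            r_mirna_mrna = r2, p_mirna_mrna = cor_p(r2),
            r_sponge_mrna = r3, p_sponge_mrna = cor_p(r3),
            x = ps$x, K = ps$K, n = ps$n, N = ps$N,
            pair_hyper_p = ps$hyper_p, pair_score = ps$score,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else empty_pairs
  if (nrow(pairs)) {
    pairs <- pairs[order(-pairs$score, pairs$hyper_p, pairs$sponge_id, pairs$mrna_id), ]
    rownames(pairs) <- NULL
  }
  triplets <- if (length(trip_rows)) do.call(rbind, trip_rows) else empty_triplets
  if (nrow(triplets)) {
    triplets <- triplets[order(-triplets$pair_score, triplets$sponge_id,
                               triplets$mirna_id, triplets$mrna_id), ]
    rownames(triplets) <- NULL
  }
  list(triplets = triplets, pairs = pairs)
}

#' Select the top-k ceRNA pairs by score
#'
#' Ties are broken by ascending hypergeometric p, then sponge id, then mRNA
#' id, so the selection is stable across runs. Fewer than k pairs are
#' returned in full.
#'
#' @param pairs the \code{pairs} data.frame from \code{\link{screen_triplets}}.
#' @param k number of pairs to keep.
#' @param order_by rank by the \code{"score"} column (-log10 p) or by the
#'   shared-miRNA count \code{"x"}.
#' @return The top-k rows of \code{pairs}.
#' @export
top_k_pairs <- function(pairs, k = 100, order_by = c("score", "x")) {
  order_by <- match.arg(order_by)
  if (k < 1) stop("k must be >= 1")
  if (!nrow(pairs)) return(pairs)
  key <- if (order_by == "score") pairs$score else pairs$x
  ord <- order(-key, pairs$hyper_p, pairs$sponge_id, pairs$mrna_id)
  out <- pairs[ord[seq_len(min(k, nrow(pairs)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
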