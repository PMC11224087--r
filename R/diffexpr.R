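#' Per-feature differential expression between two groups
#'
#' Fold change is computed from linear-scale group means; the p-value comes
#' from a two-sided two-sample t-test on log2 values (Welch by default).
#' A feature is called "up" when its fold change exceeds
#' \code{fc_threshold} at p < \code{alpha}, "down" when the fold change is
#' below \code{1/fc_threshold} at p < \code{alpha}, and "ns" otherwise —
#' the symmetric reading of a |FC| > 2 screen.
#'
#' Degenerate rows (zero variance in both groups) get p = 1 when the group
#' means agree and the smallest positive double (flagged) when they differ.
#'
#' @param m an \code{expr_matrix} of normalized linear-scale intensities
#'   with exactly two sample groups, each of size >= 2.
#' @param fc_threshold linear fold-change threshold (> 1).
#' @param alpha significance threshold on the raw t-test p-value (no
#'   multiple-testing correction, mirroring a raw p < 0.05 screen).
#' @param group_test,group_ref numerator and denominator groups of the fold
#'   change.
#' @param var_equal use the pooled-variance Student's t instead of Welch.
#' @return A data.frame ordered by feature_id with columns feature_id,
#'   class, mean_test, mean_ref (linear group means), fold_change, log2fc,
#'   p_value, direction, degenerate.
#' @export
differential_expression <- function(m, fc_threshold = 2.0, alpha = 0.05,
                                    group_test = "TULP", group_ref = "sham",
                                    var_equal = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear")
    stop("differential_expression expects a linear-scale normalized matrix")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  groups <- unique(m$samples$group)
  if (length(groups) != 2 || !all(c(group_test, group_ref) %in% groups))
    stop("matrix must contain exactly the two groups '", group_test,
         "' and '", group_ref, "'")
  idx_t <- m$samples$group == group_test
  idx_r <- m$samples$group == group_ref
  if (sum(idx_t) < 2 || sum(idx_r) < 2) stop("each group needs >= 2 samples")

  lv <- log2(m$values)
  mean_t <- rowMeans(m$values[, idx_t, drop = FALSE])
  mean_r <- rowMeans(m$values[, idx_r, drop = FALSE])
  fc <- mean_t / mean_r

  n <- nrow(lv)
  p <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    x <- lv[i, idx_t]
    y <- lv[i, idx_r]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        p[i] <- 1
      } else {
        p[i] <- .Machine$double.xmin
        degenerate[i] <- TRUE
      }
    } else {
      p[i] <- stats::t.test(x, y, var.equal = var_equal)$p.value
    }
  }
  direction <- ifelse(fc > fc_threshold & p < alpha, "up",
                      ifelse(fc < 1 / fc_threshold & p < alpha, "down", "ns"))
  out <- data.frame(feature_id = m$features$feature_id, class = m$features$class,
                    mean_test = mean_t, mean_ref = mean_r,
                    fold_change = fc, log2fc = log2(fc), p_value = p,
                    direction = direction, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  out <- out[order(out$feature_id), ]
  rownames(out) <- NULL
  out
}

#' Count up- and down-regulated features per RNA class
#'
#' @param records a DE table from \code{\link{differential_expression}}.
#' @return A data.frame with columns class, n_up, n_down (one row per class
#'   present in \code{records}; empty input gives zero rows).
#' @export
classify_counts <- function(records) {
  if (!nrow(records))
    return(data.frame(class = character(0), n_up = integer(0), n_down = integer(0),
                      stringsAsFactors = FALSE))
  classes <- sort(unique(records$class))
  data.frame(
    class = classes,
    n_up = vapply(classes, function(cl)
      sum(records$class == cl & records$direction == "up"), integer(1)),
    n_down = vapply(classes, function(cl)
      sum(records$class == cl & records$direction == "down"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of a z-scored matrix
#'
#' Thin wrapper over \code{stats::dist} + \code{stats::hclust} with the
#' defaults this pipeline uses for expression heatmaps (Euclidean distance,
#' complete linkage on row z-scores).
#'
#' @param z numeric matrix (rows are clustered).
#' @param method linkage method passed to \code{hclust}.
#' @param metric distance metric passed to \code{dist}.
#' @return A list with \code{tree} (the \code{hclust} object) and
#'   \code{leaf_order} (row ids in dendrogram order).
#' @export
hierarchical_cluster <- function(z, method = "complete", metric = "euclidean") {
  if (!is.matrix(z) || !is.numeric(z)) stop("input must be a numeric matrix")
  if (nrow(z) < 2) stop("need at least two rows to cluster")
  if (any(!is.finite(z))) stop("non-finite values in clustering input")
  tree <- stats::hclust(stats::dist(z, method = metric), method = method)
  list(tree = tree, leaf_order = rownames(z)[tree$order])
}

#' Volcano-plot coordinates for a DE table
#'
#' @param records a DE table from \code{\link{differential_expression}}.
#' @return A data.frame with feature_id, log2fc, neg_log10_p, direction.
#' @export
volcano_data <- function(records) {
  data.frame(feature_id = records$feature_id, log2fc = records$log2fc,
             neg_log10_p = -log10(records$p_value),
             direction = records$direction, stringsAsFactors = FALSE)
}
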