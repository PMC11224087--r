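#' Relative quantification from Ct tables by the 2^-ddCt method
#'
#' Technical replicates are averaged per (sample, gene) first. For each
#' gene and sample, dCt = Ct_gene - Ct_reference in the same sample, where
#' the reference is GAPDH for lncRNA/circRNA/mRNA and U6 for miRNA (the
#' map is configurable). ddCt subtracts the control group's mean dCt, so
#' the relative expression 2^-ddCt has geometric mean exactly 1 over the
#' control group. Amplification efficiency is fixed at 2 (no efficiency
#' correction). The per-gene group comparison is a two-sided t-test on
#' dCt values (the scale on which normality is most plausible).
#'
#' Samples lacking a reference measurement are excluded with a warning;
#' genes with fewer than two samples in either group get no p-value and
#' are flagged.
#'
#' @param table Ct data.frame with columns sample_id, group, gene_id,
#'   gene_class, ct and optionally replicate (as written by
#'   \code{\link{simulate_ct_table}} or \code{\link{read_ct_table}}).
#' @param control_group calibrator group (default "sham").
#' @param reference_map named character vector mapping gene_class to its
#'   reference gene id.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return A list with \code{per_sample} (gene_id, sample_id, group, dct,
#'   ddct, rq = 2^-ddct) and \code{per_gene} (gene_id, gene_class, group
#'   mean RQs, fold_change = mean RQ treated / mean RQ control, p_value,
#'   flagged).
#' @export
ddct <- function(table, control_group = "sham",
                 reference_map = c(lncRNA = "GAPDH", circRNA = "GAPDH",
                                   mRNA = "GAPDH", miRNA = "U6"),
                 var_equal = FALSE) {
  need <- c("sample_id", "group", "gene_id", "gene_class", "ct")
  if (!all(need %in% names(table)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  groups <- unique(table$group)
  if (!control_group %in% groups) stop("control group '", control_group, "' absent")
  if (length(groups) != 2) stop("Ct table must contain exactly two groups")
  treated_group <- setdiff(groups, control_group)

  # average technical replicates
  agg <- stats::aggregate(ct ~ sample_id + group + gene_id + gene_class,
                          data = table, FUN = mean)
  ref_ids <- unique(unname(reference_map))
  ref_ct <- agg[agg$gene_id %in% ref_ids, c("sample_id", "gene_id", "ct")]
  genes <- agg[!agg$gene_id %in% ref_ids, , drop = FALSE]
  if (!nrow(genes)) stop("no target genes in Ct table")
  unknown <- setdiff(unique(genes$gene_class), names(reference_map))
  if (length(unknown))
    stop("no reference gene mapped for class(es): ", paste(unknown, collapse = ", "))

  genes$ref_id <- unname(reference_map[genes$gene_class])
  key <- paste(genes$sample_id, genes$ref_id)
  ref_key <- paste(ref_ct$sample_id, ref_ct$gene_id)
  genes$ref_ct <- ref_ct$ct[match(key, ref_key)]
  miss <- is.na(genes$ref_ct)
  if (any(miss)) {
    warning(sum(miss), " (sample, gene) measurement(s) without a reference excluded")
    genes <- genes[!miss, , drop = FALSE]
  }
  genes$dct <- genes$ct - genes$ref_ct

  per_sample <- list()
  per_gene <- list()
  for (gid in sort(unique(genes$gene_id))) {
    gg <- genes[genes$gene_id == gid, , drop = FALSE]
    ctrl_dct <- gg$dct[gg$group == control_group]
    trt_dct <- gg$dct[gg$group == treated_group]
    if (!length(ctrl_dct)) stop("gene ", gid, " has no control-group samples")
    calibrator <- mean(ctrl_dct)
    gg$ddct <- gg$dct - calibrator
    gg$rq <- 2^(-gg$ddct)
    per_sample[[gid]] <- gg[, c("gene_id", "gene_class", "sample_id", "group",
                                "dct", "ddct", "rq")]
    flagged <- length(ctrl_dct) < 2 || length(trt_dct) < 2
    p <- if (flagged) NA_real_
    else if (stats::var(trt_dct) == 0 && stats::var(ctrl_dct) == 0) {
      # degenerate contrast (e.g. noiseless fixtures): same convention as DE
      if (mean(trt_dct) == mean(ctrl_dct)) 1 else .Machine$double.xmin
    } else stats::t.test(trt_dct, ctrl_dct, var.equal = var_equal)$p.value
    rq_trt <- mean(2^(-(trt_dct - calibrator)))
    rq_ctrl <- mean(2^(-(ctrl_dct - calibrator)))
    per_gene[[gid]] <- data.frame(
      gene_id = gid, gene_class = gg$gene_class[1],
      mean_rq_treated = rq_trt, mean_rq_control = rq_ctrl,
      fold_change = rq_trt / rq_ctrl, p_value = p, flagged = flagged,
      stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, per_sample)
  rownames(per_sample) <- NULL
  per_gene <- do.call(rbind, per_gene)
  rownames(per_gene) <- NULL
  list(per_sample = per_sample, per_gene = per_gene)
}

#' Read a Ct table from CSV or TSV
#'
#' @param path file with columns sample_id, group, gene_id, gene_class, ct
#'   (and optionally replicate); delimiter inferred from the extension
#'   (.csv = comma, otherwise tab).
#' @return A data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene_id", "gene_class", "ct")
  if (!all(need %in% names(out)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(out$ct)) stop("ct column must be numeric")
  out
}
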