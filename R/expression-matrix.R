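#' Expression matrix container
#'
#' A light S3 container for a features x samples intensity matrix together
#' with its feature annotation (RNA class) and sample annotation (group).
#' Values are strictly positive on the linear scale; \code{scale} records
#' whether values are raw intensities (\code{"linear"}) or log2.
#'
#' @param values numeric matrix, features x samples, finite.
#' @param feature_class character vector, one of \code{"lncRNA"},
#'   \code{"circRNA"}, \code{"miRNA"}, \code{"mRNA"} per feature.
#' @param sample_group character vector, one group label per sample
#'   (typically \code{"TULP"} and \code{"sham"}).
#' @param scale \code{"linear"} or \code{"log2"}.
#'
#' @return An object of class \code{"expr_matrix"}: a list with elements
#'   \code{values} (the matrix, dimnames = feature/sample ids),
#'   \code{features} (data.frame: feature_id, class),
#'   \code{samples} (data.frame: sample_id, group) and \code{scale}.
#' @export
expression_matrix <- function(values, feature_class, sample_group,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(fid))
    stop("duplicate feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (length(feature_class) != nrow(values))
    stop("feature_class length does not match number of rows")
  if (length(sample_group) != ncol(values))
    stop("sample_group length does not match number of columns")
  bad_class <- setdiff(unique(feature_class), c("lncRNA", "circRNA", "miRNA", "mRNA"))
  if (length(bad_class))
    stop("unknown RNA class: ", paste(bad_class, collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values in expression matrix")
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale intensities must be strictly positive")
  structure(
    list(values = values,
         features = data.frame(feature_id = fid, class = as.character(feature_class),
                               stringsAsFactors = FALSE),
         samples = data.frame(sample_id = sid, group = as.character(sample_group),
                              stringsAsFactors = FALSE),
         scale = scale),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cls <- table(x$features$class)
  grp <- table(x$samples$group)
  cat(sprintf("expr_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature id and/or sample id
#'
#' @param m an \code{expr_matrix}.
#' @param features,samples character vectors of ids (NULL keeps all).
#' @return An \code{expr_matrix} restricted to the requested ids, in the
#'   requested order.
#' @export
subset_expression <- function(m, features = NULL, samples = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  fid <- if (is.null(features)) m$features$feature_id else features
  sid <- if (is.null(samples)) m$samples$sample_id else samples
  missing_f <- setdiff(fid, m$features$feature_id)
  if (length(missing_f)) stop("unknown feature ids: ", paste(missing_f, collapse = ", "))
  missing_s <- setdiff(sid, m$samples$sample_id)
  if (length(missing_s)) stop("unknown sample ids: ", paste(missing_s, collapse = ", "))
  v <- m$values[fid, sid, drop = FALSE]
  expression_matrix(v,
                    m$features$class[match(fid, m$features$feature_id)],
                    m$samples$group[match(sid, m$samples$sample_id)],
                    scale = m$scale)
}
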