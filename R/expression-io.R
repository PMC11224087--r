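#' Write an expression matrix with its sample and feature sheets
#'
#' The matrix TSV has sample ids in the header row and feature ids in the
#' first column; values are written with 15 significant digits so a
#' write/read round trip is lossless up to float formatting. Sidecar sheets
#' carry sample group and feature class assignments.
#'
#' @param m an \code{expr_matrix}.
#' @param matrix_path,sample_sheet_path,feature_sheet_path output TSV paths.
#' @return Invisibly, the matrix path.
#' @export
write_expression <- function(m, matrix_path, sample_sheet_path, feature_sheet_path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(feature_id = rownames(m$values),
                   signif(m$values, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$features, feature_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read an expression matrix written by \code{write_expression}
#'
#' Strict reader: duplicate feature or sample ids, samples missing from the
#' sample sheet, and non-numeric cells are hard errors (no partial load).
#'
#' @param matrix_path,sample_sheet_path,feature_sheet_path TSV paths as
#'   written by \code{\link{write_expression}}.
#' @param scale scale flag to stamp on the result (files store raw numbers).
#' @return An \code{expr_matrix}.
#' @export
read_expression <- function(matrix_path, sample_sheet_path, feature_sheet_path,
                            scale = "linear") {
  for (p in c(matrix_path, sample_sheet_path, feature_sheet_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (names(raw)[1] != "feature_id") stop("matrix file must start with a 'feature_id' column")
  fid <- raw$feature_id
  if (anyDuplicated(fid))
    stop("duplicate feature ids in matrix: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  sid <- names(raw)[-1]
  if (anyDuplicated(sid))
    stop("duplicate sample ids in matrix: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (any(is.na(num))) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 vals[idx[1], idx[2]], fid[idx[1]], sid[idx[2]]))
  }
  dimnames(num) <- list(fid, sid)
  samples <- utils::read.table(sample_sheet_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  features <- utils::read.table(feature_sheet_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  missing_s <- setdiff(sid, samples$sample_id)
  if (length(missing_s))
    stop("samples missing from sample sheet: ", paste(missing_s, collapse = ", "))
  missing_f <- setdiff(fid, features$feature_id)
  if (length(missing_f))
    stop("features missing from feature sheet: ", paste(missing_f, collapse = ", "))
  expression_matrix(num,
                    features$class[match(fid, features$feature_id)],
                    samples$group[match(sid, samples$sample_id)],
                    scale = scale)
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every sample (column) onto the common rank-mean distribution:
#' after normalization each column's sorted values equal the cross-column
#' mean of per-rank values. Ties within a column receive the mean of the
#' reference values at their tied ranks. The transform is idempotent.
#'
#' @param m an \code{expr_matrix} on the linear scale.
#' @return A quantile-normalized \code{expr_matrix} (same ids, same scale).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear") stop("quantile normalization expects linear-scale intensities")
  if (ncol(m$values) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(m)
  }
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  expression_matrix(v, m$features$class, m$samples$group, scale = "linear")
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param m an \code{expr_matrix} with \code{scale == "linear"}.
#' @return The same matrix with \code{log2} values and \code{scale == "log2"}.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear") stop("matrix is already on the log2 scale")
  if (any(m$values <= 0)) stop("log2 transform requires strictly positive values")
  expression_matrix(log2(m$values), m$features$class, m$samples$group, scale = "log2")
}

#' Row z-scores of a matrix
#'
#' Centers and scales each row using the population standard deviation
#' (denominator n). Constant rows map to all-zero rows by convention.
#'
#' @param m an \code{expr_matrix} or a plain numeric matrix.
#' @return A numeric matrix of z-scores with the input's dimnames.
#' @export
zscore_rows <- function(m) {
  v <- if (inherits(m, "expr_matrix")) m$values else m
  if (!is.matrix(v) || !is.numeric(v)) stop("input must be a numeric matrix")
  mu <- rowMeans(v)
  centered <- v - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  z <- centered / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  z
}
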