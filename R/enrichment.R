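#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated as
#' \code{name<TAB>description<TAB>member1<TAB>member2...}.
#'
#' @param path GMT file.
#' @return A named list of gene sets; each element is a list with
#'   \code{description} and \code{genes} (unique character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member", i))
    if (f[1] %in% names(out)) stop("duplicate gene-set name: ", f[1])
    out[[f[1]]] <- list(description = f[2], genes = unique(f[-(1:2)]))
  }
  out
}

#' Over-representation analysis against a gene-set collection
#'
#' Upper-tail hypergeometric enrichment of a query gene list in each set,
#' sharing the scoring kernel used for ceRNA pairs, with
#' Benjamini--Hochberg correction across the tested sets. Gene sets are
#' restricted to the universe first; sets that become empty, or overlap the
#' query by fewer than \code{min_overlap} genes, are not tested. Query
#' genes outside the universe are dropped with a warning.
#'
#' @param query character vector of gene ids (e.g. DE mRNAs of a network).
#' @param collection gene sets from \code{\link{read_gmt}} (or a named list
#'   of character vectors).
#' @param universe character vector of all measured gene ids.
#' @param min_overlap minimum query/set overlap for a set to be tested.
#' @return A data.frame ranked by p then set name: set_name, description,
#'   x (overlap), K (set size in universe), n (query size), N (universe
#'   size), hyper_p, bh_q. Empty query gives zero rows with a warning.
#' @export
ora <- function(query, collection, universe, min_overlap = 1) {
  sets <- lapply(collection, function(s) if (is.list(s)) s$genes else s)
  descr <- vapply(collection, function(s)
    if (is.list(s) && !is.null(s$description)) s$description else "", character(1))
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  empty <- data.frame(set_name = character(0), description = character(0),
                      x = integer(0), K = integer(0), n = integer(0), N = integer(0),
                      hyper_p = numeric(0), bh_q = numeric(0), stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("empty query after universe restriction")
    return(empty)
  }
  N <- length(universe)
  n <- length(query)
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(unique(sets[[nm]]), universe)
    if (!length(members)) next
    x <- length(intersect(query, members))
    if (x < min_overlap) next
    K <- length(members)
    rows[[length(rows) + 1L]] <- data.frame(
      set_name = nm, description = descr[[nm]], x = x, K = K, n = n, N = N,
      hyper_p = hyper_upper_tail(x, K, n, N), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$hyper_p, method = "BH")
  out <- out[order(out$hyper_p, out$set_name), ]
  rownames(out) <- NULL
  out
}
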