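#' Scan target sequences for canonical miRNA seed-match sites
#'
#' Implements the TargetScan-style canonical site classes. The seed is
#' miRNA positions 2--8 counted from the 5' end; a site is a Watson--Crick
#' match (no G:U wobble) of the target sense strand to the reverse
#' complement of the seed region. Reading the target 5' to 3', a site is
#' laid out as \code{[m8 match][6mer core][A1 position]}:
#' \itemize{
#'   \item 8mer: positions 2--8 matched and an A opposite miRNA position 1;
#'   \item 7mer-m8: positions 2--8 matched, no A1;
#'   \item 7mer-A1: positions 2--7 matched plus the A1 anchor;
#'   \item 6mer: positions 2--7 matched only.
#' }
#' The per-site score is the site-class weight (8mer = 4, 7mer-m8 = 3,
#' 7mer-A1 = 2, 6mer = 1). \code{site_start} is the 1-based coordinate of
#' the first matched base of the reported site on the target sense strand.
#'
#' @param mirna_seqs named character vector of miRNA sequences (A/C/G/U;
#'   T accepted and treated as U), length >= 8 each.
#' @param target_seqs named character vector of target sequences with a
#'   \code{target_class} attribute or classes supplied via
#'   \code{target_class}.
#' @param min_site_type weakest site class to report, one of
#'   "8mer", "7mer-m8", "7mer-A1", "6mer".
#' @param target_class optional named character vector mapping target id to
#'   RNA class; defaults to class inferred from the id prefix
#'   (lnc/circ/mRNA) and "mRNA" otherwise.
#' @return A data.frame of hits ordered by (mirna_id, target_id,
#'   site_start): mirna_id, target_id, target_class, site_start, site_type,
#'   score, source = "scanner". One row per (miRNA, target, site).
#' @export
scan_targets <- function(mirna_seqs, target_seqs, min_site_type = "7mer-m8",
                         target_class = NULL) {
  site_levels <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  if (!min_site_type %in% names(site_levels))
    stop("min_site_type must be one of: ", paste(names(site_levels), collapse = ", "))
  if (is.null(names(mirna_seqs)) || is.null(names(target_seqs)))
    stop("sequences must be named by id")
  check_seq <- function(seqs, what) {
    for (id in names(seqs)) {
      s <- seqs[[id]]
      if (!nzchar(s)) stop("empty ", what, " sequence: ", id)
      if (grepl("[^ACGUTacgut]", s))
        stop("ambiguity code or invalid character in ", what, " sequence: ", id)
    }
  }
  check_seq(mirna_seqs, "miRNA")
  check_seq(target_seqs, "target")
  if (any(nchar(mirna_seqs) < 8)) stop("miRNA sequences must be >= 8 nt")
  norm <- function(s) chartr("Tt", "Uu", toupper(s))
  mirna_seqs <- vapply(mirna_seqs, norm, character(1))
  targets_u <- vapply(target_seqs, norm, character(1))
  if (is.null(target_class)) {
    target_class <- ifelse(startsWith(names(target_seqs), "lnc"), "lncRNA",
                    ifelse(startsWith(names(target_seqs), "circ"), "circRNA", "mRNA"))
    names(target_class) <- names(target_seqs)
  }
  min_rank <- site_levels[[min_site_type]]

  hits <- list()
  for (mid in names(mirna_seqs)) {
    mir <- mirna_seqs[[mid]]
    core <- revcomp_rna(substr(mir, 2, 7), u = "U")   # match to positions 2-7
    m8 <- revcomp_rna(substr(mir, 8, 8), u = "U")     # base pairing position 8
    for (tid in names(targets_u)) {
      tgt <- targets_u[[tid]]
      L <- nchar(tgt)
      starts <- unlist(gregexpr(core, tgt, fixed = TRUE))
      starts <- starts[starts > 0]
      for (s in starts) {
        has_m8 <- s > 1 && substr(tgt, s - 1, s - 1) == m8
        a1_pos <- s + 6
        has_a1 <- a1_pos <= L && substr(tgt, a1_pos, a1_pos) == "A"
        type <- if (has_m8 && has_a1) "8mer"
                else if (has_m8) "7mer-m8"
                else if (has_a1) "7mer-A1"
                else "6mer"
        if (site_levels[[type]] < min_rank) next
        site_start <- if (has_m8) s - 1L else s
        hits[[length(hits) + 1L]] <- data.frame(
          mirna_id = mid, target_id = tid,
          target_class = unname(target_class[[tid]]),
          site_start = as.integer(site_start), site_type = type,
          score = unname(site_levels[[type]]), source = "scanner",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(mirna_id = character(0), target_id = character(0),
               target_class = character(0), site_start = integer(0),
               site_type = character(0), score = numeric(0),
               source = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$target_id, out$site_start), ]
  rownames(out) <- NULL
  out
}

#' Import an external miRNA-target prediction table
#'
#' Reads a miRanda-style TSV (columns mirna_id, target_id, score, optional
#' energy and site_start). No score filter is applied by default. When
#' \code{known_ids} is given, hits whose ids do not resolve are dropped
#' with a warning reporting the excluded count.
#'
#' @param path TSV file with a header line.
#' @param known_ids optional character vector of valid feature ids.
#' @param target_class optional named map target_id -> RNA class (defaults
#'   to prefix inference as in \code{\link{scan_targets}}).
#' @return A data.frame in the \code{\link{scan_targets}} layout with
#'   \code{source = "imported"}.
#' @export
import_target_table <- function(path, known_ids = NULL, target_class = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || all(!nzchar(lines))) {
    warning("empty target table: ", path)
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), site_start = integer(0),
                      site_type = character(0), score = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("mirna_id", "target_id", "score")
  if (!all(need %in% header))
    stop("target table must have columns: ", paste(need, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop(sprintf("malformed line %d in %s: expected %d fields, got %d",
                   i + 1L, path, length(header), length(f)))
    rec <- as.list(f)
    names(rec) <- header
    score <- suppressWarnings(as.numeric(rec$score))
    if (is.na(score))
      stop(sprintf("malformed line %d in %s: non-numeric score '%s'",
                   i + 1L, path, rec$score))
    site_start <- if ("site_start" %in% header)
      suppressWarnings(as.integer(rec$site_start)) else NA_integer_
    recs[[i]] <- data.frame(mirna_id = rec$mirna_id, target_id = rec$target_id,
                            site_start = site_start, score = score,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (!is.null(known_ids)) {
    ok <- out$mirna_id %in% known_ids & out$target_id %in% known_ids
    if (any(!ok))
      warning(sum(!ok), " imported hit(s) with unknown ids excluded")
    out <- out[ok, , drop = FALSE]
  }
  if (is.null(target_class)) {
    target_class <- ifelse(startsWith(out$target_id, "lnc"), "lncRNA",
                    ifelse(startsWith(out$target_id, "circ"), "circRNA", "mRNA"))
  } else {
    target_class <- unname(target_class[out$target_id])
  }
  out <- data.frame(mirna_id = out$mirna_id, target_id = out$target_id,
                    target_class = target_class, site_start = out$site_start,
                    site_type = NA_character_, score = out$score,
                    source = "imported", stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$target_id, out$site_start), ]
  rownames(out) <- NULL
  out
}

#' Collapse target hits to membership maps
#'
#' Multiple sites of a miRNA on the same target collapse to a single
#' membership. The two maps are mutually consistent by construction.
#'
#' @param hits a hits data.frame from \code{\link{scan_targets}} or
#'   \code{\link{import_target_table}}.
#' @return A list with \code{by_mirna} (named list: miRNA id -> sorted
#'   character vector of target ids) and \code{by_target} (target id ->
#'   sorted vector of miRNA ids).
#' @export
target_sets <- function(hits) {
  if (!nrow(hits)) return(list(by_mirna = list(), by_target = list()))
  uniq <- unique(hits[, c("mirna_id", "target_id")])
  by_mirna <- lapply(split(uniq$target_id, uniq$mirna_id), function(x) sort(unique(x)))
  by_target <- lapply(split(uniq$mirna_id, uniq$target_id), function(x) sort(unique(x)))
  list(by_mirna = by_mirna, by_target = by_target)
}

#' Write a hits table as TSV
#' @param hits a hits data.frame.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
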