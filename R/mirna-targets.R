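SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
# strongest-evidence precedence when merging duplicate edges
EVIDENCE_RANK <- c(imported = 0L, "8mer" = 4L, "7mer-m8" = 3L,
                   "7mer-A1" = 2L, "6mer" = 1L)

#' Canonical miRNA seed matching against target sequences
#'
#' Scans target sense-strand sequences for exact seed sites of each
#' miRNA. Writing the target 5'-3', a site is the reverse complement of
#' the miRNA seed region: \code{7mer-m8} uses miRNA positions 2-8,
#' \code{6mer} positions 2-7, \code{7mer-A1} positions 2-7 followed by an
#' \code{A} opposite miRNA position 1, and \code{8mer} positions 2-8
#' followed by that \code{A}. miRNA sequences may be RNA or DNA (U and T
#' are equivalent); all non-overlapping occurrences are reported with
#' 0-based offsets.
#'
#' @param mirna_seqs named character vector (or
#'   \code{Biostrings::XStringSet}) of miRNA sequences, 5'-3'.
#' @param target_seqs named character vector (or \code{XStringSet}) of
#'   target DNA sequences.
#' @param site_types subset of \code{c("8mer", "7mer-m8", "7mer-A1",
#'   "6mer")}; default \code{"7mer-m8"}.
#' @param target_class class annotation stored on every emitted edge
#'   (single string or named vector per target id).
#' @return data.frame of target edges: \code{mirna_id}, \code{target_id},
#'   \code{target_class}, \code{evidence} (strongest site type found),
#'   \code{n_sites}, \code{positions} (comma-separated 0-based offsets of
#'   the strongest type).
#' @export
seed_match <- function(mirna_seqs, target_seqs, site_types = "7mer-m8",
                       target_class = NA_character_) {
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  mirna_seqs <- as_named_sequences(mirna_seqs, "miRNA")
  target_seqs <- as_named_sequences(target_seqs, "target")
  mirna_seqs <- toupper(chartr("Uu", "Tt", mirna_seqs))
  target_seqs <- toupper(chartr("Uu", "Tt", target_seqs))
  check_iupac(mirna_seqs)
  check_iupac(target_seqs)
  classes <- if (length(target_class) == 1L)
    stats::setNames(rep(target_class, length(target_seqs)),
                    names(target_seqs))
  else target_class

  rows <- list()
  for (m in names(mirna_seqs)) {
    seq <- mirna_seqs[[m]]
    if (nchar(seq) < 8L) stop("miRNA ", m, " is shorter than 8 nt")
    pats <- site_patterns(seq)
    for (t in names(target_seqs)) {
      best <- NULL
      for (st in site_types[order(-EVIDENCE_RANK[site_types])]) {
        pos <- find_all(pats[[st]], target_seqs[[t]])
        if (length(pos)) { best <- list(type = st, pos = pos); break }
      }
      if (is.null(best)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, target_id = t,
        target_class = unname(classes[t]),
        evidence = best$type, n_sites = length(best$pos),
        positions = paste(best$pos, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), evidence = character(),
                      n_sites = integer(), positions = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$mirna_id, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# seed site sequences (target 5'-3') per site type for one miRNA (DNA)
site_patterns <- function(mirna_dna) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  s2_8 <- rc(substr(mirna_dna, 2L, 8L))
  s2_7 <- rc(substr(mirna_dna, 2L, 7L))
  list("7mer-m8" = s2_8, "6mer" = s2_7,
       "8mer" = paste0(s2_8, "A"), "7mer-A1" = paste0(s2_7, "A"))
}

# non-overlapping 0-based match offsets of a fixed pattern
find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1L] == -1L) integer() else as.integer(hits) - 1L
}

as_named_sequences <- function(x, what) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  x <- vapply(x, as.character, character(1))
  if (is.null(names(x)) || any(names(x) == ""))
    stop(what, " sequences must be named")
  x
}

check_iupac <- function(seqs) {
  for (id in names(seqs)) {
    bad <- regexpr("[^ACGTRYSWKMBDHVN]", seqs[[id]])
    if (bad > 0)
      stop("non-IUPAC character in sequence ", id, " at position ", bad)
  }
  invisible(TRUE)
}

#' Load a miRNA-target edge table
#'
#' Reads a tab-separated table of known or externally predicted
#' miRNA-target relationships (the supplementary-table route) and
#' deduplicates edges on (miRNA, target).
#'
#' @param path TSV file with header columns \code{mirna_id},
#'   \code{target_id}, \code{target_class} (one of mRNA, lncRNA,
#'   circRNA).
#' @return data.frame of edges with \code{evidence = "imported"},
#'   \code{n_sites = NA}, \code{positions = ""}.
#' @export
load_target_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(df)))
    stop("target table needs columns: ", paste(need, collapse = ", "))
  ok <- df$target_class %in% c("mRNA", "lncRNA", "circRNA")
  if (!all(ok))
    stop("unknown target class \"", df$target_class[which(!ok)[1L]],
         "\" at line ", which(!ok)[1L] + 1L)
  df <- df[!duplicated(df[, c("mirna_id", "target_id")]), , drop = FALSE]
  data.frame(mirna_id = df$mirna_id, target_id = df$target_id,
             target_class = df$target_class,
             evidence = rep("imported", nrow(df)),
             n_sites = rep(NA_integer_, nrow(df)),
             positions = rep("", nrow(df)),
             stringsAsFactors = FALSE)
}

#' Merge imported and predicted target edges
#'
#' Unions edge tables and deduplicates on (miRNA, target), keeping the
#' strongest evidence annotation (8mer > 7mer-m8 > 7mer-A1 > 6mer >
#' imported).
#'
#' @param ... edge data.frames as returned by \code{\link{seed_match}} or
#'   \code{\link{load_target_table}}.
#' @return Deduplicated edge data.frame.
#' @export
merge_target_edges <- function(...) {
  all <- do.call(rbind, list(...))
  if (is.null(all) || nrow(all) == 0L) return(all)
  all <- all[order(-EVIDENCE_RANK[all$evidence]), , drop = FALSE]
  all <- all[!duplicated(all[, c("mirna_id", "target_id")]), , drop = FALSE]
  all <- all[order(all$mirna_id, all$target_id), , drop = FALSE]
  rownames(all) <- NULL
  all
}
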