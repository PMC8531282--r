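#' Assign candidate cis-target genes to lncRNAs by genomic proximity
#'
#' Pairs every lncRNA with every gene on the same chromosome whose gap is
#' within the window. The gap between two 1-based inclusive intervals A
#' and B is \code{max(0, max(startA, startB) - min(endA, endB) - 1)}:
#' overlapping or book-ended intervals have gap 0. Strand plays no role in
#' eligibility; it only annotates the lncRNA's position relative to the
#' gene on the gene's strand (\code{upstream}, \code{downstream},
#' \code{overlapping}).
#'
#' @param lncrnas data.frame with columns \code{id} (or
#'   \code{transcript_id}), \code{chrom}, \code{start}, \code{end}.
#' @param genes data.frame with columns \code{id} (or \code{gene_id}),
#'   \code{chrom}, \code{start}, \code{end} and optionally \code{strand}.
#' @param window_bp maximum gap in bp (inclusive; default 10000, the
#'   10 kb neighborhood).
#' @return data.frame sorted by (lncRNA id, gap) with columns
#'   \code{lncrna_id}, \code{gene_id}, \code{gap_bp}, \code{relpos}; one
#'   row per (lncRNA, gene) pair.
#' @export
assign_cis_targets <- function(lncrnas, genes, window_bp = 10000L) {
  lnc <- normalize_loci(lncrnas, c("id", "transcript_id", "lncrna_id"))
  gen <- normalize_loci(genes, c("id", "gene_id"))
  if (!"strand" %in% names(gen)) gen$strand <- "+"
  shared <- intersect(unique(lnc$chrom), unique(gen$chrom))
  orphan <- sum(!lnc$chrom %in% shared)
  if (orphan > 0)
    warning(orphan, " lncRNA(s) on chromosomes without any gene")
  out <- vector("list", length(shared))
  for (ci in seq_along(shared)) {
    l <- lnc[lnc$chrom == shared[ci], , drop = FALSE]
    g <- gen[gen$chrom == shared[ci], , drop = FALSE]
    if (nrow(l) == 0L || nrow(g) == 0L) next
    li <- rep(seq_len(nrow(l)), times = nrow(g))
    gi <- rep(seq_len(nrow(g)), each = nrow(l))
    gap <- pmax(0L, pmax(l$start[li], g$start[gi]) -
                  pmin(l$end[li], g$end[gi]) - 1L)
    keep <- gap <= window_bp & l$id[li] != g$id[gi]
    if (!any(keep)) next
    li <- li[keep]; gi <- gi[keep]; gap <- gap[keep]
    before <- l$end[li] < g$start[gi]   # lncRNA entirely 5' in + orientation
    after <- l$start[li] > g$end[gi]
    plus <- g$strand[gi] != "-"
    relpos <- rep("overlapping", length(gap))
    relpos[before & plus] <- "upstream"
    relpos[before & !plus] <- "downstream"
    relpos[after & plus] <- "downstream"
    relpos[after & !plus] <- "upstream"
    out[[ci]] <- data.frame(lncrna_id = l$id[li], gene_id = g$id[gi],
                            gap_bp = gap, relpos = relpos,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(lncrna_id = character(), gene_id = character(),
                      gap_bp = integer(), relpos = character(),
                      stringsAsFactors = FALSE)
  res <- unique(res)
  res <- res[order(res$lncrna_id, res$gap_bp, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

normalize_loci <- function(df, id_candidates) {
  stopifnot(is.data.frame(df))
  idcol <- intersect(id_candidates, names(df))[1L]
  if (is.na(idcol)) stop("no id column found among: ",
                         paste(id_candidates, collapse = ", "))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("locus table needs columns chrom, start, end")
  out <- data.frame(id = as.character(df[[idcol]]),
                    chrom = as.character(df$chrom),
                    start = as.integer(df$start), end = as.integer(df$end),
                    stringsAsFactors = FALSE)
  if ("strand" %in% names(df)) out$strand <- as.character(df$strand)
  if (any(out$start > out$end)) stop("start > end in locus table")
  out
}

#' Cis-regulatory network between DE-lncRNAs and DE genes
#'
#' Restricts cis pairs to those where both the lncRNA and the gene are
#' differentially expressed, annotating each endpoint with its regulation
#' direction (the up/down coloring of the published interaction figures,
#' as a categorical attribute).
#'
#' @param cis_pairs data.frame from \code{\link{assign_cis_targets}}.
#' @param de_lnc,de_mrna partitions from \code{\link{filter_de}} (lists
#'   with \code{up}/\code{down} id vectors).
#' @return data.frame of edges: \code{lncrna_id}, \code{gene_id},
#'   \code{gap_bp}, \code{relpos}, \code{lncrna_direction},
#'   \code{gene_direction}.
#' @export
de_cis_network <- function(cis_pairs, de_lnc, de_mrna) {
  dir_l <- direction_lookup(de_lnc)
  dir_g <- direction_lookup(de_mrna)
  keep <- cis_pairs$lncrna_id %in% names(dir_l) &
    cis_pairs$gene_id %in% names(dir_g)
  res <- cis_pairs[keep, , drop = FALSE]
  res$lncrna_direction <- unname(dir_l[res$lncrna_id])
  res$gene_direction <- unname(dir_g[res$gene_id])
  rownames(res) <- NULL
  res
}

direction_lookup <- function(de_part) {
  stopifnot(is.list(de_part), all(c("up", "down") %in% names(de_part)))
  stats::setNames(rep(c("up", "down"), c(length(de_part$up),
                                         length(de_part$down))),
                  c(de_part$up, de_part$down))
}
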