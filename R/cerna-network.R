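#' Negatively coexpressed miRNA-target pairs
#'
#' For every target edge whose endpoints are present in the supplied
#' expression matrices, computes the Spearman rank correlation (average
#' ranks for ties) between the miRNA and the target on
#' \code{log2(expr + 1)} across the shared samples, and keeps pairs with
#' SCC strictly below the threshold. Callers restrict the matrices to
#' differentially expressed features first; correlation is computed with
#' both groups pooled.
#'
#' @param expr_mirna expression matrix (miRNAs x samples).
#' @param expr_target expression matrix (targets x samples; same sample
#'   columns).
#' @param target_edges data.frame with \code{mirna_id}, \code{target_id}.
#' @param scc_threshold strict upper bound on SCC (default -0.7).
#' @return data.frame of retained pairs: \code{mirna_id},
#'   \code{target_id}, \code{scc}, \code{n} (samples used).
#' @export
negative_pairs <- function(expr_mirna, expr_target, target_edges,
                           scc_threshold = -0.7) {
  cors <- edge_correlations(expr_mirna, expr_target,
                            target_edges$mirna_id, target_edges$target_id,
                            method = "spearman")
  keep <- !is.na(cors$coefficient) & cors$coefficient < scc_threshold
  data.frame(mirna_id = cors$id_a[keep], target_id = cors$id_b[keep],
             scc = cors$coefficient[keep], n = cors$n[keep],
             stringsAsFactors = FALSE)
}

#' Positively coexpressed regulator-mRNA pairs
#'
#' Pearson correlation on \code{log2(expr + 1)} for candidate
#' (regulator, mRNA) pairs; pairs with PCC strictly above the threshold
#' are kept.
#'
#' @param expr_regulator expression matrix (lncRNAs/circRNAs x samples).
#' @param expr_mrna expression matrix (mRNAs x samples).
#' @param pairs data.frame with \code{regulator_id}, \code{mrna_id}; if
#'   \code{NULL}, all pairs are evaluated.
#' @param pcc_threshold strict lower bound on PCC (default 0.9).
#' @return data.frame of retained pairs: \code{regulator_id},
#'   \code{mrna_id}, \code{pcc}, \code{n}.
#' @export
coexpressed_pairs <- function(expr_regulator, expr_mrna, pairs = NULL,
                              pcc_threshold = 0.9) {
  if (is.null(pairs)) {
    pairs <- expand.grid(regulator_id = rownames(expr_regulator),
                         mrna_id = rownames(expr_mrna),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  cors <- edge_correlations(expr_regulator, expr_mrna,
                            pairs$regulator_id, pairs$mrna_id,
                            method = "pearson")
  keep <- !is.na(cors$coefficient) & cors$coefficient > pcc_threshold
  data.frame(regulator_id = cors$id_a[keep], mrna_id = cors$id_b[keep],
             pcc = cors$coefficient[keep], n = cors$n[keep],
             stringsAsFactors = FALSE)
}

# correlation per (id_a in A, id_b in B) pair on log2(x+1); skips pairs
# with missing features, warns and returns NA on constant vectors
edge_correlations <- function(expr_a, expr_b, ids_a, ids_b, method) {
  expr_a <- as.matrix(expr_a); expr_b <- as.matrix(expr_b)
  shared <- intersect(colnames(expr_a), colnames(expr_b))
  if (length(shared) < 3L)
    stop("fewer than 3 shared samples between expression matrices")
  la <- log2(expr_a[, shared, drop = FALSE] + 1)
  lb <- log2(expr_b[, shared, drop = FALSE] + 1)
  present <- ids_a %in% rownames(la) & ids_b %in% rownames(lb)
  ids_a <- as.character(ids_a[present]); ids_b <- as.character(ids_b[present])
  coef <- rep(NA_real_, length(ids_a))
  n_const <- 0L
  for (i in seq_along(ids_a)) {
    va <- la[ids_a[i], ]; vb <- lb[ids_b[i], ]
    if (max(va) == min(va) || max(vb) == min(vb)) {
      n_const <- n_const + 1L
      next
    }
    coef[i] <- stats::cor(va, vb, method = method)
  }
  if (n_const > 0L)
    warning(n_const, " pair(s) skipped: constant expression vector")
  data.frame(id_a = ids_a, id_b = ids_b, coefficient = coef,
             n = rep(length(shared), length(ids_a)),
             stringsAsFactors = FALSE)
}

#' Hypergeometric shared-sponge test
#'
#' Tests whether a regulator (lncRNA or circRNA) and an mRNA share more
#' targeting miRNAs than expected by chance. With a miRNA universe of
#' size \code{N}, \code{K} miRNAs targeting the regulator, \code{n}
#' targeting the mRNA and \code{k} targeting both, the p-value is the
#' hypergeometric upper tail \code{hypergeom_sf(k, N, K, n)}.
#'
#' @param regulator_id,mrna_id feature ids.
#' @param target_edges data.frame with \code{mirna_id}, \code{target_id}.
#' @param mirna_universe character vector of miRNA ids forming the
#'   population (typically the DE-miRNA list).
#' @return One-row data.frame: \code{regulator_id}, \code{mrna_id},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{pvalue}.
#' @export
sponge_test <- function(regulator_id, mrna_id, target_edges,
                        mirna_universe) {
  mirna_universe <- unique(as.character(mirna_universe))
  if (length(mirna_universe) == 0L) stop("empty miRNA universe")
  edges <- target_edges[target_edges$mirna_id %in% mirna_universe, ,
                        drop = FALSE]
  of_reg <- unique(edges$mirna_id[edges$target_id == regulator_id])
  of_mrna <- unique(edges$mirna_id[edges$target_id == mrna_id])
  k <- length(intersect(of_reg, of_mrna))
  data.frame(regulator_id = regulator_id, mrna_id = mrna_id,
             k = k, K = length(of_reg), n = length(of_mrna),
             N = length(mirna_universe),
             pvalue = hypergeom_sf(k, length(mirna_universe),
                                   length(of_reg), length(of_mrna)),
             stringsAsFactors = FALSE)
}

#' Assemble ceRNA triads
#'
#' A triad (regulator L, miRNA m, mRNA G) is emitted when (m, L) and
#' (m, G) are negatively coexpressed target pairs, (L, G) is a positively
#' coexpressed pair, and the shared-sponge test for (L, G) is significant
#' at \code{p_threshold} (strict). One row is produced per qualifying
#' miRNA, ordered by (regulator, mRNA, miRNA).
#'
#' @param neg_edges data.frame from \code{\link{negative_pairs}}.
#' @param coexp_edges data.frame from \code{\link{coexpressed_pairs}}.
#' @param target_edges data.frame with \code{mirna_id}, \code{target_id}.
#' @param mirna_universe miRNA population for the sponge test.
#' @param p_threshold strict sponge p cutoff (default 0.05).
#' @param directions optional named character vector (feature id ->
#'   \code{"up"}/\code{"down"}); when given, each triad carries a
#'   \code{direction_consistent} flag (regulator and mRNA same direction,
#'   miRNA opposite) as a descriptive annotation, not a filter.
#' @return data.frame with one row per triad: \code{regulator_id},
#'   \code{mirna_id}, \code{mrna_id}, \code{scc_mi_regulator},
#'   \code{scc_mi_mrna}, \code{pcc_regulator_mrna}, \code{sponge_k},
#'   \code{sponge_K}, \code{sponge_n}, \code{sponge_N}, \code{sponge_p}
#'   and (optionally) \code{direction_consistent}.
#' @export
build_triads <- function(neg_edges, coexp_edges, target_edges,
                         mirna_universe, p_threshold = 0.05,
                         directions = NULL) {
  empty <- data.frame(regulator_id = character(), mirna_id = character(),
                      mrna_id = character(), scc_mi_regulator = numeric(),
                      scc_mi_mrna = numeric(),
                      pcc_regulator_mrna = numeric(),
                      sponge_k = integer(), sponge_K = integer(),
                      sponge_n = integer(), sponge_N = integer(),
                      sponge_p = numeric(), stringsAsFactors = FALSE)
  if (nrow(coexp_edges) == 0L || nrow(neg_edges) == 0L) return(empty)
  neg_key <- paste(neg_edges$mirna_id, neg_edges$target_id, sep = "\r")
  scc_of <- stats::setNames(neg_edges$scc, neg_key)
  rows <- list()
  for (i in seq_len(nrow(coexp_edges))) {
    L <- coexp_edges$regulator_id[i]; G <- coexp_edges$mrna_id[i]
    ms <- intersect(neg_edges$mirna_id[neg_edges$target_id == L],
                    neg_edges$mirna_id[neg_edges$target_id == G])
    if (!length(ms)) next
    sp <- sponge_test(L, G, target_edges, mirna_universe)
    if (!(sp$pvalue < p_threshold)) next
    for (m in sort(ms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        regulator_id = L, mirna_id = m, mrna_id = G,
        scc_mi_regulator = unname(scc_of[paste(m, L, sep = "\r")]),
        scc_mi_mrna = unname(scc_of[paste(m, G, sep = "\r")]),
        pcc_regulator_mrna = coexp_edges$pcc[i],
        sponge_k = sp$k, sponge_K = sp$K, sponge_n = sp$n,
        sponge_N = sp$N, sponge_p = sp$pvalue,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$regulator_id, res$mrna_id, res$mirna_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(directions)) {
    dr <- directions[res$regulator_id]
    dm <- directions[res$mirna_id]
    dg <- directions[res$mrna_id]
    res$direction_consistent <- !is.na(dr) & !is.na(dm) & !is.na(dg) &
      dr == dg & dm != dr
  }
  res
}
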