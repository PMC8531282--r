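#' Grouped RNA-seq count matrix
#'
#' Light container for an integer count matrix (features x samples) with a
#' two-group sample assignment and, optionally, per-feature transcript
#' lengths for length-normalized expression (FPKM). This is the universal
#' expression input of the pipeline; one object per RNA class (mRNA,
#' lncRNA, circRNA, miRNA).
#'
#' @param counts numeric matrix of non-negative counts with feature ids as
#'   rownames and sample ids as colnames (both unique).
#' @param groups character or factor of length \code{ncol(counts)} (or a
#'   named vector covering every sample id) with exactly two levels, e.g.
#'   \code{"PMM"} (glycolytic) and \code{"SART"} (oxidative).
#' @param lengths optional named numeric vector of transcript lengths in bp
#'   (sum of exon lengths), one per feature. Required by
#'   \code{\link{fpkm_normalize}}.
#'
#' @return An object of class \code{rna_counts}: a list with elements
#'   \code{counts}, \code{groups} (factor named by sample) and
#'   \code{lengths} (or \code{NULL}).
#' @export
rna_counts <- function(counts, groups, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature ids in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids in `counts`")
  if (any(counts < 0)) stop("negative entries in `counts`")
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing))
      stop("samples without a group label: ", paste(missing, collapse = ", "))
    groups <- groups[colnames(counts)]
  } else if (length(groups) != ncol(counts)) {
    stop("`groups` must label every sample")
  }
  groups <- factor(as.character(groups))
  names(groups) <- colnames(counts)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required, got ", nlevels(groups))
  if (!is.null(lengths)) {
    if (is.null(names(lengths))) {
      if (length(lengths) != nrow(counts))
        stop("`lengths` must cover every feature")
      names(lengths) <- rownames(counts)
    }
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing))
      stop("features without a length: ", paste(utils::head(missing, 5L),
                                                collapse = ", "))
    lengths <- lengths[rownames(counts)]
    if (any(lengths <= 0)) stop("transcript lengths must be positive")
  }
  structure(list(counts = counts, groups = groups, lengths = lengths),
            class = "rna_counts")
}

#' @export
print.rna_counts <- function(x, ...) {
  cat(sprintf("rna_counts: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", levels(x$groups),
                            tabulate(x$groups)), collapse = " vs ")))
  invisible(x)
}

#' @export
dim.rna_counts <- function(x) dim(x$counts)

#' Subset an rna_counts object by feature ids
#'
#' @param x an \code{rna_counts} object.
#' @param features character vector of feature ids to keep (order kept).
#' @return An \code{rna_counts} restricted to \code{features}.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "rna_counts"))
  missing <- setdiff(features, rownames(x$counts))
  if (length(missing))
    stop("unknown feature ids: ", paste(utils::head(missing, 5L),
                                        collapse = ", "))
  rna_counts(x$counts[features, , drop = FALSE], x$groups,
             if (!is.null(x$lengths)) x$lengths[features])
}

group_columns <- function(x) {
  split(seq_along(x$groups), x$groups)
}

#' FPKM normalization
#'
#' Converts counts to fragments per kilobase of transcript per million
#' mapped reads: \code{FPKM = c * 1e9 / (L * T)} where \code{c} is the
#' count, \code{L} the transcript length in bp and \code{T} the sample's
#' total assigned counts. The identity
#' \code{sum_f FPKM * L * T / 1e9 == T} holds per sample.
#'
#' @param x an \code{rna_counts} object carrying feature lengths.
#' @return Numeric matrix of FPKM values with the axes of \code{x$counts}.
#' @export
fpkm_normalize <- function(x) {
  stopifnot(inherits(x, "rna_counts"))
  if (is.null(x$lengths))
    stop("FPKM requested but no transcript lengths are available")
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    bad <- colnames(x$counts)[totals == 0]
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  sweep(x$counts / x$lengths, 2L, totals, "/") * 1e9
}

#' Counts-per-million normalization
#'
#' Library-size scaling without length correction, used for RNA classes
#' whose abundance is not length-proportional (back-splice junction counts
#' of circRNAs, mature miRNA counts).
#'
#' @param x an \code{rna_counts} object.
#' @return Numeric matrix of CPM values.
#' @export
cpm_normalize <- function(x) {
  stopifnot(inherits(x, "rna_counts"))
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    bad <- colnames(x$counts)[totals == 0]
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  sweep(x$counts, 2L, totals, "/") * 1e6
}

#' Sample-sample correlation matrix
#'
#' Replicate-consistency check (heatmap input): correlations between
#' sample columns computed on \code{log2(expr + 1)}.
#'
#' @param expr normalized expression matrix (features x samples).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal. Pairs involving a constant sample vector are \code{NA} and
#'   raise a warning.
#' @export
sample_correlation <- function(expr, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("at least two samples are required")
  lg <- log2(expr + 1)
  constant <- apply(lg, 2L, function(v) max(v) == min(v))
  cc <- suppressWarnings(stats::cor(lg, method = method))
  if (any(constant)) {
    warning("constant sample vector(s), correlations set to NA: ",
            paste(colnames(expr)[constant], collapse = ", "))
    cc[constant, ] <- NA_real_
    cc[, constant] <- NA_real_
  }
  diag(cc) <- 1
  cc
}

#' Group presence partition (Venn counts)
#'
#' A feature counts as expressed in a group when it has a raw count of at
#' least one in at least one sample of that group. Features expressed in
#' exactly one group are group-specific; features expressed in both are
#' shared; all-zero features fall in no part, so
#' \code{group1_specific + group2_specific + shared} equals the number of
#' expressed features.
#'
#' @param x an \code{rna_counts} object.
#' @param min_count minimum raw count that marks presence (default 1).
#' @return List with \code{counts} (named numeric:
#'   \code{<group1>_specific}, \code{<group2>_specific}, \code{shared},
#'   \code{total_expressed}) and \code{assignment}, a character vector per
#'   feature in \code{{group1, group2, both, none}} (group names used).
#' @export
presence_partition <- function(x, min_count = 1) {
  stopifnot(inherits(x, "rna_counts"))
  gcols <- group_columns(x)
  gnames <- levels(x$groups)
  in1 <- rowSums(x$counts[, gcols[[1L]], drop = FALSE] >= min_count) > 0
  in2 <- rowSums(x$counts[, gcols[[2L]], drop = FALSE] >= min_count) > 0
  assignment <- rep("none", nrow(x$counts))
  assignment[in1 & !in2] <- gnames[1L]
  assignment[!in1 & in2] <- gnames[2L]
  assignment[in1 & in2] <- "both"
  names(assignment) <- rownames(x$counts)
  counts <- c(sum(in1 & !in2), sum(!in1 & in2), sum(in1 & in2))
  counts <- c(counts, sum(counts))
  names(counts) <- c(paste0(gnames, "_specific"), "shared", "total_expressed")
  list(counts = counts, assignment = assignment)
}
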