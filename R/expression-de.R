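#' Two-group negative-binomial exact test
#'
#' Conditional exact test for a difference in mean expression between two
#' groups of count samples, in the spirit of the classical exact NB test
#' for RNA-seq. Counts are first scaled to a common effective library size
#' (the geometric mean of the per-sample totals) and rounded. Under the
#' null, with a common dispersion \eqn{\phi}, the two group sums
#' \eqn{(A, B)} given their total \eqn{s} follow a negative
#' hypergeometric distribution with shape \eqn{n_g/\phi} per group, which
#' is free of the unknown mean; the two-sided p-value sums the
#' probabilities of all splits no more likely than the observed one
#' (minimum-likelihood rule). At \eqn{\phi = 0} this reduces to the
#' binomial \eqn{Bin(s, n_1/(n_1+n_2))} split.
#'
#' @param x an \code{rna_counts} object with two groups.
#' @param dispersion either a single non-negative dispersion value, or
#'   \code{"estimate"} for a common method-of-moments estimate pooled
#'   across features and groups (floored at zero).
#' @return A data.frame with one row per feature: \code{feature_id},
#'   \code{mean1}, \code{mean2} (group means of scaled counts, group order
#'   = factor level order), \code{log2fc} =
#'   \code{log2((mean2 + 0.5)/(mean1 + 0.5))}, and \code{pvalue} in
#'   \code{(0, 1]}. The dispersion used is attached as attribute
#'   \code{"dispersion"}.
#' @seealso \code{\link{filter_de}} for the significance partition.
#' @export
exact_nb_test <- function(x, dispersion = "estimate") {
  stopifnot(inherits(x, "rna_counts"))
  gcols <- group_columns(x)
  if (length(gcols) != 2L || any(lengths(gcols) < 1L))
    stop("two non-empty groups are required")
  totals <- colSums(x$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "))
  common <- exp(mean(log(totals)))
  scaled <- round(sweep(x$counts, 2L, common / totals, "*"))

  if (identical(dispersion, "estimate")) {
    dispersion <- estimate_common_dispersion(scaled, gcols)
  } else {
    if (!is.numeric(dispersion) || length(dispersion) != 1L ||
        is.na(dispersion) || dispersion < 0)
      stop("`dispersion` must be a single value >= 0 or \"estimate\"")
  }

  n1 <- length(gcols[[1L]]); n2 <- length(gcols[[2L]])
  sum1 <- rowSums(scaled[, gcols[[1L]], drop = FALSE])
  sum2 <- rowSums(scaled[, gcols[[2L]], drop = FALSE])
  mean1 <- sum1 / n1
  mean2 <- sum2 / n2
  p <- vapply(seq_len(nrow(scaled)), function(i) {
    exact_split_pvalue(sum1[i], sum2[i], n1, n2, dispersion)
  }, numeric(1))
  res <- data.frame(feature_id = rownames(x$counts),
                    mean1 = mean1, mean2 = mean2,
                    log2fc = log2((mean2 + 0.5) / (mean1 + 0.5)),
                    pvalue = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "dispersion") <- dispersion
  attr(res, "groups") <- levels(x$groups)
  res
}

# Pooled method-of-moments dispersion: var = mu + phi mu^2 within groups,
# so phi = sum(v - m) / sum(m^2) across features and groups, floored at 0.
estimate_common_dispersion <- function(scaled, gcols) {
  num <- 0; den <- 0
  for (cols in gcols) {
    if (length(cols) < 2L) next
    m <- rowMeans(scaled[, cols, drop = FALSE])
    v <- apply(scaled[, cols, drop = FALSE], 1L, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

# Two-sided conditional p-value for the split (a, s - a) of the total s
# between groups of n1 and n2 samples at common dispersion phi.
exact_split_pvalue <- function(a, b, n1, n2, phi) {
  s <- a + b
  if (s == 0) return(1)
  av <- 0:s
  if (phi == 0) {
    logp <- stats::dbinom(av, s, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    logp <- lgamma(av + r1) - lgamma(av + 1) +
      lgamma(s - av + r2) - lgamma(s - av + 1)
    logp <- logp - logsumexp(logp)
  }
  obs <- logp[a + 1L]
  # keep outcomes no more likely than observed, with a relative tolerance
  # against ties lost to floating point (as in fisher.test)
  p <- exp(logsumexp(logp[logp <= obs + 1e-7]))
  min(max(p, exp(obs)), 1)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Differential-expression filter and partition
#'
#' Applies the significance rule used throughout the pipeline: a feature
#' is differentially expressed when its raw p-value is strictly below
#' \code{p_threshold} and \code{|log2fc|} is at least \code{lfc_threshold}
#' (inclusive). Optionally p-values can be Benjamini-Hochberg adjusted
#' first; the default matches the raw-p rule.
#'
#' @param records data.frame from \code{\link{exact_nb_test}} (columns
#'   \code{feature_id}, \code{log2fc}, \code{pvalue}).
#' @param p_threshold strict p-value cutoff (default 0.05).
#' @param lfc_threshold inclusive absolute log2 fold-change cutoff
#'   (default 1).
#' @param adjust \code{"none"} (raw p, default) or \code{"BH"}.
#' @return A list: \code{table} (records plus \code{direction} in
#'   \code{{up, down, none}} and logical \code{significant}), and id
#'   vectors \code{up}, \code{down}, \code{not_de}. The three id sets are
#'   disjoint and exhaustive.
#' @export
filter_de <- function(records, p_threshold = 0.05, lfc_threshold = 1.0,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(records),
            all(c("feature_id", "log2fc", "pvalue") %in% names(records)))
  p <- records$pvalue
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sig <- (p < p_threshold) & (abs(records$log2fc) >= lfc_threshold)
  direction <- rep("none", nrow(records))
  direction[sig & records$log2fc > 0] <- "up"
  direction[sig & records$log2fc < 0] <- "down"
  table <- records
  table$direction <- direction
  table$significant <- sig
  list(table = table,
       up = records$feature_id[direction == "up"],
       down = records$feature_id[direction == "down"],
       not_de = records$feature_id[direction == "none"])
}
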