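#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for the number of marked items in \code{n} draws
#' without replacement from a population of \code{N} items of which
#' \code{K} are marked:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The sum is accumulated in log space, so it is exact to double precision
#' for the population sizes used here. This single function backs both the
#' term over-representation test and the shared-miRNA sponge test.
#'
#' @param k observed overlap (integer, \code{max(0, n+K-N) <= k <= min(K, n)}).
#' @param N population (background) size.
#' @param K marked items in the population.
#' @param n number of draws (study-set size).
#' @return Upper-tail probability in \code{(0, 1]}; \code{k = 0} gives 1.
#' @export
hypergeom_sf <- function(k, N, K, n) {
  args <- c(k = k, N = N, K = K, n = n)
  if (any(args != round(args)) || any(args < 0))
    stop("k, N, K, n must be non-negative integers")
  if (K > N || n > N)
    stop("K and n cannot exceed the population size N")
  if (k > min(K, n))
    stop("k = ", k, " exceeds min(K, n) = ", min(K, n))
  if (k < max(0, n + K - N))
    stop("k = ", k, " is below the minimum possible overlap ",
         max(0, n + K - N))
  if (k == 0) return(1)
  i <- k:min(K, n)
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(exp(logsumexp(logterms)), 1)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for enrichment of a study gene set against a
#' background universe. For a term carried by \code{K} of the \code{N}
#' background genes and \code{k} of the \code{n} study genes, the p-value
#' is \code{hypergeom_sf(k, N, K, n)}. Genes without any term annotation
#' stay in the background count \code{N} unless dropped. Terms with no
#' study gene are omitted. Significance uses a strict raw-p cutoff by
#' default (adjusted p is reported when requested but the flag column
#' still follows the chosen column).
#'
#' @param study_set character vector of study gene ids (subset of the
#'   background).
#' @param background_set character vector of background gene ids.
#' @param term_map data.frame with columns \code{gene_id}, \code{term_id}
#'   and optionally \code{term_name}, \code{category}.
#' @param p_threshold strict significance cutoff (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @param drop_unannotated if \code{TRUE}, genes absent from the term map
#'   are removed from both study and background before counting.
#' @return data.frame sorted by ascending p (ties broken by term id) with
#'   columns \code{term_id}, \code{term_name}, \code{category}, \code{k},
#'   \code{n}, \code{K}, \code{N}, \code{pvalue}, \code{p_adjusted} (NA
#'   when \code{adjust = "none"}), \code{significant}.
#' @export
enrich <- function(study_set, background_set, term_map,
                   p_threshold = 0.05, adjust = c("none", "BH"),
                   drop_unannotated = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(term_map),
            all(c("gene_id", "term_id") %in% names(term_map)))
  study_set <- unique(as.character(study_set))
  background_set <- unique(as.character(background_set))
  outside <- setdiff(study_set, background_set)
  if (length(outside))
    stop("study genes outside the background: ",
         paste(utils::head(outside, 10L), collapse = ", "))
  term_map <- term_map[term_map$gene_id %in% background_set, , drop = FALSE]
  if (drop_unannotated) {
    annotated <- unique(term_map$gene_id)
    study_set <- intersect(study_set, annotated)
    background_set <- intersect(background_set, annotated)
  }
  N <- length(background_set)
  n <- length(study_set)
  term_map <- unique(term_map[, intersect(
    c("gene_id", "term_id", "term_name", "category"), names(term_map)),
    drop = FALSE])
  Ktab <- table(term_map$term_id)
  in_study <- term_map[term_map$gene_id %in% study_set, , drop = FALSE]
  if (nrow(in_study) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), pvalue = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  ktab <- table(in_study$term_id)
  terms <- sort(names(ktab))
  meta <- term_map[!duplicated(term_map$term_id), , drop = FALSE]
  rownames(meta) <- meta$term_id
  k <- as.integer(ktab[terms])
  K <- as.integer(Ktab[terms])
  p <- mapply(hypergeom_sf, k = k, K = K, MoreArgs = list(N = N, n = n))
  res <- data.frame(
    term_id = terms,
    term_name = if ("term_name" %in% names(meta))
      as.character(meta[terms, "term_name"]) else NA_character_,
    category = if ("category" %in% names(meta))
      as.character(meta[terms, "category"]) else NA_character_,
    k = k, n = n, K = K, N = N, pvalue = p,
    row.names = NULL, stringsAsFactors = FALSE)
  res$p_adjusted <- if (adjust == "BH")
    stats::p.adjust(res$pvalue, "BH") else NA_real_
  crit <- if (adjust == "BH") res$p_adjusted else res$pvalue
  res$significant <- crit < p_threshold
  res[order(res$pvalue, res$term_id), , drop = FALSE]
}
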