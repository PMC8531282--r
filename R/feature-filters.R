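#' Structural and coding-potential filter for lncRNA candidates
#'
#' Defines the lncRNA set from assembled transcripts: a candidate is
#' accepted when its transcript length (sum of exon lengths) is at least
#' 200 bp, it has at least two exons, and both coding-potential predictors
#' call it noncoding. Rejections are attributed to the first failing rule
#' in the fixed order length, exons, coding, so the tally is
#' deterministic.
#'
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{length} (bp) and \code{n_exons}.
#' @param coding_labels data.frame with columns \code{transcript_id},
#'   \code{predictor}, \code{label} (\code{"coding"}/\code{"noncoding"}),
#'   covering every candidate with (at least) two predictors.
#' @param min_length minimum transcript length in bp (default 200,
#'   inclusive).
#' @param min_exons minimum exon count (default 2, inclusive).
#' @return List with \code{accepted} (character ids), \code{rejected}
#'   (data.frame \code{transcript_id}, \code{rule}) and \code{tally}
#'   (named integer: accepted, length, exons, coding).
#' @export
filter_lncrna_candidates <- function(transcripts, coding_labels,
                                     min_length = 200L, min_exons = 2L) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "length", "n_exons") %in%
                  names(transcripts)))
  stopifnot(is.data.frame(coding_labels),
            all(c("transcript_id", "predictor", "label") %in%
                  names(coding_labels)))
  ids <- as.character(transcripts$transcript_id)
  preds <- unique(coding_labels$predictor)
  if (length(preds) < 2L)
    stop("coding labels from at least two predictors are required")
  have <- table(factor(coding_labels$transcript_id, levels = ids),
                factor(coding_labels$predictor, levels = preds))
  unlabelled <- ids[rowSums(have > 0) < length(preds)]
  if (length(unlabelled))
    stop("candidates missing a predictor label: ",
         paste(utils::head(unlabelled, 10L), collapse = ", "))
  any_coding <- unique(
    coding_labels$transcript_id[coding_labels$label == "coding"])

  rule <- rep(NA_character_, length(ids))
  rule[transcripts$length < min_length] <- "length"
  rule[is.na(rule) & transcripts$n_exons < min_exons] <- "exons"
  rule[is.na(rule) & ids %in% any_coding] <- "coding"
  accepted <- ids[is.na(rule)]
  rejected <- data.frame(transcript_id = ids[!is.na(rule)],
                         rule = rule[!is.na(rule)],
                         stringsAsFactors = FALSE)
  tally <- c(accepted = length(accepted),
             length = sum(rejected$rule == "length"),
             exons = sum(rejected$rule == "exons"),
             coding = sum(rejected$rule == "coding"))
  list(accepted = accepted, rejected = rejected, tally = tally)
}

#' Evidence filter for circRNAs
#'
#' A back-splice candidate is retained when it is expressed (count of at
#' least \code{min_count}) in at least \code{min_samples} distinct
#' samples, irrespective of group.
#'
#' @param x an \code{rna_counts} object of back-splice junction counts.
#' @param min_samples minimum number of expressing samples (default 2).
#' @param min_count count that marks a sample as expressing (default 1).
#' @return List with \code{retained} and \code{dropped} id vectors.
#' @export
filter_circrna <- function(x, min_samples = 2L, min_count = 1L) {
  stopifnot(inherits(x, "rna_counts"))
  if (ncol(x$counts) < min_samples)
    stop("fewer samples than `min_samples`")
  n_expressing <- rowSums(x$counts >= min_count)
  keep <- n_expressing >= min_samples
  list(retained = rownames(x$counts)[keep],
       dropped = rownames(x$counts)[!keep])
}
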