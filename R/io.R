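#' Write an annotation set as GTF 2.2
#'
#' Emits one \code{transcript} line and one \code{exon} line per exon for
#' every transcript, with attributes \code{gene_id},
#' \code{transcript_id}, \code{biotype} and, for circRNAs,
#' \code{host_gene}. Coordinates are 1-based inclusive. Output is
#' deterministic (fixed row order and formatting).
#'
#' @param annotation list with \code{transcripts} and \code{exons}
#'   data.frames (see \code{\link{generate_annotation}}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  tr <- annotation$transcripts
  ex <- annotation$exons
  attr_str <- function(i) {
    s <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                 tr$gene_id[i], tr$transcript_id[i], tr$biotype[i])
    host <- tr$host_gene[i]
    if (!is.na(host)) s <- paste0(s, sprintf(' host_gene "%s";', host))
    s
  }
  lines <- character()
  for (i in seq_len(nrow(tr))) {
    a <- attr_str(i)
    lines <- c(lines, sprintf("%s\tcernaforge\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              tr$chrom[i], tr$start[i], tr$end[i],
                              tr$strand[i], a))
    exi <- ex[ex$transcript_id == tr$transcript_id[i], , drop = FALSE]
    lines <- c(lines, sprintf("%s\tcernaforge\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tr$chrom[i], exi$start, exi$end,
                              tr$strand[i], a))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF annotation into the pipeline's tables
#'
#' Parses a GTF (via rtracklayer) carrying \code{transcript} and
#' \code{exon} features with \code{gene_id}, \code{transcript_id} and
#' optionally \code{biotype}/\code{host_gene} attributes, and rebuilds
#' the \code{transcripts}/\code{exons}/\code{genes} tables (transcript
#' length = sum of exon lengths; gene loci = spans of mRNA transcripts).
#'
#' @param path GTF file.
#' @return List of data.frames \code{transcripts}, \code{exons},
#'   \code{genes}.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  exdf <- df[df$type == "exon", , drop = FALSE]
  txdf <- df[df$type == "transcript", , drop = FALSE]
  if (nrow(txdf) == 0L)
    stop("no transcript features found in ", path)
  exlen <- tapply(exdf$end - exdf$start + 1L, exdf$transcript_id, sum)
  exn <- tapply(exdf$transcript_id, exdf$transcript_id, length)
  transcripts <- data.frame(
    transcript_id = txdf$transcript_id,
    gene_id = txdf$gene_id,
    biotype = if ("biotype" %in% names(txdf)) txdf$biotype
    else NA_character_,
    chrom = txdf$seqnames, strand = txdf$strand,
    start = txdf$start, end = txdf$end,
    length = as.integer(exlen[txdf$transcript_id]),
    n_exons = as.integer(exn[txdf$transcript_id]),
    host_gene = if ("host_gene" %in% names(txdf)) txdf$host_gene
    else NA_character_,
    stringsAsFactors = FALSE)
  ord <- order(exdf$transcript_id, exdf$start)
  exdf <- exdf[ord, , drop = FALSE]
  exons <- data.frame(transcript_id = exdf$transcript_id,
                      exon_number = stats::ave(
                        seq_len(nrow(exdf)), exdf$transcript_id,
                        FUN = seq_along),
                      start = exdf$start, end = exdf$end,
                      stringsAsFactors = FALSE)
  mrna <- transcripts[!is.na(transcripts$biotype) &
                        transcripts$biotype == "mRNA", , drop = FALSE]
  genes <- data.frame(gene_id = mrna$gene_id, chrom = mrna$chrom,
                      strand = mrna$strand, start = mrna$start,
                      end = mrna$end, stringsAsFactors = FALSE)
  list(transcripts = transcripts, exons = exons, genes = genes)
}

#' Write / read a count matrix as TSV
#'
#' Header row of sample ids with a leading \code{feature_id} column.
#'
#' @param x an \code{rna_counts} object (writer) .
#' @param path file path.
#' @return \code{path} (writer), invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "rna_counts"))
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts
#' @param groups named group vector (sample -> group) or a two-column
#'   data.frame (\code{sample}, \code{group}).
#' @param lengths optional named transcript-length vector.
#' @return An \code{rna_counts} object (reader).
#' @export
read_counts <- function(path, groups, lengths = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "feature_id")
    stop("count table must start with a feature_id column: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df$feature_id)
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  rna_counts(m, groups, lengths)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences (DNA or RNA).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write the complete synthetic fixture to a directory
#'
#' Emits every file the pipeline consumes: \code{annotation.gtf}, one
#' count TSV per RNA class, \code{groups.tsv}, miRNA and target FASTA,
#' \code{target_edges.tsv}, \code{coding_labels.tsv} (two predictors,
#' noncoding for every true lncRNA, with decoy violations),
#' \code{term_map.tsv}, \code{mirna_universe.txt} (planted DE miRNAs),
#' \code{truth.json} and a ready-to-run \code{config.yaml}. All files
#' are plain text and byte-deterministic given the config.
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  p <- function(f) file.path(dir, f)
  write_gtf(sim$annotation, p("annotation.gtf"))
  for (cl in names(sim$counts))
    write_counts(sim$counts[[cl]], p(paste0("counts_", cl, ".tsv")))
  g <- sim$counts$mrna$groups
  write_tsv(data.frame(sample = names(g), group = as.character(g),
                       stringsAsFactors = FALSE), p("groups.tsv"))
  write_fasta(sim$sequences$mirna_seqs, p("mirnas.fa"))
  write_fasta(sim$sequences$target_seqs, p("targets.fa"))
  write_tsv(sim$truth$target_edges, p("target_edges.tsv"))
  write_tsv(coding_label_table(sim), p("coding_labels.tsv"))
  write_tsv(sim$truth$term_map, p("term_map.tsv"))
  de <- sim$truth$de_features
  writeLines(sort(de$feature_id[de$class == "mirna"]),
             p("mirna_universe.txt"))
  jsonlite::write_json(sim$truth, p("truth.json"), dataframe = "columns",
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(fixture_config(dir), p("config.yaml"))
  invisible(dir)
}

coding_label_table <- function(sim) {
  tr <- sim$annotation$transcripts
  cands <- tr$transcript_id[tr$biotype %in% c("lncRNA", "lncRNA_candidate")]
  coding <- sim$truth$decoys$transcript_id[
    sim$truth$decoys$violation == "coding"]
  do.call(rbind, lapply(c("cnci", "cpc"), function(pred)
    data.frame(transcript_id = cands, predictor = pred,
               label = ifelse(cands %in% coding, "coding", "noncoding"),
               stringsAsFactors = FALSE)))
}

fixture_config <- function(dir) {
  list(
    counts = list(mrna = "counts_mrna.tsv", lncrna = "counts_lncrna.tsv",
                  circrna = "counts_circrna.tsv",
                  mirna = "counts_mirna.tsv"),
    annotation = "annotation.gtf",
    groups = "groups.tsv",
    coding_labels = "coding_labels.tsv",
    target_edges = "target_edges.tsv",
    mirna_fasta = "mirnas.fa",
    target_fasta = "targets.fa",
    term_map = "term_map.tsv",
    mirna_universe = "mirna_universe.txt",
    thresholds = list(p_de = 0.05, lfc = 1.0, cis_window = 10000L,
                      scc = -0.7, pcc = 0.9, sponge_p = 0.05,
                      enrich_p = 0.05),
    outdir = "results",
    seed = 1L)
}

#' Reload a truth ledger written by \code{\link{write_fixture}}
#'
#' @param path \code{truth.json} file.
#' @return Truth list with data.frame components restored.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("de_features", "cis_pairs", "triads", "target_edges",
               "seed_sites", "decoys", "term_map")) {
    if (!is.null(truth[[nm]]))
      truth[[nm]] <- as.data.frame(truth[[nm]],
                                   stringsAsFactors = FALSE)
  }
  truth
}
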