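#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, resolves relative paths against the
#' config file's directory, and checks file existence, group labels and
#' threshold domains. All violations are collected and reported together
#' rather than failing on the first.
#'
#' @param path YAML configuration file (see the fixture's
#'   \code{config.yaml} for the schema: count tables per class,
#'   annotation GTF, groups table, coding labels, target edges and/or
#'   FASTA pair, term map, miRNA universe, thresholds, output directory,
#'   seed).
#' @return Validated configuration list of class \code{pipeline_config}
#'   with absolute paths, or an error listing every violation.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!startsWith(p, "/")) p <- file.path(base, p)
    p
  }
  need_file <- function(key, p) {
    if (is.null(p)) { note(paste0("missing required entry: ", key)); return(NULL) }
    if (!file.exists(p)) note(paste0(key, ": file not found: ", p))
    p
  }
  for (cl in c("mrna", "lncrna", "circrna", "mirna")) {
    cfg$counts[[cl]] <- need_file(paste0("counts.", cl),
                                  resolve(cfg$counts[[cl]]))
  }
  for (key in c("annotation", "groups", "coding_labels", "term_map",
                "mirna_universe"))
    cfg[[key]] <- need_file(key, resolve(cfg[[key]]))
  for (key in c("target_edges", "mirna_fasta", "target_fasta")) {
    cfg[[key]] <- resolve(cfg[[key]])
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      note(paste0(key, ": file not found: ", cfg[[key]]))
  }
  if (is.null(cfg$target_edges) &&
      (is.null(cfg$mirna_fasta) || is.null(cfg$target_fasta)))
    note("either target_edges or both mirna_fasta and target_fasta are required")

  th <- utils::modifyList(
    list(p_de = 0.05, lfc = 1.0, cis_window = 10000L, scc = -0.7,
         pcc = 0.9, sponge_p = 0.05, enrich_p = 0.05),
    if (is.null(cfg$thresholds)) list() else cfg$thresholds)
  check_range <- function(key, lo, hi, lo_ok = FALSE, hi_ok = FALSE) {
    v <- th[[key]]
    ok <- is.numeric(v) && length(v) == 1L &&
      (v > lo || (lo_ok && v == lo)) && (v < hi || (hi_ok && v == hi))
    if (!ok) note(sprintf("threshold %s = %s out of domain", key,
                          format(v)))
  }
  check_range("p_de", 0, 1)
  check_range("lfc", 0, Inf, lo_ok = TRUE)
  check_range("cis_window", 0, Inf, lo_ok = TRUE)
  check_range("scc", -1, 0)          # negative-correlation gate
  check_range("pcc", 0, 1)           # positive-correlation gate
  check_range("sponge_p", 0, 1)
  check_range("enrich_p", 0, 1)
  cfg$thresholds <- th

  if (!is.null(cfg$groups) && file.exists(cfg$groups)) {
    gdf <- utils::read.delim(cfg$groups, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(gdf))) {
      note("groups table needs columns sample, group")
    } else {
      if (length(unique(gdf$group)) != 2L)
        note("groups table must define exactly two groups")
      if (!is.null(cfg$counts$mrna) && file.exists(cfg$counts$mrna)) {
        hdr <- names(utils::read.delim(cfg$counts$mrna, nrows = 1L,
                                       check.names = FALSE))[-1L]
        missing <- setdiff(hdr, gdf$sample)
        if (length(missing))
          note(paste0("sample(s) absent from group map: ",
                      paste(missing, collapse = ", ")))
      }
    }
  }
  if (is.null(cfg$outdir)) note("missing required entry: outdir")
  else if (!startsWith(cfg$outdir, "/"))
    cfg$outdir <- file.path(base, cfg$outdir)
  if (is.null(cfg$seed)) cfg$seed <- 1L

  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: lncRNA/circRNA candidate filters, FPKM (mRNA,
#' lncRNA) and CPM (circRNA, miRNA) normalization, sample correlation,
#' the NB exact test and DE filter per class, the presence (Venn)
#' partition, 10 kb cis-target assignment and the DE-DE cis network,
#' hypergeometric enrichment of the cis-target genes and the DE-circRNA
#' host genes, miRNA-target edge assembly, and ceRNA triad inference
#' with network export. Every stage writes a TSV under \code{outdir};
#' the run report (stage counts and thresholds, JSON) is returned and
#' written as \code{report.json}. Re-running on unchanged inputs
#' reproduces identical outputs.
#'
#' @param cfg a \code{pipeline_config} from \code{\link{validate_config}}
#'   (or a path to a YAML config).
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  th <- cfg$thresholds
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  report <- list(thresholds = th, stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage_msg <- function(name, t0)
    message(sprintf("[cerna-forge] %-18s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))

  t0 <- proc.time()[["elapsed"]]
  ann <- read_annotation(cfg$annotation)
  gdf <- utils::read.delim(cfg$groups, stringsAsFactors = FALSE)
  groups <- stats::setNames(as.character(gdf$group),
                            as.character(gdf$sample))
  tr <- ann$transcripts
  tx_len <- stats::setNames(tr$length, tr$transcript_id)
  gene_len <- stats::setNames(tr$length[tr$biotype == "mRNA"],
                              tr$gene_id[tr$biotype == "mRNA"])
  counts <- list(
    mrna = read_counts(cfg$counts$mrna, groups, gene_len),
    lncrna = read_counts(cfg$counts$lncrna, groups, tx_len),
    circrna = read_counts(cfg$counts$circrna, groups),
    mirna = read_counts(cfg$counts$mirna, groups))
  stage_msg("load", t0)

  # --- candidate filters ------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  cands <- tr[tr$biotype %in% c("lncRNA", "lncRNA_candidate"), ,
              drop = FALSE]
  labels <- utils::read.delim(cfg$coding_labels, stringsAsFactors = FALSE)
  lnc_filter <- filter_lncrna_candidates(cands, labels)
  lnc_keep <- intersect(rownames(counts$lncrna$counts),
                        lnc_filter$accepted)
  counts$lncrna <- subset_features(counts$lncrna, lnc_keep)
  write_tsv(data.frame(transcript_id = lnc_filter$accepted,
                       stringsAsFactors = FALSE), out("lncrna_accepted.tsv"))
  write_tsv(lnc_filter$rejected, out("lncrna_rejected.tsv"))
  circ_filter <- filter_circrna(counts$circrna)
  counts$circrna <- subset_features(counts$circrna, circ_filter$retained)
  write_tsv(data.frame(circrna_id = circ_filter$retained,
                       stringsAsFactors = FALSE), out("circrna_retained.tsv"))
  report$stages$filters <- list(
    lncrna = as.list(lnc_filter$tally),
    circrna = list(retained = length(circ_filter$retained),
                   dropped = length(circ_filter$dropped)))
  stage_msg("filters", t0)

  # --- normalization and sample correlation -----------------------------
  t0 <- proc.time()[["elapsed"]]
  expr <- list(mrna = fpkm_normalize(counts$mrna),
               lncrna = fpkm_normalize(counts$lncrna),
               circrna = cpm_normalize(counts$circrna),
               mirna = cpm_normalize(counts$mirna))
  for (cl in names(expr))
    write_tsv(data.frame(feature_id = rownames(expr[[cl]]),
                         round(expr[[cl]], 4L), check.names = FALSE),
              out(paste0("expr_", cl, ".tsv")))
  cc <- sample_correlation(expr$mrna, "pearson")
  write_tsv(data.frame(sample = rownames(cc), round(cc, 6L),
                       check.names = FALSE), out("sample_correlation.tsv"))
  report$stages$sample_correlation <- list(
    mean_offdiag = mean(cc[upper.tri(cc)]))
  stage_msg("normalize", t0)

  # --- differential expression and presence -----------------------------
  t0 <- proc.time()[["elapsed"]]
  de <- list(); presence <- list()
  for (cl in names(counts)) {
    res <- exact_nb_test(counts[[cl]], dispersion = "estimate")
    part <- filter_de(res, th$p_de, th$lfc)
    write_tsv(transform(part$table,
                        log2fc = round(log2fc, 6L),
                        mean1 = round(mean1, 4L),
                        mean2 = round(mean2, 4L)),
              out(paste0("de_", cl, ".tsv")))
    de[[cl]] <- part
    pp <- presence_partition(counts[[cl]])
    presence[[cl]] <- pp
    report$stages$presence[[cl]] <- as.list(pp$counts)
    report$stages$de[[cl]] <- list(up = length(part$up),
                                   down = length(part$down),
                                   not_de = length(part$not_de),
                                   dispersion = attr(res, "dispersion"))
  }
  stage_msg("de", t0)

  # --- cis targets ------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  de_lnc_ids <- c(de$lncrna$up, de$lncrna$down)
  lnc_loci <- tr[tr$transcript_id %in% de_lnc_ids, , drop = FALSE]
  lnc_loci$id <- lnc_loci$transcript_id
  cis <- assign_cis_targets(lnc_loci, ann$genes, th$cis_window)
  write_tsv(cis, out("cis_pairs.tsv"))
  cis_net <- de_cis_network(cis, de$lncrna, de$mrna)
  write_tsv(cis_net, out("cis_network.tsv"))
  report$stages$cis <- list(
    pairs = nrow(cis),
    de_lncrnas = length(unique(cis$lncrna_id)),
    target_genes = length(unique(cis$gene_id)),
    de_de_edges = nrow(cis_net))
  stage_msg("cis", t0)

  # --- enrichment -------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  term_map <- utils::read.delim(cfg$term_map, stringsAsFactors = FALSE)
  background <- rownames(counts$mrna$counts)[
    presence$mrna$assignment != "none"]
  enr_cis <- enrich(intersect(unique(cis$gene_id), background),
                    background, term_map, th$enrich_p)
  write_tsv(round_p(enr_cis), out("enrichment_cis_targets.tsv"))
  de_circ <- c(de$circrna$up, de$circrna$down)
  hosts <- unique(tr$host_gene[tr$transcript_id %in% de_circ &
                                 !is.na(tr$host_gene)])
  enr_host <- enrich(intersect(hosts, background), background, term_map,
                     th$enrich_p)
  write_tsv(round_p(enr_host), out("enrichment_circ_hosts.tsv"))
  report$stages$enrichment <- list(
    cis_targets = list(terms = nrow(enr_cis),
                       significant = sum(enr_cis$significant)),
    circ_hosts = list(terms = nrow(enr_host),
                      significant = sum(enr_host$significant)))
  stage_msg("enrichment", t0)

  # --- miRNA target edges ----------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  edges <- if (!is.null(cfg$target_edges)) {
    load_target_table(cfg$target_edges)
  } else {
    mir <- read_fasta(cfg$mirna_fasta)
    targ <- read_fasta(cfg$target_fasta)
    cls <- target_class_lookup(tr)
    seed_match(mir, targ, target_class = cls)
  }
  write_tsv(edges, out("target_edges_used.tsv"))
  universe <- readLines(cfg$mirna_universe)
  universe <- universe[nzchar(universe)]
  report$stages$targets <- list(edges = nrow(edges),
                                mirna_universe = length(universe))
  stage_msg("targets", t0)

  # --- ceRNA network ----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (length(universe) == 0L) {
    report$stages$cerna <- list(skipped = TRUE,
                                reason = "empty miRNA universe")
    triads <- NULL
  } else {
    triads <- cerna_stage(expr, de, edges, universe, th, out)
    report$stages$cerna <- list(
      skipped = FALSE,
      negative_pairs = attr(triads, "n_negative"),
      coexpressed_pairs = attr(triads, "n_coexpressed"),
      triads = nrow(triads))
  }
  stage_msg("cerna", t0)

  # --- network export ---------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  classes <- target_class_lookup(tr)
  dirs <- unlist(lapply(de, direction_lookup))
  names(dirs) <- sub("^[a-z]+\\.", "", names(dirs))
  net <- cerna_network(triads, cis_net, classes, dirs)
  export_network(net, out("network.sif"), "SIF")
  export_network(net, out("network.graphml"), "GraphML")
  export_network(net, out("network_edges.tsv"), "TSV")
  report$stages$network <- list(nodes = nrow(net$nodes),
                                edges = nrow(net$edges))
  stage_msg("export", t0)

  report$elapsed_ignored <- NULL
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf("[cerna-forge] total %.1fs -> %s",
                  proc.time()[["elapsed"]] - t_all, outdir))
  invisible(report)
}

round_p <- function(df) {
  if (nrow(df)) df$pvalue <- signif(df$pvalue, 6L)
  df
}

target_class_lookup <- function(tr) {
  cls <- c(mRNA = "mRNA", lncRNA = "lncRNA", circRNA = "circRNA",
           miRNA = "miRNA")[tr$biotype]
  ids <- ifelse(tr$biotype == "mRNA", tr$gene_id, tr$transcript_id)
  stats::setNames(cls, ids)
}

# correlation gates + sponge test; writes the pair tables and returns
# the triad table with pair counts attached
cerna_stage <- function(expr, de, edges, universe, th, out) {
  de_ids <- lapply(de, function(p) c(p$up, p$down))
  expr_de <- function(cl) {
    keep <- intersect(rownames(expr[[cl]]), de_ids[[cl]])
    expr[[cl]][keep, , drop = FALSE]
  }
  e_mir <- expr_de("mirna")
  e_lnc <- expr_de("lncrna")
  e_mrna <- expr_de("mrna")
  e_circ <- expr_de("circrna")
  edges_de <- edges[edges$mirna_id %in% rownames(e_mir), , drop = FALSE]
  e_reg <- rbind(e_lnc, e_circ)

  neg_reg <- negative_pairs(e_mir, e_reg, edges_de, th$scc)
  neg_mrna <- negative_pairs(e_mir, e_mrna, edges_de, th$scc)
  neg <- rbind(neg_reg, neg_mrna)
  write_tsv(transform(neg, scc = round(scc, 6L)),
            out("negative_pairs.tsv"))

  # candidate (regulator, mRNA) pairs must already share a negative miRNA
  cand <- merge(neg_reg[, c("mirna_id", "target_id")],
                neg_mrna[, c("mirna_id", "target_id")],
                by = "mirna_id", suffixes = c("_reg", "_mrna"))
  cand <- unique(data.frame(regulator_id = cand$target_id_reg,
                            mrna_id = cand$target_id_mrna,
                            stringsAsFactors = FALSE))
  coexp <- coexpressed_pairs(e_reg, e_mrna, cand, th$pcc)
  write_tsv(transform(coexp, pcc = round(pcc, 6L)),
            out("coexpressed_pairs.tsv"))

  dirs <- unlist(lapply(de, direction_lookup))
  names(dirs) <- sub("^[a-z]+\\.", "", names(dirs))
  triads <- build_triads(neg, coexp, edges, universe, th$sponge_p,
                         directions = dirs)
  write_tsv(transform(triads,
                      scc_mi_regulator = round(scc_mi_regulator, 6L),
                      scc_mi_mrna = round(scc_mi_mrna, 6L),
                      pcc_regulator_mrna = round(pcc_regulator_mrna, 6L),
                      sponge_p = signif(sponge_p, 6L)),
            out("triads.tsv"))
  attr(triads, "n_negative") <- nrow(neg)
  attr(triads, "n_coexpressed") <- nrow(coexp)
  triads
}
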