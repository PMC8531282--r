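#' Configuration for the synthetic two-muscle dataset
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure the downstream analysis assumes: grouped negative-binomial
#' counts for four RNA classes (4 vs 4 samples by default, the
#' glycolytic-vs-oxidative design), planted differentially expressed
#' features, planted cis lncRNA placements that avoid the 10 kb decision
#' boundary, and planted ceRNA triads whose members share a latent
#' per-sample factor (entering the miRNA with negative sign and the
#' regulator/mRNA with positive sign).
#'
#' @param n_mrna,n_lncrna,n_circrna,n_mirna feature counts per RNA class.
#' @param n_per_group samples per group (default 4).
#' @param frac_de fraction of features planted as differentially
#'   expressed per class (default 0.10); triad members are always DE.
#' @param de_log2fc planted absolute log2 fold change (default 2).
#' @param nb_dispersion NB dispersion phi, so var = mu + phi mu^2
#'   (default 0.1; 0 gives Poisson counts).
#' @param mean_log_expr_mu,mean_log_expr_sigma log-normal baseline mean
#'   parameters on the natural-log scale (defaults log(200) and 1.2).
#' @param n_triads planted ceRNA triads (lncRNA, miRNA, mRNA; default 30).
#' @param triad_corr_strength latent-factor loading in [0, 1], in log2
#'   expression units per standard deviation (default 0.9).
#' @param cis_fraction fraction of lncRNAs placed within the 10 kb cis
#'   window of a gene, gap uniform in [0, 9500] bp; the rest sit at least
#'   15 kb from every gene so the boundary band is never populated
#'   (default 0.25).
#' @param library_size_range integer pair; per-sample nominal library
#'   sizes are drawn uniformly from this range and enter the NB means as
#'   relative depth factors (default 800000..1200000).
#' @param n_lncrna_decoys extra lncRNA candidates violating the
#'   structural/coding filters (cycled over short, single-exon and
#'   coding-labelled violations; default 0).
#' @param n_background_edges random miRNA-target edges planted outside
#'   the triads (default 200).
#' @param target_seq_length length in bp of simulated target sequences
#'   (default 500).
#' @param seed integer RNG seed driving every stage through fixed
#'   per-stage child seeds.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_mrna = 2000L, n_lncrna = 400L, n_circrna = 200L,
                       n_mirna = 150L, n_per_group = 4L, frac_de = 0.10,
                       de_log2fc = 2.0, nb_dispersion = 0.1,
                       mean_log_expr_mu = log(200),
                       mean_log_expr_sigma = 1.2, n_triads = 30L,
                       triad_corr_strength = 0.9, cis_fraction = 0.25,
                       library_size_range = c(800000L, 1200000L),
                       n_lncrna_decoys = 0L, n_background_edges = 200L,
                       target_seq_length = 500L, seed = 1L) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_circrna = as.integer(n_circrna),
              n_mirna = as.integer(n_mirna),
              n_per_group = as.integer(n_per_group), frac_de = frac_de,
              de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
              mean_log_expr_mu = mean_log_expr_mu,
              mean_log_expr_sigma = mean_log_expr_sigma,
              n_triads = as.integer(n_triads),
              triad_corr_strength = triad_corr_strength,
              cis_fraction = cis_fraction,
              library_size_range = as.integer(library_size_range),
              n_lncrna_decoys = as.integer(n_lncrna_decoys),
              n_background_edges = as.integer(n_background_edges),
              target_seq_length = as.integer(target_seq_length),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_mrna > 0, n_lncrna > 0, n_circrna > 0, n_mirna > 0,
              n_per_group > 0, frac_de >= 0, frac_de <= 1,
              nb_dispersion >= 0, mean_log_expr_sigma >= 0,
              n_triads >= 0, triad_corr_strength >= 0,
              triad_corr_strength <= 1, cis_fraction >= 0,
              cis_fraction <= 1, length(library_size_range) == 2L,
              all(library_size_range > 0),
              library_size_range[1] <= library_size_range[2],
              n_lncrna_decoys >= 0, n_background_edges >= 0,
              target_seq_length >= 50L, seed >= 0, seed < 2^31 - 100)
    if (n_triads > min(n_lncrna, n_mirna, n_mrna))
      stop("n_triads exceeds min(n_lncrna, n_mirna, n_mrna)")
  })
  structure(cfg, class = "sim_config")
}

child_seed <- function(seed, offset) (seed + offset) %% (2^31 - 1)

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

feature_ids <- function(cfg) {
  list(gene = sprintf("gene_%04d", seq_len(cfg$n_mrna)),
       lncrna = sprintf("lnc_%04d", seq_len(cfg$n_lncrna)),
       circrna = sprintf("circ_%04d", seq_len(cfg$n_circrna)),
       mirna = sprintf("mir_%03d", seq_len(cfg$n_mirna)),
       decoy = if (cfg$n_lncrna_decoys > 0)
         sprintf("lncdecoy_%02d", seq_len(cfg$n_lncrna_decoys))
       else character())
}

GENES_PER_CHROM <- 500L
GENE_SPACING <- 60000L   # leaves room for one cis lncRNA on each flank
CIS_GAP_MAX <- 9500L     # planted cis gaps stay below the 10 kb window
NONCIS_GAP_MIN <- 20000L # non-cis lncRNAs sit well past the 15 kb floor

#' Generate the synthetic genome annotation and truth ledger
#'
#' Lays out non-overlapping mRNA genes on synthetic chromosomes (fixed
#' 60 kb spacing), plants \code{cis_fraction} of the lncRNAs with a gap
#' uniform in [0, 9500] bp beside a host gene (at most two per gene, one
#' per flank) and the remaining lncRNAs at least 20 kb from any gene,
#' assigns every circRNA a host gene, places miRNA loci on their own
#' chromosome, and draws the planted differential-expression directions,
#' ceRNA triads and miRNA-target edges.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List with \code{annotation} (list of data.frames
#'   \code{transcripts}, \code{exons}, \code{genes}) and \code{truth}
#'   (planted DE directions, cis pairs with exact gaps, triads, target
#'   edges, decoys, the enriched term id and the term map).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_cis <- round(cfg$cis_fraction * cfg$n_lncrna)
  if (n_cis > 2L * cfg$n_mrna)
    stop("chromosome capacity insufficient: ", n_cis, " cis lncRNAs ",
         "requested but n_mrna = ", cfg$n_mrna,
         " genes host at most two each; increase n_mrna or lower ",
         "cis_fraction")
  ids <- feature_ids(cfg)
  with_seed(child_seed(cfg$seed, 1L), {
    tx <- list(); ex <- list()
    add_tx <- function(id, gene, biotype, chrom, strand, exon_starts,
                       exon_ends, host = NA_character_) {
      tx[[length(tx) + 1L]] <<- data.frame(
        transcript_id = id, gene_id = gene, biotype = biotype,
        chrom = chrom, strand = strand,
        start = min(exon_starts), end = max(exon_ends),
        length = sum(exon_ends - exon_starts + 1L),
        n_exons = length(exon_starts), host_gene = host,
        stringsAsFactors = FALSE)
      ex[[length(ex) + 1L]] <<- data.frame(
        transcript_id = id, exon_number = seq_along(exon_starts),
        start = exon_starts, end = exon_ends, stringsAsFactors = FALSE)
    }
    exon_layout <- function(start, exon_lens, intron_lens) {
      starts <- integer(length(exon_lens)); ends <- integer(length(exon_lens))
      pos <- start
      for (i in seq_along(exon_lens)) {
        starts[i] <- pos
        ends[i] <- pos + exon_lens[i] - 1L
        pos <- ends[i] + 1L + if (i < length(exon_lens)) intron_lens[i] else 0L
      }
      list(starts = starts, ends = ends)
    }

    # --- mRNA genes, one transcript each, fixed spacing -----------------
    gene_chrom <- paste0("chr",
                         (seq_len(cfg$n_mrna) - 1L) %/% GENES_PER_CHROM + 1L)
    gene_start <- integer(cfg$n_mrna); gene_end <- integer(cfg$n_mrna)
    gene_strand <- sample(c("+", "-"), cfg$n_mrna, replace = TRUE)
    cursor <- GENE_SPACING + 1L
    for (i in seq_len(cfg$n_mrna)) {
      if (i > 1L && gene_chrom[i] != gene_chrom[i - 1L])
        cursor <- GENE_SPACING + 1L
      n_e <- sample(3:10, 1L)
      lay <- exon_layout(cursor, sample(100:300, n_e, replace = TRUE),
                         sample(200:2000, max(n_e - 1L, 1L),
                                replace = TRUE))
      gene_start[i] <- lay$starts[1L]; gene_end[i] <- max(lay$ends)
      add_tx(sprintf("mrna_%04d", i), ids$gene[i], "mRNA", gene_chrom[i],
             gene_strand[i], lay$starts, lay$ends)
      cursor <- gene_end[i] + GENE_SPACING + 1L
    }

    # --- lncRNAs: cis beside a host gene, the rest far from all genes ---
    cis_lnc_idx <- sort(sample(cfg$n_lncrna, n_cis))
    cis_pairs <- list()
    tail_chrom <- gene_chrom[cfg$n_mrna]
    tail_cursor <- max(gene_end[gene_chrom == tail_chrom]) +
      NONCIS_GAP_MIN + 1L
    place_far <- function(span) {
      s <- tail_cursor
      tail_cursor <<- s + span + 30000L
      s
    }
    for (j in seq_len(cfg$n_lncrna)) {
      n_e <- sample(2:5, 1L)
      elens <- sample(150:600, n_e, replace = TRUE)
      ilens <- sample(100:500, max(n_e - 1L, 1L), replace = TRUE)
      span <- sum(elens) + sum(ilens[seq_len(n_e - 1L)])
      ci <- match(j, cis_lnc_idx)
      if (!is.na(ci)) {
        host <- (ci - 1L) %% cfg$n_mrna + 1L
        side <- if (ci <= cfg$n_mrna) "right" else "left"
        gap <- sample(0:CIS_GAP_MAX, 1L)
        start <- if (side == "right") gene_end[host] + gap + 1L
        else gene_start[host] - gap - span
        chrom <- gene_chrom[host]
        cis_pairs[[length(cis_pairs) + 1L]] <- data.frame(
          lncrna_id = ids$lncrna[j], gene_id = ids$gene[host],
          gap_bp = gap, stringsAsFactors = FALSE)
      } else {
        chrom <- tail_chrom
        start <- place_far(span)
      }
      lay <- exon_layout(start, elens, ilens)
      add_tx(ids$lncrna[j], paste0(ids$lncrna[j], "_g"), "lncRNA", chrom,
             sample(c("+", "-"), 1L), lay$starts, lay$ends)
    }

    # --- decoy lncRNA candidates violating the filters ------------------
    decoys <- data.frame(transcript_id = character(),
                         violation = character(), stringsAsFactors = FALSE)
    if (cfg$n_lncrna_decoys > 0) {
      kinds <- rep_len(c("short", "single_exon", "coding"),
                       cfg$n_lncrna_decoys)
      for (d in seq_len(cfg$n_lncrna_decoys)) {
        id <- ids$decoy[d]
        if (kinds[d] == "short") {
          elens <- c(90L, 80L)  # 170 bp total, below the 200 bp floor
          ilens <- 150L
        } else if (kinds[d] == "single_exon") {
          elens <- 800L
          ilens <- integer()
        } else {
          elens <- sample(200:400, 3L, replace = TRUE)
          ilens <- sample(100:500, 2L, replace = TRUE)
        }
        span <- sum(elens) + sum(ilens)
        lay <- exon_layout(place_far(span), elens,
                           if (length(ilens)) ilens else 1L)
        add_tx(id, paste0(id, "_g"), "lncRNA_candidate", tail_chrom, "+",
               lay$starts, lay$ends)
        decoys <- rbind(decoys, data.frame(transcript_id = id,
                                           violation = kinds[d],
                                           stringsAsFactors = FALSE))
      }
    }

    # --- circRNAs inside a host gene ------------------------------------
    circ_host <- sample(cfg$n_mrna, cfg$n_circrna, replace = TRUE)
    for (k in seq_len(cfg$n_circrna)) {
      h <- circ_host[k]
      span_h <- gene_end[h] - gene_start[h] + 1L
      clen <- min(sample(200:1000, 1L), span_h)
      off <- sample(0:(span_h - clen), 1L)
      s <- gene_start[h] + off
      add_tx(ids$circrna[k], paste0(ids$circrna[k], "_g"), "circRNA",
             gene_chrom[h], gene_strand[h], s, s + clen - 1L,
             host = ids$gene[h])
    }

    # --- miRNA loci on their own chromosome -----------------------------
    for (m in seq_len(cfg$n_mirna)) {
      s <- (m - 1L) * 1000L + 1L
      add_tx(ids$mirna[m], paste0(ids$mirna[m], "_g"), "miRNA", "chr_mir",
             "+", s, s + 21L)
    }

    transcripts <- do.call(rbind, tx)
    exons <- do.call(rbind, ex)
    mrna <- transcripts[transcripts$biotype == "mRNA", , drop = FALSE]
    genes <- data.frame(gene_id = mrna$gene_id, chrom = mrna$chrom,
                        strand = mrna$strand, start = mrna$start,
                        end = mrna$end, stringsAsFactors = FALSE)
    cis_pairs <- if (length(cis_pairs)) do.call(rbind, cis_pairs) else
      data.frame(lncrna_id = character(), gene_id = character(),
                 gap_bp = integer(), stringsAsFactors = FALSE)

    truth <- plant_truth(cfg, ids)
    truth$cis_pairs <- cis_pairs
    truth$decoys <- decoys
    list(annotation = list(transcripts = transcripts, exons = exons,
                           genes = genes),
         truth = truth)
  })
}

# draws planted DE directions, triads, target edges and the term map
# (called inside the seeded block of generate_annotation)
plant_truth <- function(cfg, ids) {
  triads <- data.frame(regulator_id = character(), mirna_id = character(),
                       mrna_id = character(), stringsAsFactors = FALSE)
  de <- list()
  mark_de <- function(feats, class, dirs) {
    de[[length(de) + 1L]] <<- data.frame(feature_id = feats, class = class,
                                         direction = dirs,
                                         stringsAsFactors = FALSE)
  }
  triad_dir <- character()
  if (cfg$n_triads > 0) {
    regs <- sample(ids$lncrna, cfg$n_triads)
    mirs <- sample(ids$mirna, cfg$n_triads)
    mrnas <- sample(ids$gene, cfg$n_triads)
    triad_dir <- sample(c("up", "down"), cfg$n_triads, replace = TRUE)
    triads <- data.frame(regulator_id = regs, mirna_id = mirs,
                         mrna_id = mrnas, stringsAsFactors = FALSE)
    mark_de(regs, "lncrna", triad_dir)
    mark_de(mrnas, "mrna", triad_dir)
    mark_de(mirs, "mirna", ifelse(triad_dir == "up", "down", "up"))
  }
  # frac_de plants background DE on top of the (always-DE) triad members
  fill_de <- function(universe, class, already) {
    extra <- round(cfg$frac_de * length(universe))
    if (extra <= 0) return()
    pool <- setdiff(universe, already)
    feats <- sample(pool, min(extra, length(pool)))
    mark_de(feats, class, sample(c("up", "down"), length(feats),
                                 replace = TRUE))
  }
  fill_de(ids$gene, "mrna", triads$mrna_id)
  fill_de(ids$lncrna, "lncrna", triads$regulator_id)
  fill_de(ids$mirna, "mirna", triads$mirna_id)
  fill_de(ids$circrna, "circrna", character())
  de <- if (length(de)) do.call(rbind, de) else
    data.frame(feature_id = character(), class = character(),
               direction = character(), stringsAsFactors = FALSE)

  # target edges: one per triad leg, plus random background edges among
  # features outside the triads (so planted sponge overlaps stay clean)
  edge <- function(m, t, cl) data.frame(mirna_id = m, target_id = t,
                                        target_class = cl,
                                        stringsAsFactors = FALSE)
  edges <- list()
  if (nrow(triads)) {
    edges[[1L]] <- edge(triads$mirna_id, triads$regulator_id, "lncRNA")
    edges[[2L]] <- edge(triads$mirna_id, triads$mrna_id, "mRNA")
  }
  if (cfg$n_background_edges > 0) {
    free_mir <- setdiff(ids$mirna, triads$mirna_id)
    targets <- data.frame(
      id = c(setdiff(ids$gene, triads$mrna_id),
             setdiff(ids$lncrna, triads$regulator_id), ids$circrna),
      stringsAsFactors = FALSE)
    targets$class <- c(
      rep("mRNA", length(setdiff(ids$gene, triads$mrna_id))),
      rep("lncRNA", length(setdiff(ids$lncrna, triads$regulator_id))),
      rep("circRNA", length(ids$circrna)))
    if (length(free_mir) && nrow(targets)) {
      mi <- sample(free_mir, cfg$n_background_edges, replace = TRUE)
      ti <- sample(nrow(targets), cfg$n_background_edges, replace = TRUE)
      bg <- edge(mi, targets$id[ti], targets$class[ti])
      edges[[length(edges) + 1L]] <- bg[!duplicated(
        bg[, c("mirna_id", "target_id")]), , drop = FALSE]
    }
  }
  target_edges <- if (length(edges)) do.call(rbind, edges) else
    edge(character(), character(), character())
  target_edges <- target_edges[!duplicated(
    target_edges[, c("mirna_id", "target_id")]), , drop = FALSE]
  rownames(target_edges) <- NULL

  # synthetic GO-like term map; TERM:0001 is planted as enriched in the
  # DE mRNA genes
  de_genes <- de$feature_id[de$class == "mrna"]
  terms <- sprintf("TERM:%04d", 1:25)
  tm <- list()
  hit1 <- ids$gene %in% de_genes &
    stats::runif(cfg$n_mrna) < 0.6
  hit1 <- hit1 | (!ids$gene %in% de_genes &
                    stats::runif(cfg$n_mrna) < 0.02)
  tm[[1L]] <- data.frame(gene_id = ids$gene[hit1],
                         term_id = rep(terms[1L], sum(hit1)),
                         stringsAsFactors = FALSE)
  for (t in 2:25) {
    hit <- stats::runif(cfg$n_mrna) < 0.05
    tm[[t]] <- data.frame(gene_id = ids$gene[hit],
                          term_id = rep(terms[t], sum(hit)),
                          stringsAsFactors = FALSE)
  }
  term_map <- do.call(rbind, tm)
  term_map$term_name <- paste0("synthetic term ",
                               sub("TERM:", "", term_map$term_id))
  term_map$category <- "BP"
  rownames(term_map) <- NULL

  list(de_features = de, triads = triads, target_edges = target_edges,
       enriched_term = terms[1L], term_map = term_map)
}

#' Simulate grouped NB count matrices for every RNA class
#'
#' Counts are negative binomial with per-feature log-normal baseline
#' means, scaled by per-sample nominal library sizes. Planted DE features
#' have the second group's mean multiplied by \code{2^(+/- de_log2fc)};
#' each planted triad owns a per-sample standard-normal latent factor
#' that shifts the log2 mean of its miRNA negatively and of its regulator
#' and mRNA positively, scaled by \code{triad_corr_strength}. circRNA
#' baselines are 20-fold lower than the other classes, reflecting sparse
#' back-splice junction coverage.
#'
#' @param annotation,truth from \code{\link{generate_annotation}}.
#' @param cfg the same \code{\link{sim_config}}.
#' @return Named list of \code{\link{rna_counts}} objects
#'   (\code{mrna}, \code{lncrna}, \code{circrna}, \code{mirna}) over
#'   samples PMM1..PMMn, SART1..SARTn with groups PMM/SART, plus
#'   attribute \code{"library_sizes"}.
#' @export
simulate_counts <- function(annotation, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tr <- annotation$transcripts
  known <- c(tr$transcript_id, tr$gene_id, annotation$genes$gene_id)
  bad <- setdiff(truth$de_features$feature_id, known)
  if (length(bad))
    stop("truth refers to features absent from the annotation: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  n <- cfg$n_per_group
  samples <- c(paste0("PMM", seq_len(n)), paste0("SART", seq_len(n)))
  groups <- stats::setNames(rep(c("PMM", "SART"), each = n), samples)

  class_ids <- list(
    mrna = annotation$genes$gene_id,
    lncrna = tr$transcript_id[tr$biotype == "lncRNA"],
    circrna = tr$transcript_id[tr$biotype == "circRNA"],
    mirna = tr$transcript_id[tr$biotype == "miRNA"])
  mrna_len <- stats::setNames(tr$length[tr$biotype == "mRNA"],
                              tr$gene_id[tr$biotype == "mRNA"])
  tx_len <- stats::setNames(tr$length, tr$transcript_id)
  class_len <- list(mrna = mrna_len[class_ids$mrna],
                    lncrna = tx_len[class_ids$lncrna],
                    circrna = tx_len[class_ids$circrna],
                    mirna = tx_len[class_ids$mirna])

  de_dir <- stats::setNames(truth$de_features$direction,
                            truth$de_features$feature_id)

  with_seed(child_seed(cfg$seed, 2L), {
    libs <- round(stats::runif(2L * n, cfg$library_size_range[1L],
                               cfg$library_size_range[2L]))
    names(libs) <- samples
    depth <- libs / mean(libs)
    # Gaussian-copula dependence for triad members: each triad owns a
    # per-sample standard-normal factor z; members mix z into their own
    # noise quantile with loading a = triad_corr_strength (negatively
    # for the miRNA), so pairwise latent correlation is +/- a^2 while
    # marginal counts remain exactly NB(mu, phi)
    a <- cfg$triad_corr_strength
    zt <- if (nrow(truth$triads))
      matrix(stats::rnorm(nrow(truth$triads) * 2L * n),
             nrow = nrow(truth$triads))
    else matrix(numeric(), nrow = 0L, ncol = 2L * n)
    mix_triad_factor <- function(feats, X) {
      if (!nrow(truth$triads) || a == 0) return(X)
      for (t in seq_len(nrow(truth$triads))) {
        row <- truth$triads[t, ]
        for (spec in list(c(row$regulator_id, 1), c(row$mrna_id, 1),
                          c(row$mirna_id, -1))) {
          i <- match(spec[1L], feats)
          if (!is.na(i))
            X[i, ] <- as.numeric(spec[2L]) * a * zt[t, ] +
              sqrt(1 - a^2) * X[i, ]
        }
      }
      X
    }
    triad_members <- unlist(truth$triads[, c("regulator_id", "mrna_id",
                                             "mirna_id")], use.names = FALSE)
    out <- list()
    for (cl in names(class_ids)) {
      feats <- class_ids[[cl]]
      base <- stats::rlnorm(length(feats),
                            cfg$mean_log_expr_mu -
                              if (cl == "circrna") log(20) else 0,
                            cfg$mean_log_expr_sigma)
      # ceRNA crosstalk concerns well-expressed transcripts; floor the
      # baseline of planted triad members at the median expression level
      base[feats %in% triad_members] <-
        pmax(base[feats %in% triad_members], exp(cfg$mean_log_expr_mu))
      dirs <- de_dir[feats]
      shift_de <- ifelse(is.na(dirs), 0,
                         ifelse(dirs == "up", cfg$de_log2fc,
                                -cfg$de_log2fc))
      log2mu <- outer(log2(base), rep(0, 2L * n), "+")
      log2mu[, (n + 1L):(2L * n)] <- log2mu[, (n + 1L):(2L * n)] + shift_de
      mu <- sweep(2^log2mu, 2L, depth, "*")
      X <- matrix(stats::rnorm(length(mu)), nrow = length(feats))
      X <- mix_triad_factor(feats, X)
      U <- pmin(stats::pnorm(X), 0.9999999999999999)
      counts <- matrix(
        if (cfg$nb_dispersion == 0) stats::qpois(U, mu)
        else stats::qnbinom(U, size = 1 / cfg$nb_dispersion, mu = mu),
        nrow = length(feats), dimnames = list(feats, samples))
      storage.mode(counts) <- "integer"
      out[[cl]] <- rna_counts(counts, groups, class_len[[cl]])
    }
    attr(out, "library_sizes") <- libs
    out
  })
}

#' Simulate miRNA and target sequences with planted seed sites
#'
#' Generates random-uniform miRNA sequences (RNA alphabet, 22 nt) and
#' random target DNA sequences for every feature appearing as a target in
#' the truth's edge table. Each planted edge receives at least one exact
#' 7mer site (the reverse complement of miRNA positions 2-8) at a
#' recorded 0-based position; background occurrences of a planted seed
#' elsewhere in the same target are scrubbed by a single-base change
#' where they do not overlap another planted site.
#'
#' @param truth truth ledger from \code{\link{generate_annotation}}.
#' @param cfg the same \code{\link{sim_config}}.
#' @param scrub_collisions disable to leave chance background matches in
#'   place (default TRUE).
#' @param target_ids ids to generate target sequences for; defaults to
#'   every feature appearing as a target in the truth's edge table.
#' @return List with \code{mirna_seqs} and \code{target_seqs} (named
#'   character vectors) and \code{seed_sites} (data.frame
#'   \code{mirna_id}, \code{target_id}, \code{pos}).
#' @export
simulate_sequences <- function(truth, cfg, scrub_collisions = TRUE,
                               target_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- feature_ids(cfg)
  L <- cfg$target_seq_length
  edges <- truth$target_edges
  if (is.null(target_ids)) target_ids <- unique(edges$target_id)
  target_ids <- sort(unique(c(target_ids, edges$target_id)))
  with_seed(child_seed(cfg$seed, 3L), {
    mirna_seqs <- vapply(ids$mirna, function(.)
      paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
            collapse = ""), character(1))
    target_seqs <- vapply(target_ids, function(.)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))

    seeds <- vapply(mirna_seqs, function(s) {
      s <- chartr("U", "T", s)
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(substr(s, 2L, 8L), "")[[1]]),
                   collapse = ""))
    }, character(1))

    sites <- list()
    if (nrow(edges)) {
      per_target <- split(seq_len(nrow(edges)), edges$target_id)
      for (t in names(per_target)) {
        rows <- per_target[[t]]
        need <- length(rows)
        if (L < 9L * need)
          stop("target sequences of length ", L, " are too short to ",
               "host ", need, " seed sites; increase target_seq_length")
        # non-overlapping 0-based slots for this target's sites
        slots <- sort(sample(seq_len(L %/% 9L) - 1L, need)) * 9L +
          sample(0:1, need, replace = TRUE)
        seq <- target_seqs[[t]]
        for (j in seq_along(rows)) {
          m <- edges$mirna_id[rows[j]]
          pos <- slots[j]
          substr(seq, pos + 1L, pos + 7L) <- seeds[[m]]
          sites[[length(sites) + 1L]] <- data.frame(
            mirna_id = m, target_id = t, pos = pos,
            stringsAsFactors = FALSE)
        }
        target_seqs[[t]] <- seq
      }
    }
    seed_sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(mirna_id = character(), target_id = character(),
                 pos = integer(), stringsAsFactors = FALSE)

    if (scrub_collisions && nrow(seed_sites)) {
      protected <- split(seed_sites$pos, seed_sites$target_id)
      for (i in seq_len(nrow(edges))) {
        t <- edges$target_id[i]
        pat <- seeds[[edges$mirna_id[i]]]
        planted <- seed_sites$pos[seed_sites$target_id == t &
                                    seed_sites$mirna_id ==
                                    edges$mirna_id[i]]
        keep_out <- protected[[t]]
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 50L) break
          hits <- find_all(pat, target_seqs[[t]])
          spurious <- setdiff(hits, planted)
          spurious <- spurious[vapply(spurious, function(p)
            all(abs(p - keep_out) > 6L), logical(1))]
          if (!length(spurious)) break
          p <- spurious[1L]
          base <- substr(target_seqs[[t]], p + 4L, p + 4L)
          repl <- setdiff(c("A", "C", "G", "T"), base)[1L]
          substr(target_seqs[[t]], p + 4L, p + 4L) <- repl
        }
      }
    }
    list(mirna_seqs = mirna_seqs, target_seqs = target_seqs,
         seed_sites = seed_sites)
  })
}

#' Generate the complete synthetic dataset
#'
#' Convenience wrapper running \code{\link{generate_annotation}},
#' \code{\link{simulate_counts}} and \code{\link{simulate_sequences}} and
#' folding the recorded seed-site positions into the truth ledger.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List with \code{cfg}, \code{annotation}, \code{truth},
#'   \code{counts} and \code{sequences}.
#' @export
simulate_dataset <- function(cfg) {
  ann <- generate_annotation(cfg)
  counts <- simulate_counts(ann$annotation, ann$truth, cfg)
  seqs <- simulate_sequences(ann$truth, cfg)
  truth <- ann$truth
  truth$seed_sites <- seqs$seed_sites
  list(cfg = cfg, annotation = ann$annotation, truth = truth,
       counts = counts, sequences = seqs)
}
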