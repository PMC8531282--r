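# Shared fixtures, generated once per test run and cached in-process.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small dataset for structural / unit checks (fast)
small_cfg <- function(...) {
  sim_config(n_mrna = 200L, n_lncrna = 60L, n_circrna = 30L,
             n_mirna = 40L, n_triads = 10L, n_background_edges = 50L,
             seed = 7L, ...)
}

small_sim <- function() cached("small_sim", simulate_dataset(small_cfg()))

# the default study-scale dataset (seed 1) and one full pipeline run on it
default_sim <- function() cached("default_sim",
                                 simulate_dataset(sim_config(seed = 1L)))

default_run <- function() cached("default_run", {
  sim <- default_sim()
  dir <- file.path(tempdir(), "cernaforge-default-fixture")
  write_fixture(sim, dir)
  cfg <- validate_config(file.path(dir, "config.yaml"))
  report <- suppressMessages(run_pipeline(cfg))
  list(sim = sim, dir = dir, outdir = cfg$outdir, report = report)
})

read_result <- function(run, file) {
  utils::read.delim(file.path(run$outdir, file), stringsAsFactors = FALSE)
}

# independent hypergeometric upper-tail oracle by subset enumeration
enum_hypergeom_sf <- function(k, N, K, n) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(subsets, 2L, function(s) sum(s %in% marked) >= k))
}

# independent two-sided binomial split oracle (phi = 0, equal groups)
enum_binomial_split <- function(s1, s2) {
  s <- s1 + s2
  if (s == 0) return(1)
  w <- choose(s, 0:s)
  sum(w[w <= w[s1 + 1] * (1 + 1e-12)]) / 2^s
}

# brute-force cis-pair oracle built on GenomicRanges
granges_cis_oracle <- function(lnc, genes, window) {
  gr_l <- GenomicRanges::GRanges(lnc$chrom,
                                 IRanges::IRanges(lnc$start, lnc$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  li <- rep(seq_len(nrow(lnc)), times = nrow(genes))
  gi <- rep(seq_len(nrow(genes)), each = nrow(lnc))
  d <- suppressWarnings(GenomicRanges::distance(gr_l[li], gr_g[gi]))
  keep <- !is.na(d) & d <= window & lnc$id[li] != genes$id[gi]
  out <- data.frame(lncrna_id = lnc$id[li][keep],
                    gene_id = genes$id[gi][keep],
                    gap_bp = d[keep], stringsAsFactors = FALSE)
  out[order(out$lncrna_id, out$gap_bp, out$gene_id), , drop = FALSE]
}

# run DE + correlation gates + sponge on in-memory counts; used for the
# end-to-end audit and the permutation null
triads_from_counts <- function(counts, edges, universe,
                               p_de = 0.05, lfc = 1, scc = -0.7,
                               pcc = 0.9, sponge_p = 0.05) {
  de <- lapply(counts, function(x) filter_de(exact_nb_test(x), p_de, lfc))
  expr <- list(mrna = fpkm_normalize(counts$mrna),
               lncrna = fpkm_normalize(counts$lncrna),
               mirna = cpm_normalize(counts$mirna))
  keep <- function(cl) {
    ids <- intersect(rownames(expr[[cl]]), c(de[[cl]]$up, de[[cl]]$down))
    expr[[cl]][ids, , drop = FALSE]
  }
  e_mir <- keep("mirna"); e_lnc <- keep("lncrna"); e_mrna <- keep("mrna")
  edges_de <- edges[edges$mirna_id %in% rownames(e_mir), , drop = FALSE]
  neg <- rbind(negative_pairs(e_mir, e_lnc, edges_de, scc),
               negative_pairs(e_mir, e_mrna, edges_de, scc))
  neg_l <- neg[neg$target_id %in% rownames(e_lnc), , drop = FALSE]
  neg_m <- neg[neg$target_id %in% rownames(e_mrna), , drop = FALSE]
  cand <- merge(neg_l[, 1:2], neg_m[, 1:2], by = "mirna_id",
                suffixes = c("_reg", "_mrna"))
  cand <- unique(data.frame(regulator_id = cand$target_id_reg,
                            mrna_id = cand$target_id_mrna,
                            stringsAsFactors = FALSE))
  coexp <- coexpressed_pairs(e_lnc, e_mrna, cand, pcc)
  build_triads(neg, coexp, edges, universe, sponge_p)
}

triad_key <- function(df)
  paste(df$regulator_id, df$mirna_id, df$mrna_id)

# permutation null: shuffle the sample labels of every RNA class
# independently, destroying the cross-class sample alignment that the
# correlation gates rely on
shuffle_samples <- function(counts) {
  lapply(counts, function(x) {
    m <- x$counts[, sample(ncol(x$counts)), drop = FALSE]
    colnames(m) <- colnames(x$counts)
    rna_counts(m, x$groups, x$lengths)
  })
}
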