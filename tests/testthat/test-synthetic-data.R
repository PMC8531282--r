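test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_triads = 50, n_mirna = 40, n_lncrna = 60,
                          n_mrna = 200), "n_triads")
  expect_error(sim_config(frac_de = 1.5))
  expect_error(sim_config(nb_dispersion = -1))
  expect_error(
    generate_annotation(sim_config(n_mrna = 5, n_lncrna = 40,
                                   cis_fraction = 1, n_triads = 0,
                                   n_mirna = 10, n_circrna = 5)),
    "capacity")
})

test_that("cis placements respect the planted gap bands", {
  cfg_all <- small_cfg(cis_fraction = 1)
  ann <- generate_annotation(cfg_all)
  expect_equal(nrow(ann$truth$cis_pairs), cfg_all$n_lncrna)
  expect_true(all(ann$truth$cis_pairs$gap_bp <= 9500))

  cfg_none <- small_cfg(cis_fraction = 0)
  ann0 <- generate_annotation(cfg_none)
  expect_equal(nrow(ann0$truth$cis_pairs), 0L)
  tr <- ann0$annotation$transcripts
  lnc <- tr[tr$biotype == "lncRNA", ]
  lnc$id <- lnc$transcript_id
  expect_equal(nrow(assign_cis_targets(lnc, ann0$annotation$genes)), 0L)
})

test_that("generation is byte-deterministic given the seed", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_fixture(simulate_dataset(cfg), d1)
  write_fixture(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("counts follow the planted NB model", {
  # Poisson limit: dispersion 0, constant library sizes, variance ~ mean
  cfg <- sim_config(n_mrna = 300L, n_lncrna = 20L, n_circrna = 5L,
                    n_mirna = 10L, n_triads = 0L, frac_de = 0,
                    nb_dispersion = 0, n_per_group = 50L,
                    library_size_range = c(1e6L, 1e6L), seed = 11L)
  sim <- simulate_dataset(cfg)
  m <- sim$counts$mrna$counts
  mu <- rowMeans(m)
  ratio <- apply(m, 1L, var) / pmax(mu, 1e-9)
  expect_gt(mean(ratio > 0.5 & ratio < 2), 0.95)

  # NB moments: var ~ mu + phi mu^2 within 20% per abundance stratum
  cfg2 <- sim_config(n_mrna = 2000L, n_lncrna = 20L, n_circrna = 5L,
                     n_mirna = 10L, n_triads = 0L, frac_de = 0,
                     nb_dispersion = 0.1, n_per_group = 100L,
                     library_size_range = c(1e6L, 1e6L), seed = 12L)
  sim2 <- simulate_dataset(cfg2)
  m2 <- sim2$counts$mrna$counts
  mu2 <- rowMeans(m2); v2 <- apply(m2, 1L, var)
  strata <- cut(log10(pmax(mu2, 1)), breaks = c(0, 1.5, 2.5, Inf))
  for (s in levels(strata)) {
    i <- which(strata == s & mu2 > 5)
    if (length(i) < 20) next
    obs <- mean(v2[i]); expd <- mean(mu2[i] + 0.1 * mu2[i]^2)
    expect_lt(abs(obs / expd - 1), 0.2, label = paste("stratum", s))
  }
})

test_that("planted DE features show the requested fold change", {
  cfg <- sim_config(n_mrna = 400L, n_lncrna = 20L, n_circrna = 5L,
                    n_mirna = 10L, n_triads = 0L, de_log2fc = 2,
                    n_per_group = 50L, seed = 13L)
  sim <- simulate_dataset(cfg)
  de <- sim$truth$de_features
  up <- de$feature_id[de$class == "mrna" & de$direction == "up"]
  m <- sim$counts$mrna$counts
  gc <- split(seq_along(sim$counts$mrna$groups), sim$counts$mrna$groups)
  lfc <- log2(rowMeans(m[up, gc$SART]) / rowMeans(m[up, gc$PMM]))
  expect_true(all(abs(lfc - 2) < 0.5))
})

test_that("triad members are negatively correlated through the shared factor", {
  cfg <- sim_config(n_mrna = 300L, n_lncrna = 60L, n_circrna = 5L,
                    n_mirna = 40L, n_triads = 20L,
                    triad_corr_strength = 0.9, n_per_group = 50L,
                    seed = 14L)
  sim <- simulate_dataset(cfg)
  tri <- sim$truth$triads
  sccs <- vapply(seq_len(nrow(tri)), function(i) {
    cor(sim$counts$mirna$counts[tri$mirna_id[i], ],
        sim$counts$mrna$counts[tri$mrna_id[i], ], method = "spearman")
  }, numeric(1))
  expect_gte(mean(sccs < 0), 0.9)
})

test_that("planted seed sites are present and truth survives a round trip", {
  sim <- small_sim()
  edges <- sim$truth$target_edges
  sites <- sim$truth$seed_sites
  # every edge has at least one recorded site at the recorded position
  expect_true(all(paste(edges$mirna_id, edges$target_id) %in%
                    paste(sites$mirna_id, sites$target_id)))
  for (i in seq_len(min(25L, nrow(sites)))) {
    m <- chartr("Uu", "Tt", sim$sequences$mirna_seqs[[sites$mirna_id[i]]])
    seed7 <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(substr(m, 2, 8), "")[[1]]),
                          collapse = ""))
    found <- substr(sim$sequences$target_seqs[[sites$target_id[i]]],
                    sites$pos[i] + 1L, sites$pos[i] + 7L)
    expect_identical(found, seed7)
  }

  d <- file.path(tempdir(), "truth-rt")
  write_fixture(sim, d)
  truth2 <- read_truth(file.path(d, "truth.json"))
  for (nm in c("de_features", "cis_pairs", "triads", "target_edges",
               "seed_sites")) {
    expect_equal(as.data.frame(truth2[[nm]]),
                 as.data.frame(sim$truth[[nm]]), label = nm)
  }
  unlink(d, recursive = TRUE)
})

test_that("fixture files round-trip through the readers", {
  sim <- small_sim()
  d <- file.path(tempdir(), "fixture-rt")
  write_fixture(sim, d)
  g <- sim$counts$mrna$groups
  back <- read_counts(file.path(d, "counts_mrna.tsv"), g)
  expect_identical(back$counts, sim$counts$mrna$counts)

  ann <- read_annotation(file.path(d, "annotation.gtf"))
  orig <- sim$annotation$transcripts
  reread <- ann$transcripts[match(orig$transcript_id,
                                  ann$transcripts$transcript_id), ]
  expect_equal(reread$n_exons, orig$n_exons)
  expect_equal(reread$length, orig$length)
  expect_equal(reread$start, orig$start)
  expect_equal(reread$host_gene, orig$host_gene)

  expect_identical(read_fasta(file.path(d, "mirnas.fa")),
                   sim$sequences$mirna_seqs)
  unlink(d, recursive = TRUE)
})
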