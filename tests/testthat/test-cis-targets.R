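loci <- function(id, chrom, start, end, strand = "+")
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)

test_that("gap arithmetic follows the 1-based inclusive convention", {
  gene <- loci("g", "chr1", 5000, 8000)
  # 17000 - 8000 - 1 = 8999 <= 10000 -> pair
  p1 <- assign_cis_targets(loci("l", "chr1", 17000, 17500), gene)
  expect_equal(p1$gap_bp, 8999L)
  expect_equal(p1$relpos, "downstream")
  # 18500 - 8000 - 1 = 10499 -> no pair
  expect_equal(nrow(assign_cis_targets(loci("l", "chr1", 18500, 19000),
                                       gene)), 0L)
  # overlap -> gap 0, relpos overlapping
  p3 <- assign_cis_targets(loci("l", "chr1", 7000, 9000), gene)
  expect_equal(p3$gap_bp, 0L)
  expect_equal(p3$relpos, "overlapping")
  # boundary: gap exactly 10000 is inside the window (inclusive)
  p4 <- assign_cis_targets(loci("l", "chr1", 18001, 18400), gene)
  expect_equal(p4$gap_bp, 10000L)
  p5 <- assign_cis_targets(loci("l", "chr1", 18002, 18400), gene)
  expect_equal(nrow(p5), 0L)
  # strand flips the relative-position label, not eligibility
  p6 <- assign_cis_targets(loci("l", "chr1", 17000, 17500),
                           loci("g", "chr1", 5000, 8000, "-"))
  expect_equal(p6$relpos, "upstream")
  # different chromosome never pairs
  expect_warning(
    p7 <- assign_cis_targets(loci("l", "chr9", 5000, 5400), gene),
    "without any gene")
  expect_equal(nrow(p7), 0L)
})

test_that("random annotations agree with the GenomicRanges oracle", {
  set.seed(31)
  for (rep in 1:50) {
    n_l <- sample(5:40, 1); n_g <- sample(5:60, 1)
    chroms <- paste0("chr", 1:3)
    lnc <- loci(paste0("L", seq_len(n_l)),
                sample(chroms, n_l, TRUE),
                s <- sample.int(200000, n_l), s + sample.int(5000, n_l))
    gen <- loci(paste0("G", seq_len(n_g)),
                sample(chroms, n_g, TRUE),
                s2 <- sample.int(200000, n_g), s2 + sample.int(20000, n_g))
    win <- sample(c(1000L, 10000L, 50000L), 1)
    mine <- assign_cis_targets(lnc, gen, win)
    oracle <- granges_cis_oracle(lnc, gen, win)
    expect_equal(mine[, c("lncrna_id", "gene_id", "gap_bp")],
                 oracle, ignore_attr = TRUE)
  }
})

test_that("enlarging the window never removes a pair", {
  set.seed(32)
  lnc <- loci(paste0("L", 1:30), "chr1",
              s <- sample.int(500000, 30), s + 1000)
  gen <- loci(paste0("G", 1:30), "chr1",
              s2 <- sample.int(500000, 30), s2 + 5000)
  prev <- character()
  for (win in c(0, 1000, 10000, 100000)) {
    cur <- with(assign_cis_targets(lnc, gen, win),
                paste(lncrna_id, gene_id))
    expect_true(all(prev %in% cur), label = paste("window", win))
    prev <- cur
  }
})

test_that("planted cis pairs are recovered exactly on the fixture", {
  sim <- small_sim()
  tr <- sim$annotation$transcripts
  lnc <- tr[tr$biotype == "lncRNA", ]
  lnc$id <- lnc$transcript_id
  got <- assign_cis_targets(lnc, sim$annotation$genes, 10000L)
  truth <- sim$truth$cis_pairs
  expect_setequal(paste(got$lncrna_id, got$gene_id, got$gap_bp),
                  paste(truth$lncrna_id, truth$gene_id, truth$gap_bp))
})

test_that("the cis network keeps only doubly-DE pairs with directions", {
  pairs <- data.frame(lncrna_id = c("l1", "l2", "l3"),
                      gene_id = c("g1", "g2", "g3"),
                      gap_bp = c(0L, 100L, 4000L),
                      relpos = c("overlapping", "upstream", "downstream"))
  de_l <- list(up = c("l1"), down = c("l3"), not_de = "l2")
  de_g <- list(up = c("g3"), down = character(), not_de = c("g1", "g2"))
  net <- de_cis_network(pairs, de_l, de_g)
  expect_equal(nrow(net), 1L)
  expect_equal(net$lncrna_id, "l3")
  expect_equal(net$lncrna_direction, "down")
  expect_equal(net$gene_direction, "up")
  # degenerate: empty DE sets give an empty but well-formed table
  empty <- de_cis_network(pairs, list(up = character(), down = character()),
                          de_g)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("lncrna_direction", "gene_direction") %in%
                    names(empty)))
})
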