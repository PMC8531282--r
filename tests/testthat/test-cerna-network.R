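# expression rows whose log2(x+1) equal the given vectors exactly
expr_from_log <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(v) 2^v - 1))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("negative pairs use average-rank Spearman with a strict gate", {
  e_mir <- expr_from_log(list(m1 = c(1, 2, 3, 4, 5, 6, 7, 8)))
  e_tgt <- expr_from_log(list(
    rev = c(8, 7, 6, 5, 4, 3, 2, 1),     # SCC -1
    tied = c(3, 2, 2, 1, 0, -1, -2, -3)))
  edges <- data.frame(mirna_id = "m1", target_id = c("rev", "tied"))
  res <- negative_pairs(e_mir, e_tgt, edges)
  expect_setequal(res$target_id, c("rev", "tied"))
  expect_equal(res$scc[res$target_id == "rev"], -1)

  # tied data: x = (1,2,2,3) vs y = (3,2,2,1) -> average ranks reverse
  e_mir2 <- expr_from_log(list(m1 = c(1, 2, 2, 3)))
  e_tgt2 <- expr_from_log(list(t1 = c(3, 2, 2, 1)))
  res2 <- negative_pairs(e_mir2, e_tgt2,
                         data.frame(mirna_id = "m1", target_id = "t1"))
  expect_equal(res2$scc, -1)

  # SCC exactly -0.7 is dropped: ranks (1..5) vs (3,5,4,2,1)
  e_mir3 <- expr_from_log(list(m1 = 1:5))
  e_tgt3 <- expr_from_log(list(t1 = c(3, 5, 4, 2, 1)))
  edge3 <- data.frame(mirna_id = "m1", target_id = "t1")
  expect_equal(cor(1:5, c(3, 5, 4, 2, 1), method = "spearman"), -0.7)
  expect_equal(nrow(negative_pairs(e_mir3, e_tgt3, edge3)), 0L)
  # ... and a slightly stronger reversal is kept (SCC -0.9)
  e_tgt3b <- expr_from_log(list(t1 = c(4, 5, 3, 2, 1)))
  expect_equal(nrow(negative_pairs(e_mir3, e_tgt3b, edge3)), 1L)

  # non-edges are never tested
  res4 <- negative_pairs(e_mir, e_tgt,
                         data.frame(mirna_id = "m1", target_id = "rev"))
  expect_equal(res4$target_id, "rev")
})

test_that("coexpressed pairs use a strict Pearson gate", {
  e_reg <- expr_from_log(list(r1 = c(1, 2, 3, 4, 5)))
  # centered integer construction: PCC exactly 9/10
  e_mrna <- expr_from_log(list(same = c(1, 2, 3, 4, 5),
                               edge = c(2, 1, 3, 4, 5),
                               anti = c(5, 4, 3, 2, 1)))
  expect_equal(cor(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5)), 0.9)
  res <- coexpressed_pairs(e_reg, e_mrna)
  expect_equal(res$mrna_id, "same")   # PCC 1 kept, 0.9 and -1 dropped
  expect_equal(res$pcc, 1)
})

test_that("degenerate correlation inputs fail loudly or warn", {
  e_a <- expr_from_log(list(a = c(1, 2)))
  e_b <- expr_from_log(list(b = c(2, 1)))
  expect_error(
    negative_pairs(e_a, e_b, data.frame(mirna_id = "a", target_id = "b")),
    "3 shared samples")
  e_c <- expr_from_log(list(a = c(1, 2, 3, 4)))
  e_flat <- expr_from_log(list(b = c(2, 2, 2, 2)))
  expect_warning(
    res <- negative_pairs(e_c, e_flat,
                          data.frame(mirna_id = "a", target_id = "b")),
    "constant")
  expect_equal(nrow(res), 0L)
})

test_that("sponge test counts shared miRNAs within the universe", {
  universe <- paste0("m", 1:10)
  edges <- data.frame(
    mirna_id = c(paste0("m", 1:5), paste0("m", 1:5)),
    target_id = rep(c("L", "G"), each = 5))
  res <- sponge_test("L", "G", edges, universe)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 5L, K = 5L, n = 5L, N = 10L),
               ignore_attr = TRUE)
  expect_equal(res$pvalue, 1 / 252, tolerance = 1e-12)

  edges2 <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4", "m1", "m2", "m3", "m9", "m10"),
    target_id = c(rep("L", 4), rep("G", 5)))
  res2 <- sponge_test("L", "G", edges2, universe)
  expect_equal(res2$k, 3L)
  expect_equal(res2$pvalue, 66 / 252, tolerance = 1e-12)

  # no shared miRNA is never significant
  edges3 <- data.frame(mirna_id = c("m1", "m2"),
                       target_id = c("L", "G"))
  expect_equal(sponge_test("L", "G", edges3, universe)$pvalue, 1)
  # miRNAs outside the universe are ignored
  edges4 <- rbind(edges2, data.frame(mirna_id = "alien",
                                     target_id = c("L", "G")))
  expect_equal(sponge_test("L", "G", edges4, universe)$k, 3L)
  expect_error(sponge_test("L", "G", edges2, character()), "universe")
})

test_that("triads require all three gates and the sponge test", {
  neg <- data.frame(mirna_id = c("m1", "m1", "m2"),
                    target_id = c("L", "G", "L"),
                    scc = c(-0.95, -0.9, -0.8), n = 8L)
  coexp <- data.frame(regulator_id = "L", mrna_id = "G", pcc = 0.97,
                      n = 8L)
  universe <- paste0("m", 1:25)
  edges <- data.frame(mirna_id = c("m1", "m1"),
                      target_id = c("L", "G"))
  tri <- build_triads(neg, coexp, edges, universe)
  expect_equal(nrow(tri), 1L)   # only m1 targets both L and G
  expect_equal(tri$mirna_id, "m1")
  expect_equal(tri$scc_mi_regulator, -0.95)
  expect_equal(tri$scc_mi_mrna, -0.9)
  expect_equal(tri$sponge_p, 1 / 25, tolerance = 1e-12)

  # insignificant sponge excludes the triad: one shared miRNA out of a
  # universe of 10 gives p = 1/10 > 0.05
  tri2 <- build_triads(neg, coexp, edges, paste0("m", 1:10))
  expect_equal(nrow(tri2), 0L)

  # direction consistency is annotated, never filtered
  dirs <- c(L = "up", G = "up", m1 = "down")
  tri3 <- build_triads(neg, coexp, edges, universe, directions = dirs)
  expect_true(tri3$direction_consistent)
  dirs2 <- c(L = "up", G = "down", m1 = "down")
  tri4 <- build_triads(neg, coexp, edges, universe, directions = dirs2)
  expect_equal(nrow(tri4), 1L)
  expect_false(tri4$direction_consistent)
})

test_that("emitted triads survive an independent re-check from raw inputs", {
  run <- default_run()
  sim <- run$sim
  tri <- read_result(run, "triads.tsv")
  expect_gt(nrow(tri), 0)
  expr <- list(mrna = fpkm_normalize(sim$counts$mrna),
               lncrna = fpkm_normalize(sim$counts$lncrna),
               mirna = cpm_normalize(sim$counts$mirna))
  lx <- function(cl, id) log2(expr[[cl]][id, ] + 1)
  edges <- sim$truth$target_edges
  ekey <- paste(edges$mirna_id, edges$target_id)
  for (i in seq_len(nrow(tri))) {
    r <- tri$regulator_id[i]; m <- tri$mirna_id[i]; g <- tri$mrna_id[i]
    expect_lt(cor(lx("mirna", m), lx("lncrna", r), method = "spearman"),
              -0.7)
    expect_lt(cor(lx("mirna", m), lx("mrna", g), method = "spearman"),
              -0.7)
    expect_gt(cor(lx("lncrna", r), lx("mrna", g)), 0.9)
    expect_lt(tri$sponge_p[i], 0.05)
    expect_true(all(paste(m, c(r, g)) %in% ekey))
  }
})

test_that("network exports round-trip", {
  tri <- data.frame(regulator_id = "L1", mirna_id = "m1", mrna_id = "G1",
                    scc_mi_regulator = -0.9, scc_mi_mrna = -0.85,
                    pcc_regulator_mrna = 0.95, sponge_k = 1L,
                    sponge_K = 1L, sponge_n = 1L, sponge_N = 40L,
                    sponge_p = 0.025)
  cls <- c(L1 = "lncRNA", m1 = "miRNA", G1 = "mRNA")
  dirs <- c(L1 = "up", m1 = "down", G1 = "up")
  net <- cerna_network(tri, classes = cls, directions = dirs)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 4L)  # 2 targets + coexpressed + sponges

  d <- tempfile(); dir.create(d)
  sif <- file.path(d, "net.sif")
  export_network(net, sif, "SIF")
  lines <- readLines(sif)
  expect_equal(length(lines), 4L)
  expect_identical(lines, sort(lines))  # stable ordering
  back_sif <- import_network(sif, "SIF")
  expect_equal(back_sif$edges[, c("source", "relation", "target")],
               net$edges[, c("source", "relation", "target")])

  gml <- file.path(d, "net.graphml")
  export_network(net, gml, "GraphML")
  back <- import_network(gml, "GraphML")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)

  tsv <- file.path(d, "net.tsv")
  export_network(net, tsv, "TSV")
  back2 <- import_network(tsv, "TSV")
  expect_equal(back2$nodes, net$nodes)
  expect_equal(back2$edges, net$edges)

  # empty network still writes valid documents
  enet <- cerna_network(NULL)
  export_network(enet, sif, "SIF")
  expect_equal(nrow(import_network(sif, "SIF")$edges), 0L)
  export_network(enet, tsv, "TSV")
  expect_equal(nrow(import_network(tsv, "TSV")$edges), 0L)

  expect_error(export_network(net, sif, "gexf"), "format")
  unlink(d, recursive = TRUE)
})
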