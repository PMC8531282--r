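make_counts <- function(m, n_per_group = NULL, lengths = NULL) {
  m <- as.matrix(m)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m)))
    rownames(m) <- paste0("f", seq_len(nrow(m)))
  n <- if (is.null(n_per_group)) ncol(m) / 2 else n_per_group
  rna_counts(m, rep(c("g1", "g2"), c(n, ncol(m) - n)), lengths)
}

test_that("FPKM follows the defining formula and conserves totals", {
  # count 10, length 1 kb, 1e6 total -> FPKM 10
  m <- matrix(c(10, 999990), ncol = 1,
              dimnames = list(c("a", "b"), "s1"))
  m <- cbind(m, s2 = c(10, 999990))
  x <- rna_counts(m, c("g1", "g2"), lengths = c(a = 1000, b = 99999))
  expect_equal(fpkm_normalize(x)["a", "s1"], 10)

  # all-zero feature stays zero
  set.seed(42)
  m <- matrix(rpois(400, 50), nrow = 50)
  m[7, ] <- 0
  x <- make_counts(m, 4, lengths = setNames(sample(200:5000, 50),
                                            paste0("f", 1:50)))
  f <- fpkm_normalize(x)
  expect_true(all(f[7, ] == 0))

  # conservation: sum_f FPKM * L * T / 1e9 == T
  totals <- colSums(x$counts)
  back <- colSums(f * x$lengths) * totals / 1e9
  expect_equal(unname(back), unname(totals), tolerance = 1e-12)

  expect_error(fpkm_normalize(make_counts(m, 4)), "lengths")
  m0 <- m; m0[, 3] <- 0
  expect_error(fpkm_normalize(make_counts(m0, 4, lengths = x$lengths)),
               "s3")
})

test_that("sample correlation is symmetric with unit diagonal", {
  set.seed(5)
  e <- matrix(rexp(300, 0.01), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  e <- cbind(e, d = e[, "a"])  # duplicated sample
  cc <- sample_correlation(e, "pearson")
  expect_identical(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_equal(cc["a", "d"], 1)
  expect_true(all(cc >= -1 & cc <= 1))

  # anti-linear on the log scale -> exactly -1
  l1 <- log2(e[, "a"] + 1)
  anti <- 2^(max(l1) + min(l1) - l1) - 1
  cc2 <- sample_correlation(cbind(e[, "a", drop = FALSE], neg = anti))
  expect_equal(cc2["a", "neg"], -1)

  # constant sample -> NA with warning, not an error
  e2 <- cbind(e[, 1:2], flat = rep(3, 100))
  expect_warning(cc3 <- sample_correlation(e2), "flat")
  expect_true(is.na(cc3["a", "flat"]))
  expect_equal(cc3["flat", "flat"], 1)
})

test_that("exact NB test matches its symmetry and degenerate cases", {
  # identical counts in both groups: lfc 0, p 1
  m <- matrix(rep(c(5, 9, 40), 4), nrow = 3)
  res <- exact_nb_test(make_counts(m, 2), dispersion = 0.1)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3), tolerance = 1e-12)

  # label swap: p invariant, lfc negates
  set.seed(8)
  m <- matrix(rnbinom(80, mu = 60, size = 10), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  x <- make_counts(m, 4)
  swapped <- rna_counts(m[, c(5:8, 1:4)],
                        rep(c("g1", "g2"), each = 4))
  r1 <- exact_nb_test(x, 0.1)
  r2 <- exact_nb_test(swapped, 0.1)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)

  expect_error(exact_nb_test(x, -0.5), "dispersion")
})

test_that("dispersion-zero limit agrees with the binomial oracle", {
  # 10 vs 0 with one sample per group: p = 2/1024
  m <- matrix(c(10, 0, 0, 10), nrow = 2,
              dimnames = list(c("hit", "bal"), c("s1", "s2")))
  res <- exact_nb_test(rna_counts(m, c("g1", "g2")), dispersion = 0)
  expect_equal(res$pvalue[1], 2 / 1024, tolerance = 1e-12)

  # grid of splits with total <= 30 against enumeration
  for (s1 in c(0, 1, 3, 7, 12, 15)) {
    for (s2 in c(0, 2, 5, 11, 15)) {
      M <- 40L
      m <- matrix(c(s1, M - s1, s2, M - s2), nrow = 2,
                  dimnames = list(c("hit", "bal"), c("s1", "s2")))
      res <- exact_nb_test(rna_counts(m, c("g1", "g2")), dispersion = 0)
      expect_equal(res$pvalue[1], enum_binomial_split(s1, s2),
                   tolerance = 1e-10,
                   label = sprintf("split %d vs %d", s1, s2))
    }
  }
})

test_that("the DE filter applies strict p and inclusive fold change", {
  rec <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    log2fc = c(2, 1.0, -0.99, -1.3, 0.2),
    pvalue = c(0.05, 0.01, 0.01, 0.003, 0.5))
  part <- filter_de(rec)
  expect_identical(part$up, "b")        # p 0.01, lfc exactly 1.0 inclusive
  expect_identical(part$down, "d")
  expect_true(all(c("a", "c", "e") %in% part$not_de))  # p = 0.05 strict
  expect_setequal(c(part$up, part$down, part$not_de), rec$feature_id)
  tab <- part$table
  expect_identical(tab$significant,
                   tab$pvalue < 0.05 & abs(tab$log2fc) >= 1)
})

test_that("presence partition conserves totals", {
  m <- rbind(only1 = c(3, 1, 0, 0), both = c(0, 2, 5, 0),
             only2 = c(0, 0, 0, 9), nowhere = c(0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  pp <- presence_partition(rna_counts(m, c("g1", "g1", "g2", "g2")))
  expect_equal(unname(pp$counts["g1_specific"]), 1)
  expect_equal(unname(pp$counts["g2_specific"]), 1)
  expect_equal(unname(pp$counts["shared"]), 1)
  expect_equal(unname(pp$counts["total_expressed"]), 3)
  expect_identical(unname(pp$assignment),
                   c("g1", "both", "g2", "none"))
})

test_that("planted DE is recovered with controlled error on the fixture", {
  sim <- default_sim()
  res <- exact_nb_test(sim$counts$mrna)
  part <- filter_de(res)
  truth <- sim$truth$de_features
  true_ids <- truth$feature_id[truth$class == "mrna"]
  called <- c(part$up, part$down)
  sens <- mean(true_ids %in% called)
  fdr <- mean(!called %in% true_ids)
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.2)
  # planted directions match called directions (up = higher in group 2)
  dirs <- setNames(truth$direction, truth$feature_id)
  hit_up <- intersect(part$up, true_ids)
  expect_true(all(dirs[hit_up] == "up"))
})
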