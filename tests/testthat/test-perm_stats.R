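test_that("Mann-Whitney U, exact enumeration and identities", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)           # 2/20 over all C(6,3) assignments
  expect_equal(mw$method, "exact")
  tie <- mann_whitney(5, 5)
  expect_equal(tie$U, 0.5)
  expect_equal(tie$p, 1)
  ## U_x + U_y = n_x n_y
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U,
                 length(x) * length(y))
  }
  ## enumeration agrees with the independent oracle, ties included
  set.seed(42)
  for (i in 1:8) {
    x <- sample(1:5, 4, replace = TRUE); y <- sample(2:6, 5, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(mann_whitney(x, y, method = "exact")$p,
                 enum_mw_pvalue(x, y))
    expect_equal(mann_whitney(x, y, alternative = "less", method = "exact")$p,
                 enum_mw_pvalue(x, y, "less"))
  }
})

test_that("normal approximation tracks the exact Mann-Whitney p for small n", {
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, sample(c(0, 1.5), 1))
    pe <- mann_whitney(x, y, method = "exact")$p
    pn <- mann_whitney(x, y, method = "normal")$p
    expect_equal(pn, pe, tolerance = 0.12)  # documented approximation error
    expect_equal(mann_whitney(x, y, method = "exact")$U,
                 mann_whitney(x, y, method = "normal")$U)
  }
})

test_that("variance permutation test: degenerate and exhaustive toy instances", {
  flat <- variance_permutation_test(list(A = c(1, 1), B = 1), seed = 1L)
  expect_equal(flat$observed, 0)
  expect_true(all(flat$null_values == 0))
  expect_equal(flat$p_value, 1)
  ## {A: [0]}, {B: [2,4]}: 3 count-preserving assignments
  toy <- variance_permutation_test(list(A = 0, B = c(2, 4)), seed = 1L)
  expect_equal(toy$method, "exhaustive")
  expect_equal(toy$observed, 4.5)
  expect_equal(sort(toy$null_values), c(0, 4.5, 4.5))
  expect_equal(toy$p_value, (1 + 2) / (3 + 1))
  expect_equal(c(toy$null_min, toy$null_max), c(0, 4.5))
})

test_that("variance test p is invariant to locus relabeling and affine transforms", {
  set.seed(44)
  dat <- lapply(1:6, function(i) rnorm(4, mean = i %% 2))
  names(dat) <- paste0("L", 1:6)
  r1 <- variance_permutation_test(dat, n_perm = 300L, seed = 9L)
  r2 <- variance_permutation_test(setNames(dat, paste0("M", 1:6)),
                                  n_perm = 300L, seed = 9L)
  expect_equal(r1$p_value, r2$p_value)
  aff <- lapply(dat, function(v) 3 * v - 7)
  r3 <- variance_permutation_test(aff, n_perm = 300L, seed = 9L)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$observed, 9 * r1$observed)
  ## zero-probe loci are dropped with a message
  expect_message(variance_permutation_test(c(dat, list(Z = numeric(0))),
                                           n_perm = 50L, seed = 1L),
                 "zero probes")
})

test_that("variance test flags a genuinely hot locus", {
  set.seed(45)
  dat <- lapply(1:20, function(i) rnorm(5))
  names(dat) <- paste0("L", 1:20)
  dat$L1 <- dat$L1 + 3
  r <- variance_permutation_test(dat, n_perm = 499L, seed = 5L)
  expect_lt(r$p_value, 0.05)
})

test_that("meiosis LTR selection applies count thresholds and the upstream rule", {
  ltrs <- data.frame(id = paste0("L", 1:4), chrom = "chr1",
                     start = c(1000L, 5000L, 9000L, 13000L),
                     end = c(1350L, 5350L, 9350L, 13350L),
                     stringsAsFactors = FALSE)
  genes <- data.frame(id = paste0("g", 1:4), chrom = "chr1",
                      start = c(1850L, 6850L, 9800L, 12000L),
                      end = c(2800L, 7800L, 10700L, 12900L),
                      strand = c("+", "+", "+", "-"),
                      stringsAsFactors = FALSE)
  counts <- matrix(c(10, 4, 4, 4, 4, 4,   # L1: total 30, growth 10 -> pass
                     9, 5, 5, 5, 5, 5,    # L2: growth 9 -> fail
                     10, 4, 4, 4, 4, 3,   # L3: total 29 -> fail
                     10, 10, 10, 10, 10, 10), 4, 6, byrow = TRUE,
                   dimnames = list(ltrs$id,
                                   c("growth", paste0("M", 1:5))))
  sel <- select_meiosis_ltrs(counts, ltrs, genes)
  ## L1 passes (gene g1 500 bp downstream, + strand); L4 passes via the
  ## - strand gene ending upstream of it... g4 ends at 12900 < L4 start
  expect_true("L1" %in% sel$ltr_id)
  expect_equal(sel$gene_id[sel$ltr_id == "L1"], "g1")
  expect_equal(sel$distance[sel$ltr_id == "L1"], 500L)
  expect_false("L2" %in% sel$ltr_id)   # growth below threshold
  expect_false("L3" %in% sel$ltr_id)   # total below threshold
  expect_true("L4" %in% sel$ltr_id)
  ## a gene 1500 bp away is beyond the upstream window
  counts2 <- counts; genes2 <- genes
  genes2$start[1] <- 2850L; genes2$end[1] <- 3800L
  sel2 <- select_meiosis_ltrs(counts2, ltrs, genes2)
  expect_false("L1" %in% sel2$ltr_id)
})

test_that("stage log ratios are zero at growth and error on zero growth counts", {
  c0 <- c(growth = 50, M1 = 100, M2 = 50, M3 = 25)
  lr <- stage_log_ratios(c0)
  expect_equal(unname(lr[c("growth", "M1", "M2", "M3")]), c(0, 1, 0, -1))
  expect_error(stage_log_ratios(c(growth = 0, M1 = 5)), "pseudocount")
  expect_silent(stage_log_ratios(c(growth = 0, M1 = 5), pseudocount = 1))
})

test_that("concatenated Pearson r matches hand-computed values", {
  m <- matrix(c(0, 1, 2), 1)
  expect_equal(concatenated_pearson(m, m), 1)
  expect_equal(concatenated_pearson(m, -m), -1)
  expect_equal(concatenated_pearson(m, matrix(c(0, 1, 3), 1)), 0.9819805,
               tolerance = 1e-6)
  ## concatenation across pairs, not averaging of per-pair correlations
  ltr <- rbind(c(0, 1, 2), c(5, 6, 7))
  gene <- rbind(c(0, 1, 2), c(5, 6, 7))
  expect_equal(concatenated_pearson(ltr, gene), 1)
  expect_error(concatenated_pearson(matrix(1, 1, 3), m), "variance")
})

test_that("set-level stage profiles are library-size normalised log2 ratios", {
  expect_equal(unname(set_level_stage_profile(
    c(growth = 50, M1 = 100), c(growth = 1e6, M1 = 1e6))[["M1"]]), 1)
  expect_equal(unname(set_level_stage_profile(
    c(growth = 80, M1 = 80), c(growth = 1e6, M1 = 1e6))[["M1"]]), 0)
  expect_equal(unname(set_level_stage_profile(
    c(growth = 80, M1 = 80), c(growth = 1e6, M1 = 2e6))[["M1"]]), -1)
  expect_error(set_level_stage_profile(c(growth = 0, M1 = 5),
                                       c(growth = 10, M1 = 10)),
               "pseudocount")
})

test_that("timepoint shuffle test: perfect coupling and exhaustive-null agreement", {
  set.seed(46)
  prof <- matrix(rnorm(40), 8, 5,
                 dimnames = list(NULL, paste0("M", 1:5)))
  r <- timepoint_permutation_test(prof, prof, n_perm = 400L, seed = 2L)
  expect_equal(r$observed, 1)
  expect_lt(r$p_value, 0.05)
  ## n = 2 pairs, 3 stages: the shuffle space is (2!)^3 = 8 combinations
  ltr <- rbind(c(1, 5, 2), c(4, 1, 7))
  gene <- rbind(c(2, 6, 1), c(3, 2, 8))
  medians8 <- vapply(0:7, function(mask) {
    perm <- ltr
    for (s in 1:3) if (bitwAnd(mask, bitwShiftL(1L, s - 1L))) {
      perm[, s] <- perm[2:1, s]
    }
    cr <- vapply(1:2, function(i) cor(perm[i, ], gene[i, ]), 0)
    median(cr)
  }, 0)
  rt <- timepoint_permutation_test(ltr, gene, n_perm = 8000L, seed = 3L)
  expect_equal(rt$observed, medians8[1])
  ## every sampled null lies in the enumerated shuffle space
  nearest <- vapply(rt$null_values, function(v) min(abs(medians8 - v)), 0)
  expect_true(all(nearest < 1e-9))
  ## sampled frequencies match the uniform-over-8 expectation within 3 sigma
  for (v in unique(round(medians8, 9))) {
    p_exp <- mean(abs(medians8 - v) < 1e-9)
    obs <- mean(abs(rt$null_values - v) < 1e-9)
    expect_lt(abs(obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 8000))
  }
})

test_that("constant profiles are dropped before the shuffle test", {
  ltr <- rbind(c(1, 2, 3, 4, 5), c(2, 2, 2, 2, 2), c(5, 3, 1, 2, 4))
  gene <- rbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), c(5, 3, 1, 2, 4))
  expect_message(r <- timepoint_permutation_test(ltr, gene, n_perm = 50L,
                                                 seed = 1L),
                 "constant")
  expect_equal(r$observed, 1)
})
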