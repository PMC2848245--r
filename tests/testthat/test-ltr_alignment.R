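test_that("pairwise identity counts matches over all aligned columns", {
  set.seed(31)
  s <- rand_dna_chr(100)
  expect_equal(pairwise_identity(s, s), 1.0)
  s10 <- "ACGTACGTAC"
  m <- s10; substr(m, 5, 5) <- "T"
  expect_equal(pairwise_identity(s10, m), 0.9)
  ## a deletion puts gap columns in the denominator
  expect_equal(pairwise_identity(s10, substr(s10, 1, 8)), 0.8)
})

test_that("pairwise identity matches the dynamic-programming oracle", {
  set.seed(32)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:12) {
    a <- rand_dna_chr(sample(20:45, 1))
    b <- if (i %% 2 == 0) rand_dna_chr(sample(20:45, 1)) else {
      x <- a
      substr(x, 5, 5) <- sample(c("A", "C", "G", "T"), 1)
      substr(x, sample(6:19, 1), nchar(x) - sample(0:5, 1))
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    expect_equal(Biostrings::score(aln), nw_align(a, b)$score)
  }
  ## unrelated sequences score well below the clustering cut-off
  set.seed(33)
  ids <- replicate(100, {
    a <- rand_dna_chr(200); b <- rand_dna_chr(200)
    expect_equal(Biostrings::score(
      Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
        substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)),
      nw_align(a, b)$score)
    pairwise_identity(a, b)
  })
  expect_true(all(ids < 0.6))
})

test_that("single-linkage clustering collapses via any cross-cluster link", {
  idm <- matrix(c(1, 0.8, 0.5,
                  0.8, 1, 0.75,
                  0.5, 0.75, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  seqs <- setNames(rep("ACGT", 3), c("A", "B", "C"))
  cl <- cluster_ltrs(seqs, threshold = 0.70, identities = idm)
  expect_equal(cl, list(c("A", "B", "C")))
  ## below-threshold identities give all singletons
  idm2 <- idm; idm2[idm2 < 1] <- 0.5
  cl2 <- cluster_ltrs(seqs, threshold = 0.70, identities = idm2)
  expect_equal(lengths(cl2), c(1L, 1L, 1L))
})

test_that("clustering equals brute-force transitive closure and ignores input order", {
  set.seed(34)
  for (rep_i in 1:8) {
    n <- 12L
    ids <- sprintf("L%02d", 1:n)
    idm <- matrix(runif(n * n, 0.4, 0.95), n, n, dimnames = list(ids, ids))
    idm[lower.tri(idm)] <- t(idm)[lower.tri(idm)]
    diag(idm) <- 1
    seqs <- setNames(rep("ACGT", n), ids)
    got <- cluster_ltrs(seqs, threshold = 0.70, identities = idm)
    want <- brute_components(idm, 0.70)
    expect_equal(got, want)
    ## order invariance
    perm <- sample(n)
    got2 <- cluster_ltrs(seqs[perm], threshold = 0.70,
                         identities = idm[perm, perm])
    expect_equal(got2, got)
  }
})

test_that("ancestor-derived solitary LTR families cluster together at 70%", {
  b <- generate_genome(small_sim_config(seed = 35L))
  loci <- b$truth$loci
  sol <- loci[loci$class == "solitary", ]
  seqs <- setNames(vapply(seq_len(nrow(sol)), function(i)
    interval_seq(b$catalog, sol$chrom[i], sol$start[i], sol$end[i]), ""),
    sol$locus_id)
  cl <- cluster_ltrs(seqs, threshold = 0.70)
  ## divergence 0.10 from one ancestor: all pairs ~80% identical
  expect_equal(length(cl), 1L)
  sweep <- cluster_threshold_sweep(seqs, thresholds = c(0.5, 0.7, 0.95))
  expect_equal(sweep$largest[sweep$threshold == 0.5], nrow(sol))
  expect_equal(sweep$n_clusters[sweep$threshold == 0.95], nrow(sol))
})

test_that("mapping midpoints project onto alignment columns through gaps", {
  rows <- c(X = paste(rep("A", 100), collapse = ""),
            Y = paste0(strrep("-", 5), strrep("A", 95)))
  aln <- make_alignment(rows)
  loci <- genomic_interval("chr1", c(0L, 1000L), c(100L, 1095L),
                           id = c("X", "Y"))
  rec <- data.frame(query_id = "p1", klass = "unique", loci = "X",
                    hits = "chr1:10:70:+", stringsAsFactors = FALSE)
  p <- project_to_alignment(rec, aln, loci = loci)
  expect_equal(p$residue, 39L)   # floor((10 + 70 - 1) / 2)
  expect_equal(p$column, 39L)
  rec2 <- data.frame(query_id = "p2", klass = "unique", loci = "Y",
                     hits = "chr1:1010:1070:+", stringsAsFactors = FALSE)
  p2 <- project_to_alignment(rec2, aln, loci = loci)
  expect_equal(p2$residue, 39L)
  expect_equal(p2$column, 44L)   # shifted past the 5 leading gaps
  ## first-instance rule: row chosen by set order, not hit order
  rec3 <- data.frame(query_id = "p3", klass = "exclusive", loci = "X;Y",
                     hits = "chr1:1010:1070:+;chr1:10:70:+",
                     stringsAsFactors = FALSE)
  p3 <- project_to_alignment(rec3, aln, set_order = c("Y", "X"), loci = loci)
  expect_equal(p3$row, "Y")
  ## absent locus is skipped with a log message
  rec4 <- data.frame(query_id = "p4", klass = "unique", loci = "Z",
                     hits = "chr1:9000:9060:+", stringsAsFactors = FALSE)
  expect_message(expect_null(project_to_alignment(rec4, aln, loci = loci)),
                 "skipped")
})

test_that("projection is monotone along a row", {
  set.seed(36)
  gapped <- paste(sample(c("A", "C", "G", "T", "-"), 400, replace = TRUE,
                         prob = c(0.22, 0.22, 0.22, 0.22, 0.12)),
                  collapse = "")
  nres <- sum(strsplit(gapped, "")[[1]] != "-")
  aln <- make_alignment(c(R = gapped))
  loci <- genomic_interval("chr1", 0L, nres, id = "R")
  starts <- sort(sample(0:(nres - 30L), 12))
  cols <- vapply(starts, function(s) {
    rec <- data.frame(query_id = "q", klass = "unique", loci = "R",
                      hits = sprintf("chr1:%d:%d:+", s, s + 20L))
    project_to_alignment(rec, aln, loci = loci)$column
  }, 0L)
  expect_true(all(diff(cols[!duplicated(starts)]) > 0))
})

test_that("flank frames follow the half-distance and 60-bp minimum rules", {
  mk <- function(dist_up, dist_dn, chrom_len = 10000L) {
    ltr <- data.frame(id = "L", chrom = "chr1", start = 4000L, end = 4350L,
                      stringsAsFactors = FALSE)
    f <- data.frame(id = c("gU", "gD"), kind = "gene", chrom = "chr1",
                    start = c(4000L - dist_up - 100L, 4350L + dist_dn),
                    end = c(4000L - dist_up, 4350L + dist_dn + 100L),
                    strand = "+", stringsAsFactors = FALSE)
    cat_ <- toy_catalog(list(chr1 = strrep("A", chrom_len)), f)
    build_flank_frame(ltr, cat_)
  }
  fr <- mk(1200L, 1200L)
  expect_equal(fr$up_flank$end - fr$up_flank$start, 500L)
  expect_equal(fr$down_flank$end - fr$down_flank$start, 500L)
  fr2 <- mk(800L, 1200L)
  expect_equal(fr2$up_flank$end - fr2$up_flank$start, 400L)
  fr3 <- mk(100L, 119L)
  expect_null(fr3$up_flank)          # half = 50 < 60
  expect_null(fr3$down_flank)        # floor(119/2) = 59 < 60
  fr4 <- mk(120L, 1200L)
  expect_equal(fr4$up_flank$end - fr4$up_flank$start, 60L)
  ## chromosome edge truncates the flank
  ltr_edge <- data.frame(id = "L", chrom = "chr1", start = 200L, end = 550L)
  cat_ <- toy_catalog(list(chr1 = strrep("A", 10000L)),
                      data.frame(id = "g", kind = "gene", chrom = "chr1",
                                 start = 8000L, end = 8100L, strand = "+",
                                 stringsAsFactors = FALSE))
  fr5 <- build_flank_frame(ltr_edge, cat_)
  expect_equal(c(fr5$up_flank$start, fr5$up_flank$end), c(0L, 200L))
})

test_that("sliding-window density matches the direct loop and is edge-truncated", {
  nr <- 5L
  d <- window_density(0:99, ncols = 100L, window = 11L, n_rows = nr)
  expect_equal(d, rep(1 / nr, 100L))
  d2 <- window_density(50L, ncols = 101L, window = 11L, n_rows = nr)
  expect_equal(d2[51], 1 / (11 * nr))
  expect_equal(sum(d2 > 0), 11L)
  set.seed(37)
  cols <- sample(0:299, 500, replace = TRUE)
  got <- window_density(cols, ncols = 300L, window = 31L, n_rows = 7L)
  counts <- tabulate(cols + 1L, nbins = 300L)
  expect_equal(got, naive_window_density(counts, 31L, 7L))
  expect_error(window_density(cols, ncols = 300L, window = 301L, n_rows = 7L),
               "window")
  expect_error(window_density(cols, ncols = 300L, window = 30L, n_rows = 7L))
})

test_that("flank contrast recovers LTR-confined transcription and is calm under the null", {
  ## null: identical intensity distributions in and around the LTRs
  set.seed(38)
  frames <- lapply(1:5, function(i) {
    base <- i * 3000L
    list(locus_id = paste0("L", i),
         ltr = data.frame(chrom = "chr1", start = base, end = base + 350L),
         up_flank = data.frame(chrom = "chr1", start = base - 500L, end = base),
         down_flank = data.frame(chrom = "chr1", start = base + 350L,
                                 end = base + 850L))
  })
  mk_probes <- function(shift_in) {
    do.call(rbind, lapply(frames, function(fr) {
      pos <- function(iv, n) {
        s <- seq(iv$start, iv$end - 60L, length.out = n)
        data.frame(chrom = "chr1", start = as.integer(s),
                   end = as.integer(s) + 60L)
      }
      rbind(cbind(pos(fr$ltr, 20), intensity = rnorm(20) + shift_in),
            cbind(pos(fr$up_flank, 20), intensity = rnorm(20)),
            cbind(pos(fr$down_flank, 20), intensity = rnorm(20)))
    }))
  }
  null_ct <- flank_contrast(frames, mk_probes(0))
  expect_gt(null_ct$p_up, 0.05)
  expect_gt(null_ct$p_down, 0.05)
  sig_ct <- flank_contrast(frames, mk_probes(3))
  expect_lt(sig_ct$p_up, 0.01)
  expect_lt(sig_ct$p_down, 0.01)
  expect_gt(sig_ct$median_in, sig_ct$median_up)
  expect_gt(sig_ct$median_in, sig_ct$median_down)
  ## complete separation puts the flank group's U at zero
  sep <- flank_contrast(frames[1], data.frame(
    chrom = "chr1", start = c(3000L, 2600L, 3400L),
    end = c(3060L, 2660L, 3460L), intensity = c(5, -1, -1)))
  expect_equal(sep$U_up, 0)
  expect_equal(sep$median_in, 5)
  expect_equal(sep$median_up, -1)
})
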