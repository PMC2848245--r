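test_that("generation is deterministic for a fixed seed and config", {
  b1 <- generate_genome(small_sim_config(seed = 51L))
  b2 <- generate_genome(small_sim_config(seed = 51L))
  expect_identical(as.character(b1$catalog$seqs), as.character(b2$catalog$seqs))
  expect_identical(b1$catalog$features, b2$catalog$features)
  expect_identical(b1$truth$stage_mult, b2$truth$stage_mult)
  b3 <- generate_genome(small_sim_config(seed = 52L))
  expect_false(identical(as.character(b1$catalog$seqs),
                         as.character(b3$catalog$seqs)))
  ## reads and probe intensities are reproducible too
  r1 <- simulate_rnaseq(b1, "M1")$reads
  r2 <- simulate_rnaseq(b2, "M1")$reads
  expect_identical(r1, r2)
})

test_that("zero divergence collapses the family: LTR probes hit every copy", {
  cfg <- small_sim_config(seed = 53L, ltr_divergence = 0,
                          element_divergence = 0,
                          within_element_divergence = 0)
  b <- generate_genome(cfg)
  f <- b$catalog$features
  ltrs <- f[f$kind == "ltr", ]
  ## a 60-mer from the middle of one LTR occurs in all of them
  probe <- interval_seq(b$catalog, ltrs$chrom[1], ltrs$start[1] + 100L,
                        ltrs$start[1] + 160L)
  hits <- find_exact_matches(probe, b$catalog)
  expect_gte(nrow(hits[hits$genome_strand == "+", ]), nrow(ltrs))
})

test_that("the chimeric arrangement partitions into two elements sharing an LTR", {
  b <- generate_genome(small_sim_config(seed = 54L))
  part <- partition_ltrs(b$catalog)
  shared <- part$ltrs[grepl(",", part$ltrs$element_id), ]
  expect_equal(nrow(shared), 1L)
  expect_length(part$elements, 3L)
  expect_equal(nrow(part$flanking), 2L * 3L - 1L)
})

test_that("probe tiling counts, strand tags and round-trip mapping", {
  cfg <- small_sim_config(seed = 55L, probe_tile_step = 60L)
  b <- generate_genome(cfg)
  probes <- simulate_probes(b)
  L <- cfg$chrom_length
  n_per_strand <- length(seq(0L, L - 60L, by = 60L))
  expect_equal(nrow(probes), 2L * n_per_strand)
  expect_equal(sort(unique(probes$strand)), c("forward", "reverse"))
  ## 3x denser tiling
  cfg2 <- small_sim_config(seed = 55L, probe_tile_step = 20L)
  b2 <- generate_genome(cfg2)
  expect_equal(nrow(simulate_probes(b2)),
               2L * length(seq(0L, L - 60L, by = 20L)))
  ## every probe maps back to its recorded source position
  set.seed(1)
  for (i in sample(nrow(probes), 25L)) {
    h <- find_exact_matches(probes$sequence[i], b$catalog)
    strand <- if (probes$strand[i] == "forward") "+" else "-"
    expect_true(any(h$chrom == probes$chrom[i] & h$start == probes$start[i] &
                      h$genome_strand == strand))
  }
})

test_that("noise-free probe intensities follow the log2 signal model", {
  set.seed(56)
  chr <- rand_dna_chr(4000)
  cat_ <- toy_catalog(list(chr1 = chr))
  mk_bundle <- function(rate) {
    tx <- data.frame(tx_id = "t1", locus_id = "t1", chrom = "chr1",
                     start = 1000L, end = 2000L, strand = "+", polyA = TRUE,
                     rate = rate, class = "gene",
                     intron_start = NA_integer_, intron_end = NA_integer_,
                     stringsAsFactors = FALSE)
    cfg <- sim_config(seed = 56L, noise_sd = 0, background_rate = 1,
                      probe_tile_step = 100L)
    sm <- matrix(1, 1, length(cfg$stages),
                 dimnames = list("t1", cfg$stages))
    structure(list(config = cfg, catalog = cat_,
                   truth = list(transcripts = tx, stage_mult = sm)),
              class = "SimBundle")
  }
  ## single active locus with rate == background: in-locus probes at log2(2) = 1
  ph <- simulate_hybmap(mk_bundle(1), simulate_probes(mk_bundle(1)))
  inside <- ph$strand == "forward" & ph$start >= 1000L & ph$start + 60L <= 2000L
  expect_true(all(ph$intensity[inside] == 1.0))
  expect_true(all(ph$intensity[!inside] == 0))
  ## no transcription at all: all intensities zero
  ph0 <- simulate_hybmap(mk_bundle(0), simulate_probes(mk_bundle(0)))
  expect_true(all(ph0$intensity == 0))
  ## a probe served by two active loci sees more signal than either alone
  mk2 <- function(rates) {
    bdl <- mk_bundle(rates[1])
    tx2 <- bdl$truth$transcripts
    tx2 <- rbind(tx2, within(tx2, { tx_id <- "t2"; locus_id <- "t2"
    rate <- rates[2] }))
    bdl$truth$transcripts <- tx2
    sm <- matrix(1, 2, length(bdl$config$stages),
                 dimnames = list(c("t1", "t2"), bdl$config$stages))
    bdl$truth$stage_mult <- sm
    bdl
  }
  b2 <- mk2(c(1, 2))
  ph2 <- simulate_hybmap(b2, simulate_probes(b2))
  expect_true(all(ph2$intensity[inside] == log2(4)))
})

test_that("read start positions follow the configured 3' bias law", {
  set.seed(57)
  chr <- rand_dna_chr(8000)
  mk <- function(beta) {
    tx <- data.frame(tx_id = "t1", locus_id = "t1", chrom = "chr1",
                     start = 500L, end = 6500L, strand = "+", polyA = TRUE,
                     rate = 10000, class = "gene",
                     intron_start = NA_integer_, intron_end = NA_integer_,
                     stringsAsFactors = FALSE)
    cfg <- sim_config(seed = 57L, read_bias_beta = beta, depth = 1,
                      n_injection_rate = 0)
    sm <- matrix(1, 1, length(cfg$stages), dimnames = list("t1", cfg$stages))
    structure(list(config = cfg, catalog = toy_catalog(list(chr1 = chr)),
                   truth = list(transcripts = tx, stage_mult = sm)),
              class = "SimBundle")
  }
  ## beta = 0: uniform start positions
  rs <- simulate_rnaseq(mk(0), "growth")
  lens <- nchar(rs$reads$sequence)
  ## de-lattice the integer starts before the KS comparison
  rel <- (rs$reads$tx_pos + runif(nrow(rs$reads))) / (6000 - lens + 1)
  expect_gt(nrow(rs$reads), 5000L)
  expect_gt(stats::ks.test(rel, "punif")$p.value, 0.01)
  ## strong bias pushes the mass toward the 3' end
  rs8 <- simulate_rnaseq(mk(8), "growth")
  rel8 <- rs8$reads$tx_pos / (6000 - nchar(rs8$reads$sequence))
  expect_gt(mean(rel8), 0.75)
  ## read lengths stay in the configured range
  expect_true(all(lens >= 30L & lens <= 51L))
  ## zero depth gives an empty read set
  rs0 <- simulate_rnaseq(mk(0), "growth", depth = 0)
  expect_equal(nrow(rs0$reads), 0L)
  expect_length(rs0$true_counts, 0L)
})

test_that("reads map back to their source locus; N injection flags a fraction", {
  cfg <- small_sim_config(seed = 58L, n_injection_rate = 0.05)
  b <- generate_genome(cfg)
  rs <- simulate_rnaseq(b, "growth")
  expect_gt(mean(grepl("N", rs$reads$sequence)), 0.01)
  loci <- b$truth$loci
  clean <- rs$reads[!grepl("N", rs$reads$sequence) &
                      rs$reads$locus_id %in%
                      loci$locus_id[loci$class != "gene"], ]
  set.seed(2)
  for (i in sample(nrow(clean), 30L)) {
    rd <- clean[i, ]
    l <- loci[match(rd$locus_id, loci$locus_id), ]
    h <- find_exact_matches(rd$sequence, b$catalog)
    ok <- h$chrom == l$chrom & h$start >= l$start & h$end <= l$end
    expect_true(any(ok))
  }
})

test_that("poly(A) selection suppresses solitary-LTR signal relative to elements", {
  count_by_class <- function(polyA) {
    cfg <- small_sim_config(seed = 59L, polyA_selection = polyA, depth = 5)
    b <- generate_genome(cfg)
    rs <- simulate_rnaseq(b, "growth")
    loci <- b$truth$loci
    cls <- loci$class[match(names(rs$true_counts), loci$locus_id)]
    tapply(rs$true_counts, cls, sum)
  }
  plain <- count_by_class(FALSE)
  selected <- count_by_class(TRUE)
  ratio_plain <- plain[["solitary"]] / plain[["element"]]
  ratio_sel <- selected[["solitary"]] / selected[["element"]]
  expect_lt(ratio_sel, ratio_plain)
})

test_that("a bundle writes consistent text files that re-import cleanly", {
  dir <- tempfile("bundle"); dir.create(dir)
  cfg <- small_sim_config(seed = 60L, depth = 1)
  b <- generate_genome(cfg)
  paths <- simulate_bundle(b, dir, stages = c("growth", "M1"))
  expect_true(all(file.exists(unlist(paths[c("genome", "annotation", "probes",
                                             "solitary_alignment")]))))
  cat2 <- parse_annotation(paths$genome, paths$annotation)
  expect_equal(nrow(cat2$features), nrow(b$catalog$features))
  probes <- read_probe_table(paths$probes)
  expect_true(all(c("id", "sequence", "strand_tag", "signal") %in% names(probes)))
  reads <- read_fastq_queries(paths$reads_growth)
  expect_gt(nrow(reads), 0L)
  aln <- read_alignment(paths$solitary_alignment)
  expect_equal(length(aln$rows), cfg$n_solitary)
  expect_equal(aln$ncols, cfg$ltr_length)
})
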