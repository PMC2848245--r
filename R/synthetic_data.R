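## Toy genomes, probe tables and staged read sets with known ground truth.
## The generator plants a family of LTR retrotransposons (near-identical
## full-length copies, divergent solitary LTRs from the same ancestor),
## genes with introns, per-locus per-strand transcription rates with an
## optional few-hot-loci regime, log-ratio probe intensities with Gaussian
## noise, and 30-51 nt reads with a tunable 3' bias and a poly(A)-selection
## mode.

#' Simulation configuration
#'
#' Returns the configuration list driving the synthetic-data generators,
#' with defaults emulating a desk-scale fission-yeast-like setup: 13
#' full-length elements (one chimeric LTR-internal-LTR-internal-LTR
#' arrangement sharing its middle LTR), 40 solitary LTRs from the same
#' family ancestor, genes with introns, 60-mer tiling probes and 30-51 nt
#' reads.
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   outputs.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_full_elements Number of full-length elements (the chimeric
#'   arrangement, when enabled, accounts for two of them).
#' @param include_chimeric Plant the shared-LTR chimeric arrangement.
#' @param n_solitary Number of solitary LTRs.
#' @param ltr_length,internal_length Element anatomy (bp).
#' @param ltr_divergence Per-site substitution probability of each solitary
#'   LTR from the family ancestor.
#' @param element_divergence Per-site private substitution probability of a
#'   full-length element copy (LTRs and internal sequence).
#' @param within_element_divergence Divergence between the two LTRs of one
#'   element (near-identical).
#' @param n_genes,gene_length,intron_probability,intron_length Gene model.
#' @param n_trna,trna_length,n_snorna,snorna_length Structural RNA features.
#' @param probe_length,probe_tile_step Probe tiling (both strands).
#' @param read_length_range Read lengths, uniform over this range (nt).
#' @param read_bias_beta 3'-bias strength: read starts are weighted
#'   proportional to `exp(beta * relative_position_toward_3')`; 0 = uniform.
#' @param polyA_selection,polyA_factor With selection on, transcripts that
#'   are not polyadenylated (solitary-LTR and antisense transcripts,
#'   structural RNAs) are downweighted by `polyA_factor`.
#' @param noise_sd Gaussian SD of probe intensity noise (log2 scale).
#' @param n_injection_rate Fraction of reads receiving an injected N.
#' @param background_rate Background intensity term `b` of the probe model.
#' @param element_rate,solitary_rate,gene_rate Mean per-locus transcription
#'   rates (sense strand), lognormal across loci with `rate_sdlog`.
#' @param antisense_factor Antisense rate as a fraction of sense rate.
#' @param rate_sdlog Lognormal spread of per-locus rates (0 = all equal).
#' @param hot_fraction Fraction of full-length elements that are "hot"
#'   (`NA` = regime off); hot loci share `hot_share` of the family-wide rate.
#' @param hot_share Share of family rate carried by hot loci.
#' @param hot_diverged In the hot regime, only hot elements carry private
#'   substitutions; cold copies stay at the family consensus (recent
#'   identical copies), so uniquely mapping probes interrogate the
#'   distinguishable, transcribed loci.
#' @param stages Stage names; first must be `growth`.
#' @param stage_sdlog SD of per-locus per-stage log2 rate multipliers.
#' @param gene_coupling_rho Correlation between a paired LTR's and its
#'   neighbour gene's stage multipliers.
#' @param n_ltr_gene_pairs Number of solitary LTRs planted within 1000 bp
#'   upstream of a gene.
#' @param pair_rate Sense rate of paired LTRs (high enough to pass the
#'   uniquely-mapped read thresholds).
#' @param pair_gap_range LTR-to-gene gap (bp), uniform over this range.
#' @param depth Expected reads per unit rate per transcript per stage.
#' @param min_gap Minimum gap between planted blocks (bp).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 100000L,
                       n_full_elements = 13L, include_chimeric = TRUE,
                       n_solitary = 40L, ltr_length = 350L,
                       internal_length = 2000L, ltr_divergence = 0.10,
                       element_divergence = 0.01,
                       within_element_divergence = 0.002,
                       n_genes = 30L, gene_length = 1500L,
                       intron_probability = 0.3, intron_length = 100L,
                       n_trna = 4L, trna_length = 75L,
                       n_snorna = 3L, snorna_length = 120L,
                       probe_length = 60L, probe_tile_step = 20L,
                       read_length_range = c(30L, 51L), read_bias_beta = 2,
                       polyA_selection = FALSE, polyA_factor = 0.1,
                       noise_sd = 0.25, n_injection_rate = 0.002,
                       background_rate = 1,
                       element_rate = 2, solitary_rate = 1, gene_rate = 5,
                       antisense_factor = 0.3, rate_sdlog = 1,
                       hot_fraction = NA, hot_share = 0.95,
                       hot_diverged = TRUE,
                       stages = c("growth", paste0("M", 1:5)),
                       stage_sdlog = 1, gene_coupling_rho = 0,
                       n_ltr_gene_pairs = 8L, pair_rate = 20,
                       pair_gap_range = c(100L, 800L),
                       depth = 10, min_gap = 250L) {
  cfg <- as.list(environment())
  stopifnot(stages[1] == "growth",
            ltr_divergence >= 0, ltr_divergence <= 1,
            element_divergence >= 0, element_divergence <= 1,
            intron_probability >= 0, intron_probability <= 1,
            polyA_factor >= 0, polyA_factor <= 1,
            all(c(element_rate, solitary_rate, gene_rate, depth) >= 0),
            background_rate > 0,
            read_length_range[1] <= read_length_range[2])
  class(cfg) <- "SimConfig"
  cfg
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## substitute each site with probability p (never to the same base)
.mutate <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a toy genome with planted features and ground truth
#'
#' Builds random background chromosomes carrying full-length LTR
#' retrotransposons (two near-identical LTRs around an internal sequence;
#' optionally one chimeric LTR-int-LTR-int-LTR arrangement), solitary LTRs
#' derived from the same family ancestor, genes with introns, tRNAs and
#' snoRNAs, plus per-locus per-strand transcription rates and per-stage
#' multipliers. A subset of solitary LTRs is planted within 1000 bp
#' upstream of genes, with stage multipliers coupled at
#' `gene_coupling_rho`.
#'
#' @param config A `SimConfig`.
#' @return An object of class `SimBundle`: list with `config`, `catalog`
#'   (a `FeatureCatalog`), and `truth` (list with `loci` rates table,
#'   `transcripts` table, `stage_mult` matrix of per-locus stage
#'   multipliers, and family sequence info).
#' @export
generate_genome <- function(config) {
  with_seed(config$seed, .generate_genome_impl(config))
}

.generate_genome_impl <- function(cfg) {
  anc_ltr <- .rand_dna(cfg$ltr_length)
  anc_int <- .rand_dna(cfg$internal_length)

  n_el <- cfg$n_full_elements
  hot_on <- !is.na(cfg$hot_fraction)
  n_hot <- if (hot_on) max(1L, round(cfg$hot_fraction * n_el)) else 0L
  hot_ix <- if (hot_on) sort(sample.int(n_el, n_hot)) else integer(0)

  ## per-element sequences: private substitutions; in the hot regime with
  ## hot_diverged, cold copies stay at the family consensus
  el_seqs <- lapply(seq_len(n_el), function(i) {
    div <- if (hot_on && cfg$hot_diverged && !(i %in% hot_ix)) 0 else
      cfg$element_divergence
    ltr <- .mutate(anc_ltr, div)
    list(ltr5 = ltr, ltr3 = .mutate(ltr, cfg$within_element_divergence),
         int = .mutate(anc_int, div))
  })

  sol_seqs <- vapply(seq_len(cfg$n_solitary), function(i)
    .mutate(anc_ltr, cfg$ltr_divergence), "")

  mk_gene <- function() {
    has_intron <- stats::runif(1) < cfg$intron_probability
    if (has_intron) {
      e1 <- sample(seq(200L, cfg$gene_length - 200L), 1L)
      list(seq = .rand_dna(cfg$gene_length + cfg$intron_length),
           len = cfg$gene_length + cfg$intron_length,
           intron = c(e1, e1 + cfg$intron_length))   # 0-based within gene
    } else {
      list(seq = .rand_dna(cfg$gene_length), len = cfg$gene_length,
           intron = NULL)
    }
  }

  ## ---- assemble blocks (relative feature layout + sequence) ----
  blocks <- list()
  add_block <- function(b) blocks[[length(blocks) + 1L]] <<- b

  el_id <- 0L
  i <- 1L
  while (i <= n_el) {
    if (cfg$include_chimeric && i == 1L && n_el >= 2L) {
      a <- el_seqs[[1]]; b <- el_seqs[[2]]
      seq <- paste0(a$ltr5, a$int, a$ltr3, b$int, b$ltr3)
      L <- cfg$ltr_length; I <- cfg$internal_length
      feats <- data.frame(
        kind = c("ltr", "retro_internal", "ltr", "retro_internal", "ltr"),
        off = c(0L, L, L + I, 2L * L + I, 2L * L + 2L * I),
        len = c(L, I, L, I, L),
        label = c("el1_ltr5", "el1_int", "chim_mid_ltr", "el2_int", "el2_ltr3"),
        stringsAsFactors = FALSE)
      add_block(list(type = "chimeric", seq = seq, feats = feats,
                     elements = c(1L, 2L)))
      i <- i + 2L
    } else {
      e <- el_seqs[[i]]
      seq <- paste0(e$ltr5, e$int, e$ltr3)
      L <- cfg$ltr_length; I <- cfg$internal_length
      feats <- data.frame(
        kind = c("ltr", "retro_internal", "ltr"),
        off = c(0L, L, L + I), len = c(L, I, L),
        label = paste0("el", i, c("_ltr5", "_int", "_ltr3")),
        stringsAsFactors = FALSE)
      add_block(list(type = "element", seq = seq, feats = feats,
                     elements = i))
      i <- i + 1L
    }
  }

  n_pairs <- min(cfg$n_ltr_gene_pairs, cfg$n_solitary, cfg$n_genes)
  for (k in seq_len(n_pairs)) {
    g <- mk_gene()
    gap <- sample(seq(cfg$pair_gap_range[1], cfg$pair_gap_range[2]), 1L)
    seq <- paste0(sol_seqs[k], .rand_dna(gap), g$seq)
    feats <- data.frame(kind = c("ltr", "gene"),
                        off = c(0L, cfg$ltr_length + gap),
                        len = c(cfg$ltr_length, g$len),
                        label = c(paste0("sol", k), paste0("gene", k)),
                        stringsAsFactors = FALSE)
    if (!is.null(g$intron)) {
      feats <- rbind(feats, data.frame(
        kind = "intron", off = cfg$ltr_length + gap + g$intron[1],
        len = cfg$intron_length, label = paste0("gene", k, "_intron"),
        stringsAsFactors = FALSE))
    }
    add_block(list(type = "pair", seq = seq, feats = feats, pair = k,
                   gene_strand = "+"))
  }
  for (k in seq(n_pairs + 1L, length.out = cfg$n_solitary - n_pairs)) {
    feats <- data.frame(kind = "ltr", off = 0L, len = cfg$ltr_length,
                        label = paste0("sol", k), stringsAsFactors = FALSE)
    add_block(list(type = "solitary", seq = sol_seqs[k], feats = feats))
  }
  for (k in seq(n_pairs + 1L, length.out = cfg$n_genes - n_pairs)) {
    g <- mk_gene()
    feats <- data.frame(kind = "gene", off = 0L, len = g$len,
                        label = paste0("gene", k), stringsAsFactors = FALSE)
    if (!is.null(g$intron)) {
      feats <- rbind(feats, data.frame(
        kind = "intron", off = g$intron[1], len = cfg$intron_length,
        label = paste0("gene", k, "_intron"), stringsAsFactors = FALSE))
    }
    add_block(list(type = "gene", seq = g$seq, feats = feats,
                   gene_strand = sample(c("+", "-"), 1L)))
  }
  for (k in seq_len(cfg$n_trna)) {
    add_block(list(type = "trna", seq = .rand_dna(cfg$trna_length),
                   feats = data.frame(kind = "trna", off = 0L,
                                      len = cfg$trna_length,
                                      label = paste0("trna", k),
                                      stringsAsFactors = FALSE)))
  }
  for (k in seq_len(cfg$n_snorna)) {
    add_block(list(type = "snorna", seq = .rand_dna(cfg$snorna_length),
                   feats = data.frame(kind = "snorna", off = 0L,
                                      len = cfg$snorna_length,
                                      label = paste0("sno", k),
                                      stringsAsFactors = FALSE)))
  }

  ## ---- place blocks on chromosomes ----
  blocks <- blocks[sample.int(length(blocks))]
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  cursor <- setNames(rep(0L, cfg$n_chromosomes), chrom_names)
  placed <- list()
  chr_i <- 1L
  for (b in blocks) {
    blen <- nchar(b$seq)
    gap <- cfg$min_gap + sample.int(200L, 1L)
    tries <- 0L
    while (cursor[chr_i] + gap + blen + cfg$min_gap > cfg$chrom_length) {
      chr_i <- chr_i %% cfg$n_chromosomes + 1L
      tries <- tries + 1L
      if (tries > cfg$n_chromosomes) {
        stop("features exceed chromosome capacity; increase chrom_length")
      }
    }
    b$chrom <- chrom_names[chr_i]
    b$start <- cursor[chr_i] + gap
    placed[[length(placed) + 1L]] <- b
    cursor[chr_i] <- b$start + blen
    chr_i <- chr_i %% cfg$n_chromosomes + 1L
  }

  ## background sequence, then splice in the blocks
  chrs <- lapply(chrom_names, function(x) .rand_dna(cfg$chrom_length))
  names(chrs) <- chrom_names
  for (b in placed) {
    substr(chrs[[b$chrom]], b$start + 1L, b$start + nchar(b$seq)) <- b$seq
  }
  seqs <- Biostrings::DNAStringSet(unlist(chrs))

  ## ---- feature table ----
  feat_rows <- list()
  for (b in placed) {
    f <- b$feats
    strand <- rep("+", nrow(f))
    if (!is.null(b$gene_strand)) strand[f$kind %in% c("gene", "intron")] <- b$gene_strand
    feat_rows[[length(feat_rows) + 1L]] <- data.frame(
      id = f$label, kind = f$kind, chrom = b$chrom,
      start = b$start + f$off, end = b$start + f$off + f$len,
      strand = strand, stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feat_rows)
  features <- features[order(features$chrom, features$start), , drop = FALSE]
  rownames(features) <- NULL
  catalog <- structure(list(seqs = seqs, features = features),
                       class = "FeatureCatalog")

  ## ---- rates and transcripts ----
  rlnorm2 <- function(n, mean) if (cfg$rate_sdlog <= 0) rep(mean, n) else
    stats::rlnorm(n, meanlog = log(mean), sdlog = cfg$rate_sdlog)

  el_rate <- rlnorm2(n_el, cfg$element_rate)
  if (hot_on) {
    R <- n_el * cfg$element_rate
    el_rate <- numeric(n_el)
    el_rate[hot_ix] <- cfg$hot_share * R / length(hot_ix)
    el_rate[-hot_ix] <- (1 - cfg$hot_share) * R / (n_el - length(hot_ix))
  }
  sol_rate <- rlnorm2(cfg$n_solitary, cfg$solitary_rate)
  if (n_pairs > 0L) sol_rate[seq_len(n_pairs)] <- cfg$pair_rate
  gene_rate <- rlnorm2(cfg$n_genes, cfg$gene_rate)

  loci <- list(); tx <- list()
  add_tx <- function(id, locus, chrom, start, end, strand, polyA, rate, class,
                     intron = NULL) {
    tx[[length(tx) + 1L]] <<- data.frame(
      tx_id = id, locus_id = locus, chrom = chrom, start = start, end = end,
      strand = strand, polyA = polyA, rate = rate, class = class,
      intron_start = if (is.null(intron)) NA_integer_ else intron[1],
      intron_end = if (is.null(intron)) NA_integer_ else intron[2],
      stringsAsFactors = FALSE)
  }
  half <- cfg$ltr_length %/% 2L
  for (b in placed) {
    if (b$type %in% c("element", "chimeric")) {
      for (j in seq_along(b$elements)) {
        ei <- b$elements[j]
        lid <- paste0("EL", ei)
        ## transcript: mid 5' LTR to mid 3' LTR
        if (b$type == "chimeric") {
          offs <- if (j == 1L) c(0L, 2L * cfg$ltr_length + cfg$internal_length) else
            c(cfg$ltr_length + cfg$internal_length,
              2L * (cfg$ltr_length + cfg$internal_length))
        } else {
          offs <- c(0L, cfg$ltr_length + cfg$internal_length)
        }
        s <- b$start + offs[1] + half
        e <- b$start + offs[2] + half
        strand <- sample(c("+", "-"), 1L)
        loci[[lid]] <- data.frame(
          locus_id = lid, class = "element", chrom = b$chrom,
          start = b$start + offs[1], end = b$start + offs[2] + cfg$ltr_length,
          strand = strand, rate_sense = el_rate[ei],
          rate_antisense = el_rate[ei] * cfg$antisense_factor,
          hot = ei %in% hot_ix, pair_gene = NA_character_,
          stringsAsFactors = FALSE)
        add_tx(paste0(lid, "_s"), lid, b$chrom, s, e, strand, TRUE,
               el_rate[ei], "element")
        add_tx(paste0(lid, "_as"), lid, b$chrom, s, e,
               if (strand == "+") "-" else "+", FALSE,
               el_rate[ei] * cfg$antisense_factor, "element")
      }
    } else if (b$type %in% c("solitary", "pair")) {
      k <- if (b$type == "pair") b$pair else
        as.integer(sub("sol", "", b$feats$label[b$feats$kind == "ltr"]))
      lid <- paste0("sol", k)
      s <- b$start; e <- b$start + cfg$ltr_length
      loci[[lid]] <- data.frame(
        locus_id = lid, class = "solitary", chrom = b$chrom, start = s,
        end = e, strand = "+", rate_sense = sol_rate[k],
        rate_antisense = sol_rate[k] * cfg$antisense_factor,
        hot = FALSE,
        pair_gene = if (b$type == "pair") paste0("gene", k) else NA_character_,
        stringsAsFactors = FALSE)
      add_tx(paste0(lid, "_f"), lid, b$chrom, s, e, "+", FALSE,
             sol_rate[k], "solitary")
      add_tx(paste0(lid, "_r"), lid, b$chrom, s, e, "-", FALSE,
             sol_rate[k] * cfg$antisense_factor, "solitary")
    }
    if (b$type %in% c("pair", "gene")) {
      gf <- b$feats[b$feats$kind == "gene", ]
      k <- as.integer(sub("gene", "", gf$label))
      gid <- gf$label
      intr <- b$feats[b$feats$kind == "intron", ]
      intron <- if (nrow(intr)) c(b$start + intr$off, b$start + intr$off + intr$len)
      else NULL
      gs <- if (b$type == "pair") "+" else b$gene_strand
      loci[[gid]] <- data.frame(
        locus_id = gid, class = "gene", chrom = b$chrom,
        start = b$start + gf$off, end = b$start + gf$off + gf$len,
        strand = gs, rate_sense = gene_rate[k], rate_antisense = 0,
        hot = FALSE, pair_gene = NA_character_, stringsAsFactors = FALSE)
      add_tx(paste0(gid, "_tx"), gid, b$chrom, b$start + gf$off,
             b$start + gf$off + gf$len, gs, TRUE, gene_rate[k], "gene",
             intron = intron)
    }
  }
  loci <- do.call(rbind, loci); rownames(loci) <- NULL
  tx <- do.call(rbind, tx); rownames(tx) <- NULL

  ## ---- per-locus stage multipliers (log2-normal), LTR-gene coupling ----
  stages <- cfg$stages
  sm <- matrix(1, nrow(loci), length(stages),
               dimnames = list(loci$locus_id, stages))
  z <- matrix(stats::rnorm(nrow(loci) * (length(stages) - 1L), 0, cfg$stage_sdlog),
              nrow(loci), length(stages) - 1L)
  rownames(z) <- loci$locus_id
  for (k in seq_len(n_pairs)) {
    lz <- z[paste0("sol", k), ]
    eps <- stats::rnorm(length(stages) - 1L, 0, cfg$stage_sdlog)
    z[paste0("gene", k), ] <- cfg$gene_coupling_rho * lz +
      sqrt(1 - cfg$gene_coupling_rho^2) * eps
  }
  sm[, -1] <- 2^z

  structure(list(config = cfg, catalog = catalog,
                 truth = list(loci = loci, transcripts = tx, stage_mult = sm,
                              ancestor_ltr = anc_ltr, hot = hot_ix)),
            class = "SimBundle")
}

#' @export
print.SimBundle <- function(x, ...) {
  cat("SimBundle:", length(x$catalog$seqs), "chromosome(s),",
      nrow(x$catalog$features), "feature(s),",
      nrow(x$truth$transcripts), "transcript(s)\n")
  invisible(x)
}

## strand-specific RNA sequence of one transcript row (spliced, 5'->3')
.tx_rna <- function(bundle, t) {
  s <- interval_seq(bundle$catalog, t$chrom, t$start, t$end)
  if (!is.na(t$intron_start)) {
    rel <- c(t$intron_start, t$intron_end) - t$start
    s <- paste0(substr(s, 1L, rel[1]), substr(s, rel[2] + 1L, nchar(s)))
  }
  if (t$strand == "-") s <- .revcomp(s)
  s
}

#' Tile strand-tagged probes over a simulated genome
#'
#' Emits `probe_length`-mers every `probe_tile_step` bp on both strands of
#' every chromosome. A probe's sequence equals the sequence of the strand it
#' interrogates (reverse-strand probes carry the reverse complement of the
#' forward genome).
#'
#' @param bundle A `SimBundle`.
#' @return A data.frame `probe_id`, `sequence`, `strand`
#'   (`forward`/`reverse`), `chrom`, `start` (0-based).
#' @export
simulate_probes <- function(bundle) {
  cfg <- bundle$config
  out <- list()
  for (chr in names(bundle$catalog$seqs)) {
    cs <- as.character(bundle$catalog$seqs[[chr]])
    L <- nchar(cs)
    starts <- seq(0L, L - cfg$probe_length, by = cfg$probe_tile_step)
    fwd <- substring(cs, starts + 1L, starts + cfg$probe_length)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)))
    out[[length(out) + 1L]] <- data.frame(
      probe_id = sprintf("p_%s_%d_f", chr, starts), sequence = fwd,
      strand = "forward", chrom = chr, start = starts,
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      probe_id = sprintf("p_%s_%d_r", chr, starts), sequence = rev,
      strand = "reverse", chrom = chr, start = starts,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate strand-resolved probe intensities
#'
#' The noise-free intensity of a probe is
#' `log2((sum of rates of loci whose transcript on the probe's strand
#' contains an exact match to the probe + b) / b)` with `b` the background
#' rate; Gaussian noise of SD `noise_sd` is added on the log2 scale.
#' Growth-phase rates are used (the hybridization assay profiles growth
#' phase).
#'
#' @param bundle A `SimBundle`.
#' @param probes Output of [simulate_probes()].
#' @return `probes` with added columns `intensity` and `truth_intensity`
#'   (noise-free).
#' @export
simulate_hybmap <- function(bundle, probes) {
  cfg <- bundle$config
  tx <- bundle$truth$transcripts
  acc <- numeric(nrow(probes))
  for (s in c("forward", "reverse")) {
    gstrand <- if (s == "forward") "+" else "-"
    pi <- which(probes$strand == s)
    if (length(pi) == 0L) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes$sequence[pi]))
    txs <- tx[tx$strand == gstrand & tx$rate > 0, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      rna <- Biostrings::DNAString(.tx_rna(bundle, txs[j, ]))
      if (length(rna) < cfg$probe_length) next
      hits <- Biostrings::matchPDict(pd, rna)
      contained <- which(S4Vectors::elementNROWS(hits) > 0L)
      acc[pi[contained]] <- acc[pi[contained]] + txs$rate[j]
    }
  }
  truth_int <- log2((acc + cfg$background_rate) / cfg$background_rate)
  probes$truth_intensity <- truth_int
  probes$intensity <- with_seed(cfg$seed + 7L,
    truth_int + stats::rnorm(nrow(probes), 0, cfg$noise_sd))
  probes
}

#' Simulate an RNA-Seq read set for one stage
#'
#' Per transcript, the read count is Poisson with mean
#' `rate * stage_multiplier * depth` (times `polyA_factor` for
#' non-polyadenylated transcripts when poly(A) selection is on). Read start
#' positions along the transcript are weighted proportional to
#' `exp(beta * relative_position_toward_3')`; lengths are uniform over
#' `read_length_range`; a small fraction of reads receives an injected N.
#'
#' @param bundle A `SimBundle`.
#' @param stage Stage name (must be in `config$stages`).
#' @param depth Overrides `config$depth` when given.
#' @return A list: `reads` (data.frame `read_id`, `sequence`, `tx_id`,
#'   `locus_id`, `tx_pos`), `true_counts` (named per-locus read totals),
#'   `stage`.
#' @export
simulate_rnaseq <- function(bundle, stage, depth = NULL) {
  cfg <- bundle$config
  stopifnot(stage %in% cfg$stages)
  if (is.null(depth)) depth <- cfg$depth
  tx <- bundle$truth$transcripts
  sm <- bundle$truth$stage_mult
  seed <- cfg$seed + 100L + match(stage, cfg$stages)
  with_seed(seed, {
    out <- list()
    for (j in seq_len(nrow(tx))) {
      t <- tx[j, ]
      lambda <- t$rate * sm[t$locus_id, stage] * depth
      if (cfg$polyA_selection && !t$polyA) lambda <- lambda * cfg$polyA_factor
      n <- stats::rpois(1L, lambda)
      if (n == 0L) next
      rna <- .tx_rna(bundle, t)
      Lt <- nchar(rna)
      lens <- sample(seq(cfg$read_length_range[1], cfg$read_length_range[2]),
                     n, replace = TRUE)
      lens <- pmin(lens, Lt)
      maxs <- Lt - lens                       # max 0-based start
      beta <- cfg$read_bias_beta
      u <- stats::runif(n)
      relpos <- if (beta == 0) u else log1p(u * (exp(beta) - 1)) / beta
      starts <- as.integer(floor(relpos * (maxs + 1 - 1e-9)))
      seqs <- substring(rna, starts + 1L, starts + lens)
      out[[length(out) + 1L]] <- data.frame(
        read_id = sprintf("rd_%s_%s_%d", stage, t$tx_id, seq_len(n)),
        sequence = seqs, tx_id = t$tx_id, locus_id = t$locus_id,
        tx_pos = starts, stringsAsFactors = FALSE)
    }
    reads <- if (length(out)) do.call(rbind, out) else
      data.frame(read_id = character(0), sequence = character(0),
                 tx_id = character(0), locus_id = character(0),
                 tx_pos = integer(0), stringsAsFactors = FALSE)
    rownames(reads) <- NULL
    if (nrow(reads) > 0L && cfg$n_injection_rate > 0) {
      hit <- which(stats::runif(nrow(reads)) < cfg$n_injection_rate)
      for (i in hit) {
        pos <- sample.int(nchar(reads$sequence[i]), 1L)
        substr(reads$sequence[i], pos, pos) <- "N"
      }
    }
    counts <- if (nrow(reads)) {
      tt <- table(reads$locus_id)
      setNames(as.vector(tt), names(tt))
    } else setNames(numeric(0), character(0))
    list(reads = reads, true_counts = counts, stage = stage)
  })
}

#' Write a simulated read set as FASTQ
#' @param rnaseq Output of [simulate_rnaseq()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rnaseq, path) {
  r <- rnaseq$reads
  if (nrow(r) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", r$read_id), r$sequence, "+",
                           strrep("I", nchar(r$sequence))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a probe intensity table as TSV
#'
#' Columns: `probe_id`, `sequence`, `strand`, `intensity_1` (and the
#' noise-free truth as `truth_intensity`).
#' @param probes Output of [simulate_hybmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  df <- data.frame(probe_id = probes$probe_id, sequence = probes$sequence,
                   strand = probes$strand, intensity_1 = probes$intensity,
                   truth_intensity = probes$truth_intensity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count-level generator of coupled LTR-gene stage profiles
#'
#' Lightweight generator for statistical calibration of the timepoint
#' shuffle test: per pair, growth and per-stage read counts are Poisson
#' around a base mean scaled by log2-normal stage multipliers, with the
#' gene's multipliers correlated to the LTR's at `rho`.
#'
#' @param n_pairs Number of LTR-gene pairs.
#' @param rho Coupling between LTR and gene stage multipliers.
#' @param base_mu Mean growth-phase read count.
#' @param stage_sdlog SD of log2 stage multipliers.
#' @param n_stages Number of meiosis stages.
#' @param seed Integer seed.
#' @return A list `ltr_counts`, `gene_counts` (matrices pairs x
#'   (growth + stages)), and the log-ratio matrices `ltr_lr`, `gene_lr`
#'   (pairs x stages, pseudocount 0.5 guards against zero counts).
#' @export
simulate_coupled_profiles <- function(n_pairs = 8L, rho = 0, base_mu = 100,
                                      stage_sdlog = 1, n_stages = 5L,
                                      seed = 1L) {
  with_seed(seed, {
    zl <- matrix(stats::rnorm(n_pairs * n_stages, 0, stage_sdlog),
                 n_pairs, n_stages)
    zg <- rho * zl + sqrt(1 - rho^2) *
      matrix(stats::rnorm(n_pairs * n_stages, 0, stage_sdlog),
             n_pairs, n_stages)
    draw <- function(z) {
      g <- stats::rpois(n_pairs, base_mu)
      m <- matrix(stats::rpois(n_pairs * n_stages, base_mu * 2^z),
                  n_pairs, n_stages)
      cbind(growth = g, m)
    }
    lc <- draw(zl); gc_ <- draw(zg)
    stages <- paste0("M", seq_len(n_stages))
    colnames(lc) <- colnames(gc_) <- c("growth", stages)
    lr <- function(m) log2((m[, stages, drop = FALSE] + 0.5) / (m[, "growth"] + 0.5))
    list(ltr_counts = lc, gene_counts = gc_,
         ltr_lr = lr(lc), gene_lr = lr(gc_))
  })
}

#' Write a simulation bundle to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `probes.tsv` (with intensities),
#' one `reads_<stage>.fastq` per stage, `truth.json`, and
#' `solitary_alignment.fa` / `elements_alignment.fa` (the family sequences;
#' with substitution-only divergence the equal-length set is already a
#' valid alignment).
#'
#' @param bundle A `SimBundle`.
#' @param dir Output directory (created if absent).
#' @param stages Stages to emit reads for (default: all configured).
#' @return Named list of output paths.
#' @export
simulate_bundle <- function(bundle, dir, stages = bundle$config$stages) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                annotation = file.path(dir, "annotation.gff3"),
                probes = file.path(dir, "probes.tsv"),
                truth = file.path(dir, "truth.json"),
                solitary_alignment = file.path(dir, "solitary_alignment.fa"),
                elements_alignment = file.path(dir, "elements_alignment.fa"))
  Biostrings::writeXStringSet(bundle$catalog$seqs, paths$genome)
  write_catalog_gff(bundle$catalog, paths$annotation)
  probes <- simulate_hybmap(bundle, simulate_probes(bundle))
  write_probe_table(probes, paths$probes)
  for (st in stages) {
    p <- file.path(dir, paste0("reads_", st, ".fastq"))
    write_fastq(simulate_rnaseq(bundle, st), p)
    paths[[paste0("reads_", st)]] <- p
  }
  loci <- bundle$truth$loci
  sol <- loci[loci$class == "solitary", ]
  sol_seqs <- vapply(seq_len(nrow(sol)), function(i)
    interval_seq(bundle$catalog, sol$chrom[i], sol$start[i], sol$end[i]), "")
  writeLines(paste0(">", sol$locus_id, "\n", sol_seqs), paths$solitary_alignment)
  el <- loci[loci$class == "element", ]
  el_seqs <- vapply(seq_len(nrow(el)), function(i)
    interval_seq(bundle$catalog, el$chrom[i], el$start[i], el$end[i]), "")
  writeLines(paste0(">", el$locus_id, "\n", el_seqs), paths$elements_alignment)
  jsonlite::write_json(list(loci = loci,
                            stage_mult = as.data.frame(bundle$truth$stage_mult),
                            seed = bundle$config$seed),
                       paths$truth, digits = NA)
  invisible(paths)
}
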