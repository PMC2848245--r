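## End-to-end orchestration: the growth-phase analysis (probe intensity
## distributions, two-scenario locus signals, per-locus means, flank
## contrast, alignment densities) and the meiosis analysis (LTR-gene pair
## selection, stage profiles, correlation + shuffle test, set-level
## profiles). Runs are seeded and every filter count is logged.

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing ", what, ": ", if (is.null(path)) "(not set)" else path)
  }
  path
}

.log_lines <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  writeLines(msg, con)
}

## parse "chrom:start:end:strand;..." hit strings into an interval frame
.hits_to_intervals <- function(records) {
  keep <- records$hits != ""
  rec <- records[keep, , drop = FALSE]
  parts <- strsplit(rec$hits, ";", fixed = TRUE)
  flat <- unlist(parts)
  f <- strsplit(flat, ":", fixed = TRUE)
  data.frame(query_id = rep(rec$query_id, lengths(parts)),
             chrom = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 2L)),
             end = as.integer(vapply(f, `[`, "", 3L)),
             genome_strand = vapply(f, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Run the growth-phase analysis
#'
#' Parses genome and annotation, partitions the LTRs, maps the probe table
#' against the full-length element set (exclusive allowed) and the solitary
#' LTR set (unique only), and writes the growth-phase report bundle:
#' intensity distributions, the equal-split / single-locus-max / unique-only
#' locus signals, per-locus mean intensities, flank-contrast statistics, and
#' a sliding-window density profile over the solitary LTR alignment.
#'
#' @param paths Named list of input paths: `genome`, `annotation`, `probes`,
#'   and optionally `solitary_alignment`.
#' @param out_dir Output directory (created).
#' @param seed Integer seed, recorded in the stats report.
#' @param gap_tol LTR/internal adjacency tolerance (bp).
#' @param window Sliding-window length for the alignment density (odd bp).
#' @return Invisibly, a list with the main in-memory results and the output
#'   paths.
#' @export
run_growth_analysis <- function(paths, out_dir, seed = 1L, gap_tol = 50L,
                                window = 301L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_growth.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  catalog <- parse_annotation(.need_file(paths$genome, "genome FASTA"),
                              .need_file(paths$annotation, "annotation GFF3"))
  probes <- read_probe_table(.need_file(paths$probes, "probe table"))
  part <- partition_ltrs(catalog, gap_tol = gap_tol)
  spans <- element_spans(part)
  sol <- part$solitary
  .log_lines(con, "seed\t", seed)
  .log_lines(con, "n_probes\t", nrow(probes))
  .log_lines(con, "n_elements\t", nrow(spans), "\tn_solitary\t", nrow(sol))

  hits <- find_hits_table(probes, catalog)
  .log_lines(con, "probes_with_N\t", length(attr(hits, "ambiguous_ids")))
  rec_fl <- map_query_table(probes, catalog, spans, "exclusive_ok", hits = hits)
  rec_sol <- map_query_table(probes, catalog, sol, "unique_only", hits = hits)
  for (lbl in c("fl", "sol")) {
    cc <- attr(if (lbl == "fl") rec_fl else rec_sol, "class_counts")
    .log_lines(con, "classes_", lbl, "\tunique=", cc["unique"],
               "\texclusive=", cc["exclusive"], "\texcluded=", cc["excluded"])
  }

  sig <- rbind(equal_split(rec_fl, spans, by_strand = TRUE),
               single_locus_max(rec_fl, spans, by_strand = TRUE),
               assign_signal(rec_fl, spans, "unique_only", by_strand = TRUE))
  write_signal_table(sig, file.path(out_dir, "element_signals.tsv"))

  means <- per_locus_mean_intensity(rec_sol, sol)
  utils::write.table(means, file.path(out_dir, "solitary_locus_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  uni <- rec_sol[rec_sol$klass == "unique", , drop = FALSE]
  hist <- intensity_histogram(uni$signal[uni$strand_tag == "forward"],
                              uni$signal[uni$strand_tag == "reverse"])
  utils::write.table(hist, file.path(out_dir, "solitary_intensity_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  frames <- build_flank_frames(sol, catalog)
  write_flank_table(frames, file.path(out_dir, "flank_frames.tsv"))
  upos <- .hits_to_intervals(uni)
  upos$intensity <- uni$signal[match(upos$query_id, uni$query_id)]
  contrast <- flank_contrast(frames, upos)
  .log_lines(con, "flank_n\tin=", contrast$n_in, "\tup=", contrast$n_up,
             "\tdown=", contrast$n_down)

  density <- NULL
  if (!is.null(paths$solitary_alignment) && file.exists(paths$solitary_alignment)) {
    aln <- read_alignment(paths$solitary_alignment)
    proj <- project_records(uni, aln, loci = sol)
    if (aln$ncols >= window) {
      density <- window_density(proj$column, aln$ncols, window = window,
                                n_rows = length(aln$rows))
      utils::write.table(
        data.frame(column = seq_len(aln$ncols) - 1L, density = density),
        file.path(out_dir, "alignment_density.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      .log_lines(con, "alignment shorter than window; density skipped")
    }
  }

  stats <- list(seed = seed, flank_contrast = contrast[c(
    "median_in", "median_up", "median_down", "U_up", "p_up", "U_down",
    "p_down", "n_in", "n_up", "n_down")])
  jsonlite::write_json(stats, file.path(out_dir, "growth_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(catalog = catalog, partition = part, records_fl = rec_fl,
                 records_sol = rec_sol, signals = sig, means = means,
                 contrast = contrast, density = density,
                 out_dir = out_dir, log = log_path))
}

#' Run the meiosis time-course analysis
#'
#' Maps the per-stage read sets uniquely against solitary LTRs and genes,
#' selects LTR-gene pairs by the uniquely-mapped count thresholds and the
#' 1000-bp upstream rule, computes stage log2-ratio profiles, the
#' concatenated Pearson correlation, the within-timepoint shuffle test, and
#' set-level stage profiles from exclusively mapping reads.
#'
#' @param paths Named list with `genome`, `annotation`, and one
#'   `reads_<stage>` FASTQ per stage (`growth`, `M1`..`M5` by default).
#' @param out_dir Output directory.
#' @param seed Seed for the permutation test.
#' @param stages Stage names (first must be `growth`).
#' @param n_perm Permutations for the shuffle test.
#' @param min_total,min_growth,upstream_within Pair-selection thresholds.
#' @param pseudocount Pseudocount for the stage log ratios (0 by default;
#'   use a positive value when a stage may have zero counts).
#' @return Invisibly, a list with counts, the selected pairs, the profile
#'   matrices, `concatenated_r`, the `PermutationResult` (or `NULL` if
#'   fewer than two pairs), and set-level profiles.
#' @export
run_meiosis_analysis <- function(paths, out_dir, seed = 1L,
                                 stages = c("growth", paste0("M", 1:5)),
                                 n_perm = 10000L, min_total = 30L,
                                 min_growth = 10L, upstream_within = 1000L,
                                 pseudocount = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_meiosis.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  catalog <- parse_annotation(.need_file(paths$genome, "genome FASTA"),
                              .need_file(paths$annotation, "annotation GFF3"))
  part <- partition_ltrs(catalog)
  sol <- part$solitary
  spans <- element_spans(part)
  genes <- catalog$features[catalog$features$kind == "gene", , drop = FALSE]

  ltr_counts <- matrix(0, nrow(sol), length(stages),
                       dimnames = list(sol$id, stages))
  gene_counts <- matrix(0, nrow(genes), length(stages),
                        dimnames = list(genes$id, stages))
  excl_sol <- excl_fl <- totals <- setNames(numeric(length(stages)), stages)
  for (st in stages) {
    reads <- read_fastq_queries(
      .need_file(paths[[paste0("reads_", st)]], paste0(st, " FASTQ")))
    totals[st] <- nrow(reads)
    if (nrow(reads) == 0L) {
      .log_lines(con, "stage ", st, ": empty FASTQ")
      next
    }
    hits <- find_hits_table(reads, catalog)
    .log_lines(con, "stage ", st, ": reads=", nrow(reads), " with_N=",
               length(attr(hits, "ambiguous_ids")))
    rs <- map_query_table(reads, catalog, sol, "unique_only", hits = hits)
    rg <- map_query_table(reads, catalog, genes, "unique_only", hits = hits)
    re_s <- map_query_table(reads, catalog, sol, "exclusive_ok", hits = hits)
    re_f <- map_query_table(reads, catalog, spans, "exclusive_ok", hits = hits)
    cnt <- function(rec) {
      k <- rec[rec$klass == "unique", , drop = FALSE]
      tab <- table(k$loci)
      tab
    }
    tu <- cnt(rs); ltr_counts[names(tu), st] <- as.vector(tu)
    tg <- cnt(rg); gene_counts[names(tg), st] <- as.vector(tg)
    excl_sol[st] <- sum(re_s$klass %in% c("unique", "exclusive"))
    excl_fl[st] <- sum(re_f$klass %in% c("unique", "exclusive"))
  }

  pairs <- select_meiosis_ltrs(ltr_counts, sol, genes, min_total = min_total,
                               min_growth = min_growth,
                               upstream_within = upstream_within)
  utils::write.table(pairs, file.path(out_dir, "ltr_gene_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_lines(con, "selected_pairs\t", nrow(pairs))

  mstages <- setdiff(stages, "growth")
  result <- list(counts_ltr = ltr_counts, counts_gene = gene_counts,
                 pairs = pairs, perm = NULL, concatenated_r = NA_real_)
  stats <- list(seed = seed, n_pairs = nrow(pairs), perm_skipped = FALSE)
  if (nrow(pairs) >= 2L) {
    lr <- function(cmat, ids) t(vapply(ids, function(i)
      stage_log_ratios(cmat[i, ], pseudocount = pseudocount)[mstages],
      setNames(numeric(length(mstages)), mstages)))
    ltr_lr <- lr(ltr_counts, pairs$ltr_id)
    gene_lr <- lr(gene_counts, pairs$gene_id)
    ## a zero stage count with pseudocount 0 gives an infinite log ratio;
    ## such pairs cannot enter the correlation machinery and are dropped
    finite <- is.finite(rowSums(ltr_lr)) & is.finite(rowSums(gene_lr))
    if (any(!finite)) {
      .log_lines(con, "dropping ", sum(!finite),
                 " pair(s) with non-finite log ratios")
      pairs <- pairs[finite, , drop = FALSE]
      ltr_lr <- ltr_lr[finite, , drop = FALSE]
      gene_lr <- gene_lr[finite, , drop = FALSE]
    }
    if (nrow(pairs) >= 2L) {
      prof <- data.frame(
        entity_id = c(rep(pairs$ltr_id, each = length(mstages)),
                      rep(pairs$gene_id, each = length(mstages))),
        stage = rep(mstages, 2L * nrow(pairs)),
        log_ratio = c(as.vector(t(ltr_lr)), as.vector(t(gene_lr))))
      utils::write.table(prof, file.path(out_dir, "stage_profiles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      r <- concatenated_pearson(ltr_lr, gene_lr)
      perm <- timepoint_permutation_test(ltr_lr, gene_lr, n_perm = n_perm,
                                         seed = seed)
      write_perm_result(perm, "timepoint_shuffle",
                        file.path(out_dir, "timepoint_perm.json"))
      result$pairs <- pairs
      result$perm <- perm
      result$concatenated_r <- r
      result$ltr_lr <- ltr_lr
      result$gene_lr <- gene_lr
      stats$concatenated_r <- r
      stats$observed_median_r <- perm$observed
      stats$perm_p <- perm$p_value
      stats$significant_at_0.01 <- perm$p_value < 0.01
    } else {
      .log_lines(con, "fewer than 2 usable pairs; permutation test skipped")
      stats$perm_skipped <- TRUE
    }
  } else {
    .log_lines(con, "fewer than 2 selected LTRs; permutation test skipped")
    stats$perm_skipped <- TRUE
  }

  set_prof <- list()
  for (nm in c("solitary", "full_length")) {
    ec <- if (nm == "solitary") excl_sol else excl_fl
    if (all(totals > 0) && ec[["growth"]] > 0) {
      set_prof[[nm]] <- set_level_stage_profile(ec, totals)
    }
  }
  if (length(set_prof)) {
    sp <- do.call(rbind, lapply(names(set_prof), function(nm)
      data.frame(set = nm, stage = names(set_prof[[nm]]),
                 log_ratio = unname(set_prof[[nm]]))))
    utils::write.table(sp, file.path(out_dir, "set_level_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result$set_profiles <- set_prof
  jsonlite::write_json(stats, file.path(out_dir, "meiosis_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
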