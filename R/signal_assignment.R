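## Per-locus activity under the two bounding assignment scenarios, per-locus
## averages, intensity distributions, and abundance/density metrics.

.locus_lengths <- function(loci) {
  setNames(loci$end - loci$start, loci$id)
}

.records_loci_list <- function(records) {
  strsplit(records$loci, ";", fixed = TRUE)
}

.signal_frame <- function(loci, value, scenario, strand, lengths) {
  data.frame(locus_id = loci, scenario = scenario, strand = strand,
             value = value, density = value / lengths[loci],
             stringsAsFactors = FALSE, row.names = NULL)
}

## shared worker: per-locus totals under one scenario for one strand slice
.assign_one <- function(records, loci, scenario) {
  lens <- .locus_lengths(loci)
  keep <- records$klass %in% c("unique", "exclusive")
  if (scenario == "unique_only") keep <- records$klass == "unique"
  rec <- records[keep, , drop = FALSE]
  val <- setNames(numeric(nrow(loci)), loci$id)
  if (nrow(rec) > 0L) {
    ll <- .records_loci_list(rec)
    w <- switch(scenario,
                equal_split = rec$signal / lengths(ll),
                single_locus_max = rec$signal,
                unique_only = rec$signal)
    contrib <- rowsum(rep(w, lengths(ll)), unlist(ll))
    val[rownames(contrib)] <- contrib[, 1]
  }
  val
}

#' Per-locus signal under an assignment scenario
#'
#' Converts classified mapping records into per-locus activity. Three
#' scenarios bracket the truth under multi-mapping ambiguity:
#' \describe{
#'   \item{`equal_split`}{each query contributes `signal / n_loci` to every
#'     locus it hits (two LTRs sharing one read get 0.5 read each); per-locus
#'     values sum to the total assigned signal.}
#'   \item{`single_locus_max`}{every locus is granted the full signal of all
#'     queries that can hit it -- a per-locus upper bound, computed
#'     independently per locus (not one globally consistent allocation).}
#'   \item{`unique_only`}{only uniquely mapping queries count -- a floor.}
#' }
#' Excluded records are ignored (their number is returned as an attribute).
#'
#' @param records Mapping table from [map_query_table()] (reads have
#'   `signal = 1`).
#' @param loci Interval data.frame of the analysis set (`id`, `start`, `end`).
#' @param scenario One of `"equal_split"`, `"single_locus_max"`,
#'   `"unique_only"`.
#' @param by_strand Split probe records by their `strand_tag` and emit one
#'   row per locus and strand; otherwise strand is `"combined"`.
#' @return A data.frame `locus_id`, `scenario`, `strand`, `value`, `density`
#'   (value per bp of locus length).
#' @export
assign_signal <- function(records, loci,
                          scenario = c("equal_split", "single_locus_max",
                                       "unique_only"),
                          by_strand = FALSE) {
  scenario <- match.arg(scenario)
  lens <- .locus_lengths(loci)
  n_excluded <- sum(records$klass == "excluded")
  if (by_strand) {
    out <- do.call(rbind, lapply(unique(records$strand_tag), function(s) {
      v <- .assign_one(records[records$strand_tag == s, , drop = FALSE],
                       loci, scenario)
      .signal_frame(names(v), unname(v), scenario,
                    switch(s, forward = "forward", reverse = "reverse", s),
                    lens)
    }))
  } else {
    v <- .assign_one(records, loci, scenario)
    out <- .signal_frame(names(v), unname(v), scenario, "combined", lens)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Equal-split assignment (lower scenario)
#' @inheritParams assign_signal
#' @return See [assign_signal()].
#' @export
equal_split <- function(records, loci, by_strand = FALSE) {
  assign_signal(records, loci, "equal_split", by_strand)
}

#' Single-locus maximum (upper bound)
#' @inheritParams assign_signal
#' @return See [assign_signal()].
#' @export
single_locus_max <- function(records, loci, by_strand = FALSE) {
  assign_signal(records, loci, "single_locus_max", by_strand)
}

#' Per-probe equal-split values
#'
#' The per-probe analogue of the equal-split scenario used for intensity
#' distributions: each in-set probe's intensity divided by its number of
#' possible mappings (genome-wide hits).
#'
#' @param records Mapping table of probes (unique + exclusive records used).
#' @return A data.frame `query_id`, `strand_tag`, `value`.
#' @export
per_probe_split_values <- function(records) {
  rec <- records[records$klass %in% c("unique", "exclusive"), , drop = FALSE]
  data.frame(query_id = rec$query_id, strand_tag = rec$strand_tag,
             value = rec$signal / rec$n_hits,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean probe intensity per locus (uniquely mapping probes)
#'
#' Arithmetic mean of the intensities of uniquely mapping probes contained
#' in each locus, per probe strand; loci with no probes are omitted.
#'
#' @param records Mapping table of probes classified against the locus set.
#' @param loci Interval data.frame of the locus set.
#' @return A data.frame `locus_id`, `strand`, `n_probes`, `mean_intensity`.
#' @export
per_locus_mean_intensity <- function(records, loci) {
  rec <- records[records$klass == "unique", , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(locus_id = character(0), strand = character(0),
                      n_probes = integer(0), mean_intensity = numeric(0)))
  }
  locus <- vapply(.records_loci_list(rec), `[`, "", 1L)
  key <- paste(locus, rec$strand_tag, sep = "\r")
  m <- rowsum(rec$signal, key) / as.vector(table(key)[sort(unique(key))])
  parts <- strsplit(rownames(m), "\r", fixed = TRUE)
  out <- data.frame(locus_id = vapply(parts, `[`, "", 1L),
                    strand = vapply(parts, `[`, "", 2L),
                    n_probes = as.vector(table(key)[sort(unique(key))]),
                    mean_intensity = m[, 1],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$locus_id, out$strand), , drop = FALSE]
}

#' Binned intensity distribution per strand
#'
#' Groups values into bins of fixed width covering the data range and
#' reports the fraction of values per bin and strand (each strand's
#' fractions sum to 1 when any value is present).
#'
#' @param forward,reverse Numeric intensity vectors (either may be empty).
#' @param bin_width Positive bin width.
#' @return A data.frame `bin_lo`, `bin_hi`, `fraction_forward`,
#'   `fraction_reverse`.
#' @export
intensity_histogram <- function(forward, reverse = numeric(0), bin_width = 0.5) {
  stopifnot(bin_width > 0)
  all_v <- c(forward, reverse)
  if (length(all_v) == 0L) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      fraction_forward = numeric(0),
                      fraction_reverse = numeric(0)))
  }
  lo <- floor(min(all_v) / bin_width) * bin_width
  hi <- max(all_v)
  edges <- seq(lo, lo + bin_width * ceiling((hi - lo) / bin_width + 1e-9),
               by = bin_width)
  if (edges[length(edges)] <= hi) edges <- c(edges, edges[length(edges)] + bin_width)
  frac <- function(v) {
    if (length(v) == 0L) return(rep(0, length(edges) - 1L))
    tabulate(findInterval(v, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1L) / length(v)
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             fraction_forward = frac(forward), fraction_reverse = frac(reverse))
}

#' Abundance metrics: log10 read counts and read density
#'
#' Read density (count per bp) is biased against long transcripts under
#' 3'-biased library protocols, so the log10-transformed absolute count is
#' provided alongside it as the length-unbiased abundance measure.
#'
#' @param counts Named numeric vector of per-locus read counts.
#' @param lengths Named numeric vector of locus lengths (bp), same names.
#' @param pseudocount Added to counts before log10 (must be > 0 when any
#'   count is zero).
#' @return A data.frame `locus_id`, `count`, `log10_count`, `density`.
#' @export
abundance_metrics <- function(counts, lengths, pseudocount = 1) {
  lengths <- lengths[names(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("every locus needs a positive length")
  }
  if (any(counts == 0) && pseudocount <= 0) {
    stop("zero counts present: pseudocount must be > 0")
  }
  data.frame(locus_id = names(counts), count = unname(counts),
             log10_count = log10(unname(counts) + pseudocount),
             density = unname(counts / lengths),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write locus signals as TSV (`locus_id`, `scenario`, `strand`, `value`,
#' `density`)
#' @param signals Output of [assign_signal()] (rows may be concatenated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signals, path) {
  utils::write.table(signals[, c("locus_id", "scenario", "strand", "value",
                                 "density")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
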