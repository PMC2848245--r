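## Solitary-LTR clustering by pairwise identity, projection of mappings onto
## alignment columns, flank coordinate frames, and sliding-window densities.

#' Read an aligned FASTA into an alignment object
#'
#' @param path Aligned FASTA path (gap character `-`).
#' @return An object of class `LtrAlignment`: list with `rows` (named
#'   character vector of gapped sequences), `ncols`, and `seq_to_col`
#'   (per row, an integer vector mapping 0-based residue index `i` --
#'   element `i + 1` -- to its 0-based alignment column).
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  make_alignment(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' Build an alignment object from gapped sequences
#' @param rows Named character vector of equal-length gapped sequences.
#' @return An `LtrAlignment` (see [read_alignment()]).
#' @export
make_alignment <- function(rows) {
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("all gapped sequences must have the same length")
  seq_to_col <- lapply(rows, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] != "-") - 1L
  })
  structure(list(rows = rows, ncols = w, seq_to_col = seq_to_col),
            class = "LtrAlignment")
}

#' @export
print.LtrAlignment <- function(x, ...) {
  cat("LtrAlignment:", length(x$rows), "rows x", x$ncols, "columns\n")
  invisible(x)
}

#' Pairwise identity from a global alignment
#'
#' Globally aligns two sequences (match +1, mismatch -1, gap -2 per gapped
#' position) and returns matched positions divided by aligned columns; gap
#' columns count in the denominator, so length differences are penalized.
#'
#' @param a,b DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / ncols
}

#' Single-linkage clustering of LTR sequences by pairwise identity
#'
#' Edges connect pairs with identity at or above `threshold`; clusters are
#' the connected components (a cluster absorbs another whenever any member
#' of one is similar enough to any member of the other). Output ordering is
#' canonical -- clusters sorted by their smallest member id, members sorted
#' within each cluster -- so the result is invariant to input order.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param threshold Identity cut-off (default 0.70).
#' @param identities Optional precomputed symmetric identity matrix
#'   (dimnames = sequence ids); computed via [pairwise_identity()] if absent.
#' @return A list of character vectors of sequence ids.
#' @export
cluster_ltrs <- function(seqs, threshold = 0.70, identities = NULL) {
  ids <- names(seqs)
  stopifnot(length(ids) >= 1L)
  if (is.null(identities)) identities <- identity_matrix(seqs)
  identities <- identities[ids, ids, drop = FALSE]
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (identities[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  cl <- unname(lapply(split(ids, comp), sort))
  cl[order(vapply(cl, `[`, "", 1L))]
}

#' All pairwise identities of a sequence set
#' @param seqs Named character vector of DNA sequences.
#' @return A symmetric matrix of identity fractions (diagonal 1).
#' @export
identity_matrix <- function(seqs) {
  ids <- names(seqs)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
      }
    }
  }
  m
}

#' Cluster-size diagnostic across identity thresholds
#'
#' Reports, for each threshold, the number of clusters and the size of the
#' largest -- the diagnostic used to pick a similarity cut-off by watching
#' how cluster sizes change.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param thresholds Identity thresholds to sweep.
#' @return A data.frame `threshold`, `n_clusters`, `largest`.
#' @export
cluster_threshold_sweep <- function(seqs, thresholds = seq(0.5, 0.95, by = 0.05)) {
  idm <- identity_matrix(seqs)
  do.call(rbind, lapply(thresholds, function(th) {
    cl <- cluster_ltrs(seqs, threshold = th, identities = idm)
    data.frame(threshold = th, n_clusters = length(cl),
               largest = max(lengths(cl)))
  }))
}

#' Project a mapping record onto an alignment column
#'
#' Selects the first locus in `set_order` hit by the query, takes the
#' midpoint residue of the hit on that sequence (left-of-center for
#' even-length queries: `floor((start + end - 1) / 2)` in 0-based
#' coordinates), and transfers it to the corresponding alignment column.
#'
#' @param record One row of a mapping table ([map_query_table()]).
#' @param alignment An `LtrAlignment` whose rows are named by locus id.
#' @param set_order Character vector fixing the "first instance" order of
#'   loci (defaults to the alignment row order).
#' @param loci Interval data.frame giving each locus's genomic interval and
#'   strand (alignment rows hold the strand-oriented locus sequence).
#' @return A list `row` (locus id), `residue` (0-based index on the locus
#'   sequence), `column` (0-based alignment column); `NULL` (with a message)
#'   when no hit locus is present in the alignment.
#' @export
project_to_alignment <- function(record, alignment, set_order = names(alignment$rows),
                                 loci) {
  hit_loci <- strsplit(record$loci, ";", fixed = TRUE)[[1]]
  sel <- set_order[set_order %in% hit_loci & set_order %in% names(alignment$rows)]
  if (length(sel) == 0L) {
    message("query ", record$query_id, ": no hit locus in alignment; skipped")
    return(NULL)
  }
  row_id <- sel[1]
  li <- loci[match(row_id, loci$id), ]
  hits <- do.call(rbind, lapply(strsplit(record$hits, ";", fixed = TRUE)[[1]],
                                function(h) {
    p <- strsplit(h, ":", fixed = TRUE)[[1]]
    data.frame(chrom = p[1], start = as.integer(p[2]), end = as.integer(p[3]),
               stringsAsFactors = FALSE)
  }))
  inside <- hits$chrom == li$chrom & hits$start >= li$start & hits$end <= li$end
  if (!any(inside)) {
    message("query ", record$query_id, ": hit not contained in ", row_id, "; skipped")
    return(NULL)
  }
  h <- hits[which(inside)[1], ]
  if (identical(li$strand, "-")) {
    s_on <- li$end - h$end
    e_on <- li$end - h$start
  } else {
    s_on <- h$start - li$start
    e_on <- h$end - li$start
  }
  residue <- floor((s_on + e_on - 1) / 2)
  col <- alignment$seq_to_col[[row_id]][residue + 1L]
  list(row = row_id, residue = residue, column = col)
}

#' Project many records onto alignment columns
#' @inheritParams project_to_alignment
#' @param records Mapping table (unique/exclusive rows are used).
#' @return A data.frame `query_id`, `row`, `residue`, `column`.
#' @export
project_records <- function(records, alignment, set_order = names(alignment$rows),
                            loci) {
  rec <- records[records$klass %in% c("unique", "exclusive"), , drop = FALSE]
  out <- lapply(seq_len(nrow(rec)), function(i) {
    p <- project_to_alignment(rec[i, ], alignment, set_order, loci)
    if (is.null(p)) return(NULL)
    data.frame(query_id = rec$query_id[i], row = p$row, residue = p$residue,
               column = p$column, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(query_id = character(0), row = character(0),
                                      residue = integer(0), column = integer(0))
  out
}

#' Build a flank coordinate frame around a solitary LTR
#'
#' Up to `max_flank` bp of flanking sequence is taken on each side. If the
#' distance to the nearest other annotated feature is below `near_threshold`
#' only half that distance is used, and if that half falls below `min_flank`
#' no flank is included on that side. Flanks are truncated at chromosome
#' edges.
#'
#' @param ltr One row of an LTR locus table (`id`, `chrom`, `start`, `end`).
#' @param catalog A `FeatureCatalog` (all features except the LTR itself are
#'   distance obstacles).
#' @param max_flank,near_threshold,min_flank Rule parameters (bp).
#' @return A list `locus_id`, `ltr` interval, `up_flank`, `down_flank`
#'   (each a `(chrom, start, end)` data.frame or `NULL`).
#' @export
build_flank_frame <- function(ltr, catalog, max_flank = 500L,
                              near_threshold = 1000L, min_flank = 60L) {
  f <- catalog$features
  f <- f[!(f$id == ltr$id) & f$chrom == ltr$chrom, , drop = FALSE]
  clen <- Biostrings::width(catalog$seqs)[match(ltr$chrom, names(catalog$seqs))]
  up_feats <- f[f$end <= ltr$start, , drop = FALSE]
  dn_feats <- f[f$start >= ltr$end, , drop = FALSE]
  d_up <- if (nrow(up_feats)) ltr$start - max(up_feats$end) else Inf
  d_dn <- if (nrow(dn_feats)) min(dn_feats$start) - ltr$end else Inf
  flank_len <- function(d) {
    if (d >= near_threshold) return(max_flank)
    half <- floor(d / 2)
    if (half < min_flank) 0L else as.integer(half)
  }
  lu <- min(flank_len(d_up), ltr$start)          # truncate at chromosome edge
  ld <- min(flank_len(d_dn), clen - ltr$end)
  mk <- function(s, e) if (e > s)
    data.frame(chrom = ltr$chrom, start = s, end = e, stringsAsFactors = FALSE)
  else NULL
  list(locus_id = ltr$id,
       ltr = data.frame(chrom = ltr$chrom, start = ltr$start, end = ltr$end,
                        stringsAsFactors = FALSE),
       up_flank = mk(ltr$start - lu, ltr$start),
       down_flank = mk(ltr$end, ltr$end + ld))
}

#' Flank frames for a table of LTR loci
#' @param ltrs LTR locus table.
#' @inheritParams build_flank_frame
#' @return A list of flank frames (see [build_flank_frame()]).
#' @export
build_flank_frames <- function(ltrs, catalog, max_flank = 500L,
                               near_threshold = 1000L, min_flank = 60L) {
  lapply(seq_len(nrow(ltrs)), function(i)
    build_flank_frame(ltrs[i, ], catalog, max_flank, near_threshold, min_flank))
}

#' Write flank frames as TSV
#' (`locus_id`, `up_start`, `up_end`, `down_start`, `down_end`; empty flanks
#' as NA)
#' @param frames List from [build_flank_frames()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flank_table <- function(frames, path) {
  g <- function(x, f) if (is.null(x)) NA_integer_ else x[[f]]
  df <- do.call(rbind, lapply(frames, function(fr)
    data.frame(locus_id = fr$locus_id,
               up_start = g(fr$up_flank, "start"), up_end = g(fr$up_flank, "end"),
               down_start = g(fr$down_flank, "start"),
               down_end = g(fr$down_flank, "end"))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sliding-window density over alignment columns
#'
#' Centered moving average of per-column counts, divided by the number of
#' aligned sequences ("reads mapped per sequence in the alignment"). At the
#' alignment ends the window is truncated and the average taken over the
#' available columns.
#'
#' @param columns Integer vector of 0-based column positions (one entry per
#'   mapped query), or a two-column data.frame `(column, weight)` for
#'   weighted counts.
#' @param ncols Number of alignment columns.
#' @param window Odd window length (default 301).
#' @param n_rows Number of sequences in the alignment.
#' @return Numeric vector of length `ncols` (density per column).
#' @export
window_density <- function(columns, ncols, window = 301L, n_rows) {
  stopifnot(window %% 2L == 1L)
  if (window > ncols) stop("window larger than the alignment")
  counts <- numeric(ncols)
  if (is.data.frame(columns)) {
    agg <- rowsum(columns[[2]], columns[[1]])
    counts[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  } else if (length(columns) > 0L) {
    tab <- table(columns)
    counts[as.integer(names(tab)) + 1L] <- as.vector(tab)
  }
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(ncols) - half, 1L)
  hi <- pmin(seq_len(ncols) + half, ncols)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L) / n_rows
}

#' Compare in-LTR probe intensities with their flanking compartments
#'
#' Uniquely mapping probes are assigned to the in-LTR, upstream-flank or
#' downstream-flank compartment of their locus by interval containment;
#' medians per compartment are reported together with one-sided
#' Mann-Whitney comparisons testing whether each flank is lower than the
#' in-LTR compartment (U reported for the flank group, so complete
#' separation gives U = 0).
#'
#' @param frames List of flank frames ([build_flank_frames()]).
#' @param probes Data.frame of uniquely mapped probes with columns `chrom`,
#'   `start`, `end`, `intensity`.
#' @return A list `median_in`, `median_up`, `median_down`, `U_up`, `p_up`,
#'   `U_down`, `p_down`, `n_in`, `n_up`, `n_down`.
#' @export
flank_contrast <- function(frames, probes) {
  comp <- function(field) {
    ivs <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(frames, function(fr) fr[[field]])))
    if (is.null(ivs) || nrow(probes) == 0L) return(numeric(0))
    ivs$id <- paste0("c", seq_len(nrow(ivs)))
    inside <- lengths(contained_in(probes, ivs)) > 0L
    probes$intensity[inside]
  }
  vin <- comp("ltr"); vup <- comp("up_flank"); vdn <- comp("down_flank")
  test <- function(flank) {
    if (length(flank) == 0L || length(vin) == 0L) {
      message("empty compartment: comparison skipped")
      return(list(U = NA_real_, p = NA_real_))
    }
    mw <- mann_whitney(flank, vin, alternative = "less")
    list(U = mw$U, p = mw$p)
  }
  tu <- test(vup); td <- test(vdn)
  list(median_in = stats::median(vin), median_up = stats::median(vup),
       median_down = stats::median(vdn),
       U_up = tu$U, p_up = tu$p, U_down = td$U, p_down = td$p,
       n_in = length(vin), n_up = length(vup), n_down = length(vdn))
}

#' Align sequences with an external aligner (optional subprocess hook)
#'
#' Writes the sequences to a temporary FASTA, runs `aligner` (e.g. mafft)
#' and reads the aligned result back. Purely optional glue: nothing in the
#' package requires an external aligner, and substitution-only sequence
#' families of equal length are already valid alignments as-is.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param aligner Command to run; must accept a FASTA path as final argument
#'   and write aligned FASTA to stdout.
#' @param args Extra command-line arguments.
#' @return An `LtrAlignment`.
#' @export
align_external <- function(seqs, aligner = "mafft", args = "--auto") {
  if (Sys.which(aligner) == "") stop("aligner not found on PATH: ", aligner)
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fin)
  status <- system2(aligner, c(args, shQuote(fin)), stdout = fout,
                    stderr = FALSE)
  if (status != 0L) stop(aligner, " exited with status ", status)
  read_alignment(fout)
}
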