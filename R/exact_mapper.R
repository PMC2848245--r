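## Exact-match placement of reads and probes on both genome strands, with
## exclusive/unique classification against a target feature set. Only
## perfect matches are considered; queries containing N are dropped.

#' Find all exact genomic matches of a query sequence
#'
#' Reports every genomic position where the query occurs verbatim on the
#' forward strand (`genome_strand = "+"`) or where its reverse complement
#' occurs (`genome_strand = "-"`). Queries containing ambiguous calls (N)
#' return no hits and are flagged. A palindromic query (equal to its own
#' reverse complement) yields one hit per position, reported on the forward
#' strand.
#'
#' @param sequence Query DNA string (A/C/G/T/N).
#' @param catalog A `FeatureCatalog` (only `$seqs` is used).
#' @param dedup_palindrome Collapse the duplicate reverse-strand hits of a
#'   palindromic query (default `TRUE`).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `genome_strand`; attribute `ambiguous` is `TRUE` when the
#'   query contained an N.
#' @export
find_exact_matches <- function(sequence, catalog, dedup_palindrome = TRUE) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), genome_strand = character(0),
                      stringsAsFactors = FALSE)
  if (grepl("N", sequence, fixed = TRUE)) {
    attr(empty, "ambiguous") <- TRUE
    return(empty)
  }
  pat <- Biostrings::DNAString(sequence)
  rcp <- Biostrings::reverseComplement(pat)
  palindrome <- as.character(rcp) == as.character(pat)
  out <- list()
  for (chr in names(catalog$seqs)) {
    subj <- catalog$seqs[[chr]]
    m <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
    if (length(m) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = Biostrings::start(m) - 1L,
        end = Biostrings::end(m), genome_strand = "+",
        stringsAsFactors = FALSE)
    }
    if (!(palindrome && dedup_palindrome)) {
      m <- Biostrings::matchPattern(rcp, subj, fixed = TRUE)
      if (length(m) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), genome_strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$chrom, res$start, res$genome_strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "ambiguous") <- FALSE
  res
}

## Vectorized exact matching of many (possibly variable-length) queries.
## One PDict over fixed-width query prefixes seeds candidate positions;
## candidates are then verified against the full query (vectorized string
## comparison), so the semantics are exact full-length matching. Returns
## one data.frame: query_id, chrom, start, end, genome_strand.
.match_many <- function(ids, seqs, catalog, dedup_palindrome = TRUE) {
  keep <- !grepl("N", seqs, fixed = TRUE)
  ids_k <- ids[keep]; seqs_k <- seqs[keep]
  out <- list()
  if (length(seqs_k) > 0L) {
    lens <- nchar(seqs_k)
    w <- min(lens)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(substr(seqs_k, 1L, w)))
    pal <- vapply(seqs_k, function(s)
      identical(s, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))), TRUE, USE.NAMES = FALSE)
    scan_strand <- function(subj_str, subj) {
      m <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) return(NULL)
      qi <- rep(seq_along(seqs_k), cnt)
      s1 <- Biostrings::start(unlist(m))        # 1-based seed start
      ok <- s1 + lens[qi] - 1L <= nchar(subj_str)
      qi <- qi[ok]; s1 <- s1[ok]
      full <- substring(subj_str, s1, s1 + lens[qi] - 1L)
      hit <- full == seqs_k[qi]
      list(qi = qi[hit], s1 = s1[hit])
    }
    for (chr in names(catalog$seqs)) {
      subj <- catalog$seqs[[chr]]
      clen <- length(subj)
      subj_str <- as.character(subj)
      f <- scan_strand(subj_str, subj)
      if (!is.null(f)) {
        out[[length(out) + 1L]] <- data.frame(
          query_id = ids_k[f$qi], chrom = chr, start = f$s1 - 1L,
          end = f$s1 - 1L + lens[f$qi], genome_strand = "+",
          stringsAsFactors = FALSE)
      }
      ## reverse strand: search the queries in the reverse-complemented
      ## chromosome and flip coordinates back
      rsubj <- Biostrings::reverseComplement(subj)
      r <- scan_strand(as.character(rsubj), rsubj)
      if (!is.null(r)) {
        drop_pal <- dedup_palindrome & pal[r$qi]
        qi <- r$qi[!drop_pal]; s1 <- r$s1[!drop_pal]
        if (length(qi)) {
          out[[length(out) + 1L]] <- data.frame(
            query_id = ids_k[qi], chrom = chr,
            start = clen - (s1 - 1L) - lens[qi],
            end = clen - (s1 - 1L), genome_strand = "-",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(query_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               genome_strand = character(0), stringsAsFactors = FALSE)
  attr(hits, "ambiguous_ids") <- ids[!keep]
  hits
}

#' Classify a query's genome-wide hits against a target feature set
#'
#' A hit is in-set iff its full interval lies within one target interval.
#' With all hits in-set the record is `unique` (exactly one hit) or
#' `exclusive` (several); any out-of-set hit, or no hit at all, excludes the
#' query. In `mode = "unique_only"` (the rule for solitary-LTR probes and
#' all non-LTR reference features) exclusive records are demoted to
#' excluded.
#'
#' @param hits Hit data.frame from [find_exact_matches()] (genome-wide).
#' @param target_set Interval data.frame with an `id` column.
#' @param mode `"exclusive_ok"` or `"unique_only"`.
#' @return A list: `klass`, `reason`, `n_hits`, `n_in_set`, `loci`
#'   (distinct ids of target features containing hits).
#' @export
classify_hits <- function(hits, target_set, mode = c("exclusive_ok", "unique_only")) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0L) {
    return(list(klass = "excluded", reason = "no_match", n_hits = 0L,
                n_in_set = 0L, loci = character(0)))
  }
  cont <- contained_in(hits, target_set)
  n_in <- sum(lengths(cont) > 0L)
  loci <- unique(target_set$id[unlist(cont)])
  if (n_in < nrow(hits)) {
    list(klass = "excluded", reason = "outside_set", n_hits = nrow(hits),
         n_in_set = n_in, loci = loci)
  } else if (nrow(hits) == 1L) {
    list(klass = "unique", reason = NA_character_, n_hits = 1L,
         n_in_set = 1L, loci = loci)
  } else if (mode == "exclusive_ok") {
    list(klass = "exclusive", reason = NA_character_, n_hits = nrow(hits),
         n_in_set = n_in, loci = loci)
  } else {
    list(klass = "excluded", reason = "multi_hit", n_hits = nrow(hits),
         n_in_set = n_in, loci = loci)
  }
}

#' Map a table of queries and classify each against a target set
#'
#' Exact-matches every query genome-wide on both strands, then applies the
#' exclusivity/uniqueness classification of [classify_hits()]. Output rows
#' follow input order; a malformed or ambiguous query never aborts the run.
#'
#' @param queries Data.frame with columns `id`, `sequence`, and optionally
#'   `kind`, `strand_tag`, `signal` (probe intensity; reads default to
#'   signal 1).
#' @param catalog A `FeatureCatalog`.
#' @param target_set Interval data.frame with `id` column.
#' @param mode `"exclusive_ok"` or `"unique_only"` (see [classify_hits()]).
#' @param hits Optional precomputed genome-wide hit table (as produced
#'   internally), so one matching pass can be classified against several
#'   target sets.
#' @return A data.frame, one row per query: `query_id`, `n_hits`,
#'   `n_in_set`, `n_loci`, `klass`, `reason`, `loci` (";"-joined),
#'   `hits` ("chrom:start:end:strand" ";"-joined), `strand_tag`, `signal`.
#'   Attribute `class_counts` summarises the classes.
#' @export
map_query_table <- function(queries, catalog, target_set,
                            mode = c("exclusive_ok", "unique_only"),
                            hits = NULL) {
  mode <- match.arg(mode)
  n <- nrow(queries)
  if (anyDuplicated(queries$id)) stop("query ids must be unique")
  strand_tag <- if ("strand_tag" %in% names(queries)) queries$strand_tag else rep("none", n)
  signal <- if ("signal" %in% names(queries)) queries$signal else rep(1, n)
  out <- data.frame(query_id = as.character(queries$id),
                    n_hits = rep(0L, n), n_in_set = rep(0L, n),
                    n_loci = rep(0L, n), klass = rep("excluded", n),
                    reason = rep("no_match", n), loci = rep("", n),
                    hits = rep("", n), strand_tag = strand_tag,
                    signal = signal, stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(out, "class_counts") <- c(unique = 0L, exclusive = 0L, excluded = 0L)
    return(out)
  }
  if (is.null(hits)) {
    hits <- .match_many(out$query_id, as.character(queries$sequence), catalog)
  }
  amb <- attr(hits, "ambiguous_ids")
  out$reason[out$query_id %in% amb] <- "ambiguous_N"
  if (nrow(hits) > 0L) {
    ## containment of every hit in the target set, then a vectorized
    ## per-query rollup (kept loop-free: query tables can be large)
    cont <- contained_in(hits, target_set)
    in_set <- lengths(cont) > 0L
    qf <- factor(hits$query_id, levels = out$query_id)
    nh <- tabulate(qf, nbins = n)
    ni <- unname(vapply(split(in_set, qf), sum, 0L))
    loci_per_hit <- lapply(cont, function(ix) target_set$id[ix])
    grp_loci <- split(loci_per_hit, qf)   # level order == input order
    loci_u <- lapply(grp_loci, function(l) sort(unique(unlist(l))))
    o <- order(qf, hits$chrom, hits$start, hits$genome_strand)
    hs <- sprintf("%s:%d:%d:%s", hits$chrom[o], hits$start[o], hits$end[o],
                  hits$genome_strand[o])
    hits_str <- vapply(split(hs, qf[o]), paste, "", collapse = ";")
    out$n_hits <- nh
    out$n_in_set <- ni
    out$n_loci <- unname(lengths(loci_u))
    out$loci <- unname(vapply(loci_u, paste, "", collapse = ";"))
    out$hits <- unname(hits_str)
    has <- nh > 0L
    klass <- rep("excluded", n)
    reason <- out$reason
    reason[has & ni < nh] <- "outside_set"
    ok <- has & ni == nh
    klass[ok & nh == 1L] <- "unique"
    reason[ok & nh == 1L] <- NA_character_
    if (mode == "exclusive_ok") {
      klass[ok & nh > 1L] <- "exclusive"
      reason[ok & nh > 1L] <- NA_character_
    } else {
      reason[ok & nh > 1L] <- "multi_hit"
    }
    out$klass <- klass
    out$reason <- reason
  }
  attr(out, "class_counts") <- c(
    unique = sum(out$klass == "unique"),
    exclusive = sum(out$klass == "exclusive"),
    excluded = sum(out$klass == "excluded"))
  out
}

#' Genome-wide exact hit table for a set of queries
#'
#' One matching pass usable by several [map_query_table()] classifications
#' (pass it as the `hits` argument).
#'
#' @param queries Query data.frame (`id`, `sequence`).
#' @param catalog A `FeatureCatalog`.
#' @return A data.frame `query_id`, `chrom`, `start`, `end`, `genome_strand`
#'   with attribute `ambiguous_ids` (queries containing N).
#' @export
find_hits_table <- function(queries, catalog) {
  .match_many(as.character(queries$id), as.character(queries$sequence),
              catalog)
}

#' Read a FASTQ file into a query table
#'
#' Qualities are ignored; each record becomes one query of kind `"read"`.
#' @param path FASTQ path.
#' @return A data.frame with `id`, `sequence`, `kind`, `strand_tag`.
#' @export
read_fastq_queries <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  n <- length(reads)
  data.frame(id = if (n) sub("\\s.*$", "", names(reads)) else character(0),
             sequence = as.character(reads), kind = rep("read", n),
             strand_tag = rep("none", n), stringsAsFactors = FALSE)
}

#' Read a probe TSV into a query table
#'
#' Expected columns: `probe_id`, `sequence`, `strand`, then one intensity
#' column per sample; `signal` is taken from `intensity_col`.
#' @param path TSV path.
#' @param intensity_col Name of the intensity column to use as `signal`
#'   (default: the first column after `strand`).
#' @return A data.frame with `id`, `sequence`, `kind`, `strand_tag`, `signal`.
#' @export
read_probe_table <- function(path, intensity_col = NULL) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(intensity_col)) intensity_col <- names(tb)[4]
  data.frame(id = tb$probe_id, sequence = tb$sequence, kind = "probe",
             strand_tag = tb$strand, signal = tb[[intensity_col]],
             stringsAsFactors = FALSE)
}

#' Write a mapping table as TSV
#' @param records Output of [map_query_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(records, path) {
  utils::write.table(records[, c("query_id", "n_hits", "n_in_set", "klass",
                                 "loci", "hits")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
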