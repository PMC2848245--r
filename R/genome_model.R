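## Genome + annotation model: feature catalog, full-length vs solitary LTR
## partition, and intergenic/intronic background construction.

.default_kind_map <- c(
  long_terminal_repeat = "ltr", LTR = "ltr", LTR_retrotransposon = "ltr",
  transposable_element = "retro_internal", retrotransposon = "retro_internal",
  gene = "gene", protein_coding_gene = "gene",
  intron = "intron",
  tRNA = "trna", tRNA_gene = "trna",
  snoRNA = "snorna", snoRNA_gene = "snorna"
)

#' Parse a genome and its annotation into a feature catalog
#'
#' Reads a FASTA genome and a GFF3 annotation and returns a catalog holding
#' the chromosome sequences plus a feature table with 0-based half-open
#' coordinates (GFF3's 1-based inclusive coordinates are converted at this
#' boundary). GFF3 `type` values are mapped to the catalog's feature kinds
#' (`ltr`, `retro_internal`, `gene`, `intron`, `trna`, `snorna`, `other`).
#'
#' @param genome_fasta Path to the genome FASTA file.
#' @param annotation_gff Path to the GFF3 annotation.
#' @param kind_map Named character vector mapping GFF3 `type` strings to
#'   feature kinds; unmapped types become `"other"`.
#' @return An object of class `FeatureCatalog`: a list with `seqs`
#'   (a [Biostrings::DNAStringSet] named by chromosome) and `features`
#'   (a data.frame with columns `id`, `kind`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
parse_annotation <- function(genome_fasta, annotation_gff,
                             kind_map = .default_kind_map) {
  if (!file.exists(genome_fasta)) stop("genome FASTA not found: ", genome_fasta)
  if (!file.exists(annotation_gff)) stop("annotation GFF3 not found: ", annotation_gff)
  .validate_gff_lines(annotation_gff)
  seqs <- Biostrings::readDNAStringSet(genome_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(annotation_gff, format = "gff3")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chrom), names(seqs))
  if (length(unknown) > 0L) {
    stop("annotation references chromosome(s) absent from the FASTA: ",
         paste(unknown, collapse = ", "))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  miss <- is.na(ids) | ids == ""
  ids[miss] <- paste0("feat", seq_len(length(gr)))[miss]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  type <- as.character(gr$type)
  kind <- unname(kind_map[type])
  kind[is.na(kind)] <- "other"
  feats <- data.frame(
    id = ids, kind = kind, chrom = chrom,
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = sub("\\*", "*", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
  too_big <- feats$end > Biostrings::width(seqs)[match(feats$chrom, names(seqs))]
  if (any(too_big)) {
    stop("feature(s) exceed chromosome bounds: ",
         paste(feats$id[too_big], collapse = ", "))
  }
  structure(list(seqs = seqs, features = feats), class = "FeatureCatalog")
}

## light pre-validation so malformed lines are reported by line number
.validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) stop("malformed GFF3 line ", i, ": fewer than 8 fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    if (e < s) stop("malformed GFF3 line ", i, ": end < start")
  }
  invisible(TRUE)
}

#' @export
print.FeatureCatalog <- function(x, ...) {
  cat("FeatureCatalog:", length(x$seqs), "chromosome(s),",
      nrow(x$features), "feature(s)\n")
  print(table(x$features$kind))
  invisible(x)
}

#' Write a feature catalog back to GFF3
#'
#' Inverse of [parse_annotation()] (coordinates converted back to 1-based
#' inclusive); re-parsing the output yields identical intervals.
#'
#' @param catalog A `FeatureCatalog`.
#' @param path Output GFF3 path.
#' @param type_map Named character vector mapping feature kinds to GFF3
#'   `type` strings.
#' @return `path`, invisibly.
#' @export
write_catalog_gff <- function(catalog, path,
                              type_map = c(ltr = "long_terminal_repeat",
                                           retro_internal = "transposable_element",
                                           gene = "gene", intron = "intron",
                                           trna = "tRNA", snorna = "snoRNA",
                                           other = "region")) {
  f <- catalog$features
  type <- unname(type_map[f$kind])
  type[is.na(type)] <- "region"
  lines <- c("##gff-version 3",
             paste(f$chrom, "ltrquant", type, f$start + 1L, f$end, ".",
                   f$strand, ".", paste0("ID=", f$id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Extract the sequence of an interval
#'
#' @param catalog A `FeatureCatalog`.
#' @param chrom,start,end Interval (0-based half-open).
#' @param strand If `"-"`, the reverse complement is returned.
#' @return A character scalar.
#' @export
interval_seq <- function(catalog, chrom, start, end, strand = "+") {
  s <- Biostrings::subseq(catalog$seqs[[chrom]], start + 1L, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Partition LTR features into full-length elements and solitary LTRs
#'
#' An LTR within `gap_tol` bp of a retrotransposon internal sequence on its
#' correct side is a flanking LTR; an internal sequence flanked by LTRs on
#' both sides defines a full-length element. Adjacent elements may share an
#' LTR: the chimeric LTR-internal-LTR-internal-LTR arrangement yields two
#' elements referencing one middle LTR, so 13 elements can hold 25 (not 26)
#' element-resident LTRs. All remaining LTRs are solitary.
#'
#' @param catalog A `FeatureCatalog` with `ltr` and `retro_internal` features.
#' @param gap_tol Maximum LTR-to-internal gap (bp) for adjacency.
#' @return A list with `elements` (list of full-length elements: `id`,
#'   `ltr_ids`, `internal` and `span` intervals), `ltrs` (data.frame of all
#'   LTR loci: `id`, `chrom`, `start`, `end`, `strand`, `role`, `element_id`,
#'   with the element ids of a shared LTR comma-joined) and `solitary` /
#'   `flanking` subsets of `ltrs`.
#' @export
partition_ltrs <- function(catalog, gap_tol = 50L) {
  f <- catalog$features
  ltr <- f[f$kind == "ltr", , drop = FALSE]
  int <- f[f$kind == "retro_internal", , drop = FALSE]
  ltr <- ltr[order(ltr$chrom, ltr$start), , drop = FALSE]
  int <- int[order(int$chrom, int$start), , drop = FALSE]
  role <- setNames(rep("solitary", nrow(ltr)), ltr$id)
  elem_of <- setNames(vector("list", nrow(ltr)), ltr$id)
  elements <- list()
  for (j in seq_len(nrow(int))) {
    ij <- int[j, ]
    same <- ltr[ltr$chrom == ij$chrom, , drop = FALSE]
    up <- same[same$end <= ij$start & (ij$start - same$end) <= gap_tol, , drop = FALSE]
    dn <- same[same$start >= ij$end & (same$start - ij$end) <= gap_tol, , drop = FALSE]
    if (nrow(up) == 0L || nrow(dn) == 0L) {
      warning("internal sequence ", ij$id,
              " lacks a flanking LTR on one side; excluded, adjacent LTR(s) kept solitary")
      next
    }
    up <- up[which.max(up$end), ]   # nearest on each side
    dn <- dn[which.min(dn$start), ]
    eid <- paste0("FL", length(elements) + 1L)
    elements[[eid]] <- list(
      id = eid, ltr_ids = c(up$id, dn$id),
      internal = ij[, c("id", "chrom", "start", "end", "strand")],
      span = data.frame(chrom = ij$chrom, start = up$start, end = dn$end,
                        stringsAsFactors = FALSE)
    )
    for (lid in c(up$id, dn$id)) {
      role[lid] <- "flanking"
      elem_of[[lid]] <- c(elem_of[[lid]], eid)
    }
  }
  ltrs <- data.frame(
    id = ltr$id, chrom = ltr$chrom, start = ltr$start, end = ltr$end,
    strand = ltr$strand, role = unname(role[ltr$id]),
    element_id = vapply(elem_of[ltr$id], function(e)
      if (is.null(e)) NA_character_ else paste(e, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  list(elements = elements,
       ltrs = ltrs,
       solitary = ltrs[ltrs$role == "solitary", , drop = FALSE],
       flanking = ltrs[ltrs$role == "flanking", , drop = FALSE])
}

#' Element spans as an interval table
#'
#' One interval per full-length element, spanning 5' LTR start to 3' LTR end.
#' @param partition Output of [partition_ltrs()].
#' @return An interval data.frame with one row per element.
#' @export
element_spans <- function(partition) {
  if (length(partition$elements) == 0L) {
    return(genomic_interval(character(0), integer(0), integer(0))[0, ])
  }
  do.call(rbind, lapply(partition$elements, function(e)
    data.frame(id = e$id, chrom = e$span$chrom, start = e$span$start,
               end = e$span$end, strand = "*", stringsAsFactors = FALSE)))
}

#' Construct background reference sets (intergenic and intronic)
#'
#' Intergenic sequence is the chromosome minus protein-coding genes extended
#' by `utr_flank` bp on both sides (to skip putative UTRs), tRNAs, snoRNAs,
#' LTRs and retrotransposon internal sequences; pieces shorter than
#' `min_len` are dropped. Intronic intervals come straight from the
#' annotation, with the same length filter.
#'
#' @param catalog A `FeatureCatalog`.
#' @param utr_flank Flank (bp) added to both sides of each gene.
#' @param min_len Minimum retained interval length (bp).
#' @return A list with interval data.frames `intergenic` and `intronic`,
#'   plus the parameters used.
#' @export
build_background <- function(catalog, utr_flank = 240L, min_len = 100L) {
  f <- catalog$features
  lens <- setNames(Biostrings::width(catalog$seqs), names(catalog$seqs))
  mask <- f[f$kind %in% c("gene", "trna", "snorna", "ltr", "retro_internal"), ,
            drop = FALSE]
  is_gene <- mask$kind == "gene"
  mask$start <- ifelse(is_gene, pmax(0L, mask$start - utr_flank), mask$start)
  mask$end <- ifelse(is_gene,
                     pmin(lens[mask$chrom], mask$end + utr_flank), mask$end)
  inter <- list()
  for (chr in names(lens)) {
    m <- mask[mask$chrom == chr, , drop = FALSE]
    if (nrow(m) == 0L) {
      gaps <- IRanges::IRanges(1L, lens[[chr]])
    } else {
      gaps <- IRanges::gaps(IRanges::reduce(.as_iranges(m)),
                            start = 1L, end = lens[[chr]])
    }
    if (length(gaps) == 0L) next
    inter[[chr]] <- data.frame(
      chrom = chr, start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
      stringsAsFactors = FALSE)
  }
  intergenic <- if (length(inter)) do.call(rbind, inter) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  rownames(intergenic) <- NULL
  intergenic <- intergenic[.interval_len(intergenic) >= min_len, , drop = FALSE]
  intergenic$id <- if (nrow(intergenic)) paste0("intergenic", seq_len(nrow(intergenic))) else character(0)
  intronic <- f[f$kind == "intron", c("id", "chrom", "start", "end"), drop = FALSE]
  intronic <- intronic[.interval_len(intronic) >= min_len, , drop = FALSE]
  rownames(intergenic) <- rownames(intronic) <- NULL
  list(intergenic = intergenic[, c("id", "chrom", "start", "end")],
       intronic = intronic,
       utr_flank = utr_flank, min_len = min_len)
}

#' Write the LTR partition as a TSV table
#'
#' Columns, in order: `id`, `chrom`, `start`, `end`, `role`, `element_id`.
#' @param partition Output of [partition_ltrs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ltr_table <- function(partition, path) {
  utils::write.table(partition$ltrs[, c("id", "chrom", "start", "end", "role",
                                        "element_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
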