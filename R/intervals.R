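## Genomic intervals are plain data.frames with 0-based half-open coordinates
## (chrom, start, end, strand). GFF3 I/O converts at the boundary.

#' Construct a genomic interval table
#'
#' Intervals are 0-based, half-open (`start` inclusive, `end` exclusive), the
#' convention used throughout the package; GFF3 import/export converts at the
#' I/O boundary.
#'
#' @param chrom Chromosome identifiers.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand One of `"+"`, `"-"`, `"*"` per interval.
#' @param id Optional interval identifiers.
#' @return A data.frame with columns `id`, `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*", id = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (is.null(id)) id <- paste0("iv", seq_len(n))
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  bad <- df$start < 0L | df$end <= df$start
  if (any(bad)) {
    stop("invalid interval(s): ", paste(df$id[bad], collapse = ", "),
         " (need 0 <= start < end)")
  }
  if (!all(df$strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  df
}

## 0-based half-open -> IRanges (1-based closed)
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.interval_len <- function(df) df$end - df$start

## distance between two half-open intervals on the same chromosome:
## 0 if they touch or overlap, else the gap size
.interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(b_start - a_end, a_start - b_end))
}

#' Indices of intervals in `x` fully contained in some interval of `set`
#'
#' Containment is strict interval containment on the same chromosome
#' (`[start, end)` of the query inside `[start, end)` of a set member);
#' partial overlap does not count.
#'
#' @param x,set Interval data.frames (see [genomic_interval()]).
#' @return A list, one element per row of `x`, of the row indices of `set`
#'   that contain it (possibly empty).
#' @keywords internal
contained_in <- function(x, set) {
  out <- vector("list", nrow(x))
  if (nrow(x) == 0L || nrow(set) == 0L) {
    for (i in seq_along(out)) out[[i]] <- integer(0)
    return(out)
  }
  for (chr in unique(x$chrom)) {
    xi <- which(x$chrom == chr)
    si <- which(set$chrom == chr)
    if (length(si) == 0L) {
      for (i in xi) out[[i]] <- integer(0)
      next
    }
    hits <- IRanges::findOverlaps(.as_iranges(x[xi, , drop = FALSE]),
                                  .as_iranges(set[si, , drop = FALSE]),
                                  type = "within")
    hl <- split(si[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(xi)))
    for (k in seq_along(xi)) out[[xi[k]]] <- unname(hl[[k]])
  }
  out
}

## run expr with a private RNG stream seeded by `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
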