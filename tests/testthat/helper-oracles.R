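## Independent oracles used to cross-check the implementation: a naive
## every-offset exact-match scan, a hand-rolled Needleman-Wunsch DP, a
## brute-force transitive closure, and a direct sliding-window loop.

## catalog from plain character chromosomes + a feature table
toy_catalog <- function(seqs, features = NULL) {
  if (is.null(features)) {
    features <- data.frame(id = character(0), kind = character(0),
                           chrom = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           stringsAsFactors = FALSE)
  }
  structure(list(seqs = Biostrings::DNAStringSet(unlist(seqs)),
                 features = features),
            class = "FeatureCatalog")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rand_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## naive scan: compare the query against every offset of every chromosome,
## both strands (substring equality; no index structure shared with the
## implementation)
naive_exact_scan <- function(query, seqs, substr_cache = NULL) {
  k <- nchar(query)
  rc <- revcomp_chr(query)
  palindrome <- rc == query
  out <- list()
  for (chr in names(seqs)) {
    L <- nchar(seqs[[chr]])
    if (k > L) next
    subs <- if (!is.null(substr_cache)) substr_cache[[chr]][[as.character(k)]]
    else substring(seqs[[chr]], 1:(L - k + 1), k:L)
    fwd <- which(subs == query) - 1L
    if (length(fwd)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = fwd, end = fwd + k, genome_strand = "+",
        stringsAsFactors = FALSE)
    }
    if (!palindrome) {
      rev <- which(subs == rc) - 1L
      if (length(rev)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = rev, end = rev + k, genome_strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               genome_strand = character(0), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$genome_strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

substr_cache_for <- function(seqs, lengths) {
  lapply(seqs, function(s) {
    L <- nchar(s)
    out <- lapply(lengths, function(k) substring(s, 1:(L - k + 1), k:L))
    names(out) <- as.character(lengths)
    out
  })
}

## Needleman-Wunsch, match +1 / mismatch -1 / gap -2 per gapped position.
## Returns the optimal global score; with traceback = TRUE also the number
## of matched positions and aligned columns of one optimal alignment.
nw_align <- function(a, b, traceback = FALSE) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  M[1, ] <- -2 * (0:m)
  M[, 1] <- -2 * (0:n)
  for (i in 1:n) {
    sub <- ifelse(A[i] == B, 1, -1)
    tmp <- pmax(M[i, 1:m] + sub, M[i, 2:(m + 1)] - 2)
    row <- numeric(m + 1L)
    row[1] <- M[i + 1L, 1]
    for (j in 1:m) row[j + 1L] <- max(tmp[j], row[j] - 2)
    M[i + 1L, ] <- row
  }
  if (!traceback) return(list(score = M[n + 1L, m + 1L]))
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L &&
        M[i + 1L, j + 1L] == M[i, j] + (if (A[i] == B[j]) 1 else -1)) {
      matches <- matches + (A[i] == B[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && M[i + 1L, j + 1L] == M[i, j + 1L] - 2) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = M[n + 1L, m + 1L], matches = matches, cols = cols,
       identity = matches / cols)
}

## brute-force transitive closure of the >= threshold similarity graph
brute_components <- function(idm, threshold) {
  adj <- idm >= threshold
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- apply(adj, 1L, function(r) paste(sort(rownames(idm)[r]), collapse = ";"))
  cl <- lapply(unique(unname(comp)), function(k) strsplit(k, ";", fixed = TRUE)[[1]])
  cl[order(vapply(cl, `[`, "", 1L))]
}

## direct per-column recomputation of the truncated sliding-window average
naive_window_density <- function(counts, window, n_rows) {
  half <- (window - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(c) {
    lo <- max(1L, c - half); hi <- min(n, c + half)
    mean(counts[lo:hi]) / n_rows
  }, 0)
}

## exhaustive Mann-Whitney null: all group assignments of the pooled values
enum_mw_pvalue <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  U <- u_of(x, y)
  us <- apply(utils::combn(length(pooled), nx), 2L, function(ix)
    u_of(pooled[ix], pooled[-ix]))
  switch(alternative,
         less = mean(us <= U),
         greater = mean(us >= U),
         two.sided = min(1, 2 * min(mean(us <= U), mean(us >= U))))
}
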