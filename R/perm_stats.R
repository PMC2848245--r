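## Mann-Whitney comparisons, the between-locus variance permutation test,
## meiosis stage log-ratio profiles, and the within-timepoint shuffle
## correlation test.

#' Mann-Whitney U test
#'
#' U is reported for the first-named group: the number of pairs `(x_i, y_j)`
#' with `x_i > y_j`, ties counting 0.5. For small samples
#' (`n_x + n_y <= 12`) without the caller forcing otherwise, the p-value is
#' computed by exhaustive enumeration of all group assignments of the pooled
#' values (ties handled exactly); larger samples use the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (direction of
#'   the `x` group relative to `y`).
#' @param method `"auto"` (enumeration when `n_x + n_y <= 12`), `"exact"`,
#'   or `"normal"`.
#' @return A list `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y)
  U <- .u_stat(x, y)
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = U, p = 1, method = "degenerate"))
  }
  if (method == "auto") method <- if (nx + ny <= 12L) "exact" else "normal"
  if (method == "exact") {
    pooled <- c(x, y)
    picks <- utils::combn(nx + ny, nx)
    us <- apply(picks, 2L, function(ix) .u_stat(pooled[ix], pooled[-ix]))
    p <- switch(alternative,
                less = mean(us <= U),
                greater = mean(us >= U),
                two.sided = min(1, 2 * min(mean(us <= U), mean(us >= U))))
  } else {
    p <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = alternative, exact = FALSE, correct = TRUE))$p.value
  }
  list(U = U, p = p, method = method)
}

.u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Empirical permutation p-value
#'
#' Sampled nulls use the add-one convention `(1 + k) / (n + 1)`; the
#' two-sided p doubles the smaller tail proportion `count / n_perm`, floored
#' at `1 / n_perm` and capped at 1 (one exceedance among 10,000 permutations
#' therefore reports a two-sided significance level of 2e-4).
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistics.
#' @param tail `"one_sided_ge"` or `"two_sided"`.
#' @return p-value in `(0, 1]`.
#' @export
perm_pvalue <- function(observed, null, tail = c("one_sided_ge", "two_sided")) {
  tail <- match.arg(tail)
  n <- length(null)
  if (tail == "one_sided_ge") {
    (1 + sum(null >= observed)) / (n + 1)
  } else {
    p_ge <- max(sum(null >= observed), 1L) / n
    p_le <- max(sum(null <= observed), 1L) / n
    min(1, 2 * min(p_ge, p_le))
  }
}

.perm_result <- function(observed, null, n_perm, p, tail, seed, method) {
  structure(list(observed = observed, null_values = null, n_perm = n_perm,
                 p_value = p, tail = tail, seed = seed, method = method,
                 null_min = min(null), null_max = max(null)),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat("PermutationResult (", x$method, "): observed = ",
      format(x$observed), ", null range [", format(x$null_min), ", ",
      format(x$null_max), "], n_perm = ", x$n_perm,
      ", p = ", format(x$p_value), " (", x$tail, ")\n", sep = "")
  invisible(x)
}

#' Between-locus variance permutation test
#'
#' Tests whether per-locus mean probe intensities vary more between loci
#' than expected if probes were randomly distributed. The observed statistic
#' is the sample variance (n-1 denominator) of per-locus mean intensities.
#' Null sets shuffle the pooled intensities between loci while preserving
#' each locus's probe count. When the count-preserving assignment space has
#' at most `exhaustive_limit` members the null is enumerated exhaustively
#' (the observed assignment is one of them); otherwise `n_perm` random
#' shuffles are drawn. Forward- and reverse-strand probes are analysed as
#' separate invocations.
#'
#' @param intensities_by_locus Named list: locus id -> numeric vector of
#'   probe intensities (loci with zero probes are dropped with a message).
#' @param n_perm Number of shuffles in sampled mode.
#' @param seed Integer seed for the shuffles.
#' @param exhaustive_limit Enumerate exhaustively when the number of
#'   distinct count-preserving assignments is at most this.
#' @return A `PermutationResult` (one-sided, large variance rejects); the
#'   add-one p-value convention `(1 + k) / (N + 1)` is used in both modes.
#' @export
variance_permutation_test <- function(intensities_by_locus, n_perm = 10000L,
                                      seed = 1L, exhaustive_limit = 1e5) {
  empty <- lengths(intensities_by_locus) == 0L
  if (any(empty)) {
    message("dropping ", sum(empty), " locus/loci with zero probes")
    intensities_by_locus <- intensities_by_locus[!empty]
  }
  if (length(intensities_by_locus) < 2L) {
    stop("need at least two loci with probes")
  }
  sizes <- lengths(intensities_by_locus)
  pooled <- unlist(intensities_by_locus, use.names = FALSE)
  grp <- rep(seq_along(sizes), sizes)
  observed <- stats::var(vapply(intensities_by_locus, mean, 0))
  n_assign <- .n_assignments(sizes)
  if (!is.na(n_assign) && n_assign <= exhaustive_limit) {
    null <- .enumerate_assignment_variances(pooled, sizes)
    p <- (1 + sum(null >= observed - 1e-12)) / (length(null) + 1)
    return(.perm_result(observed, null, length(null), p, "one_sided_ge",
                        seed, "exhaustive"))
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pm <- sample(pooled)
    stats::var(rowsum(pm, grp)[, 1] / sizes)
  }, 0))
  p <- perm_pvalue(observed, null, "one_sided_ge")
  .perm_result(observed, null, n_perm, p, "one_sided_ge", seed, "sampled")
}

## number of distinct count-preserving index assignments: multinomial
## coefficient n! / prod(n_i!) (NA on overflow)
.n_assignments <- function(sizes) {
  v <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
  if (!is.finite(v) || v > .Machine$integer.max) NA_real_ else round(v)
}

## enumerate all ways to deal `pooled` into groups of the given sizes,
## recording the variance of group means for each
.enumerate_assignment_variances <- function(pooled, sizes) {
  out <- numeric(0)
  recurse <- function(avail, k, means) {
    if (k > length(sizes)) {
      out[[length(out) + 1L]] <<- stats::var(means)
      return(invisible(NULL))
    }
    if (k == length(sizes)) {        # last group is forced
      recurse(integer(0), k + 1L, c(means, mean(pooled[avail])))
      return(invisible(NULL))
    }
    picks <- utils::combn(length(avail), sizes[k])
    for (c_i in seq_len(ncol(picks))) {
      ix <- picks[, c_i]
      recurse(avail[-ix], k + 1L, c(means, mean(pooled[avail[ix]])))
    }
    invisible(NULL)
  }
  recurse(seq_along(pooled), 1L, numeric(0))
  unlist(out)
}

#' Select meiosis LTR-gene pairs
#'
#' Keeps LTRs with at least `min_total` uniquely mapped reads over all
#' stages combined and at least `min_growth` in growth phase, that lie
#' within `upstream_within` bp upstream of a protein-coding gene (relative
#' to the gene's orientation), and pairs each with the nearest such gene.
#'
#' @param counts Data.frame or matrix of uniquely mapped read counts,
#'   rownames = LTR ids, columns = stages (must include `growth`).
#' @param ltrs LTR locus table (`id`, `chrom`, `start`, `end`).
#' @param genes Gene table (`id`, `chrom`, `start`, `end`, `strand`).
#' @param min_total,min_growth Count thresholds.
#' @param upstream_within Maximum upstream gap (bp).
#' @return A data.frame `ltr_id`, `gene_id`, `distance`, `total_reads`,
#'   `growth_reads`.
#' @export
select_meiosis_ltrs <- function(counts, ltrs, genes, min_total = 30L,
                                min_growth = 10L, upstream_within = 1000L) {
  counts <- as.matrix(counts)
  pass <- rowSums(counts) >= min_total & counts[, "growth"] >= min_growth
  out <- list()
  for (lid in rownames(counts)[pass]) {
    l <- ltrs[match(lid, ltrs$id), ]
    g <- genes[genes$chrom == l$chrom, , drop = FALSE]
    ## upstream of a gene, relative to gene orientation
    plus <- g$strand == "+" & g$start >= l$end
    minus <- g$strand == "-" & g$end <= l$start
    gap <- ifelse(plus, g$start - l$end, ifelse(minus, l$start - g$end, NA))
    ok <- !is.na(gap) & gap <= upstream_within
    if (!any(ok)) next
    j <- which(ok)[which.min(gap[ok])]
    out[[lid]] <- data.frame(ltr_id = lid, gene_id = g$id[j],
                             distance = gap[j],
                             total_reads = sum(counts[lid, ]),
                             growth_reads = counts[lid, "growth"],
                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ltr_id = character(0), gene_id = character(0),
               distance = integer(0), total_reads = numeric(0),
               growth_reads = numeric(0))
  rownames(res) <- NULL
  res
}

#' Stage log2 ratio profile vs growth
#'
#' `log2((count_stage + c) / (count_growth + c))` for each stage; the growth
#' ratio is 0 by construction. With `pseudocount = 0` (the default -- the
#' selection thresholds guarantee nonzero growth counts) a zero growth count
#' is an error.
#'
#' @param counts Named numeric vector over stages, including `growth`.
#' @param pseudocount Non-negative constant `c`.
#' @return Named numeric vector of log2 ratios (same stages).
#' @export
stage_log_ratios <- function(counts, pseudocount = 0) {
  if (!"growth" %in% names(counts)) stop("counts must include a growth stage")
  g <- counts[["growth"]] + pseudocount
  if (g <= 0) stop("zero growth count: use a positive pseudocount")
  log2((counts + pseudocount) / g)
}

#' Pearson correlation over concatenated LTR and gene profiles
#'
#' Concatenates every pair's meiosis-stage log ratios (growth is the ratio
#' baseline and excluded) into one LTR vector and one gene vector and
#' returns the product-moment correlation.
#'
#' @param ltr_mat,gene_mat Numeric matrices (pairs x stages) of log2 ratios,
#'   matching rows; columns are the meiosis stages.
#' @return Pearson r.
#' @export
concatenated_pearson <- function(ltr_mat, gene_mat) {
  x <- as.vector(t(ltr_mat)); y <- as.vector(t(gene_mat))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a concatenated profile: correlation undefined")
  }
  stats::cor(x, y)
}

## per-row Pearson r between two matrices (rows are profiles)
.row_cor <- function(a, b) {
  ac <- a - rowMeans(a); bc <- b - rowMeans(b)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  r <- rowSums(ac * bc) / den
  r[den == 0] <- NA_real_
  r
}

#' Within-timepoint shuffle test for LTR-gene profile coupling
#'
#' The observed statistic is the median over pairs of the per-pair Pearson
#' correlation between an LTR's and its neighbouring gene's meiosis-stage
#' log ratios. Null sets shuffle the LTR values among LTRs independently
#' within each stage (all M1 values shuffled together, likewise M2..M5),
#' recompute the per-pair correlations against the unshuffled genes, and
#' record the median. Pairs with a constant profile on either side are
#' dropped with a message. The two-sided p doubles the smaller tail,
#' floored at `1 / n_perm` (see [perm_pvalue()]).
#'
#' @param ltr_mat,gene_mat Matrices (pairs x meiosis stages) of log2 ratios.
#' @param n_perm Number of shuffles (default 10000).
#' @param seed Integer seed.
#' @return A `PermutationResult` with the observed median correlation.
#' @export
timepoint_permutation_test <- function(ltr_mat, gene_mat, n_perm = 10000L,
                                       seed = 1L) {
  ltr_mat <- as.matrix(ltr_mat); gene_mat <- as.matrix(gene_mat)
  stopifnot(nrow(ltr_mat) == nrow(gene_mat), ncol(ltr_mat) == ncol(gene_mat))
  const <- apply(ltr_mat, 1L, stats::sd) == 0 | apply(gene_mat, 1L, stats::sd) == 0
  if (any(const)) {
    message("dropping ", sum(const), " pair(s) with a constant profile")
    ltr_mat <- ltr_mat[!const, , drop = FALSE]
    gene_mat <- gene_mat[!const, , drop = FALSE]
  }
  n <- nrow(ltr_mat)
  if (n < 2L) stop("need at least two LTR-gene pairs")
  observed <- stats::median(.row_cor(ltr_mat, gene_mat))
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- apply(ltr_mat, 2L, sample)
    stats::median(.row_cor(perm, gene_mat), na.rm = TRUE)
  }, 0))
  p <- perm_pvalue(observed, null, "two_sided")
  .perm_result(observed, null, n_perm, p, "two_sided", seed, "sampled")
}

#' Set-level stage profile from exclusive read counts
#'
#' The relative transcription level of an LTR set at a stage is the number
#' of reads mapping exclusively to the set divided by the stage's total
#' library size; the output is the log2 ratio of each stage's relative level
#' to the growth-phase relative level.
#'
#' @param exclusive_counts Named numeric vector of exclusive read counts per
#'   stage (must include `growth`).
#' @param totals Named numeric vector of total reads per stage (all > 0).
#' @param pseudocount Added to exclusive counts (default 0; required > 0 if
#'   the growth count is 0).
#' @return Named numeric vector of log2 ratios.
#' @export
set_level_stage_profile <- function(exclusive_counts, totals, pseudocount = 0) {
  stopifnot(all(names(exclusive_counts) %in% names(totals)))
  totals <- totals[names(exclusive_counts)]
  if (any(totals <= 0)) stop("stage totals must be positive")
  rel <- (exclusive_counts + pseudocount) / totals
  if (rel[["growth"]] <= 0) stop("zero growth relative level: use a pseudocount")
  log2(rel / rel[["growth"]])
}

#' Serialize a permutation result as JSON
#' @param result A `PermutationResult`.
#' @param test Character label for the report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_perm_result <- function(result, test, path) {
  jsonlite::write_json(list(
    test = test, observed = result$observed, n_perm = result$n_perm,
    seed = result$seed, p_value = result$p_value,
    null_min = result$null_min, null_max = result$null_max,
    null_quantiles = as.list(stats::quantile(result$null_values,
                                             c(0.025, 0.5, 0.975)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
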