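## Windowed selection statistics: per-gene overlap-weighted means of window
## values, empirical standardization against a length-matched gene background,
## genome-wide empirical window p-values, and the two SFS statistics computed
## in-house (nucleotide diversity and Fay & Wu's H).  Linkage-based (iHS) and
## divergence-based (alpha) statistics are never computed here; they enter
## only as precomputed window values.

#' Read a window-statistic table
#'
#' @param path TSV with header columns chrom, start, end, pop, stat, value
#'   (1-based inclusive windows).
#' @return data.frame with those columns.
#' @export
read_window_stats <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "pop", "stat", "value")
  if (!all(need %in% names(t)))
    stop("read_window_stats: missing columns ",
         paste(setdiff(need, names(t)), collapse = ", "))
  if (any(t$start > t$end)) stop("read_window_stats: start > end")
  if (any(!is.finite(t$value))) stop("read_window_stats: non-finite values")
  t[need]
}

#' Overlap-weighted mean of window statistics over a gene
#'
#' Weighted mean of the window values overlapping the gene, weighted by the
#' number of overlapping base pairs, for one population and statistic.
#' Splitting a window into contiguous pieces with the same value leaves the
#' result unchanged (weight additivity).
#'
#' @param gene list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param windows data.frame of windows for a single population and statistic
#'   (columns `chrom`, `start`, `end`, `value`).
#' @return The weighted mean, or `NA` (with a warning) if no window overlaps.
#' @export
gene_weighted_mean <- function(gene, windows) {
  w <- windows[windows$chrom == gene$chrom, , drop = FALSE]
  ov <- pmin(w$end, gene$end) - pmax(w$start, gene$start) + 1
  keep <- ov > 0
  if (!any(keep)) {
    warning("gene_weighted_mean: no window overlaps the gene")
    return(NA_real_)
  }
  sum(w$value[keep] * ov[keep]) / sum(ov[keep])
}

#' Length-matched background gene set
#'
#' Selects genes whose length (end - start + 1) is within `tolerance_bp` of
#' `target_length_bp` (inclusive bounds), excluding the focal gene, to form
#' the empirical distribution against which the focal gene is standardized.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @param target_length_bp target length in bp.
#' @param tolerance_bp half-width of the accepted length band.
#' @param exclude gene id(s) to drop (the focal gene).
#' @return The matching subset of `genes` (error if empty: no background to
#'   standardize against).
#' @export
length_matched_genes <- function(genes, target_length_bp, tolerance_bp,
                                 exclude = NULL) {
  len <- genes$end - genes$start + 1
  keep <- abs(len - target_length_bp) <= tolerance_bp
  if (!is.null(exclude)) keep <- keep & !(genes$gene %in% exclude)
  out <- genes[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("length_matched_genes: no genes within tolerance; cannot standardize")
  rownames(out) <- NULL
  out
}

#' Standardize a focal value against an empirical background
#'
#' @param focal the focal gene's statistic value.
#' @param background values of the length-matched background genes (>= 30).
#' @return list with `z` (`(x - mean) / sd` of the background) and `quantile`
#'   (fraction of background values strictly below `x`).
#' @export
standardize_statistic <- function(focal, background) {
  if (length(background) < 30)
    stop("standardize_statistic: need >= 30 background values")
  s <- stats::sd(background)
  if (s == 0) stop("standardize_statistic: zero background standard deviation")
  list(z = (focal - mean(background)) / s,
       quantile = mean(background < focal))
}

#' Genome-wide empirical window p-value
#'
#' Frequency of genomic windows with a statistic value strictly greater than
#' the observed value (ties do not count).
#'
#' @param observed the observed value.
#' @param window_values all genomic window values for the statistic.
#' @return p in `[0, 1]`.
#' @export
empirical_window_pvalue <- function(observed, window_values) {
  if (length(window_values) < 1)
    stop("empirical_window_pvalue: no window values")
  mean(window_values > observed)
}

#' Nucleotide diversity
#'
#' Per-site nucleotide diversity over a haplotype subset: the sum over
#' polymorphic sites of `2 p (1 - p) n / (n - 1)` (the unbiased
#' heterozygosity estimator, `n` haplotypes, `p` the ALT frequency in the
#' subset), divided by the accessible span in bp.  Identical to the mean
#' pairwise Hamming distance between haplotypes divided by the span.
#'
#' @param m a [locus_matrix()].
#' @param haplotypes haplotype column names (default: all).
#' @param span_bp accessible span; defaults to the site position range.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(m, haplotypes = NULL, span_bp = NULL) {
  h <- if (is.null(haplotypes)) m$hap else m$hap[, haplotypes, drop = FALSE]
  n <- ncol(h)
  if (n < 2) stop("nucleotide_diversity: need >= 2 haplotypes")
  if (is.null(span_bp)) span_bp <- diff(range(m$sites$pos)) + 1
  if (span_bp <= 0) stop("nucleotide_diversity: span_bp must be positive")
  p <- rowMeans(h)
  sum(2 * p * (1 - p) * n / (n - 1)) / span_bp
}

#' Fay and Wu's H
#'
#' Contrast of intermediate- against high-frequency derived variants over a
#' haplotype subset: `H = theta_pi - theta_H`, with
#' `theta_pi = sum_i 2 S_i i (n - i) / (n (n - 1))` and
#' `theta_H = sum_i 2 S_i i^2 / (n (n - 1))`, where `S_i` is the number of
#' polarized sites with derived count `i` (`1 <= i <= n - 1`).  Negative
#' values indicate an excess of high-frequency derived alleles, the
#' hitchhiking signature.
#'
#' @param m a polarized [locus_matrix()].
#' @param haplotypes haplotype column names (default: all).
#' @return H (0 for monomorphic data).
#' @export
fay_wu_h <- function(m, haplotypes = NULL) {
  if (!any(m$sites$polarized))
    stop("fay_wu_h: matrix has no polarized sites")
  dh <- derived_haplotypes(m)
  if (!is.null(haplotypes)) dh <- dh[, haplotypes, drop = FALSE]
  n <- ncol(dh)
  if (n < 3) stop("fay_wu_h: need >= 3 haplotypes")
  cnt <- rowSums(dh)
  cnt <- cnt[cnt >= 1 & cnt <= n - 1]
  if (length(cnt) == 0) return(0)
  i <- seq_len(n - 1)
  S <- tabulate(cnt, nbins = n - 1)
  theta_pi <- sum(2 * S * i * (n - i)) / (n * (n - 1))
  theta_h <- sum(2 * S * i^2) / (n * (n - 1))
  theta_pi - theta_h
}

#' Per-gene standardized statistic table across populations
#'
#' Convenience wrapper for the full scan: for each population and statistic
#' in the window table, computes the focal gene's overlap-weighted mean, the
#' same for every length-matched background gene, and the resulting z-score.
#' The populations-by-statistics z-score matrix is the input to
#' [project_populations()].
#'
#' @param windows data.frame from [read_window_stats()].
#' @param genes gene table (columns `gene`, `chrom`, `start`, `end`).
#' @param focal_gene focal gene id (must appear in `genes`).
#' @param target_length_bp,tolerance_bp background length matching (defaults:
#'   the focal gene's own length, 20 kb).
#' @return list with `z` (populations x statistics matrix), `focal` (raw
#'   focal means), `n_background`.
#' @export
standardize_gene_scan <- function(windows, genes, focal_gene,
                                  target_length_bp = NULL,
                                  tolerance_bp = 20000) {
  fg <- genes[genes$gene == focal_gene, , drop = FALSE]
  if (nrow(fg) != 1) stop("standardize_gene_scan: focal gene not found")
  if (is.null(target_length_bp)) target_length_bp <- fg$end - fg$start + 1
  bg <- length_matched_genes(genes, target_length_bp, tolerance_bp,
                             exclude = focal_gene)
  pops <- sort(unique(windows$pop))
  stats_ <- sort(unique(windows$stat))
  z <- matrix(NA_real_, length(pops), length(stats_),
              dimnames = list(pops, stats_))
  focal <- z
  for (p in pops) for (s in stats_) {
    w <- windows[windows$pop == p & windows$stat == s, , drop = FALSE]
    fv <- gene_weighted_mean(fg, w)
    bv <- vapply(seq_len(nrow(bg)),
                 function(i) suppressWarnings(gene_weighted_mean(bg[i, ], w)),
                 numeric(1))
    bv <- bv[!is.na(bv)]
    focal[p, s] <- fv
    z[p, s] <- standardize_statistic(fv, bv)$z
  }
  list(z = z, focal = focal, n_background = nrow(bg))
}
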