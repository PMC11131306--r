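## Archaic-introgression summaries at the locus: per-individual counts of
## Sprime-predicted introgressed alleles, per-haplotype difference counts to
## each archaic genome, outlier haplotype flagging, and detection of the
## introgression-depletion region around the locus in a reference map.

#' Read a Sprime-style score table
#'
#' Expects a TSV with header columns CHROM, POS, ID, REF, ALT, ALLELE,
#' SEGMENT, SCORE, where ALLELE is the putatively introgressed allele coded
#' 0 (REF) or 1 (ALT), or given as the allele base.
#'
#' @param path TSV file.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `introgressed_allele` (the base), `segment`, `score`.
#' @export
read_sprime_tsv <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(t) <- toupper(names(t))
  need <- c("CHROM", "POS", "REF", "ALT", "ALLELE", "SEGMENT", "SCORE")
  if (!all(need %in% names(t)))
    stop("read_sprime_tsv: missing columns ",
         paste(setdiff(need, names(t)), collapse = ", "))
  allele <- as.character(t$ALLELE)
  allele[allele == "0"] <- t$REF[allele == "0"]
  allele[allele == "1"] <- t$ALT[allele == "1"]
  if (any(t$SCORE < 0)) stop("read_sprime_tsv: negative scores")
  data.frame(chrom = as.character(t$CHROM), pos = as.numeric(t$POS),
             ref = toupper(t$REF), alt = toupper(t$ALT),
             introgressed_allele = toupper(allele),
             segment = t$SEGMENT, score = t$SCORE, stringsAsFactors = FALSE)
}

#' Count Sprime-predicted introgressed alleles per haplotype and individual
#'
#' Sprime records are matched to matrix sites by exact (chrom, pos, ref, alt);
#' unmatched or allele-inconsistent records are counted and reported, not
#' fatal.  Each haplotype's count is the number of matched sites at which it
#' carries the putatively introgressed allele; an individual's count sums its
#' two haplotypes (allele copies, not carrier sites).
#'
#' @param m a [locus_matrix()].
#' @param sprime data.frame from [read_sprime_tsv()].
#' @return list with `per_haplotype` (named vector), `per_individual` (named
#'   vector), `n_matched_sites`, `n_unmatched_records`.
#' @export
count_introgressed_alleles <- function(m, sprime) {
  hap_n <- setNames(numeric(ncol(m$hap)), colnames(m$hap))
  n_unmatched <- 0L
  if (nrow(sprime) > 0) {
    key_m <- site_key(m$sites$chrom, m$sites$pos, m$sites$ref, m$sites$alt)
    i <- match(site_key(sprime$chrom, sprime$pos, sprime$ref, sprime$alt), key_m)
    bad_allele <- !is.na(i) &
      !(sprime$introgressed_allele == sprime$ref |
          sprime$introgressed_allele == sprime$alt)
    n_unmatched <- sum(is.na(i)) + sum(bad_allele)
    if (n_unmatched > 0)
      warning("count_introgressed_alleles: ", n_unmatched,
              " Sprime record(s) not matched to matrix sites; skipped")
    use <- !is.na(i) & !bad_allele
    rows <- i[use]
    is_alt <- sprime$introgressed_allele[use] == sprime$alt[use]
    h <- m$hap[rows, , drop = FALSE]
    h[!is_alt, ] <- 1L - h[!is_alt, , drop = FALSE]
    hap_n <- colSums(h)
  } else {
    rows <- integer(0)
  }
  mod <- modern_samples(m)
  ind_n <- setNames(hap_n[paste0(mod, "_1")] + hap_n[paste0(mod, "_2")], mod)
  list(per_haplotype = hap_n, per_individual = ind_n,
       n_matched_sites = length(rows), n_unmatched_records = n_unmatched)
}

#' Per-haplotype difference counts to an archaic genome
#'
#' Sum over sites of `|h - g/2|`, where `h` is the haplotype allele and `g`
#' the archaic ALT dosage, so heterozygous archaic sites contribute 0.5; the
#' count is therefore real-valued.
#'
#' @param m a [locus_matrix()].
#' @param archaic_id archaic sample id present in the matrix.
#' @return Named numeric vector of per-haplotype difference counts.
#' @export
hap_archaic_differences <- function(m, archaic_id) {
  if (!archaic_id %in% colnames(m$arc))
    stop("hap_archaic_differences: unknown archaic id ", archaic_id)
  g <- m$arc[, archaic_id] / 2
  colSums(abs(m$hap - g))
}

#' Flag haplotypes with outlying introgressed-allele counts
#'
#' Flags haplotypes whose count exceeds the extreme-outlier fence
#' `Q3 + fence * IQR` of the count distribution (default `fence = 3`).
#'
#' @param counts named numeric vector of per-haplotype counts (>= 8 values).
#' @param fence IQR multiplier.
#' @return Character vector of flagged haplotype ids (possibly empty).
#' @export
flag_outlier_haplotypes <- function(counts, fence = 3) {
  if (length(counts) < 8)
    stop("flag_outlier_haplotypes: need at least 8 haplotypes")
  q <- stats::quantile(counts, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + fence * (q[2] - q[1])
  names(counts)[counts > thr]
}

#' Introgression-depletion region around a locus
#'
#' Given the sorted positions of reference-panel introgressed markers on a
#' chromosome, finds the maximal interval containing the locus with zero
#' markers (bounded by the flanking markers, or by the chromosome ends when
#' supplied), and ranks its length among all inter-marker gap lengths on the
#' chromosome: `p = #(gaps >= this length) / #gaps` (one-sided,
#' larger-is-rarer).  This chromosome-wide gap-length rank is a deliberate
#' simplification of genome-wide depletion tests published with such maps.
#' If the locus itself contains a marker the depletion has length 0 and
#' `p = 1`.
#'
#' @param positions sorted marker positions (numeric).
#' @param locus a [locus_region()] (flank included).
#' @param chrom_range optional `c(first, last)` base of the chromosome; when
#'   supplied, the terminal gaps are included.
#' @return list with `interval` (`c(start, end)` of marker-free positions),
#'   `length_bp`, `empirical_p`, `n_gaps`.
#' @export
find_depletion_region <- function(positions, locus, chrom_range = NULL) {
  positions <- sort(unique(as.numeric(positions)))
  if (length(positions) < 2)
    stop("find_depletion_region: need at least two markers")
  b <- region_bounds(locus)
  bounds <- positions
  if (!is.null(chrom_range))
    bounds <- c(chrom_range[1] - 1, bounds, chrom_range[2] + 1)
  gaps <- cbind(utils::head(bounds, -1) + 1, utils::tail(bounds, -1) - 1)
  gap_len <- pmax(gaps[, 2] - gaps[, 1] + 1, 0)
  inside <- any(positions >= b[1] & positions <= b[2])
  if (inside)
    return(list(interval = c(NA_real_, NA_real_), length_bp = 0,
                empirical_p = 1, n_gaps = nrow(gaps)))
  g <- which(gaps[, 1] <= b[1] & gaps[, 2] >= b[2])
  if (length(g) == 0)
    stop("find_depletion_region: locus is not contained in a single gap ",
         "(does it span a chromosome end beyond the marker range?)")
  len <- gap_len[g[1]]
  list(interval = gaps[g[1], ], length_bp = len,
       empirical_p = sum(gap_len >= len) / length(gap_len),
       n_gaps = nrow(gaps))
}
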