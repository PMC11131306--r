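#' Genomic region of interest
#'
#' A target region in 1-based inclusive coordinates with an optional symmetric
#' flank, following the common "gene boundaries plus flank" convention used
#' when extracting a locus from whole-genome VCFs.
#'
#' @param chrom chromosome name (character scalar).
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param flank non-negative number of base pairs added on each side.
#' @return An object of class `locus_region` with fields `chrom`, `start`,
#'   `end`, `flank`.
#' @examples
#' locus_region("11", 68080077, 68216743, flank = 5e5)
#' @export
locus_region <- function(chrom, start, end, flank = 0) {
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  start <- as.numeric(start); end <- as.numeric(end); flank <- as.numeric(flank)
  if (is.na(start) || is.na(end) || start > end)
    stop("locus_region: start must be <= end")
  if (is.na(flank) || flank < 0)
    stop("locus_region: flank must be >= 0")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 flank = flank),
            class = "locus_region")
}

#' @export
print.locus_region <- function(x, ...) {
  cat(sprintf("<locus_region> %s:%s-%s (+/- %s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$flank, big.mark = ",")))
  invisible(x)
}

region_bounds <- function(region) {
  c(max(1, region$start - region$flank), region$end + region$flank)
}

#' Read a region from a BED file
#'
#' BED is 0-based half-open; the returned [locus_region()] is 1-based
#' inclusive.  Only the first record (or the record matching `name`) is used.
#'
#' @param path BED file path (chrom, start, end, and optionally name).
#' @param name optional feature name to select.
#' @param flank flank passed to [locus_region()].
#' @return A [locus_region()].
#' @export
read_region_bed <- function(path, name = NULL, flank = 0) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!is.null(name)) {
    if (ncol(bed) < 4) stop("read_region_bed: BED file has no name column")
    bed <- bed[bed[[4]] == name, , drop = FALSE]
    if (nrow(bed) == 0) stop("read_region_bed: no record named ", name)
  }
  locus_region(bed[1, 1], as.numeric(bed[1, 2]) + 1, as.numeric(bed[1, 3]),
               flank = flank)
}

#' Read a sample-to-population panel
#'
#' @param path TSV with columns `sample`, `pop`, `super_pop` (header required).
#' @return data.frame with those three columns.
#' @export
read_panel <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "pop", "super_pop")
  if (!all(need %in% names(p)))
    stop("read_panel: panel must have columns sample, pop, super_pop")
  p[need]
}

## ---- merged locus matrix ---------------------------------------------------

new_locus_matrix <- function(sites, hap, arc, meta) {
  structure(list(sites = sites, hap = hap, arc = arc, meta = meta),
            class = "locus_matrix")
}

#' Construct a merged locus matrix
#'
#' The central container of the package: an ordered table of biallelic SNV
#' sites together with a complete phased haplotype matrix for modern samples
#' (0/1 ALT indicators, two columns per individual) and a complete dosage
#' matrix for archaic samples (0/1/2 ALT copies).  Normally produced by
#' [merge_datasets()] or [simulate_locus()] rather than called directly.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, `aa`
#'   (ancestral allele, `NA` if unknown), `polarized`, `derived_is_alt`.
#' @param hap integer matrix, sites x modern haplotypes, entries in `{0,1}`;
#'   column names `"<sample>_1"`, `"<sample>_2"`.
#' @param arc integer matrix, sites x archaic samples, entries in `{0,1,2}`.
#' @param meta data.frame with columns `sample`, `kind` (`"modern"` or
#'   `"archaic"`), `pop`, `super_pop`.
#' @return An object of class `locus_matrix`.
#' @export
locus_matrix <- function(sites, hap, arc, meta) {
  m <- new_locus_matrix(sites, hap, arc, meta)
  validate_locus_matrix(m)
  m
}

validate_locus_matrix <- function(m) {
  s <- m$sites
  stopifnot(is.data.frame(s),
            all(c("chrom", "pos", "ref", "alt", "polarized") %in% names(s)))
  if (is.unsorted(s$pos, strictly = TRUE))
    stop("locus_matrix: site positions must be strictly increasing")
  if (any(s$ref == s$alt)) stop("locus_matrix: ref == alt at some site")
  if (anyNA(m$hap) || anyNA(m$arc))
    stop("locus_matrix: missing entries are not allowed after merging")
  if (nrow(m$hap) != nrow(s) || nrow(m$arc) != nrow(s))
    stop("locus_matrix: matrix row counts disagree with the site table")
  if (!all(m$hap %in% 0:1)) stop("locus_matrix: haplotype entries must be 0/1")
  if (!all(m$arc %in% 0:2)) stop("locus_matrix: archaic dosages must be 0/1/2")
  invisible(m)
}

#' @export
print.locus_matrix <- function(x, ...) {
  nmod <- sum(x$meta$kind == "modern")
  cat(sprintf(paste0("<locus_matrix> %d sites (%d polarized) x ",
                     "%d modern haplotypes (%d individuals) + %d archaics\n"),
              nrow(x$sites), sum(x$sites$polarized), ncol(x$hap), nmod,
              ncol(x$arc)))
  invisible(x)
}

#' @export
summary.locus_matrix <- function(object, ...) {
  s <- object$sites
  alt_freq <- rowMeans(object$hap)
  out <- list(n_sites = nrow(s), n_polarized = sum(s$polarized),
              n_haplotypes = ncol(object$hap), n_archaics = ncol(object$arc),
              n_monomorphic_modern = sum(alt_freq %in% c(0, 1)),
              pos_range = range(s$pos))
  class(out) <- "summary.locus_matrix"
  out
}

#' @export
print.summary.locus_matrix <- function(x, ...) {
  cat(sprintf("Sites: %d (%d polarized, %d monomorphic in moderns)\n",
              x$n_sites, x$n_polarized, x$n_monomorphic_modern))
  cat(sprintf("Modern haplotypes: %d; archaic samples: %d\n",
              x$n_haplotypes, x$n_archaics))
  cat(sprintf("Position range: %d-%d\n", x$pos_range[1], x$pos_range[2]))
  invisible(x)
}

modern_samples <- function(m) m$meta$sample[m$meta$kind == "modern"]
archaic_samples <- function(m) m$meta$sample[m$meta$kind == "archaic"]

hap_columns_of <- function(m, samples) {
  cols <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  miss <- setdiff(cols, colnames(m$hap))
  if (length(miss)) stop("unknown haplotype columns: ",
                         paste(miss, collapse = ", "))
  cols
}

#' Derived-allele matrices of a polarized locus matrix
#'
#' For polarized sites the derived allele is ALT when the ancestral allele
#' equals REF and REF otherwise; unpolarized sites are excluded.
#'
#' @param m a polarized [locus_matrix()].
#' @return `derived_haplotypes()`: 0/1 matrix of derived-allele indicators over
#'   polarized sites; `derived_dosages()`: 0/1/2 matrix of derived-allele
#'   dosages for the archaic samples over the same rows.  Both carry the
#'   polarized-site row indices as attribute `"site_index"`.
#' @export
derived_haplotypes <- function(m) {
  idx <- which(m$sites$polarized)
  h <- m$hap[idx, , drop = FALSE]
  flip <- !m$sites$derived_is_alt[idx]
  h[flip, ] <- 1L - h[flip, , drop = FALSE]
  attr(h, "site_index") <- idx
  h
}

#' @rdname derived_haplotypes
#' @export
derived_dosages <- function(m) {
  idx <- which(m$sites$polarized)
  g <- m$arc[idx, , drop = FALSE]
  flip <- !m$sites$derived_is_alt[idx]
  g[flip, ] <- 2L - g[flip, , drop = FALSE]
  attr(g, "site_index") <- idx
  g
}
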