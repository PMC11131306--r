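## Screening of archaic missense variants: sequencing-quality filters,
## pathogenicity-prediction filters, a conservation filter, domain
## restriction, prioritization flags, and classification of predicted
## stability changes against a fixed free-energy threshold.

#' Screening criteria for archaic missense variants
#'
#' Thresholds applied by [screen_variants()].  Quality bounds follow the
#' read-level filters used for archaic genome calls (base quality >= 23,
#' alignment quality >= 150, inclusive comparisons); the pathogenicity and
#' conservation cutoffs are configurable conventions: SIFT <= 0.05 and
#' PolyPhen >= 0.85 are the predictors' customary "damaging" bands, and
#' phyloP >= 2.0 marks strong cross-species conservation.
#'
#' @param min_base_quality,min_alignment_quality phred-scale minima.
#' @param max_sift maximum SIFT score still called damaging.
#' @param min_polyphen minimum PolyPhen score called damaging.
#' @param min_phylop minimum per-base conservation score.
#' @param require_domain if `TRUE`, the residue must lie in the annotated
#'   domain of interest (for LRP5, the first beta-propeller, where
#'   high-bone-mass mutations cluster).
#' @return An object of class `screen_criteria`.
#' @export
screen_criteria <- function(min_base_quality = 23, min_alignment_quality = 150,
                            max_sift = 0.05, min_polyphen = 0.85,
                            min_phylop = 2.0, require_domain = TRUE) {
  structure(list(min_base_quality = min_base_quality,
                 min_alignment_quality = min_alignment_quality,
                 max_sift = max_sift, min_polyphen = min_polyphen,
                 min_phylop = min_phylop, require_domain = require_domain),
            class = "screen_criteria")
}

#' Read a variant annotation table
#'
#' @param path TSV with one row per variant; required columns: `chrom`,
#'   `pos`, `ref`, `alt`, `protein_change`, `residue`, `base_quality`,
#'   `alignment_quality`, `sift`, `polyphen`, `phylop`, `in_domain`,
#'   `carriers` (comma-separated individual ids), `hbm_residue`; optional:
#'   `gnomad_frequency`, `ddg_kcal_mol`.
#' @return data.frame of annotations.
#' @export
read_variant_table <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt", "protein_change", "residue",
            "base_quality", "alignment_quality", "sift", "polyphen",
            "phylop", "in_domain", "carriers", "hbm_residue")
  miss <- setdiff(need, names(t))
  if (length(miss))
    stop("read_variant_table: missing column(s) ", paste(miss, collapse = ", "))
  t$in_domain <- as.logical(t$in_domain)
  t$hbm_residue <- as.logical(t$hbm_residue)
  t
}

#' Packaged example: archaic LRP5 missense variant table
#'
#' Returns the packaged annotation table for the five archaic LRP5 missense
#' variants (p.A67T, p.A67V, p.R186Q, p.M282R, p.R291Q; GRCh37 positions,
#' SIFT/PolyPhen scores, gnomAD frequencies, carrier individuals and, where
#' reported, FoldX stability changes), optionally together with synthetic
#' decoy variants that each violate exactly one screening rule.  The base
#' quality, alignment quality and phyloP columns are synthetic placeholders
#' consistent with the quality and conservation filters these variants are
#' known to satisfy; they are not published per-variant measurements.
#'
#' @param decoys include the synthetic decoy variants.
#' @return data.frame of annotations.
#' @export
lrp5_example_variants <- function(decoys = FALSE) {
  v <- read_variant_table(system.file("extdata", "lrp5_archaic_variants.tsv",
                                      package = "paleolocus"))
  if (decoys) {
    d <- read_variant_table(system.file("extdata",
                                        "lrp5_decoy_variants_synthetic.tsv",
                                        package = "paleolocus"))
    v <- rbind(v, d)
  }
  v
}

#' Screen archaic missense variants
#'
#' A variant passes iff `base_quality >= min`, `alignment_quality >= min`,
#' `sift <= max`, `polyphen >= min`, `phylop >= min`, and (when
#' `require_domain`) the residue lies in the annotated domain.  All
#' comparisons are inclusive.  Every violated rule is reported, so the pass
#' set is independent of rule evaluation order.
#'
#' @param variants data.frame from [read_variant_table()].
#' @param criteria a [screen_criteria()].
#' @return list with `pass` (the passing subset), `fail` (the rest),
#'   `reasons` (named list: violated rule names per variant, empty for
#'   passes).
#' @export
screen_variants <- function(variants, criteria = screen_criteria()) {
  need <- c("base_quality", "alignment_quality", "sift", "polyphen", "phylop",
            "in_domain")
  for (f in need) {
    if (!f %in% names(variants))
      stop("screen_variants: missing required annotation field '", f, "'")
    if (anyNA(variants[[f]]))
      stop("screen_variants: missing values in required field '", f, "'")
  }
  checks <- list(
    base_quality = variants$base_quality >= criteria$min_base_quality,
    alignment_quality =
      variants$alignment_quality >= criteria$min_alignment_quality,
    sift = variants$sift <= criteria$max_sift,
    polyphen = variants$polyphen >= criteria$min_polyphen,
    phylop = variants$phylop >= criteria$min_phylop,
    domain = if (criteria$require_domain) variants$in_domain
             else rep(TRUE, nrow(variants)))
  ok_mat <- do.call(cbind, checks)
  pass <- rowSums(!ok_mat) == 0
  reasons <- lapply(seq_len(nrow(variants)),
                    function(i) colnames(ok_mat)[!ok_mat[i, ]])
  names(reasons) <- variants$protein_change
  list(pass = variants[pass, , drop = FALSE],
       fail = variants[!pass, , drop = FALSE],
       reasons = reasons)
}

#' Prioritization flags for passing variants
#'
#' Flags variants found in more than one archaic individual
#' (`multi_individual`), variants sharing a protein residue with another
#' passing variant (`shared_residue`), and variants at residues mutated in
#' reported modern-human high-bone-mass cases (`hbm_residue`).
#'
#' @param variants passing variants from [screen_variants()].
#' @return The variants with three added logical flag columns.
#' @export
prioritize_variants <- function(variants) {
  carriers <- strsplit(ifelse(is.na(variants$carriers), "",
                              variants$carriers), ",")
  variants$multi_individual <- lengths(lapply(carriers, trimws)) > 1
  variants$shared_residue <- stats::ave(rep(1, nrow(variants)),
                                        variants$residue, FUN = length) > 1
  variants$hbm_residue <- as.logical(variants$hbm_residue)
  variants
}

#' Classify a predicted stability change
#'
#' A variant is called destabilizing when its predicted folding free-energy
#' change exceeds `threshold` kcal/mol (strictly); the default 1.6 kcal/mol
#' corresponds to twice the standard deviation of the FoldX predictor.
#' Missing values are classified `"unknown"`.
#'
#' @param ddg_kcal_mol predicted free-energy change(s), kcal/mol.
#' @param threshold kcal/mol.
#' @return Character vector in `{"below_threshold", "destabilizing",
#'   "unknown"}`.
#' @export
classify_stability <- function(ddg_kcal_mol, threshold = 1.6) {
  ifelse(is.na(ddg_kcal_mol), "unknown",
         ifelse(ddg_kcal_mol > threshold, "destabilizing", "below_threshold"))
}
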