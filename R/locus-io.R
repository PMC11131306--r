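## VCF reading, filtering, merging and polarization.
## All coordinates are 1-based inclusive (VCF convention); BED inputs are
## converted at the reader.  Indels, spanning deletions ('*') and multiallelic
## records are excluded at read time; strand flips are never auto-repaired.

site_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

## Extract and filter the fixed columns of a vcfR object to biallelic SNVs
## inside the region.  Returns the row index kept plus a site data.frame.
vcf_snv_sites <- function(vcf, region) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  b <- region_bounds(region)
  keep <- chrom == region$chrom & pos >= b[1] & pos <= b[2] &
    !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  aa <- vcfR::extract.info(vcf, element = "AA")
  if (is.null(aa)) aa <- rep(NA_character_, length(pos))
  idx <- which(keep)
  idx <- idx[order(pos[idx])]
  sites <- data.frame(chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
                      alt = alt[idx], aa = aa[idx], stringsAsFactors = FALSE)
  list(idx = idx, sites = sites)
}

## Classify the ancestral-allele string against ref/alt (case-insensitive;
## lowercase marks low-confidence ancestral calls in the 1000G convention).
## Anything outside {ref, alt} -- ".", "N", "-", indel strings -- leaves the
## site unpolarized.
polarize_sites <- function(sites) {
  aa <- toupper(trimws(ifelse(is.na(sites$aa), "", sites$aa)))
  aa <- sub("\\|.*$", "", aa)   # 1000G AA can be "a|||": first field is the allele
  polarized <- aa == sites$ref | aa == sites$alt
  sites$polarized <- polarized
  sites$derived_is_alt <- ifelse(polarized, aa == sites$ref, NA)
  sites
}

#' Read phased modern genotypes from a VCF
#'
#' Reads a (possibly bgzipped) VCF of phased modern genomes, restricts to
#' biallelic SNVs inside `region`, and expands the phased genotypes into a
#' sites x haplotypes 0/1 ALT-indicator matrix (two columns per individual,
#' named `"<sample>_1"` and `"<sample>_2"`).  The ancestral allele is parsed
#' case-insensitively from the `AA` INFO tag; values outside `{REF, ALT}`
#' leave the site unpolarized.
#'
#' @param path VCF file.
#' @param region a [locus_region()].
#' @param panel optional data.frame from [read_panel()] supplying population
#'   codes; samples missing from the panel get `NA` codes.
#' @return list with `sites` (site table including polarization flags), `hap`
#'   (0/1 haplotype matrix) and `meta` (sample metadata).
#' @export
read_modern_vcf <- function(path, region, panel = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  sel <- vcf_snv_sites(vcf, region)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[sel$idx, , drop = FALSE]
  samples <- colnames(gt)
  if (length(samples) == 0) stop("read_modern_vcf: VCF has no sample columns")

  called <- !is.na(gt) & grepl("^[01][|/][01]$", gt)
  keep_site <- rowSums(called) == ncol(gt)
  gt <- gt[keep_site, , drop = FALSE]
  sites <- sel$sites[keep_site, , drop = FALSE]

  slashed <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(slashed)) {
    w <- which(slashed, arr.ind = TRUE)[1, ]
    stop(sprintf("read_modern_vcf: unphased genotype at %s:%d for sample %s",
                 sites$chrom[w[1]], sites$pos[w[1]], samples[w[2]]))
  }

  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  hap <- matrix(0L, nrow = nrow(gt), ncol = 2 * length(samples))
  hap[, seq(1, ncol(hap), 2)] <- a1
  hap[, seq(2, ncol(hap), 2)] <- a2
  colnames(hap) <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))

  sites <- polarize_sites(sites)
  rownames(sites) <- NULL
  meta <- data.frame(sample = samples, kind = "modern",
                     pop = NA_character_, super_pop = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    i <- match(meta$sample, panel$sample)
    meta$pop <- panel$pop[i]
    meta$super_pop <- panel$super_pop[i]
  }
  list(sites = sites, hap = hap, meta = meta)
}

#' Read a single archaic genome from a VCF
#'
#' Restricts to biallelic SNVs inside `region` and converts the single
#' sample's genotypes into 0/1/2 ALT dosages.  Sites with missing or
#' half-called genotypes are flagged uncalled (`NA` dosage) and later removed
#' by [merge_datasets()].
#'
#' @param path single-sample VCF file.
#' @param region a [locus_region()].
#' @param sample_id identifier to use for the sample (defaults to the VCF
#'   header name).
#' @return list with `sites`, `dosage` (integer vector, `NA` = uncalled) and
#'   `meta` (one-row data.frame).
#' @export
read_archaic_vcf <- function(path, region, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  sel <- vcf_snv_sites(vcf, region)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (ncol(gt) != 1)
    stop("read_archaic_vcf: expected a single-sample VCF, found ",
         ncol(gt), " samples (one file per archaic individual)")
  if (is.null(sample_id)) sample_id <- colnames(gt)[1]
  g <- gt[sel$idx, 1]
  ok <- grepl("^[01][|/][01]$", g)
  dosage <- rep(NA_integer_, length(g))
  dosage[ok] <- as.integer(substr(g[ok], 1, 1)) + as.integer(substr(g[ok], 3, 3))
  sites <- polarize_sites(sel$sites)
  rownames(sites) <- NULL
  list(sites = sites, dosage = dosage,
       meta = data.frame(sample = sample_id, kind = "archaic",
                         pop = "ARC", super_pop = "ARC",
                         stringsAsFactors = FALSE))
}

#' Merge modern haplotypes with archaic genotypes
#'
#' Intersects sites on (chrom, pos, ref, alt) across the modern dataset and
#' every archaic dataset, drops any site uncalled in at least one input, and
#' returns a complete [locus_matrix()].  Sites present at the same position
#' with disagreeing REF/ALT alleles abort with a report (strand flips are not
#' auto-repaired, since silent repair would corrupt polarization).  Sites
#' monomorphic across the merged dataset are retained: they still carry
#' identity-by-state information between moderns and archaics, and the
#' SFS statistics ignore them.
#'
#' @param modern result of [read_modern_vcf()].
#' @param archaics list of results of [read_archaic_vcf()].
#' @return A [locus_matrix()].
#' @export
merge_datasets <- function(modern, archaics) {
  if (length(archaics) == 0) stop("merge_datasets: no archaic datasets given")
  key_m <- site_key(modern$sites$chrom, modern$sites$pos,
                    modern$sites$ref, modern$sites$alt)
  pos_key_m <- paste(modern$sites$chrom, modern$sites$pos)
  keep <- rep(TRUE, length(key_m))
  for (a in archaics) {
    key_a <- site_key(a$sites$chrom, a$sites$pos, a$sites$ref, a$sites$alt)
    pos_key_a <- paste(a$sites$chrom, a$sites$pos)
    clash <- pos_key_m %in% pos_key_a & !(key_m %in% key_a)
    if (any(clash))
      stop("merge_datasets: REF/ALT mismatch at site(s) ",
           paste(utils::head(key_m[clash], 5), collapse = ", "))
    i <- match(key_m, key_a)
    keep <- keep & !is.na(i) & !is.na(a$dosage[i])
  }
  if (!any(keep)) stop("merge_datasets: no sites survive the merge")

  sites <- modern$sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  hap <- modern$hap[keep, , drop = FALSE]
  key <- key_m[keep]
  arc <- vapply(archaics, function(a) {
    a$dosage[match(key, site_key(a$sites$chrom, a$sites$pos,
                                 a$sites$ref, a$sites$alt))]
  }, numeric(nrow(sites)))
  arc <- matrix(as.integer(arc), nrow = nrow(sites))
  colnames(arc) <- vapply(archaics, function(a) a$meta$sample, character(1))
  meta <- rbind(modern$meta, do.call(rbind, lapply(archaics, `[[`, "meta")))
  rownames(meta) <- NULL
  locus_matrix(sites, hap, arc, meta)
}

#' Re-polarize a merged matrix from its AA tags
#'
#' Recomputes the polarization flags of each site from the stored ancestral
#' allele.  Unpolarizable sites (AA missing or outside `{REF, ALT}`) are
#' flagged, not dropped; downstream derived-allele analyses exclude them via
#' [derived_haplotypes()].
#'
#' @param m a [locus_matrix()].
#' @return The matrix with refreshed `polarized` and `derived_is_alt` flags.
#' @export
polarize_matrix <- function(m) {
  m$sites <- polarize_sites(m$sites)
  m
}

## ---- merged-matrix serialization ------------------------------------------

#' Write and re-read a merged locus matrix
#'
#' `write_merged()` writes a merged matrix to a directory as `merged.vcf`
#' (moderns phased with `|`, archaics unphased with `/`, AA in INFO),
#' `sites.tsv` (chrom, pos, ref, alt, aa, polarized) and `panel.tsv`.
#' `read_merged()` reconstructs the identical object.
#'
#' @param m a [locus_matrix()].
#' @param dir output directory (created if needed).
#' @return `write_merged()` the directory, invisibly; `read_merged()` a
#'   [locus_matrix()].
#' @export
write_merged <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mod <- modern_samples(m)
  gt_mod <- matrix(paste0(m$hap[, seq(1, ncol(m$hap), 2), drop = FALSE], "|",
                          m$hap[, seq(2, ncol(m$hap), 2), drop = FALSE]),
                   nrow = nrow(m$sites))
  arc_gt <- c("0/0", "0/1", "1/1")[m$arc + 1L]
  gt <- cbind(gt_mod, matrix(arc_gt, nrow = nrow(m$sites)))
  write_vcf(file.path(dir, "merged.vcf"), m$sites,
            c(mod, archaic_samples(m)), gt)
  utils::write.table(m$sites[c("chrom", "pos", "ref", "alt", "aa", "polarized")],
                     file.path(dir, "sites.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$meta, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_merged
#' @export
read_merged <- function(dir) {
  meta <- utils::read.table(file.path(dir, "panel.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  vcf <- vcfR::read.vcfR(file.path(dir, "merged.vcf"), verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  aa <- vcfR::extract.info(vcf, element = "AA")
  aa[!is.na(aa) & aa == "."] <- NA
  sites <- polarize_sites(data.frame(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], aa = aa,
    stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  mod <- meta$sample[meta$kind == "modern"]
  arcs <- meta$sample[meta$kind == "archaic"]
  gm <- gt[, mod, drop = FALSE]
  hap <- matrix(0L, nrow(gm), 2 * length(mod))
  hap[, seq(1, ncol(hap), 2)] <- as.integer(substr(gm, 1, 1))
  hap[, seq(2, ncol(hap), 2)] <- as.integer(substr(gm, 3, 3))
  colnames(hap) <- as.vector(rbind(paste0(mod, "_1"), paste0(mod, "_2")))
  ga <- gt[, arcs, drop = FALSE]
  arc <- matrix(as.integer(substr(ga, 1, 1)) + as.integer(substr(ga, 3, 3)),
                nrow(ga), dimnames = list(NULL, arcs))
  locus_matrix(sites, hap, arc, meta)
}

## Minimal VCFv4.2 writer for the matrix-shaped data this package produces.
## No timestamps: identical inputs yield byte-identical files.
write_vcf <- function(path, sites, samples, gt) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  info <- paste0("AA=", ifelse(is.na(sites$aa), ".", sites$aa))
  body <- cbind(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref, sites$alt, ".", "PASS", info, "GT", gt)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}
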