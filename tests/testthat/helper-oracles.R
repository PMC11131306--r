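# Independent oracles and tiny fixture builders shared across the suite.

# Brute-force IBS distance matrix: explicit double loop over objects using
# the per-pair kernel definitions, independent of the vectorized code path.
brute_force_ibs <- function(m) {
  scaled <- cbind(m$hap, m$arc / 2)
  n <- ncol(scaled)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- mean(abs(scaled[, i] - scaled[, j]))
  }
  dimnames(D) <- list(c(colnames(m$hap), colnames(m$arc)),
                      c(colnames(m$hap), colnames(m$arc)))
  D
}

# Mean pairwise Hamming distance between haplotype columns, divided by span.
brute_force_pi <- function(h, span) {
  n <- ncol(h)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(h[, i] != h[, j])
  }
  tot / choose(n, 2) / span
}

# Procrustes RMS after centering and optimal rotation/reflection.
procrustes_rms <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  s <- svd(t(B) %*% A)
  sqrt(mean((A - B %*% (s$u %*% t(s$v)))^2))
}

# Write a small VCF from explicit field vectors (for reader tests).
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, samples,
                           aa = NULL, info = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  if (is.null(info)) info <- if (is.null(aa)) "." else paste0("AA=", aa)
  gt <- matrix(gt, nrow = length(pos), byrow = TRUE)  # site-major literals
  body <- apply(cbind(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT", gt),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  path
}

# Small hand-assembled merged matrix (no VCF round trip involved).
toy_matrix <- function(hap, arc, pos = NULL, aa = NULL, ref = NULL,
                       alt = NULL, chrom = "11", pops = NULL) {
  hap <- as.matrix(hap)
  arc <- as.matrix(arc)
  ns <- nrow(hap)
  if (is.null(pos)) pos <- seq(1000, by = 500, length.out = ns)
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("G", ns)
  if (is.null(aa)) aa <- ref
  n_ind <- ncol(hap) / 2
  ids <- sprintf("S%02d", seq_len(n_ind))
  colnames(hap) <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
  if (is.null(colnames(arc)))
    colnames(arc) <- paste0("ARC", seq_len(ncol(arc)))
  if (is.null(pops)) pops <- rep("POP1", n_ind)
  sites <- paleolocus:::polarize_sites(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, aa = aa,
               stringsAsFactors = FALSE))
  meta <- rbind(data.frame(sample = ids, kind = "modern", pop = pops,
                           super_pop = pops, stringsAsFactors = FALSE),
                data.frame(sample = colnames(arc), kind = "archaic",
                           pop = "ARC", super_pop = "ARC",
                           stringsAsFactors = FALSE))
  locus_matrix(sites, hap, arc, meta)
}

# Exchangeable null for the conservation test: replace the archaic panel by
# four relabeled modern individuals drawn from the same simulated pool.
pseudo_archaic_null_p <- function(seed, n_sets = 1000) {
  sim <- simulate_locus(simulation_config(seed = seed, delta = 0,
                                          n_introgressed = 0, drift = 0))
  m <- sim$matrix
  set.seed(seed)
  ids <- sample(paleolocus:::modern_samples(m), 4)
  c1 <- paste0(ids, "_1"); c2 <- paste0(ids, "_2")
  arc <- m$hap[, c1, drop = FALSE] + m$hap[, c2, drop = FALSE]
  colnames(arc) <- paste0("PSEUDO", seq_along(ids))
  keep <- setdiff(paleolocus:::modern_samples(m), ids)
  keepcols <- as.vector(rbind(paste0(keep, "_1"), paste0(keep, "_2")))
  meta <- rbind(m$meta[m$meta$kind == "modern" & m$meta$sample %in% keep, ],
                data.frame(sample = colnames(arc), kind = "archaic",
                           pop = "ARC", super_pop = "ARC"))
  m2 <- locus_matrix(m$sites, m$hap[, keepcols, drop = FALSE], arc, meta)
  resample_conservation_test(m2, keep, sim$track, n_sets = n_sets,
                             seed = seed)$empirical_p
}
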