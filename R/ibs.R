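## Identity-by-state dissimilarities between modern haplotypes and archaic
## genotypes.  All three kernels are per-site means of |a - b| on a common
## [0,1] scale where a haplotype allele is 0/1 and an archaic "scaled
## genotype" is dosage/2, so a heterozygous archaic site contributes 0.5
## against either haplotype allele.  Means (not sums) keep pairs comparable
## if site subsets ever differ; ordination is invariant to the global scale.

check_shared <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must cover the same sites")
  if (length(a) == 0) stop("zero shared sites")
}

#' Identity-by-state dissimilarities
#'
#' Per-site mean IBS dissimilarities in `[0,1]` between two phased haplotypes
#' (`hap_hap_distance`), a haplotype and an archaic diploid dosage vector
#' (`hap_gt_distance`, the dosage is scaled by 1/2), and two archaic dosage
#' vectors (`gt_gt_distance`, absolute dosage difference scaled by 1/2).
#'
#' @param h1,h2,h haplotype vectors with entries in `{0,1}`.
#' @param g,g1,g2 dosage vectors with entries in `{0,1,2}`.
#' @return A dissimilarity in `[0,1]`.
#' @examples
#' hap_hap_distance(c(1, 0, 1, 0), c(1, 1, 1, 1))  # 0.5
#' hap_gt_distance(c(1, 0, 1), c(2, 0, 1))         # 1/6
#' gt_gt_distance(c(2, 1, 0), c(0, 1, 2))          # 2/3
#' @export
hap_hap_distance <- function(h1, h2) {
  check_shared(h1, h2)
  stopifnot(all(h1 %in% 0:1), all(h2 %in% 0:1))
  mean(abs(h1 - h2))
}

#' @rdname hap_hap_distance
#' @export
hap_gt_distance <- function(h, g) {
  check_shared(h, g)
  stopifnot(all(h %in% 0:1), all(g %in% 0:2))
  mean(abs(h - g / 2))
}

#' @rdname hap_hap_distance
#' @export
gt_gt_distance <- function(g1, g2) {
  check_shared(g1, g2)
  stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2))
  mean(abs(g1 - g2) / 2)
}

#' IBS distance matrix over haplotypes and archaic genotypes
#'
#' Builds the weighted dissimilarity matrix consumed by [weighted_mds()]: one
#' object per modern haplotype and one per archaic sample, pairwise distances
#' from the three IBS kernels (all equal to a per-site mean L1 distance after
#' scaling archaic dosages by 1/2), and the one-fifth-style weights of
#' [assign_weights()] attached.
#'
#' @param m a [locus_matrix()].
#' @param weights optional weight vector (defaults to [assign_weights()] on
#'   the matrix metadata).
#' @return An object of class `ibs_dist`: list with `labels`, `D` (symmetric,
#'   zero diagonal, entries in `[0,1]`), `weights` (summing to 1), `kind`
#'   (`"modern"`/`"archaic"` per object) and `group` (population codes).
#' @export
build_distance_matrix <- function(m, weights = NULL) {
  scaled <- cbind(m$hap, m$arc / 2)
  if (ncol(scaled) < 2) stop("build_distance_matrix: need at least 2 objects")
  D <- as.matrix(stats::dist(t(scaled), method = "manhattan")) / nrow(scaled)
  labels <- c(colnames(m$hap), colnames(m$arc))
  dimnames(D) <- list(labels, labels)
  mod <- m$meta[m$meta$kind == "modern", , drop = FALSE]
  arc <- m$meta[m$meta$kind == "archaic", , drop = FALSE]
  kind <- c(rep("modern", ncol(m$hap)), rep("archaic", ncol(m$arc)))
  group <- c(rep(mod$super_pop, each = 2), arc$pop)
  if (is.null(weights))
    weights <- assign_weights(n_archaic = nrow(arc), n_haplotypes = ncol(m$hap))
  structure(list(labels = labels, D = D, weights = weights, kind = kind,
                 group = group),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat(sprintf("<ibs_dist> %d objects (%d modern haplotypes, %d archaic)\n",
              length(x$labels), sum(x$kind == "modern"),
              sum(x$kind == "archaic")))
  cat(sprintf("  distance range %.4f-%.4f; weights sum to %g\n",
              min(x$D[upper.tri(x$D)]), max(x$D), sum(x$weights)))
  invisible(x)
}

#' Write an IBS distance matrix to TSV
#'
#' Writes both the square labelled matrix and a long format (obj1, obj2,
#' distance).
#'
#' @param d an `ibs_dist` object.
#' @param square_path,long_path output files (either may be `NULL` to skip).
#' @return Invisibly, `d`.
#' @export
write_distance_tsv <- function(d, square_path = NULL, long_path = NULL) {
  if (!is.null(square_path))
    utils::write.table(data.frame(label = d$labels, d$D, check.names = FALSE),
                       square_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    ut <- which(upper.tri(d$D), arr.ind = TRUE)
    utils::write.table(data.frame(obj1 = d$labels[ut[, 1]],
                                  obj2 = d$labels[ut[, 2]],
                                  distance = d$D[ut]),
                       long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(d)
}
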