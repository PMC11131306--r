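## Two ordinations are used at the locus: a weighted classical MDS of the
## haplotype/archaic IBS matrix (weights chosen so the whole modern panel
## carries the same mass as each single archaic genome), and an ordinal SMACOF
## of the Euclidean distances between populations in standardized
## selection-statistic space.

#' Sample-size-balancing ordination weights
#'
#' With `A` archaic samples and `H` modern haplotypes, every archaic sample
#' gets weight `1/(A+1)` and every modern haplotype `1/((A+1) * H)`, so the
#' modern panel as a whole carries the same weight as each archaic genome
#' (with 4 archaics, one fifth each) and weights sum to 1.  This prevents the
#' thousands of modern haplotypes from dominating the MDS geometry.
#'
#' @param meta optional sample metadata (as in a [locus_matrix()]); modern
#'   samples count two haplotypes each.
#' @param n_archaic,n_haplotypes explicit counts, used when `meta` is `NULL`.
#' @return Numeric weight vector ordered haplotypes first, then archaics.
#' @examples
#' w <- assign_weights(n_archaic = 4, n_haplotypes = 5008)
#' sum(w)  # 1
#' @export
assign_weights <- function(meta = NULL, n_archaic = NULL, n_haplotypes = NULL) {
  if (!is.null(meta)) {
    n_archaic <- sum(meta$kind == "archaic")
    n_haplotypes <- 2 * sum(meta$kind == "modern")
  }
  if (is.null(n_archaic) || is.null(n_haplotypes) ||
      n_archaic < 1 || n_haplotypes < 1)
    stop("assign_weights: need at least one archaic sample and one modern haplotype")
  c(rep(1 / ((n_archaic + 1) * n_haplotypes), n_haplotypes),
    rep(1 / (n_archaic + 1), n_archaic))
}

new_ordination <- function(labels, points, method, explained_variance = NULL,
                           eig = NULL, weights = NULL, stress1 = NULL,
                           n_iterations = NULL, converged = NA, group = NULL) {
  colnames(points) <- paste0("axis", seq_len(ncol(points)))
  rownames(points) <- labels
  structure(list(labels = labels, points = points, method = method,
                 explained_variance = explained_variance, eig = eig,
                 weights = weights, stress1 = stress1,
                 n_iterations = n_iterations, converged = converged,
                 group = group),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination: %s> %d objects in %d dimensions\n",
              x$method, nrow(x$points), ncol(x$points)))
  if (!is.null(x$explained_variance))
    cat("  explained variance:",
        paste(sprintf("%.2f%%", 100 * x$explained_variance), collapse = ", "),
        "\n")
  if (!is.null(x$stress1))
    cat(sprintf("  stress-1 = %.6g after %d iterations (converged: %s)\n",
                x$stress1, x$n_iterations, x$converged))
  invisible(x)
}

#' @export
plot.ordination <- function(x, axes = c(1, 2), col = NULL, pch = 19,
                            cex = 0.7, ...) {
  pts <- x$points[, axes, drop = FALSE]
  if (ncol(pts) == 1) pts <- cbind(pts, 0)
  if (is.null(col)) {
    col <- if (!is.null(x$group)) as.integer(factor(x$group)) else 1
  }
  labs <- colnames(x$points)[axes]
  if (!is.null(x$explained_variance) &&
      all(axes <= length(x$explained_variance)))
    labs <- sprintf("%s (%.1f%%)", labs, 100 * x$explained_variance[axes])
  graphics::plot(pts, col = col, pch = pch, cex = cex,
                 xlab = labs[1], ylab = if (length(labs) > 1) labs[2] else "",
                 ...)
  invisible(x)
}

## Fix axis signs so the largest-magnitude coordinate on each axis is
## positive: reproducible orientation across eigen-solver implementations.
fix_axis_signs <- function(points) {
  for (k in seq_len(ncol(points))) {
    i <- which.max(abs(points[, k]))
    if (points[i, k] < 0) points[, k] <- -points[, k]
  }
  points
}

#' Weighted classical multidimensional scaling
#'
#' Classical (Torgerson) MDS generalized to per-object weights: the matrix
#' `-D^2/2` is double-centered with the weight vector as centering mass
#' (`B = (I - 1 w') (-D^2/2) (I - w 1')`), the symmetrized matrix
#' `W^{1/2} B W^{1/2}` is eigendecomposed (guaranteeing real eigenvalues), and
#' coordinates are back-transformed so the weighted sum of squares on each
#' axis equals its eigenvalue.  With equal weights this reduces exactly to
#' [stats::cmdscale()].  Negative-eigenvalue axes are dropped; explained
#' variance is reported as each eigenvalue over the sum of positive
#' eigenvalues.  Zero-weight objects are excluded from the eigenproblem and
#' placed afterwards by the standard out-of-sample formula, so they cannot
#' influence any other object's coordinates.
#'
#' @param D an `ibs_dist` object from [build_distance_matrix()], or a
#'   symmetric dissimilarity matrix.
#' @param k number of axes requested (if fewer positive eigenvalues exist,
#'   fewer axes are returned with a warning).
#' @param weights per-object non-negative weights summing to 1; taken from
#'   `D` when it is an `ibs_dist`.
#' @return An `ordination` object with `points`, `eig`, `explained_variance`.
#' @export
weighted_mds <- function(D, k = 2, weights = NULL) {
  group <- NULL
  if (inherits(D, "ibs_dist")) {
    if (is.null(weights)) weights <- D$weights
    group <- D$group
    D <- D$D
  }
  n <- nrow(D)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(nrow(D) == ncol(D), length(weights) == n, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weighted_mds: weights must sum to 1")
  if (k < 1) stop("weighted_mds: k must be >= 1")
  labels <- if (!is.null(rownames(D))) rownames(D) else paste0("obj", seq_len(n))

  act <- which(weights > 0)
  w <- weights[act]
  A <- -0.5 * D[act, act, drop = FALSE]^2
  Jw <- diag(length(act)) - outer(rep(1, length(act)), w)
  B <- Jw %*% A %*% t(Jw)
  sw <- sqrt(w)
  S <- (B * outer(sw, sw))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12 & e$values > 0)
  if (length(pos) == 0) stop("weighted_mds: no positive eigenvalues")
  if (k > length(pos)) {
    warning("weighted_mds: only ", length(pos),
            " positive eigenvalues; returning fewer axes than requested")
    k <- length(pos)
  }
  lambda <- e$values[pos[seq_len(k)]]
  V <- e$vectors[, pos[seq_len(k)], drop = FALSE]
  X <- (V / sw) %*% diag(sqrt(lambda), k)

  points <- matrix(NA_real_, n, k)
  points[act, ] <- X
  if (length(act) < n) {
    # out-of-sample placement of zero-weight objects:
    # beta_i = -1/2 (d^2_{new,i} - B_ii); x_new = diag(1/lambda) X' W beta
    Bii <- diag(B)
    WX <- X * w
    for (j in setdiff(seq_len(n), act)) {
      beta <- -0.5 * (D[j, act]^2 - Bii)
      points[j, ] <- as.vector(crossprod(WX, beta)) / lambda
    }
  }
  points <- fix_axis_signs(points)
  new_ordination(labels, points, method = "wMDS",
                 explained_variance = lambda / sum(e$values[pos]),
                 eig = e$values[pos], weights = weights, group = group,
                 converged = TRUE)
}

## Primary-approach monotone (isotonic) regression of configuration distances
## on the dissimilarity order: ties in the dissimilarities are broken by the
## current distances, so tied dissimilarities may receive unequal disparities.
monotone_disparities <- function(delta, d) {
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  dhat[ord] <- stats::isoreg(d[ord])$yf
  dhat
}

#' Ordinal SMACOF multidimensional scaling
#'
#' Minimizes stress-1 by majorization ("scaling by majorizing a complicated
#' function"): disparities are fitted to the configuration distances by
#' monotone regression on the rank order of the input dissimilarities
#' (primary approach to ties), rescaled by the optimal least-squares factor,
#' and the configuration is updated by the Guttman transform.  Raw stress is
#' non-increasing across iterations by construction.  Initialization is the
#' metric (Torgerson) solution by default, or random configurations when
#' `n_init > 1` (controlled by `seed`), keeping the lowest-stress solution.
#'
#' @param D symmetric zero-diagonal dissimilarity matrix.
#' @param k embedding dimension.
#' @param seed integer seed used for random initializations.
#' @param max_iter maximum majorization iterations per start.
#' @param tol convergence tolerance on the relative stress-1 change.
#' @param n_init number of starts (first is Torgerson, the rest random).
#' @return An `ordination` object with `points`, `stress1`, `n_iterations`,
#'   `converged`, and the per-iteration stress trace as attribute
#'   `"stress_trace"` on the object (`$stress_trace`).
#' @export
smacof_ordinal <- function(D, k = 2, seed = NULL, max_iter = 300,
                           tol = 1e-6, n_init = 1) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop("smacof_ordinal: dissimilarity matrix must be symmetric")
  if (any(diag(D) != 0)) stop("smacof_ordinal: diagonal must be zero")
  labels <- if (!is.null(rownames(D))) rownames(D) else paste0("obj", seq_len(n))
  ut <- upper.tri(D)
  delta <- D[ut]
  if (length(unique(delta)) == 1)
    warning("smacof_ordinal: all dissimilarities are equal (degenerate ties)")

  run_one <- function(X) {
    pair_d <- function(X) as.matrix(stats::dist(X))[ut]
    d <- pair_d(X)
    trace <- numeric(0)
    stress <- Inf
    converged <- FALSE
    iter <- 0
    Dhat <- matrix(0, n, n)
    for (iter in seq_len(max_iter)) {
      dhat <- monotone_disparities(delta, d)
      s <- sum(d * dhat)
      if (s > 0) dhat <- dhat * s / sum(dhat^2)  # optimal LS rescaling
      new_stress <- sqrt(sum((dhat - d)^2) / sum(d^2))
      trace <- c(trace, new_stress)
      if (is.finite(stress) && abs(stress - new_stress) < tol * max(stress, 1e-12)) {
        stress <- new_stress
        converged <- TRUE
        break
      }
      stress <- new_stress
      # Guttman transform
      Dhat[ut] <- dhat; Dhat[lower.tri(Dhat)] <- t(Dhat)[lower.tri(Dhat)]
      dm <- as.matrix(stats::dist(X))
      ratio <- ifelse(dm > 0, Dhat / dm, 0)
      Bm <- -ratio
      diag(Bm) <- -rowSums(Bm)
      X <- Bm %*% X / n
      d <- pair_d(X)
    }
    list(X = X, stress = stress, trace = trace, iter = iter,
         converged = converged)
  }

  # Torgerson start (padded with zero columns if D has lower rank)
  X0 <- suppressWarnings(stats::cmdscale(D, k = k))
  if (ncol(X0) < k) X0 <- cbind(X0, matrix(0, n, k - ncol(X0)))
  best <- run_one(X0)
  if (n_init > 1) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n_init - 1)) {
      cand <- run_one(matrix(stats::rnorm(n * k), n, k) * max(delta))
      if (cand$stress < best$stress) best <- cand
    }
  }
  out <- new_ordination(labels, fix_axis_signs(best$X), method = "SMACOF",
                        stress1 = best$stress, n_iterations = best$iter,
                        converged = best$converged)
  out$stress_trace <- best$trace
  out
}

#' Project populations from standardized selection statistics
#'
#' Computes Euclidean distances between populations in the space of their
#' standardized per-gene selection statistics and projects them with
#' [smacof_ordinal()].  The table must be complete (complete-case
#' requirement): any missing cell aborts.
#'
#' @param std_stats numeric matrix or data.frame, populations x statistics
#'   (row names = population codes).
#' @param k embedding dimension.
#' @param seed,max_iter,tol,n_init passed to [smacof_ordinal()].
#' @return An `ordination` object.
#' @export
project_populations <- function(std_stats, k = 2, seed = NULL,
                                max_iter = 300, tol = 1e-6, n_init = 1) {
  m <- as.matrix(std_stats)
  if (!is.numeric(m)) stop("project_populations: table must be numeric")
  if (nrow(m) < 3) stop("project_populations: need at least 3 populations")
  if (anyNA(m)) stop("project_populations: table has missing cells")
  D <- as.matrix(stats::dist(m))
  smacof_ordinal(D, k = k, seed = seed, max_iter = max_iter, tol = tol,
                 n_init = n_init)
}

#' Write ordination outputs to TSV
#'
#' @param ord an `ordination` object.
#' @param coords_path coordinates TSV (label, axes, weight, group).
#' @param scree_path optional scree TSV (axis, eigenvalue, explained
#'   variance); only written for weighted MDS results.
#' @return Invisibly, `ord`.
#' @export
write_ordination_tsv <- function(ord, coords_path, scree_path = NULL) {
  df <- data.frame(label = ord$labels, ord$points, check.names = FALSE)
  if (!is.null(ord$weights)) df$weight <- ord$weights
  if (!is.null(ord$group)) df$group <- ord$group
  utils::write.table(df, coords_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(scree_path) && !is.null(ord$eig))
    utils::write.table(data.frame(axis = seq_along(ord$eig),
                                  eigenvalue = ord$eig,
                                  explained_variance = ord$eig / sum(ord$eig)),
                       scree_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ord)
}
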