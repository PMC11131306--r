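## Synthetic input bundles emulating the statistical structure the pipeline
## assumes: multi-population phased modern haplotypes, four deeply diverged
## archaic diploid genotypes, lineage-specific mutations whose conservation
## distributions differ by a controllable shift, introgressed tracts copied
## from a donor archaic into a configurable number of haplotypes, and the
## matching conservation/Sprime/window/gene/annotation files.
##
## Sites are generated independently given their lineage labels and
## frequency law (no coalescent machinery): that is sufficient for the SFS-,
## IBS- and conservation-based statistics under test, and linkage exists
## exactly where the analyses need it, through the introgressed tracts.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a 1 Mb locus,
#' 2 populations of 50 diploid individuals (200 haplotypes), 4 archaic
#' genomes, around 600 biallelic SNVs split 300/150/150 into shared,
#' modern-lineage (EMH) and archaic-lineage (ARC) sites, a neutral derived-
#' frequency law (probability proportional to 1/i for derived count i),
#' standard-normal background conservation with EMH-lineage sites shifted by
#' `delta = 1`, and an introgressed tract spanning the central fifth of the
#' locus copied from the first archaic into 3 recipient haplotypes.
#'
#' @param seed integer seed; all randomness flows from it through named
#'   child streams per component.
#' @param chrom chromosome label.
#' @param locus_start first base of the locus.
#' @param locus_length locus length in bp.
#' @param n_populations,n_per_pop modern panel structure.
#' @param archaic_ids archaic sample names (their count sets the panel size).
#' @param n_shared,n_emh,n_arc expected site counts per lineage class
#'   (realized counts are Poisson).
#' @param sfs_law `"neutral"` (weights 1/i), `"high_freq"` (weights i,
#'   enriching high-frequency derived alleles), or a numeric weight vector
#'   over derived counts `1..H-1`.
#' @param delta conservation shift added to EMH-lineage site scores.
#' @param cons_sd background conservation standard deviation.
#' @param drift standard deviation of the log-normal per-population carrier
#'   weights (0 = exchangeable populations).
#' @param n_introgressed number of recipient haplotypes `k`.
#' @param tract `c(start, end)` of the introgressed tract (default: central
#'   fifth of the locus); must lie within the locus.
#' @param donor donor archaic id (default: first of `archaic_ids`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, chrom = "11", locus_start = 68000000,
                              locus_length = 1000000, n_populations = 2,
                              n_per_pop = 50,
                              archaic_ids = c("AltaiNea", "Vindija33.19",
                                              "Chagyrskaya", "Denisova"),
                              n_shared = 300, n_emh = 150, n_arc = 150,
                              sfs_law = "neutral", delta = 1, cons_sd = 1,
                              drift = 0.5, n_introgressed = 3, tract = NULL,
                              donor = NULL) {
  if (is.null(tract))
    tract <- round(locus_start + c(0.4, 0.6) * locus_length)
  if (is.null(donor)) donor <- archaic_ids[1]
  cfg <- list(seed = seed, chrom = chrom, locus_start = locus_start,
              locus_length = locus_length, n_populations = n_populations,
              n_per_pop = n_per_pop, archaic_ids = archaic_ids,
              n_shared = n_shared, n_emh = n_emh, n_arc = n_arc,
              sfs_law = sfs_law, delta = delta, cons_sd = cons_sd,
              drift = drift, n_introgressed = n_introgressed, tract = tract,
              donor = donor)
  stopifnot(n_shared >= 0, n_emh >= 0, n_arc >= 0, n_introgressed >= 0,
            is.finite(delta), length(archaic_ids) >= 1)
  if (tract[1] < locus_start ||
      tract[2] > locus_start + locus_length - 1 || tract[1] > tract[2])
    stop("simulation_config: tract must lie within the locus")
  if (!donor %in% archaic_ids)
    stop("simulation_config: donor must be one of archaic_ids")
  structure(cfg, class = "simulation_config")
}

sfs_weights <- function(law, H) {
  i <- seq_len(H - 1)
  if (is.numeric(law)) {
    if (length(law) != H - 1) stop("sfs_law weight vector must have length H-1")
    return(law / sum(law))
  }
  w <- switch(law, neutral = 1 / i, high_freq = i,
              stop("unknown sfs_law: ", law))
  w / sum(w)
}

#' Per-population carrier weights
#'
#' Draws, for each site, a log-normal weight per population
#' (`exp(N(0, drift))`) with which that population's haplotypes are favoured
#' when the site's derived-allele carriers are placed.  With `drift = 0` all
#' populations are exchangeable; larger values create allele-frequency
#' differentiation that separates populations in ordination.
#'
#' @param n_populations number of populations.
#' @param n_sites number of sites.
#' @param drift log-normal standard deviation.
#' @return `n_populations` x `n_sites` matrix of positive weights.
#' @export
make_population_structure <- function(n_populations, n_sites, drift) {
  matrix(exp(stats::rnorm(n_populations * n_sites, 0, drift)),
         n_populations, n_sites)
}

#' Simulate a merged locus dataset with known truth
#'
#' Generates a complete [locus_matrix()] and the ground truth behind it.
#' Site positions are placed uniformly at random without collision; each
#' site gets a lineage label (class counts Poisson around the configured
#' expectations), an ancestral and derived base (the `AA` tag is set so
#' polarization recovers the simulated derived allele exactly), derived
#' carriers drawn from the configured frequency law (shared and EMH sites;
#' exact carrier counts, placed with the population-structure weights),
#' archaic derived dosages (shared and ARC sites, conditioned on presence;
#' EMH sites are ancestral in every archaic), and a conservation score
#' (background normal, shifted by `delta` at EMH-lineage sites).  Finally
#' the donor archaic is made homozygous across the introgressed tract, with
#' derived alleles fixed at ARC-lineage tract sites, and `k` recipient
#' haplotypes receive the donor's alleles across the tract.
#'
#' @param config a [simulation_config()].
#' @return An object of class `locus_sim`: list with `matrix` (a
#'   [locus_matrix()]), `track` (a [conservation_track()]), `truth` (per-site
#'   lineage labels and scores, recipient haplotype ids, tract, per-site
#'   introgressed alleles, Sprime-style scores) and `config`.
#' @export
simulate_locus <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  child <- setNames(sample.int(.Machine$integer.max, 6),
                    c("sites", "frequencies", "archaic", "conservation",
                      "introgression", "tables"))
  H <- 2 * cfg$n_populations * cfg$n_per_pop
  A <- length(cfg$archaic_ids)

  ## -- sites ------------------------------------------------------------
  set.seed(child["sites"])
  n_cls <- c(shared = stats::rpois(1, cfg$n_shared),
             EMH = stats::rpois(1, cfg$n_emh),
             ARC = stats::rpois(1, cfg$n_arc))
  n_sites <- sum(n_cls)
  if (n_sites > cfg$locus_length)
    stop("simulate_locus: more sites than locus positions")
  pos <- sort(sample.int(cfg$locus_length, n_sites)) + cfg$locus_start - 1
  lineage <- sample(rep(names(n_cls), n_cls))
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n_sites, replace = TRUE)
  der <- unname(vapply(anc, function(a) sample(setdiff(bases, a), 1),
                       character(1)))
  anc_is_ref <- stats::runif(n_sites) < 0.5
  ref <- ifelse(anc_is_ref, anc, der)
  alt <- ifelse(anc_is_ref, der, anc)

  ## -- modern derived carriers ------------------------------------------
  set.seed(child["frequencies"])
  w_sfs <- sfs_weights(cfg$sfs_law, H)
  popw <- make_population_structure(cfg$n_populations, n_sites, cfg$drift)
  hap_pop <- rep(seq_len(cfg$n_populations), each = 2 * cfg$n_per_pop)
  dh <- matrix(0L, n_sites, H)  # derived-allele indicators
  poly <- which(lineage != "ARC")
  counts <- sample.int(H - 1, length(poly), replace = TRUE, prob = w_sfs)
  for (j in seq_along(poly)) {
    s <- poly[j]
    carriers <- sample.int(H, counts[j], prob = popw[hap_pop, s])
    dh[s, carriers] <- 1L
  }

  ## -- archaic derived dosages ------------------------------------------
  set.seed(child["archaic"])
  dg <- matrix(0L, n_sites, A)
  with_arc <- which(lineage != "EMH")
  for (s in with_arc) {
    repeat {
      g <- stats::rbinom(A, 2, stats::runif(1, 0.2, 0.8))
      if (sum(g) >= 1) break
    }
    dg[s, ] <- g
  }

  ## -- conservation ------------------------------------------------------
  set.seed(child["conservation"])
  score <- stats::rnorm(n_sites, ifelse(lineage == "EMH", cfg$delta, 0),
                        cfg$cons_sd)

  ## -- introgressed tract ------------------------------------------------
  set.seed(child["introgression"])
  donor_col <- match(cfg$donor, cfg$archaic_ids)
  in_tract <- pos >= cfg$tract[1] & pos <= cfg$tract[2]
  # donor homozygous across the tract so recipients can match it exactly;
  # derived fixed at ARC-lineage tract sites so the tract is detectable
  het <- in_tract & dg[, donor_col] == 1L
  dg[het, donor_col] <- 2L * stats::rbinom(sum(het), 1, 0.5)
  fix_arc <- in_tract & lineage == "ARC"
  dg[fix_arc, donor_col] <- 2L
  recipients <- integer(0)
  if (cfg$n_introgressed > 0) {
    recipients <- sort(sample.int(H, cfg$n_introgressed))
    dh[in_tract, recipients] <- dg[in_tract, donor_col] / 2L
  }

  set.seed(child["tables"])
  sprime_score <- round(stats::runif(sum(fix_arc), 100, 500), 1)
  genes <- synthetic_gene_table(cfg)

  ## -- assemble ----------------------------------------------------------
  mod_ids <- sprintf("IND%03d", seq_len(cfg$n_populations * cfg$n_per_pop))
  pops <- paste0("POP", rep(seq_len(cfg$n_populations), each = cfg$n_per_pop))
  hap <- dh
  flip <- !anc_is_ref  # derived is REF there: ALT indicator = 1 - derived
  hap[flip, ] <- 1L - hap[flip, , drop = FALSE]
  arc <- dg
  arc[flip, ] <- 2L - arc[flip, , drop = FALSE]
  storage.mode(hap) <- "integer"
  storage.mode(arc) <- "integer"
  colnames(hap) <- as.vector(rbind(paste0(mod_ids, "_1"),
                                   paste0(mod_ids, "_2")))
  colnames(arc) <- cfg$archaic_ids
  sites <- polarize_sites(data.frame(chrom = cfg$chrom, pos = pos, ref = ref,
                                     alt = alt, aa = anc,
                                     stringsAsFactors = FALSE))
  meta <- rbind(data.frame(sample = mod_ids, kind = "modern", pop = pops,
                           super_pop = pops, stringsAsFactors = FALSE),
                data.frame(sample = cfg$archaic_ids, kind = "archaic",
                           pop = "ARC", super_pop = "ARC",
                           stringsAsFactors = FALSE))
  m <- locus_matrix(sites, hap, arc, meta)
  truth <- list(lineage = lineage, score = score,
                derived_base = der, ancestral_base = anc,
                recipients = colnames(hap)[recipients],
                tract = cfg$tract, donor = cfg$donor,
                sprime_sites = which(fix_arc), sprime_score = sprime_score)
  structure(list(matrix = m,
                 track = conservation_track(cfg$chrom, pos, score),
                 truth = truth, genes = genes, config = cfg),
            class = "locus_sim")
}

#' @export
print.locus_sim <- function(x, ...) {
  cat(sprintf("<locus_sim> seed %d: %d sites (%s), %d recipients of a %s tract\n",
              x$config$seed, nrow(x$matrix$sites),
              paste(names(table(x$truth$lineage)), table(x$truth$lineage),
                    sep = "=", collapse = ", "),
              length(x$truth$recipients),
              format(diff(x$config$tract) + 1, big.mark = ",")))
  print(x$matrix)
  invisible(x)
}

#' Write a simulated dataset as a file bundle
#'
#' Emits every input format the pipeline consumes: a phased modern VCF with
#' `AA` INFO tags, one unphased VCF per archaic genome, a per-base
#' conservation bedGraph, a Sprime-style TSV (the ARC-lineage derived alleles
#' inside the tract, with a segment id and positive scores), a window
#' statistic TSV (nucleotide diversity per 10 kb window per population), a
#' gene BED (a focal gene plus length-matched and off-length decoys), the
#' sample panel TSV, a variant annotation TSV (the packaged example table),
#' and the ground truth as JSON.  Identical configurations produce
#' byte-identical bundles.
#'
#' @param sim a `locus_sim` from [simulate_locus()].
#' @param dir output directory (created if needed).
#' @param window_bp window size for the emitted diversity statistics.
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(sim, dir, window_bp = 10000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- sim$matrix
  cfg <- sim$config
  paths <- c(modern = file.path(dir, "modern.vcf"))
  gt_mod <- matrix(paste0(m$hap[, seq(1, ncol(m$hap), 2), drop = FALSE], "|",
                          m$hap[, seq(2, ncol(m$hap), 2), drop = FALSE]),
                   nrow = nrow(m$sites))
  write_vcf(paths["modern"], m$sites, modern_samples(m), gt_mod)
  for (a in colnames(m$arc)) {
    p <- file.path(dir, paste0("archaic_", a, ".vcf"))
    paths[a] <- p
    write_vcf(p, m$sites, a,
              matrix(c("0/0", "0/1", "1/1")[m$arc[, a] + 1L], ncol = 1))
  }

  paths["panel"] <- file.path(dir, "panel.tsv")
  utils::write.table(m$meta, paths["panel"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths["conservation"] <- file.path(dir, "conservation.bedGraph")
  writeLines(sprintf("%s\t%d\t%d\t%s", cfg$chrom, sim$track$pos - 1,
                     sim$track$pos, formatC(sim$track$score, format = "f",
                                            digits = 6)),
             paths["conservation"])

  paths["sprime"] <- file.path(dir, "sprime.tsv")
  si <- sim$truth$sprime_sites
  sprime <- data.frame(CHROM = cfg$chrom, POS = m$sites$pos[si],
                       ID = ".", REF = m$sites$ref[si], ALT = m$sites$alt[si],
                       ALLELE = sim$truth$derived_base[si],
                       SEGMENT = "seg1", SCORE = sim$truth$sprime_score)
  utils::write.table(sprime, paths["sprime"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths["windows"] <- file.path(dir, "windows.tsv")
  utils::write.table(windowed_pi(m, window_bp), paths["windows"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  paths["genes"] <- file.path(dir, "genes.bed")
  genes <- sim$genes
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chrom, genes$start - 1,
                     genes$end, genes$gene), paths["genes"])

  paths["variants"] <- file.path(dir, "variants.tsv")
  file.copy(system.file("extdata", "lrp5_archaic_variants.tsv",
                        package = "paleolocus"),
            paths["variants"], overwrite = TRUE)

  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

## Per-population nucleotide diversity on fixed-width windows.
windowed_pi <- function(m, window_bp) {
  pops <- unique(m$meta$pop[m$meta$kind == "modern"])
  lo <- floor(min(m$sites$pos) / window_bp) * window_bp
  hi <- max(m$sites$pos)
  starts <- seq(lo, hi, by = window_bp)
  win <- findInterval(m$sites$pos, starts)
  out <- list()
  for (p in pops) {
    ids <- m$meta$sample[m$meta$kind == "modern" & m$meta$pop == p]
    h <- m$hap[, hap_columns_of(m, ids), drop = FALSE]
    n <- ncol(h)
    fr <- rowMeans(h)
    contrib <- 2 * fr * (1 - fr) * n / (n - 1)
    pi_w <- vapply(seq_along(starts), function(i) {
      sum(contrib[win == i]) / window_bp
    }, numeric(1))
    out[[p]] <- data.frame(chrom = m$sites$chrom[1], start = starts + 1,
                           end = starts + window_bp, pop = p, stat = "pi",
                           value = pi_w)
  }
  do.call(rbind, out)
}

## Focal gene over the tract midpoint plus decoy genes with lengths spread
## around the focal length (about half land inside a +/-20 kb matching band).
synthetic_gene_table <- function(cfg, focal_length = 136690, n_decoys = 80) {
  focal_start <- max(cfg$locus_start,
                     round(mean(cfg$tract)) - round(focal_length / 2))
  lens <- round(focal_length + stats::runif(n_decoys, -40000, 40000))
  starts <- cfg$locus_start +
    round(stats::runif(n_decoys) * (cfg$locus_length - max(lens) - 1))
  data.frame(gene = c("FOCAL", sprintf("DECOY%02d", seq_len(n_decoys))),
             chrom = cfg$chrom,
             start = c(focal_start, starts),
             end = c(focal_start + focal_length - 1, starts + lens - 1),
             stringsAsFactors = FALSE)
}

#' Read a simulated bundle back through the standard readers
#'
#' Reads the modern and archaic VCFs of a [write_bundle()] directory with
#' [read_modern_vcf()]/[read_archaic_vcf()] and merges them with
#' [merge_datasets()].
#'
#' @param dir bundle directory.
#' @param region optional [locus_region()]; inferred from the site range of
#'   the modern VCF when omitted.
#' @return A [locus_matrix()].
#' @export
read_bundle <- function(dir, region = NULL) {
  panel <- utils::read.table(file.path(dir, "panel.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  if (is.null(region)) {
    v <- utils::read.table(file.path(dir, "modern.vcf"), comment.char = "#",
                           sep = "\t")
    region <- locus_region(as.character(v[1, 1]), min(v[, 2]), max(v[, 2]))
  }
  modern <- read_modern_vcf(file.path(dir, "modern.vcf"), region,
                            panel = data.frame(sample = panel$sample,
                                               pop = panel$pop,
                                               super_pop = panel$super_pop))
  arcs <- panel$sample[panel$kind == "archaic"]
  archaics <- lapply(arcs, function(a) {
    read_archaic_vcf(file.path(dir, paste0("archaic_", a, ".vcf")), region)
  })
  merge_datasets(modern, archaics)
}
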