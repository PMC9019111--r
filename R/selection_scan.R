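#' Define a core region
#'
#' The EHH anchor region: 1-based start, end-exclusive end, so its length
#' is `end - start` (e.g. the 2L:2,420,443-2,426,521 region spanning Vgsc
#' codon 995 is 6,078 bp).
#'
#' @param start 1-based start position (included).
#' @param end End position (excluded).
#' @return List of class `core_region` with `start`, `end`, `length`.
#' @export
core_region <- function(start, end) {
  if (end <= start) stop("core_region: end must exceed start")
  structure(list(start = as.integer(start), end = as.integer(end),
                 length = as.integer(end - start)),
            class = "core_region")
}

.core_sites <- function(haps, core) {
  which(haps$sites$pos >= core$start & haps$sites$pos < core$end)
}

#' Enumerate core haplotypes and label them by focal-allele content
#'
#' Collects the distinct allele strings over the core region, drops those
#' at cohort frequency not above `min_frequency` (strictly greater than,
#' "above 1%"), and labels retained cores by the focal alleles they carry:
#' within each focal class cores are numbered by decreasing frequency
#' (`F1` = most frequent core carrying the F allele); cores carrying no
#' focal allele are labelled `wt`.
#'
#' @param haps A `haplotype_matrix`.
#' @param core A [core_region()].
#' @param min_frequency Retention threshold, strict (default 0.01).
#' @param focal_alleles Named list of logical carrier vectors (length =
#'   haplotype count); names are the label stems (e.g. `F`, `S`, `L`).
#' @return Object of class `core_haplotype_set`: `cores` (data.frame
#'   `core_id`, `seq`, `count`, `frequency`, `label`), `assignment`
#'   (haplotype -> core_id, NA for dropped cores), `core`, `site_index`.
#' @export
define_core_haplotypes <- function(haps, core, min_frequency = 0.01,
                                   focal_alleles = list()) {
  sites <- .core_sites(haps, core)
  if (length(sites) == 0L) stop("define_core_haplotypes: empty core region")
  g <- haps$geno[sites, , drop = FALSE]
  seqs <- apply(g, 2, paste, collapse = "")
  n <- ncol(g)
  tab <- sort(table(seqs), decreasing = TRUE)
  keep <- tab[tab / n > min_frequency]
  cores <- data.frame(core_id = seq_along(keep), seq = names(keep),
                      count = as.integer(keep),
                      frequency = as.numeric(keep) / n,
                      stringsAsFactors = FALSE)
  assignment <- match(seqs, cores$seq)
  # label cores by focal content, numbering within class by frequency rank
  labels <- rep("wt", nrow(cores))
  for (k in names(focal_alleles)) {
    carries <- vapply(seq_len(nrow(cores)), function(i) {
      idx <- which(assignment == i)
      length(idx) > 0L && mean(focal_alleles[[k]][idx]) >= 0.5
    }, logical(1))
    hit <- which(carries & labels == "wt")
    labels[hit] <- paste0(k, seq_along(hit))
  }
  cores$label <- labels
  structure(list(cores = cores, assignment = assignment, core = core,
                 site_index = sites),
            class = "core_haplotype_set")
}

#' @export
print.core_haplotype_set <- function(x, ...) {
  cat("core_haplotype_set:", nrow(x$cores), "cores over",
      x$core$length, "bp [", x$core$start, ",", x$core$end, ")\n")
  print(x$cores[, c("core_id", "count", "frequency", "label")])
  invisible(x)
}

# excluded-site mask: cohort-wide singletons and missense sites
.ehh_excluded <- function(haps, effects = NULL) {
  counts <- rowSums(haps$geno != 0L)
  singleton <- counts == 1L
  nonsyn <- rep(FALSE, nrow(haps$sites))
  if (!is.null(effects)) {
    ns <- unique(effects$site_index[
      effects$effect_class %in% c("missense", "nonsense")])
    nonsyn[ns] <- TRUE
  }
  singleton | nonsyn
}

#' Extended haplotype homozygosity decay from a core haplotype
#'
#' For the carriers of one core haplotype, EHH at a site is the probability
#' that two randomly drawn carriers are identical at every included site
#' from the core edge out to that site: partition the carriers by their
#' haplotype prefix and compute `sum(choose(c_i, 2)) / choose(n, 2)`.
#' Cohort-wide singleton sites and non-synonymous sites are excluded from
#' the partitioning (they do not reflect shared ancestry of the flanking
#' background). EHH equals 1 at the core and is non-increasing outward.
#'
#' @param haps A `haplotype_matrix`.
#' @param core_set A `core_haplotype_set`.
#' @param core_id Which core to follow.
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param effects Optional annotation table ([annotate_all_sites()]) used to
#'   exclude non-synonymous sites.
#' @return Data.frame of class `ehh_curve`: `position`, `ehh`, plus
#'   attributes `direction`, `n_carriers`.
#' @export
ehh_decay <- function(haps, core_set, core_id,
                      direction = c("downstream", "upstream"),
                      effects = NULL) {
  direction <- match.arg(direction)
  carriers <- which(core_set$assignment == core_id)
  if (length(carriers) < 2L)
    stop("ehh_decay: fewer than 2 carriers of core ", core_id)
  excluded <- .ehh_excluded(haps, effects)
  pos <- haps$sites$pos
  if (direction == "downstream") {
    sites <- which(pos >= core_set$core$end & !excluded)
    sites <- sites[order(pos[sites])]
  } else {
    sites <- which(pos < core_set$core$start & !excluded)
    sites <- sites[order(pos[sites], decreasing = TRUE)]
  }
  n <- length(carriers)
  denom <- choose(n, 2)
  part <- rep(1L, n)                 # partition class per carrier
  out_pos <- integer(length(sites)); out_ehh <- numeric(length(sites))
  for (k in seq_along(sites)) {
    alleles <- haps$geno[sites[k], carriers]
    part <- as.integer(factor(paste(part, alleles)))
    cnt <- tabulate(part)
    out_pos[k] <- pos[sites[k]]
    out_ehh[k] <- sum(choose(cnt, 2)) / denom
  }
  structure(data.frame(position = out_pos, ehh = out_ehh),
            direction = direction, n_carriers = n, core_id = core_id,
            class = c("ehh_curve", "data.frame"))
}

#' Moving-window haplotype homozygosity
#'
#' Per window, the unbiased probability that two randomly drawn haplotypes
#' of the subset are identical across the window's sites:
#' `H = sum(c_i (c_i - 1)) / (n (n - 1))` over distinct-haplotype class
#' sizes. H = 1 when all haplotypes are identical in the window and 0 when
#' all are distinct.
#'
#' @param haps A `haplotype_matrix`.
#' @param windows Data.frame with `start`, `end` (1-based inclusive).
#' @param subset Haplotype indices (>= 2).
#' @return The `windows` data.frame with an added `homozygosity` column.
#' @export
window_homozygosity <- function(haps, windows, subset) {
  stopifnot(nrow(windows) >= 1L, length(subset) >= 2L)
  n <- length(subset)
  windows$homozygosity <- vapply(seq_len(nrow(windows)), function(i) {
    sel <- haps$sites$pos >= windows$start[i] & haps$sites$pos <= windows$end[i]
    g <- haps$geno[sel, subset, drop = FALSE]
    cnt <- table(apply(g, 2, paste, collapse = ""))
    sum(cnt * (cnt - 1)) / (n * (n - 1))
  }, numeric(1))
  windows
}

#' Tile a region into windows
#'
#' @param start,end Region bounds (1-based inclusive).
#' @param size Window size in bp.
#' @param step Step between window starts (default `size`, non-overlapping).
#' @return Data.frame with `start`, `end`.
#' @export
tile_windows <- function(start, end, size, step = size) {
  starts <- seq(start, end, by = step)
  data.frame(start = starts, end = pmin(starts + size - 1, end))
}

#' Scan for regions of fixed divergence between two haplotype groups
#'
#' Counts, per window, the sites at which group A is fixed for one allele
#' and group B fixed for a different allele; contiguous windows with a
#' positive count are merged into divergence tracts. Used to locate e.g. a
#' gene-conversion tract separating two otherwise near-identical sweep
#' groups.
#'
#' @param haps A `haplotype_matrix`.
#' @param idx_a,idx_b Haplotype indices of the two groups.
#' @param windows Data.frame with `start`, `end`.
#' @return List with `windows` (adds `fixed_diffs`) and `tracts`
#'   (data.frame `start`, `end`, `fixed_diffs` of merged tracts).
#' @export
divergence_region_scan <- function(haps, idx_a, idx_b, windows) {
  stopifnot(length(idx_a) >= 1L, length(idx_b) >= 1L)
  ga <- haps$geno[, idx_a, drop = FALSE]
  gb <- haps$geno[, idx_b, drop = FALSE]
  fixed_a <- apply(ga, 1, function(x) length(unique(x)) == 1L)
  fixed_b <- apply(gb, 1, function(x) length(unique(x)) == 1L)
  fixed_diff <- fixed_a & fixed_b & (ga[, 1L] != gb[, 1L])
  pos <- haps$sites$pos
  windows$fixed_diffs <- vapply(seq_len(nrow(windows)), function(i)
    sum(fixed_diff & pos >= windows$start[i] & pos <= windows$end[i]),
    integer(1))
  hit <- windows$fixed_diffs > 0L
  tracts <- NULL
  if (any(hit)) {
    r <- rle(hit)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    tracts <- data.frame(
      start = windows$start[starts[runs]],
      end = windows$end[ends[runs]],
      fixed_diffs = vapply(runs, function(k)
        sum(windows$fixed_diffs[starts[k]:ends[k]]), integer(1)))
  } else {
    tracts <- data.frame(start = integer(0), end = integer(0),
                         fixed_diffs = integer(0))
  }
  list(windows = windows, tracts = tracts)
}

#' Genetic map with a constant recombination rate
#'
#' @param rate_cM_per_Mb Recombination rate (default 1 cM/Mb).
#' @return Function mapping a bp span to cM.
#' @export
genetic_map <- function(rate_cM_per_Mb = 1.0) {
  stopifnot(rate_cM_per_Mb >= 0)
  structure(function(bp) bp * rate_cM_per_Mb / 1e6,
            rate = rate_cM_per_Mb, class = "genetic_map")
}

#' Pairwise shared-haplotype lengths around a core
#'
#' For every unordered pair of carriers, extends independently on each
#' flank from the core until the first mismatch at an included site; the
#' shared length is the genetic-map length (cM) of the maximal interval of
#' identity (both flank extents plus the core). Pairs identical to the edge
#' of the analysed region are censored at the edge and flagged. The median
#' is summarized with a seeded percentile-bootstrap confidence interval.
#'
#' @param haps A `haplotype_matrix`.
#' @param carriers Haplotype indices of the group (>= 2).
#' @param core A [core_region()].
#' @param map A [genetic_map()] (default 1 cM/Mb).
#' @param effects Optional annotation table for non-synonymous exclusion.
#' @param reps Bootstrap replicates (default 2000).
#' @param level CI level (default 0.95).
#' @param seed Random seed.
#' @param label Group label carried into the result.
#' @return List of class `shared_length_result`: `lengths_cM` per pair,
#'   `censored` flags, `median_cM`, `ci` (length 2), `reps`, `seed`.
#' @export
shared_haplotype_lengths <- function(haps, carriers, core,
                                     map = genetic_map(), effects = NULL,
                                     reps = 2000L, level = 0.95, seed = 1L,
                                     label = NA) {
  if (length(carriers) < 2L)
    stop("shared_haplotype_lengths: need >= 2 carriers")
  excluded <- .ehh_excluded(haps, effects)
  pos <- haps$sites$pos
  down <- which(pos >= core$end & !excluded); down <- down[order(pos[down])]
  up <- which(pos < core$start & !excluded)
  up <- up[order(pos[up], decreasing = TRUE)]
  span_lo <- min(pos); span_hi <- max(pos)
  gd <- haps$geno[down, carriers, drop = FALSE]
  gu <- haps$geno[up, carriers, drop = FALSE]
  pairs <- utils::combn(seq_along(carriers), 2)
  lengths_bp <- numeric(ncol(pairs)); censored <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    md <- which(gd[, i] != gd[, j])
    mu <- which(gu[, i] != gu[, j])
    cens <- FALSE
    if (length(md)) ext_d <- pos[down[md[1L]]] - 1L - (core$end - 1L)
    else { ext_d <- span_hi - (core$end - 1L); cens <- TRUE }
    if (length(mu)) ext_u <- core$start - (pos[up[mu[1L]]] + 1L)
    else { ext_u <- core$start - span_lo; cens <- TRUE }
    lengths_bp[k] <- core$length + max(ext_d, 0) + max(ext_u, 0)
    censored[k] <- cens
  }
  lengths_cM <- map(lengths_bp)
  med <- stats::median(lengths_cM)
  set.seed(seed)
  boot <- replicate(reps, stats::median(
    sample(lengths_cM, length(lengths_cM), replace = TRUE)))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(label = label, lengths_cM = lengths_cM,
                 censored = censored, median_cM = med, ci = ci,
                 level = level, reps = reps, seed = seed),
            class = "shared_length_result")
}

#' Correlation between first-detection year and shared-haplotype length
#'
#' Pearson correlation (with the two-sided t-transform p-value) between the
#' year each haplotype group was first detected and its median shared
#' length — a crude test of whether older sweeps have shorter haplotypes.
#'
#' @param first_year Numeric vector of first-detection years per group.
#' @param median_length Numeric vector of median shared lengths (cM).
#' @return List: `r`, `df`, `p_value`, `defined` (FALSE with zero variance).
#' @export
detection_year_correlation <- function(first_year, median_length) {
  stopifnot(length(first_year) == length(median_length))
  if (length(first_year) < 3L)
    stop("detection_year_correlation: need >= 3 groups")
  if (stats::sd(first_year) == 0 || stats::sd(median_length) == 0)
    return(list(r = NA_real_, df = length(first_year) - 2L,
                p_value = NA_real_, defined = FALSE))
  ct <- stats::cor.test(first_year, median_length, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p_value = ct$p.value, defined = TRUE)
}
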