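#' Per-population allele frequencies
#'
#' Computes, for every (site, alternate allele) pair, the exact haplotype
#' count ratio within each population. Frequencies of all alleles at a site
#' sum to 1 within each population.
#'
#' @param haps A `haplotype_matrix`.
#' @param grouping Optional character vector assigning each haplotype to a
#'   population; defaults to `haps$meta$population`.
#' @return Data.frame of class `allele_frequency_table`: one row per
#'   (site, alt) with columns `site_index`, `chrom`, `pos`, `ref`, `alt`,
#'   `alt_index`, one frequency column per population, and `max_freq`.
#'   Attribute `n_haps` holds per-population haplotype counts.
#' @export
allele_frequencies <- function(haps, grouping = haps$meta$population) {
  stopifnot(length(grouping) == ncol(haps$geno))
  pops <- sort(unique(grouping))
  n_haps <- vapply(pops, function(p) sum(grouping == p), integer(1))
  if (any(n_haps == 0L)) stop("allele_frequencies: empty population")
  rows <- list()
  for (i in seq_len(nrow(haps$sites))) {
    s <- haps$sites[i, ]
    alts <- strsplit(s$alts, ",")[[1]]
    g <- haps$geno[i, ]
    for (j in seq_along(alts)) {
      freqs <- vapply(pops, function(p)
        sum(g[grouping == p] == j) / n_haps[[p]], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        site_index = i, chrom = s$chrom, pos = s$pos, ref = s$ref,
        alt = alts[j], alt_index = j,
        as.list(stats::setNames(freqs, pops)),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$max_freq <- do.call(pmax, out[, pops, drop = FALSE])
  attr(out, "populations") <- pops
  attr(out, "n_haps") <- n_haps
  class(out) <- c("allele_frequency_table", "data.frame")
  out
}

#' Filter alleles by maximum per-population frequency
#'
#' Keeps alleles whose frequency reaches `threshold` ("at or above", i.e.
#' `>=`) in at least one population — the screen used to shortlist
#' potentially functional resistance alleles.
#'
#' @param table An `allele_frequency_table`.
#' @param threshold Frequency threshold in (0, 1]; default 0.05.
#' @return The filtered table (rows with `max_freq >= threshold`).
#' @export
filter_by_max_frequency <- function(table, threshold = 0.05) {
  stopifnot(threshold > 0, threshold <= 1)
  out <- table[table$max_freq >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# carrier mask of one (site, alt) allele across haplotypes
.carrier <- function(haps, allele) {
  haps$geno[allele[1L], ] == allele[2L]
}

#' Lewontin's D' between two alleles
#'
#' Computes D = p_ab - p_a p_b over the haplotype set and normalizes by the
#' maximum attainable |D| given the allele frequencies, so that D' = 1 means
#' one allele is found only in combination with the other and D' = -1 that
#' they are never found together. Multi-allelic sites are handled per
#' allele (carrier vs non-carrier), so they contribute one result per
#' allele pair.
#'
#' @param haps A `haplotype_matrix`.
#' @param allele_a,allele_b Length-2 integer vectors `(site_index,
#'   alt_index)`.
#' @param subset Optional haplotype indices to restrict to.
#' @return List of class `ld_result`: `D`, `Dmax`, `Dprime`, `defined`
#'   (FALSE when either allele is absent or fixed, in which case `Dprime`
#'   is `NA`).
#' @export
lewontin_dprime <- function(haps, allele_a, allele_b, subset = NULL) {
  a <- .carrier(haps, allele_a)
  b <- .carrier(haps, allele_b)
  if (!is.null(subset)) { a <- a[subset]; b <- b[subset] }
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    return(structure(list(allele_a = allele_a, allele_b = allele_b,
                          D = NA_real_, Dmax = NA_real_, Dprime = NA_real_,
                          defined = FALSE), class = "ld_result"))
  }
  pab <- mean(a & b)
  D <- pab - pa * pb
  Dmax <- if (D > 0) min(pa * (1 - pb), (1 - pa) * pb)
          else       min(pa * pb, (1 - pa) * (1 - pb))
  Dprime <- if (D == 0) 0 else D / Dmax
  structure(list(allele_a = allele_a, allele_b = allele_b,
                 D = D, Dmax = Dmax, Dprime = Dprime, defined = TRUE),
            class = "ld_result")
}

#' Pairwise D' matrix over a set of alleles
#'
#' @param haps A `haplotype_matrix`.
#' @param alleles Data.frame with `site_index` and `alt_index` columns (one
#'   row per allele, e.g. a filtered [allele_frequencies()] table).
#' @param subset Optional haplotype indices.
#' @return Square numeric matrix of D' values (`NA` where undefined).
#' @export
dprime_matrix <- function(haps, alleles, subset = NULL) {
  k <- nrow(alleles)
  lab <- paste0(alleles$pos, ifelse(is.null(alleles$alt), "",
                                    paste0(":", alleles$alt)))
  out <- matrix(NA_real_, k, k, dimnames = list(lab, lab))
  for (i in seq_len(k)) {
    out[i, i] <- 1
    for (j in seq_len(k)[-seq_len(i)]) {
      r <- lewontin_dprime(haps,
                           c(alleles$site_index[i], alleles$alt_index[i]),
                           c(alleles$site_index[j], alleles$alt_index[j]),
                           subset)
      out[i, j] <- out[j, i] <- r$Dprime
    }
  }
  out
}

.interval_length <- function(interval) {
  # 1-based inclusive interval c(start, end)
  interval[2L] - interval[1L] + 1L
}

#' Nucleotide diversity of a haplotype subset
#'
#' Mean pairwise Hamming difference over all unordered haplotype pairs in
#' the subset, across sites falling inside `interval`, divided by the
#' interval length — per-bp pi with the unbiased n-choose-2 denominator.
#'
#' @param haps A `haplotype_matrix`.
#' @param subset Haplotype indices (>= 2).
#' @param interval `c(start, end)` genomic interval, 1-based inclusive.
#' @param label Optional subset label carried into the result.
#' @return List of class `diversity_result`: `label`, `interval`,
#'   `mean_pairwise_diff`, `pi_per_bp`.
#' @export
nucleotide_diversity <- function(haps, subset, interval, label = NA) {
  if (length(subset) < 2L)
    stop("nucleotide_diversity: subset must contain at least 2 haplotypes")
  in_win <- haps$sites$pos >= interval[1L] & haps$sites$pos <= interval[2L]
  g <- haps$geno[in_win, subset, drop = FALSE]
  n <- length(subset)
  # sum over sites of cross-class pair counts = total pairwise differences
  total <- 0
  for (i in seq_len(nrow(g))) {
    cnt <- tabulate(g[i, ] + 1L)
    total <- total + (choose(n, 2) - sum(choose(cnt, 2)))
  }
  mpd <- total / choose(n, 2)
  structure(list(label = label, interval = interval,
                 mean_pairwise_diff = mpd,
                 pi_per_bp = mpd / .interval_length(interval)),
            class = "diversity_result")
}

# Nei-Gojobori style opportunity counts for one codon: of the 9 possible
# single-base changes, the fraction that are synonymous accrues to S, the
# rest (incl. changes to/from stop) to N. Returns c(N, S) with N + S = 3.
.codon_opportunities <- function(codon) {
  bases <- c("A", "C", "G", "T")
  cb <- strsplit(codon, "")[[1]]
  aa <- Biostrings::GENETIC_CODE[[codon]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(bases, cb[p])) {
    mut <- cb; mut[p] <- b
    if (Biostrings::GENETIC_CODE[[paste(mut, collapse = "")]] == aa)
      syn <- syn + 1
  }
  c(N = 3 - syn / 3, S = syn / 3)
}

#' Ratio of non-synonymous to synonymous nucleotide diversity
#'
#' piN is the mean pairwise difference restricted to missense sites divided
#' by the number of non-synonymous site-opportunities in the coding
#' sequence; piS likewise for synonymous sites. Opportunities are counted
#' per codon as the fraction of the 9 possible single-base changes that are
#' synonymous vs non-synonymous (Nei-Gojobori style). With
#' `normalize = FALSE`, the raw ratio of per-variant-site diversities is
#' returned instead (no opportunity normalization).
#'
#' @param haps A `haplotype_matrix`.
#' @param subset Haplotype indices (>= 2).
#' @param effects Annotation table from [annotate_all_sites()] restricted to
#'   `alt_index == 1` or otherwise one row per site, aligned with
#'   `haps$sites` via `site_index`.
#' @param model The [gene_model()] (codon opportunity counting).
#' @param reference Plus-strand chromosome sequence.
#' @param normalize Use opportunity normalization (default TRUE).
#' @return List of class `diversity_result` with `piN`, `piS`, `ratio`
#'   (`NA`, flagged `ratio_defined = FALSE`, when piS = 0), and the
#'   opportunity counts `n_sites_N`, `n_sites_S`.
#' @export
pin_pis_ratio <- function(haps, subset, effects, model, reference,
                          normalize = TRUE) {
  if (length(subset) < 2L) stop("pin_pis_ratio: subset must be >= 2")
  eff_class <- rep(NA_character_, nrow(haps$sites))
  eff_class[effects$site_index] <- effects$effect_class
  n <- length(subset)
  pair_diffs <- function(rows) {
    tot <- 0
    for (i in rows) {
      cnt <- tabulate(haps$geno[i, subset] + 1L)
      tot <- tot + (choose(n, 2) - sum(choose(cnt, 2)))
    }
    tot / choose(n, 2)
  }
  dN <- pair_diffs(which(eff_class %in% c("missense", "nonsense")))
  dS <- pair_diffs(which(eff_class == "synonymous"))
  if (normalize) {
    reference <- toupper(as.character(reference))
    codons <- vapply(seq_len(model$cds_length / 3L), function(cn) {
      paste(vapply((cn - 1L) * 3L + 1:3, function(cp) {
        gp <- .genomic_coord(cp, model)
        b <- substr(reference, gp, gp)
        if (model$strand == "-") .COMPLEMENT[[b]] else b
      }, character(1)), collapse = "")
    }, character(1))
    opp <- rowSums(vapply(codons, .codon_opportunities, numeric(2)))
    nN <- opp[["N"]]; nS <- opp[["S"]]
  } else {
    nN <- sum(eff_class %in% c("missense", "nonsense"), na.rm = TRUE)
    nS <- sum(eff_class == "synonymous", na.rm = TRUE)
  }
  piN <- if (nN > 0) dN / nN else NA_real_
  piS <- if (nS > 0) dS / nS else NA_real_
  ratio_defined <- !is.na(piS) && piS > 0
  structure(list(label = NA, interval = NULL, pi_per_bp = NA_real_,
                 piN = piN, piS = piS,
                 ratio = if (ratio_defined) piN / piS else NA_real_,
                 ratio_defined = ratio_defined,
                 n_sites_N = nN, n_sites_S = nS),
            class = "diversity_result")
}

#' Dirichlet Monte-Carlo test for an excess of F/S heterozygotes
#'
#' Tests whether the observed number of individuals heterozygous for two
#' resistance alleles (e.g. L995F/L995S) is lower than expected under
#' Hardy-Weinberg proportions, which would be expected if carrying both
#' alleles conferred a fitness advantage (or the two alleles segregate in
#' partially isolated demes). Each replicate draws allele frequencies from
#' Dirichlet(counts + 1) (a flat prior over the three-allele simplex),
#' forms Hardy-Weinberg genotype probabilities, draws genotype counts for
#' `n` diploids from the implied multinomial, and records the F/S
#' heterozygote count; since the marginal count of a single multinomial
#' category is binomial, the count is drawn as Binomial(n, 2 p_F p_S). The
#' empirical p-value is the fraction of replicates whose simulated count is
#' strictly greater than the observed count.
#'
#' @param c_F,c_S,c_wt Haplotype counts of the two resistance alleles and
#'   wild type (must sum to `2 * n`).
#' @param n Number of diploid individuals.
#' @param observed_het Observed count of F/S heterozygotes.
#' @param reps Monte-Carlo replicates (default 1e6).
#' @param seed Random seed (integer, required for reproducibility).
#' @return List of class `het_excess_result`: the inputs plus `p_value`.
#' @export
het_excess_test <- function(c_F, c_S, c_wt, n, observed_het,
                            reps = 1e6, seed) {
  if (reps < 1) stop("het_excess_test: reps must be >= 1")
  if (c_F + c_S + c_wt != 2L * n)
    stop("het_excess_test: allele counts must sum to 2n")
  if (observed_het > n) stop("het_excess_test: observed_het > n")
  if (!missing(seed)) set.seed(seed) else seed <- NA
  exceed <- 0
  chunk <- 250000L
  done <- 0
  while (done < reps) {
    m <- min(chunk, reps - done)
    gF <- stats::rgamma(m, shape = c_F + 1)
    gS <- stats::rgamma(m, shape = c_S + 1)
    gW <- stats::rgamma(m, shape = c_wt + 1)
    tot <- gF + gS + gW
    sim <- stats::rbinom(m, n, 2 * (gF / tot) * (gS / tot))
    exceed <- exceed + sum(sim > observed_het)
    done <- done + m
  }
  structure(list(c_F = c_F, c_S = c_S, c_wt = c_wt, n = n,
                 observed_het = observed_het, reps = reps, seed = seed,
                 p_value = exceed / reps),
            class = "het_excess_result")
}

#' @export
print.het_excess_result <- function(x, ...) {
  cat(sprintf(
    "het-excess test: obs %d/%d F/S heterozygotes (counts %d/%d/%d), p = %.4g (%g reps)\n",
    x$observed_het, x$n, x$c_F, x$c_S, x$c_wt, x$p_value, x$reps))
  invisible(x)
}

#' Write an allele frequency table as TSV (percentages)
#'
#' @param table An `allele_frequency_table`.
#' @param path Output path.
#' @export
write_frequency_tsv <- function(table, path) {
  pops <- attr(table, "populations")
  out <- as.data.frame(table)
  out[pops] <- lapply(out[pops], function(x) round(100 * x, 1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
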