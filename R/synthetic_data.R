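#' Configuration for the synthetic sweep-cohort generator
#'
#' Fully parameterizes a seeded synthetic cohort: a random reference
#' sequence carrying one protein-coding gene, background (wild-type)
#' diversity built from founder haplotypes recombined into mosaics, and a
#' set of selective-sweep haplotype groups, each a near-identical copy of
#' one founder carrying a planted resistance allele, with exponential
#' recombination tails onto wild-type backgrounds, private new mutations,
#' secondary missense mutations radiating on one group, and a
#' gene-conversion-like divergence tract distinguishing two otherwise
#' identical groups.
#'
#' The defaults emulate the structure of a multi-country phased cohort:
#' 8 population cohorts of two species (400 haplotypes), wild-type
#' diversity around 1.4e-3 per bp, within-sweep-group diversity around
#' 1e-5 per bp, and 12 sweep groups (five on each of two focal kdr-like
#' alleles, plus two groups on private putative-resistance alleles).
#'
#' @param region_length Total simulated region (bp).
#' @param chrom Chromosome name written to the outputs.
#' @param gene_start,gene_end Gene interval (1-based inclusive).
#' @param exons Data.frame of CDS exon `start`, `end` (total length
#'   divisible by 3).
#' @param populations Data.frame: `population`, `species`, `year`,
#'   `n_haplotypes` (even).
#' @param n_founders Number of wild-type founder haplotypes.
#' @param switch_rate Mosaic founder-switch rate per bp (background LD).
#' @param theta Background mutation density per bp (expected segregating
#'   sites = `theta * region_length`).
#' @param sweep_groups Data.frame: `name`, `focal` (focal-allele class:
#'   `F`, `S`, or `L`), `near_pos` (target genomic position of the focal
#'   codon), `gr` (per-bp per-flank recombination-time parameter: the
#'   distance from the core to the nearest breakpoint is Exponential(gr)),
#'   `new_mut_rate` (expected private mutations per carrier), plus one
#'   integer column per population giving carrier counts.
#' @param secondary Data.frame of secondary missense mutations planted on
#'   nested carrier subsets of the first sweep group: `near_pos`,
#'   `n_carriers` (must be non-increasing; subsets are nested).
#' @param conversion `NULL` or list `recipient` (group name), `donor`
#'   (group name whose founder the recipient shares), `tract`
#'   (`c(start, end)`), `n_fixed_diffs` (derived alleles planted fixed in
#'   the recipient across the tract).
#' @param seed Integer seed (mandatory).
#' @return Object of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(
    region_length = 500000L,
    chrom = "sim2L",
    gene_start = 240001L,
    gene_end = 260000L,
    exons = data.frame(
      start = c(240001L, 243001L, 248001L, 252001L, 257001L),
      end   = c(240900L, 244200L, 249500L, 253800L, 258602L)),
    populations = data.frame(
      population = sprintf("pop%02d", 1:8),
      species = rep(c("gambiae", "coluzzii"), 4),
      year = c(2009L, 2010L, 2011L, 2012L, 2009L, 2000L, 2011L, 2012L),
      n_haplotypes = rep(50L, 8)),
    n_founders = 25L,
    switch_rate = 1e-5,
    theta = 0.0055,
    sweep_groups = NULL,
    secondary = data.frame(near_pos = c(240500L, 249000L, 257500L),
                           n_carriers = c(30L, 15L, 8L)),
    conversion = list(recipient = "S5", donor = "S4",
                      tract = c(249600L, 250400L), n_fixed_diffs = 6L),
    seed) {
  if (missing(seed)) stop("sweep_sim_config: seed is mandatory")
  if (is.null(sweep_groups)) {
    z <- function(...) c(...)
    sweep_groups <- data.frame(
      name = c("F1", "F2", "F3", "F4", "F5",
               "S1", "S2", "S3", "S4", "S5", "L1", "L2"),
      focal_id = c(rep("F", 5), rep("S", 5), "L1", "L2"),
      near_pos = c(rep(248500L, 5), rep(248520L, 5), 252800L, 243500L),
      gr = c(1.5e-6, 3e-6, 3e-6, 2e-6, 2.5e-6,
             1e-6, 2e-6, 2.5e-6, 3e-6, 3e-6, 4e-6, 3e-6),
      new_mut_rate = rep(1.0, 12),
      pop01 = z(20, 10, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
      pop02 = z(10, 10, 0, 0, 0, 0, 0, 0, 0, 0, 15, 0),
      pop03 = z(10, 0, 15, 0, 0, 0, 0, 0, 0, 0, 0, 0),
      pop04 = z(10, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
      pop05 = z(0, 0, 0, 10, 7, 0, 10, 0, 7, 7, 0, 0),
      pop06 = z(0, 0, 0, 10, 8, 0, 10, 0, 8, 8, 0, 0),
      pop07 = z(0, 0, 0, 0, 0, 15, 0, 10, 0, 0, 0, 0),
      pop08 = z(0, 0, 0, 0, 0, 15, 0, 10, 0, 0, 0, 10))
  }
  cfg <- structure(
    list(region_length = as.integer(region_length), chrom = chrom,
         gene_start = as.integer(gene_start), gene_end = as.integer(gene_end),
         exons = exons, populations = populations,
         n_founders = as.integer(n_founders), switch_rate = switch_rate,
         theta = theta, sweep_groups = sweep_groups, secondary = secondary,
         conversion = conversion, seed = as.integer(seed)),
    class = "sweep_sim_config")
  validate_sweep_sim_config(cfg)
  cfg
}

#' Validate a sweep simulation configuration
#'
#' @param cfg A `sweep_sim_config`.
#' @return The config, invisibly; stops with a list of violations otherwise.
#' @export
validate_sweep_sim_config <- function(cfg) {
  errs <- character(0)
  pops <- cfg$populations$population
  carrier_cols <- intersect(pops, names(cfg$sweep_groups))
  if (length(carrier_cols) != length(pops))
    errs <- c(errs, "sweep_groups must have one carrier column per population")
  else {
    per_pop <- colSums(cfg$sweep_groups[, carrier_cols, drop = FALSE])
    over <- per_pop > cfg$populations$n_haplotypes
    if (any(over))
      errs <- c(errs, paste0("carrier counts exceed population size in: ",
                             paste(pops[over], collapse = ", ")))
  }
  if (any(cfg$populations$n_haplotypes %% 2L != 0L))
    errs <- c(errs, "n_haplotypes must be even (diploid pairing)")
  if (sum(cfg$exons$end - cfg$exons$start + 1L) %% 3L != 0L)
    errs <- c(errs, "CDS length not divisible by 3")
  if (any(cfg$exons$start < cfg$gene_start | cfg$exons$end > cfg$gene_end))
    errs <- c(errs, "exons outside gene interval")
  if (cfg$gene_end > cfg$region_length)
    errs <- c(errs, "gene outside region")
  if (!is.null(cfg$conversion)) {
    if (!all(c(cfg$conversion$recipient, cfg$conversion$donor) %in%
             cfg$sweep_groups$name))
      errs <- c(errs, "conversion recipient/donor not among sweep groups")
    if (cfg$conversion$tract[2L] > cfg$region_length)
      errs <- c(errs, "conversion tract outside region")
  }
  if (!is.null(cfg$secondary) && nrow(cfg$secondary) &&
      is.unsorted(rev(cfg$secondary$n_carriers)))
    errs <- c(errs, "secondary n_carriers must be non-increasing (nested)")
  if (length(errs))
    stop("invalid sweep_sim_config:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(cfg)
}

# random DNA with stop codons removed from the CDS frame
.sim_reference <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$region_length, replace = TRUE)
  model <- gene_model("SIM1-RA", cfg$chrom, "+", cfg$exons)
  for (cn in seq_len(model$cds_length / 3L)) {
    gp <- vapply((cn - 1L) * 3L + 1:3, .genomic_coord, integer(1),
                 model = model)
    codon <- paste(ref[gp], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) ref[gp[3L]] <- "C"
  }
  list(reference = paste(ref, collapse = ""), model = model)
}

# first CDS position at/after near_pos where some substitution is missense;
# returns c(pos, alt as character)
.find_missense_site <- function(reference, model, near_pos, taken) {
  bases <- c("A", "C", "G", "T")
  cds_positions <- sort(unlist(Map(seq, model$cds_exons$start,
                                   model$cds_exons$end)))
  cand <- c(cds_positions[cds_positions >= near_pos],
            rev(cds_positions[cds_positions < near_pos]))
  for (p in cand) {
    if (p %in% taken) next
    ref_base <- substr(reference, p, p)
    for (alt in setdiff(bases, ref_base)) {
      eff <- annotate_codon_effect(variant_site(model$chrom, p, ref_base, alt),
                                   1L, model, reference)
      if (eff$effect_class == "missense") return(list(pos = p, alt = alt))
    }
  }
  stop("no missense site found near ", near_pos)
}

#' Generate a synthetic phased cohort with planted sweep groups
#'
#' Runs the seeded construction described in [sweep_sim_config()]:
#' (1) draw a reference sequence (stop-free CDS frame); (2) draw background
#' variant sites at density `theta` with a 1/i-weighted founder frequency
#' spectrum and build each wild-type haplotype as a founder mosaic with
#' Poisson switch points; (3) for each sweep group, copy its (group-
#' specific) founder, set the focal allele, and give each carrier
#' independent Exponential(`gr`) breakpoint distances per flank beyond
#' which it continues as a fresh wild-type mosaic, plus Poisson private new
#' mutations; (4) plant secondary missense mutations on nested carrier
#' subsets of the first group; (5) plant the gene-conversion divergence
#' tract (the recipient group shares the donor's founder and receives
#' `n_fixed_diffs` derived alleles fixed across the tract); (6) pair
#' haplotypes into diploids within populations.
#'
#' @param cfg A [sweep_sim_config()].
#' @param dir Output directory; when non-NULL, writes `reference.fa`,
#'   `genes.gff3`, `cohort.vcf`, `metadata.tsv`, `truth.tsv` and
#'   `config.json`.
#' @return List of class `sweep_cohort`: `haps` (a `haplotype_matrix`),
#'   `truth` (data.frame `hap_id`, `group`), `model` (the `gene_model`),
#'   `reference`, `focal_sites` (data.frame of planted focal/secondary/
#'   tract alleles), `secondary_carriers`, `config`, `files`.
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  validate_sweep_sim_config(cfg)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  L <- cfg$region_length
  simref <- .sim_reference(cfg)
  reference <- simref$reference
  model <- simref$model
  pops <- cfg$populations
  n_hap <- sum(pops$n_haplotypes)
  groups <- cfg$sweep_groups

  # --- planted site selection (deterministic given the reference) ---------
  # one focal allele per focal class: groups sharing a focal_id (e.g. the
  # five F groups) carry the same planted resistance allele
  taken <- integer(0)
  focal <- list()
  for (fid in unique(groups$focal_id)) {
    np <- groups$near_pos[match(fid, groups$focal_id)]
    fs <- .find_missense_site(reference, model, np, taken)
    taken <- c(taken, fs$pos)
    focal[[fid]] <- fs
  }
  sec <- list()
  if (!is.null(cfg$secondary) && nrow(cfg$secondary)) {
    for (i in seq_len(nrow(cfg$secondary))) {
      fs <- .find_missense_site(reference, model, cfg$secondary$near_pos[i],
                                taken)
      taken <- c(taken, fs$pos)
      sec[[i]] <- fs
    }
  }
  conv_pos <- integer(0)
  if (!is.null(cfg$conversion)) {
    tr <- cfg$conversion$tract
    avail <- setdiff(seq(tr[1L], tr[2L]), taken)
    conv_pos <- sort(sample(avail, cfg$conversion$n_fixed_diffs))
    taken <- c(taken, conv_pos)
  }

  # --- background sites over founders -------------------------------------
  n_bg <- stats::rpois(1, cfg$theta * L)
  bg_pos <- sort(sample(setdiff(seq_len(L), taken), n_bg))
  nf <- cfg$n_founders
  k_weights <- 1 / seq_len(nf - 1L)
  bg_count <- sample(nf - 1L, n_bg, replace = TRUE, prob = k_weights)
  founders <- matrix(0L, n_bg, nf)
  for (i in seq_len(n_bg))
    founders[i, sample(nf, bg_count[i])] <- 1L

  # a wild-type haplotype: founder mosaic over the background sites
  wt_mosaic <- function() {
    n_sw <- stats::rpois(1, cfg$switch_rate * L)
    cuts <- sort(stats::runif(n_sw, 1, L))
    seg <- findInterval(bg_pos, cuts) + 1L
    founder_per_seg <- sample(nf, n_sw + 1L, replace = TRUE)
    founders[cbind(seq_len(n_bg), founder_per_seg[seg])]
  }

  # --- assemble haplotypes -------------------------------------------------
  # per-group founder: distinct founders, recipient shares donor's
  g_founder <- seq_len(nrow(groups))
  if (!is.null(cfg$conversion)) {
    ri <- match(cfg$conversion$recipient, groups$name)
    di <- match(cfg$conversion$donor, groups$name)
    g_founder[ri] <- g_founder[di]
  }
  g_founder <- ((g_founder - 1L) %% nf) + 1L

  bg_mat <- matrix(0L, n_bg, n_hap)
  labels <- character(n_hap)
  pop_of <- character(n_hap)
  focal_mat <- matrix(0L, length(focal), n_hap)
  rownames(focal_mat) <- names(focal)
  hap_i <- 0L
  group_members <- stats::setNames(vector("list", nrow(groups)), groups$name)
  for (p in seq_len(nrow(pops))) {
    pname <- pops$population[p]
    n_p <- pops$n_haplotypes[p]
    filled <- 0L
    for (gi in seq_len(nrow(groups))) {
      n_c <- groups[[pname]][gi]
      if (n_c == 0L) next
      core_pos <- focal[[groups$focal_id[gi]]]$pos
      for (k in seq_len(n_c)) {
        hap_i <- hap_i + 1L; filled <- filled + 1L
        d_up <- stats::rexp(1, rate = groups$gr[gi])
        d_down <- stats::rexp(1, rate = groups$gr[gi])
        inside <- bg_pos >= core_pos - d_up & bg_pos <= core_pos + d_down
        hap <- wt_mosaic()
        hap[inside] <- founders[inside, g_founder[gi]]
        bg_mat[, hap_i] <- hap
        focal_mat[groups$focal_id[gi], hap_i] <- 1L
        labels[hap_i] <- groups$name[gi]
        pop_of[hap_i] <- pname
        group_members[[groups$name[gi]]] <-
          c(group_members[[groups$name[gi]]], hap_i)
      }
    }
    for (k in seq_len(n_p - filled)) {
      hap_i <- hap_i + 1L
      bg_mat[, hap_i] <- wt_mosaic()
      labels[hap_i] <- "wt"
      pop_of[hap_i] <- pname
    }
  }

  # --- secondary missense mutations on nested subsets of group 1 ----------
  sec_mat <- matrix(0L, length(sec), n_hap)
  sec_carriers <- list()
  if (length(sec)) {
    g1 <- group_members[[groups$name[1L]]]
    pool <- g1
    for (i in seq_along(sec)) {
      n_c <- min(cfg$secondary$n_carriers[i], length(pool))
      carriers <- sort(sample(pool, n_c))
      sec_mat[i, carriers] <- 1L
      sec_carriers[[i]] <- carriers
      pool <- carriers                      # nesting
    }
  }

  # --- gene-conversion divergence tract ------------------------------------
  conv_mat <- matrix(0L, length(conv_pos), n_hap)
  if (length(conv_pos)) {
    rec <- group_members[[cfg$conversion$recipient]]
    conv_mat[, rec] <- 1L
  }

  # --- private new mutations -----------------------------------------------
  priv_pos <- integer(0); priv_hap <- integer(0)
  all_taken <- c(taken, bg_pos)
  for (gi in seq_len(nrow(groups))) {
    for (h in group_members[[groups$name[gi]]]) {
      n_m <- stats::rpois(1, groups$new_mut_rate[gi])
      if (n_m > 0L) {
        ps <- sample(setdiff(seq_len(L), c(all_taken, priv_pos)), n_m)
        priv_pos <- c(priv_pos, ps)
        priv_hap <- c(priv_hap, rep(h, n_m))
      }
    }
  }
  priv_mat <- matrix(0L, length(priv_pos), n_hap)
  if (length(priv_pos))
    priv_mat[cbind(seq_along(priv_pos), priv_hap)] <- 1L

  # --- assemble site table and genotype matrix ----------------------------
  base_alt <- function(pos) {
    vapply(pos, function(p) {
      rb <- substr(reference, p, p)
      sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    }, character(1))
  }
  focal_pos <- vapply(focal, `[[`, integer(1), "pos")
  focal_alt <- vapply(focal, `[[`, character(1), "alt")
  sec_pos <- vapply(sec, function(x) x$pos, integer(1))
  sec_alt <- vapply(sec, function(x) x$alt, character(1))
  all_pos <- c(bg_pos, focal_pos, sec_pos, conv_pos, priv_pos)
  all_alt <- c(base_alt(bg_pos), focal_alt, sec_alt,
               base_alt(conv_pos), base_alt(priv_pos))
  geno <- rbind(bg_mat, focal_mat, sec_mat, conv_mat, priv_mat)
  ord <- order(all_pos)
  geno <- geno[ord, , drop = FALSE]
  all_pos <- all_pos[ord]; all_alt <- all_alt[ord]
  refs <- vapply(all_pos, function(p) substr(reference, p, p), character(1))
  # drop monomorphic rows (e.g. background count draws that landed on 0)
  poly <- rowSums(geno) > 0L
  geno <- geno[poly, , drop = FALSE]
  sites <- data.frame(chrom = rep(cfg$chrom, sum(poly)),
                      pos = all_pos[poly],
                      ref = refs[poly], alts = all_alt[poly],
                      n_alleles = rep(2L, sum(poly)),
                      stringsAsFactors = FALSE)

  # --- diploid pairing within populations ----------------------------------
  hap_order <- integer(0)
  sample_ids <- character(0)
  for (p in seq_len(nrow(pops))) {
    idx <- which(pop_of == pops$population[p])
    idx <- idx[sample.int(length(idx))]
    hap_order <- c(hap_order, idx)
    sample_ids <- c(sample_ids,
                    sprintf("%s_s%02d", pops$population[p],
                            seq_len(length(idx) / 2L)))
  }
  geno <- geno[, hap_order, drop = FALSE]
  labels <- labels[hap_order]; pop_of <- pop_of[hap_order]
  hap_ids <- paste0(rep(sample_ids, each = 2L), c("_a", "_b"))
  colnames(geno) <- hap_ids
  pidx <- match(pop_of, pops$population)
  meta <- data.frame(hap_id = hap_ids,
                     sample_id = rep(sample_ids, each = 2L),
                     population = pop_of, species = pops$species[pidx],
                     year = pops$year[pidx], stringsAsFactors = FALSE)
  haps <- haplotype_matrix(geno, sites, meta)
  truth <- data.frame(hap_id = hap_ids, group = labels,
                      stringsAsFactors = FALSE)
  focal_sites <- data.frame(
    kind = c(rep("focal", length(focal_pos)),
             rep("secondary", length(sec_pos)),
             rep("conversion", length(conv_pos))),
    name = c(names(focal), sprintf("sec%d", seq_along(sec_pos)),
             sprintf("conv%d", seq_along(conv_pos))),
    pos = c(focal_pos, sec_pos, conv_pos),
    alt = c(focal_alt, sec_alt, all_alt[match(conv_pos, all_pos)]),
    stringsAsFactors = FALSE)
  sec_carriers <- lapply(sec_carriers, function(ix)
    hap_ids[match(ix, hap_order)])

  out <- structure(
    list(haps = haps, truth = truth, model = model, reference = reference,
         focal_sites = focal_sites, secondary_carriers = sec_carriers,
         config = cfg, files = NULL),
    class = "sweep_cohort")
  if (!is.null(dir)) out$files <- write_cohort(out, dir)
  out
}

#' Write a synthetic cohort to standard files
#'
#' @param cohort A `sweep_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  paths <- c(reference = file.path(dir, "reference.fa"),
             gff = file.path(dir, "genes.gff3"),
             vcf = file.path(dir, "cohort.vcf"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  seq <- Biostrings::DNAStringSet(cohort$reference)
  names(seq) <- cfg$chrom
  Biostrings::writeXStringSet(seq, paths[["reference"]], width = 80L)
  widths <- cfg$exons$end - cfg$exons$start + 1L
  before <- c(0L, cumsum(widths)[-length(widths)])
  phase <- (3L - before %% 3L) %% 3L
  gff <- c("##gff-version 3",
           sprintf("%s\tkdrhap\tgene\t%d\t%d\t.\t+\t.\tID=SIM1",
                   cfg$chrom, cfg$gene_start, cfg$gene_end),
           sprintf("%s\tkdrhap\tmRNA\t%d\t%d\t.\t+\t.\tID=SIM1-RA;Parent=SIM1",
                   cfg$chrom, cfg$gene_start, cfg$gene_end),
           sprintf("%s\tkdrhap\tCDS\t%d\t%d\t.\t+\t%d\tID=cds%d;Parent=SIM1-RA",
                   cfg$chrom, cfg$exons$start, cfg$exons$end,
                   phase, seq_len(nrow(cfg$exons))))
  writeLines(gff, paths[["gff"]])
  write_phased_vcf(cohort$haps, paths[["vcf"]])
  samples <- unique(cohort$haps$meta[, c("sample_id", "population",
                                         "species", "year")])
  utils::write.table(samples, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(config_to_json(cfg), paths[["config"]])
  paths
}

#' Write a haplotype matrix as a phased VCF
#'
#' @param haps A `haplotype_matrix` (haplotype columns in sample pairs).
#' @param path Output path.
#' @export
write_phased_vcf <- function(haps, path) {
  n_s <- ncol(haps$geno) / 2L
  samples <- haps$meta$sample_id[seq(1L, by = 2L, length.out = n_s)]
  a <- haps$geno[, seq(1L, by = 2L, length.out = n_s), drop = FALSE]
  b <- haps$geno[, seq(2L, by = 2L, length.out = n_s), drop = FALSE]
  gt <- matrix(paste0(a, "|", b), nrow = nrow(a))
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", haps$sites$chrom[1L], ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(haps$sites$chrom, haps$sites$pos, ".", haps$sites$ref,
                haps$sites$alts, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Serialize / restore a simulation config as JSON
#'
#' @param cfg A `sweep_sim_config`.
#' @return JSON string.
#' @export
config_to_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' @rdname config_to_json
#' @param json JSON string or path to a JSON file.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  conv <- x$conversion
  if (!is.null(conv)) conv$tract <- as.integer(conv$tract)
  sweep_sim_config(
    region_length = x$region_length, chrom = x$chrom,
    gene_start = x$gene_start, gene_end = x$gene_end,
    exons = as.data.frame(x$exons),
    populations = as.data.frame(x$populations),
    n_founders = x$n_founders, switch_rate = x$switch_rate, theta = x$theta,
    sweep_groups = as.data.frame(x$sweep_groups),
    secondary = if (is.null(x$secondary)) NULL else as.data.frame(x$secondary),
    conversion = conv, seed = x$seed)
}

#' Focal-allele carrier masks of a synthetic cohort
#'
#' Logical carrier vectors for the two kdr-like focal classes and the
#' combined private-allele class, in the form expected by
#' [hierarchical_groups()], [network_groups()] and
#' [define_core_haplotypes()].
#'
#' @param cohort A `sweep_cohort`.
#' @return Named list `F`, `S`, `L` of logical vectors (one per haplotype).
#' @export
focal_carrier_masks <- function(cohort) {
  fs <- cohort$focal_sites[cohort$focal_sites$kind == "focal", ]
  site_of <- match(fs$pos, cohort$haps$sites$pos)
  masks <- lapply(seq_len(nrow(fs)), function(i) {
    if (is.na(site_of[i])) rep(FALSE, ncol(cohort$haps$geno))
    else cohort$haps$geno[site_of[i], ] == 1L
  })
  names(masks) <- fs$name
  out <- masks[intersect(c("F", "S"), names(masks))]
  lm <- masks[startsWith(names(masks), "L")]
  if (length(lm)) out$L <- Reduce(`|`, lm)
  out
}

#' Check byte-identical regeneration of a cohort
#'
#' Generates the cohort twice from the same config (same seed) into
#' temporary directories and compares the VCF and TSV outputs byte for
#' byte.
#'
#' @param cfg A `sweep_sim_config`.
#' @return TRUE when all outputs are identical.
#' @export
regenerate_check <- function(cfg) {
  d1 <- tempfile("cohortA"); d2 <- tempfile("cohortB")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  f1 <- generate_cohort(cfg, d1)$files
  f2 <- generate_cohort(cfg, d2)$files
  comp <- c("vcf", "metadata", "truth")
  all(vapply(comp, function(k)
    identical(readLines(f1[[k]]), readLines(f2[[k]])), logical(1)))
}
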