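#' Pipeline configuration
#'
#' Bundles inputs (either file paths or a simulation config), stage
#' toggles, and the analysis parameters of every stage. All randomness is
#' driven by explicit seeds recorded in the manifest.
#'
#' @param sim A [sweep_sim_config()], or NULL to read files.
#' @param vcf,gff,fasta,metadata Input paths (ignored when `sim` given).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, a subset of the
#'   default.
#' @param gene_interval `c(start, end)` of the focal gene; defaults to the
#'   simulated gene when `sim` is given.
#' @param core `c(start, end_exclusive)` core region; defaults to a 6 kb
#'   region centred on the simulated focal sites.
#' @param freq_threshold Allele-frequency filter threshold.
#' @param cut_height,min_group_size Clustering parameters.
#' @param max_edge_dist Network edge-pruning distance.
#' @param map_rate Genetic-map rate, cM/Mb.
#' @param k_folds,max_depth,cv_repeats Assay-design parameters.
#' @param het_reps Monte-Carlo replicates for the heterozygote-excess test.
#' @param seed Master seed for stage-level randomness.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, vcf = NULL, gff = NULL, fasta = NULL,
                            metadata = NULL, out_dir = "kdrhap_out",
                            stages = c("annotate", "freqs", "ld", "groups",
                                       "scan", "hetexcess", "panel"),
                            gene_interval = NULL, core = NULL,
                            freq_threshold = 0.05, cut_height = 4,
                            min_group_size = 3L, max_edge_dist = 2L,
                            map_rate = 1.0, k_folds = 5L, max_depth = 8L,
                            cv_repeats = 10L, het_reps = 1e6, seed = 1L) {
  if (is.null(sim) && (is.null(vcf) || is.null(gff) || is.null(fasta) ||
                       is.null(metadata)))
    stop("pipeline_config: provide either `sim` or all input paths")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order — codon-effect annotation, allele
#' frequencies and filtering, D' between filtered missense alleles,
#' haplotype grouping by clustering and median-joining network (with
#' concordance), selection scans (core haplotypes, EHH, moving-window
#' homozygosity, shared lengths), the heterozygote-excess test for
#' populations where both kdr-like alleles segregate, and the SNP-panel
#' assay design — writing per-stage TSV/JSON outputs plus a manifest with
#' parameters, seeds and md5 checksums. Reruns with the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    outputs[[length(outputs) + 1L]] <<- p
    p
  }

  if (!is.null(config$sim)) {
    cohort <- generate_cohort(config$sim, dir = file.path(config$out_dir,
                                                          "cohort"))
    outputs <- c(outputs, unname(cohort$files))
    haps <- cohort$haps
    model <- cohort$model
    reference <- cohort$reference
    focal <- focal_carrier_masks(cohort)
    gene_interval <- config$gene_interval
    if (is.null(gene_interval))
      gene_interval <- c(config$sim$gene_start, config$sim$gene_end)
    core_bounds <- config$core
    if (is.null(core_bounds)) {
      fpos <- cohort$focal_sites$pos[cohort$focal_sites$kind == "focal"]
      mid <- round(mean(range(fpos[1:2])))
      core_bounds <- c(mid - 3000L, mid + 3078L)
    }
  } else {
    haps <- read_phased_vcf(config$vcf, config$metadata)
    models <- read_gene_models(config$gff)
    model <- models[[1L]]
    reference <- read_reference(config$fasta)[[model$chrom]]
    gene_interval <- config$gene_interval
    core_bounds <- config$core
    if (is.null(gene_interval) || is.null(core_bounds))
      stop("run_pipeline: gene_interval and core required for file inputs")
    focal <- NULL
  }
  core <- core_region(core_bounds[1L], core_bounds[2L])

  effects <- annotate_all_sites(haps, model, reference)
  if ("annotate" %in% config$stages)
    write_annotation_tsv(effects, emit("annotation.tsv"))

  freqs <- allele_frequencies(haps)
  kept <- filter_by_max_frequency(freqs, config$freq_threshold)
  if ("freqs" %in% config$stages) {
    write_frequency_tsv(freqs, emit("allele_frequencies.tsv"))
    write_frequency_tsv(kept, emit("alleles_filtered.tsv"))
  }

  if ("ld" %in% config$stages) {
    ns_kept <- kept[kept$site_index %in%
                    effects$site_index[effects$effect_class == "missense"], ]
    if (nrow(ns_kept) >= 2L) {
      dp <- dprime_matrix(haps, ns_kept)
      utils::write.table(round(dp, 4), emit("dprime.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
    }
  }

  labels_hc <- labels_net <- NULL
  if ("groups" %in% config$stages && !is.null(focal)) {
    d <- pairwise_hamming(haps, window = gene_interval)
    labels_hc <- hierarchical_groups(d, focal,
                                     cut_height = config$cut_height,
                                     min_group_size = config$min_group_size)
    net <- median_joining_network(haps, window = gene_interval,
                                  max_edge_dist = config$max_edge_dist)
    net <- annotate_nonsynonymous_edges(net, effects)
    labels_net <- network_groups(net, focal, config$min_group_size)
    conc <- concordance(labels_hc, labels_net)
    write_network_dot(net, emit("network.dot"))
    grp <- population_group_table(labels_net, haps$meta$population)
    utils::write.table(grp$counts, emit("group_counts.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    writeLines(jsonlite::toJSON(list(
      concordance = as.numeric(conc),
      n_groups_hc = length(unique(labels_hc)),
      n_groups_net = length(unique(labels_net))), auto_unbox = TRUE),
      emit("grouping.json"))
  }

  if ("scan" %in% config$stages && !is.null(focal)) {
    cs <- define_core_haplotypes(haps, core, focal_alleles = focal)
    curves <- list()
    for (cid in cs$cores$core_id[cs$cores$count >= 2L]) {
      for (dir in c("upstream", "downstream")) {
        e <- ehh_decay(haps, cs, cid, dir, effects)
        curves[[length(curves) + 1L]] <- data.frame(
          core_id = cid, label = cs$cores$label[cid], direction = dir, e)
      }
    }
    utils::write.table(do.call(rbind, curves), emit("ehh.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    win <- tile_windows(min(haps$sites$pos), max(haps$sites$pos), 20000L)
    wh <- window_homozygosity(haps, win, seq_len(n_haplotypes(haps)))
    utils::write.table(wh, emit("window_homozygosity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    map <- genetic_map(config$map_rate)
    shared <- list()
    for (cid in cs$cores$core_id[cs$cores$count >= 2L &
                                 cs$cores$label != "wt"]) {
      res <- shared_haplotype_lengths(
        haps, which(cs$assignment == cid), core, map, effects,
        seed = config$seed, label = cs$cores$label[cid])
      shared[[length(shared) + 1L]] <- list(
        label = res$label, median_cM = res$median_cM, ci = res$ci,
        n_pairs = length(res$lengths_cM), censored = sum(res$censored))
    }
    writeLines(jsonlite::toJSON(shared, auto_unbox = TRUE, digits = NA),
               emit("shared_lengths.json"))
  }

  if ("hetexcess" %in% config$stages && !is.null(focal)) {
    het <- list()
    for (p in unique(haps$meta$population)) {
      sel <- haps$meta$population == p
      cF <- sum(focal$F[sel]); cS <- sum(focal$S[sel])
      if (cF == 0L || cS == 0L) next
      n <- sum(sel) / 2L
      sidx <- which(sel)
      a <- sidx[seq(1L, length(sidx), by = 2L)]
      b <- sidx[seq(2L, length(sidx), by = 2L)]
      obs <- sum((focal$F[a] & focal$S[b]) | (focal$S[a] & focal$F[b]))
      r <- het_excess_test(cF, cS, 2L * n - cF - cS, n, obs,
                           reps = config$het_reps, seed = config$seed)
      het[[p]] <- list(c_F = cF, c_S = cS, n = n, observed_het = obs,
                       p_value = r$p_value, reps = r$reps, seed = r$seed)
    }
    writeLines(jsonlite::toJSON(het, auto_unbox = TRUE, digits = NA),
               emit("het_excess.json"))
  }

  if ("panel" %in% config$stages && !is.null(focal) &&
      !is.null(labels_net)) {
    panel <- group_frequency_table(haps, labels_net, gene_interval)
    utils::write.table(panel, emit("panel_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    X <- feature_matrix(haps, gene_interval)
    cv <- stratified_cv_accuracy(X, labels_net, max_depth = config$max_depth,
                                 k_folds = config$k_folds,
                                 repeats = config$cv_repeats,
                                 seed = config$seed)
    utils::write.table(cv, emit("cv_accuracy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("kdrhap")),
    stages = config$stages, seed = config$seed,
    parameters = list(freq_threshold = config$freq_threshold,
                      cut_height = config$cut_height,
                      max_edge_dist = config$max_edge_dist,
                      core = core_bounds, gene_interval = gene_interval,
                      map_rate = config$map_rate, k_folds = config$k_folds,
                      max_depth = config$max_depth),
    outputs = data.frame(path = unlist(outputs),
                         md5 = unname(tools::md5sum(unlist(outputs)))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
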