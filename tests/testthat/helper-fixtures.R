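# toy haplotype matrix from a plain sites x haplotypes 0/1 matrix
toy_haps <- function(g, pos = seq_len(nrow(g)), pop = "p") {
  g <- as.matrix(g)
  n <- ncol(g)
  pop <- rep_len(pop, n)
  haplotype_matrix(
    g,
    data.frame(chrom = "chr", pos = pos, ref = "A", alts = "T",
               stringsAsFactors = FALSE),
    data.frame(hap_id = paste0("h", seq_len(n)),
               sample_id = paste0("s", ceiling(seq_len(n) / 2)),
               population = pop, species = "sp", year = 2000,
               stringsAsFactors = FALSE))
}

# reference string with a CDS spliced in at a given offset
toy_reference <- function(cds, offset = 100L, total = 400L) {
  pre <- strrep("A", offset)
  post <- strrep("A", max(total - offset - nchar(cds), 0L))
  paste0(pre, cds, post)
}

# small two-population simulation config for fast tests
small_sim_config <- function(seed, gr = 2e-6, n_groups = 3L,
                             new_mut_rate = 0.5, theta = 0.004) {
  groups <- data.frame(
    name = c("F1", "S1", "F2")[seq_len(n_groups)],
    focal_id = c("F", "S", "F")[seq_len(n_groups)],
    near_pos = c(56500L, 56520L, 56540L)[seq_len(n_groups)],
    gr = rep_len(gr, n_groups),
    new_mut_rate = rep_len(new_mut_rate, n_groups),
    p1 = c(10L, 8L, 0L)[seq_len(n_groups)],
    p2 = c(6L, 4L, 8L)[seq_len(n_groups)])
  sweep_sim_config(
    region_length = 120000L, gene_start = 50001L, gene_end = 70000L,
    exons = data.frame(start = c(50001L, 56001L, 62001L),
                       end = c(51500L, 57800L, 63701L)),
    populations = data.frame(
      population = c("p1", "p2"), species = c("gambiae", "coluzzii"),
      year = c(2009L, 2011L), n_haplotypes = c(40L, 40L)),
    n_founders = 12L, theta = theta, switch_rate = 1e-5,
    sweep_groups = groups, secondary = NULL, conversion = NULL,
    seed = seed)
}

# brute-force pairwise Hamming oracle
hamming_oracle <- function(g) {
  n <- ncol(g)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(g[, i] != g[, j])
  d
}

# brute-force EHH oracle: explicit prefix-string partitions over the
# included sites, walking away from the core
ehh_oracle <- function(geno_flank, carriers) {
  n <- length(carriers)
  denom <- choose(n, 2)
  prefix <- rep("", n)
  vapply(seq_len(nrow(geno_flank)), function(k) {
    prefix <<- paste(prefix, geno_flank[k, carriers])
    cnt <- table(prefix)
    sum(choose(cnt, 2)) / denom
  }, numeric(1))
}
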