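test_that("codon effects are annotated correctly on the plus strand", {
  ref <- toy_reference("ATGCTTTAA", offset = 100L)
  m <- gene_model("tx1", "chr", "+", data.frame(start = 101, end = 109))
  eff <- annotate_codon_effect(variant_site("chr", 104, "C", "T"), 1L, m, ref)
  expect_equal(eff$codon_number, 2L)
  expect_equal(eff$aa_change, "L2F")
  expect_equal(eff$effect_class, "missense")

  eff <- annotate_codon_effect(variant_site("chr", 106, "T", "G"), 1L, m, ref)
  expect_equal(eff$aa_change, "L2L")
  expect_equal(eff$effect_class, "synonymous")
})

test_that("minus-strand annotation reverse-complements alleles and codons", {
  # plus-strand TTACATCAT at 201-209; CDS reads ATGATGTAA
  ref <- paste0(strrep("A", 200), "TTACATCAT", strrep("A", 100))
  m <- gene_model("tx2", "chr", "-", data.frame(start = 201, end = 209))
  eff <- annotate_codon_effect(variant_site("chr", 205, "A", "G"), 1L, m, ref)
  expect_equal(eff$codon_number, 2L)
  expect_equal(eff$aa_change, "M2T")
  expect_equal(eff$effect_class, "missense")
})

test_that("positions outside the CDS are non-coding; errors are raised", {
  ref <- toy_reference("ATGCTTTAA", offset = 100L)
  m <- gene_model("tx1", "chr", "+", data.frame(start = 101, end = 109))
  eff <- annotate_codon_effect(variant_site("chr", 50, "A", "G"), 1L, m, ref)
  expect_equal(eff$effect_class, "non-coding")
  expect_true(is.na(eff$codon_number))
  expect_error(
    annotate_codon_effect(variant_site("chr", 104, "G", "T"), 1L, m, ref),
    "reference mismatch")
  expect_error(gene_model("bad", "chr", "+", data.frame(start = 1, end = 10)),
               "divisible by 3")
  expect_error(gene_model("bad", "chr", "+",
                          data.frame(start = c(1, 5), end = c(6, 10))),
               "overlap")
})

test_that("nonsense changes are classed separately from missense", {
  # TGG (Trp) -> TGA (stop) via G>A at codon position 3
  ref <- toy_reference("ATGTGGTAA", offset = 100L)
  m <- gene_model("tx1", "chr", "+", data.frame(start = 101, end = 109))
  eff <- annotate_codon_effect(variant_site("chr", 106, "G", "A"), 1L, m, ref)
  expect_equal(eff$effect_class, "nonsense")
})

test_that("every third-position change in a 4-fold degenerate codon is synonymous", {
  # exhaustive over the 4-fold codon families of the standard code
  four_fold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  bases <- c("A", "C", "G", "T")
  for (stem in four_fold) {
    for (third in bases) {
      cds <- paste0("ATG", stem, third, "TAA")
      ref <- toy_reference(cds, offset = 100L)
      m <- gene_model("tx", "chr", "+", data.frame(start = 101, end = 109))
      for (alt in setdiff(bases, third)) {
        eff <- annotate_codon_effect(
          variant_site("chr", 106, third, alt), 1L, m, ref)
        expect_equal(eff$effect_class, "synonymous")
      }
    }
  }
})

test_that("strand symmetry: minus-strand model equals reverse-complemented construction", {
  set.seed(31)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:10) {
    # random stop-free CDS of 4 codons on the minus strand
    codons <- replicate(4, paste(sample(c("A", "C", "G", "T"), 3,
                                        replace = TRUE), collapse = ""))
    codons[codons %in% c("TAA", "TAG", "TGA")] <- "ATG"
    cds <- paste(codons, collapse = "")
    rc <- paste(rev(comp[strsplit(cds, "")[[1]]]), collapse = "")
    ref_minus <- toy_reference(rc, offset = 50L, total = 200L)
    m_minus <- gene_model("tx", "chr", "-", data.frame(start = 51, end = 62))
    ref_plus <- toy_reference(cds, offset = 50L, total = 200L)
    m_plus <- gene_model("tx", "chr", "+", data.frame(start = 51, end = 62))
    p_minus <- sample(51:62, 1)
    cds_i <- 62 - p_minus + 1     # position within the CDS frame
    p_plus <- 50 + cds_i
    ref_base_minus <- substr(ref_minus, p_minus, p_minus)
    alt_minus <- sample(setdiff(c("A", "C", "G", "T"), ref_base_minus), 1)
    e1 <- annotate_codon_effect(
      variant_site("chr", p_minus, ref_base_minus, alt_minus), 1L,
      m_minus, ref_minus)
    e2 <- annotate_codon_effect(
      variant_site("chr", p_plus, comp[[ref_base_minus]],
                   comp[[alt_minus]]), 1L, m_plus, ref_plus)
    expect_equal(e1$aa_change, e2$aa_change)
    expect_equal(e1$effect_class, e2$effect_class)
  }
})

test_that("effects across transcripts flag discordant classifications", {
  ref <- toy_reference("ATGCTTTAA", offset = 100L)
  m1 <- gene_model("tx1", "chr", "+", data.frame(start = 101, end = 109))
  v <- variant_site("chr", 104, "C", "T")
  single <- effects_across_transcripts(v, 1L, list(m1), ref)
  expect_equal(nrow(single), 1L)
  expect_false(single$discordant)
  expect_equal(single$aa_change, annotate_codon_effect(v, 1L, m1, ref)$aa_change)

  m2 <- gene_model("tx2", "chr", "+", data.frame(start = 101, end = 109))
  both <- effects_across_transcripts(v, 1L, list(m1, m2), ref)
  expect_false(any(both$discordant))

  # transcript lacking the exon containing the SNP: non-coding there
  ref3 <- paste0(toy_reference("ATGCTTTAA", offset = 100L, total = 150L),
                 "ATGTAA", strrep("A", 50))
  m3 <- gene_model("tx3", "chr", "+", data.frame(start = 151, end = 156))
  disc <- effects_across_transcripts(v, 1L, list(m1, m3), ref3)
  expect_equal(disc$effect_class, c("missense", "non-coding"))
  expect_true(all(disc$discordant))
})

test_that("codon maps from global protein alignment handle gaps", {
  cm <- build_codon_map("MKLVVF", "MKLAVVF")
  expect_equal(cm$pairs$a, 1:6)
  expect_equal(cm$pairs$b, c(1:3, 5:7))
  expect_equal(cm$unmapped_b, 4L)
  expect_equal(length(cm$unmapped_a), 0L)
  expect_equal(map_codon(cm, 4L), 5L)
  expect_error(build_codon_map("MK1", "MK"), "non-amino-acid")
  expect_error(build_codon_map("", "MK"), "empty")
})

test_that("aligning a protein to itself yields the identity map", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:5) {
    p <- paste(sample(aas, sample(10:40, 1), replace = TRUE), collapse = "")
    cm <- build_codon_map(p, p)
    expect_equal(cm$pairs$a, seq_len(nchar(p)))
    expect_equal(cm$pairs$b, seq_len(nchar(p)))
    expect_equal(length(cm$unmapped_a) + length(cm$unmapped_b), 0L)
  }
})

test_that("cohort files round-trip through the GFF3/FASTA/VCF readers", {
  cfg <- small_sim_config(seed = 402L)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cfg, dir = dir)
  models <- read_gene_models(coh$files[["gff"]])
  expect_named(models, "SIM1-RA")
  expect_equal(models[["SIM1-RA"]]$cds_exons, coh$model$cds_exons)
  ref <- read_reference(coh$files[["reference"]])
  expect_equal(unname(nchar(ref[cfg$chrom])), cfg$region_length)
  expect_equal(ref[[cfg$chrom]], coh$reference)
  haps <- read_phased_vcf(coh$files[["vcf"]], coh$files[["metadata"]])
  expect_equal(unname(haps$geno), unname(coh$haps$geno))
  expect_equal(haps$sites$pos, coh$haps$sites$pos)
  expect_equal(haps$meta$population, coh$haps$meta$population)
})

test_that("unphased genotypes are rejected", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"), vcf)
  writeLines(c("sample_id\tpopulation\tspecies\tyear",
               "s1\tp\tsp\t2000"), meta)
  expect_error(read_phased_vcf(vcf, meta), "unphased")
})
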