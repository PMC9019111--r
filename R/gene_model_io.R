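#' Construct a gene model
#'
#' A gene model holds the coding structure of one transcript: an ordered set
#' of CDS exons on one strand of one chromosome. It provides the codon
#' numbering frame against which SNP effects are annotated.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons Two-column matrix or data.frame of (start, end) pairs in
#'   1-based inclusive genomic coordinates, non-overlapping.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(transcript_id, chrom, strand, cds_exons) {
  stopifnot(strand %in% c("+", "-"))
  ex <- as.data.frame(cds_exons)
  names(ex)[1:2] <- c("start", "end")
  ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  if (any(ex$end < ex$start))
    stop("gene_model: exon end < start")
  if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
    stop("gene_model: exons overlap")
  len <- sum(ex$end - ex$start + 1)
  if (len %% 3L != 0L)
    stop("gene_model: total CDS length (", len, ") not divisible by 3")
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         cds_exons = ex, cds_length = len),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$transcript_id, "on", x$chrom, x$strand, "strand;",
      nrow(x$cds_exons), "CDS exons,", x$cds_length, "bp (",
      x$cds_length / 3L, "codons )\n")
  invisible(x)
}

#' Construct a variant site
#'
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position.
#' @param ref Reference nucleotide.
#' @param alts Character vector of one or more alternate nucleotides.
#' @return An object of class `variant_site`.
#' @export
variant_site <- function(chrom, pos, ref, alts) {
  ref <- toupper(ref); alts <- toupper(alts)
  if (any(alts == ref)) stop("variant_site: alt equal to ref")
  if (anyDuplicated(alts)) stop("variant_site: duplicated alts")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alts = alts),
            class = "variant_site")
}

# genomic position -> 1-based CDS coordinate (NA outside CDS), honouring
# strand: CDS coordinate 1 is the first coding base in transcription order.
.cds_coord <- function(pos, model) {
  ex <- model$cds_exons
  widths <- ex$end - ex$start + 1L
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    before + (pos - ex$start[hit] + 1L)
  } else {
    n <- nrow(ex)
    after <- if (hit < n) sum(widths[seq(hit + 1L, n)]) else 0L
    after + (ex$end[hit] - pos + 1L)
  }
}

# CDS coordinate -> genomic position (inverse of .cds_coord)
.genomic_coord <- function(cds_pos, model) {
  ex <- model$cds_exons
  widths <- ex$end - ex$start + 1L
  if (model$strand == "+") {
    cum <- cumsum(widths)
    hit <- which(cds_pos <= cum)[1L]
    before <- if (hit > 1L) cum[hit - 1L] else 0L
    ex$start[hit] + (cds_pos - before - 1L)
  } else {
    cum <- cumsum(rev(widths))
    hit_rev <- which(cds_pos <= cum)[1L]
    before <- if (hit_rev > 1L) cum[hit_rev - 1L] else 0L
    hit <- nrow(ex) - hit_rev + 1L
    ex$end[hit] - (cds_pos - before - 1L)
  }
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate the codon effect of a single-nucleotide substitution
#'
#' Maps a SNP onto the coding frame of a transcript and reports the codon
#' number, reference and alternate amino acids, and the effect class
#' (synonymous / missense / nonsense). Positions outside the CDS return an
#' effect of class `"non-coding"`. Minus-strand transcripts are handled by
#' complementing the alleles and reading codons in transcription order.
#'
#' @param variant A [variant_site()].
#' @param alt_index Which alternate allele to annotate (default 1).
#' @param model A [gene_model()].
#' @param reference Character string (or `DNAString`) with the plus-strand
#'   chromosome sequence covering all exons; position `i` of the string is
#'   genomic position `i`.
#' @return A one-row data.frame with columns `transcript_id`, `codon_number`,
#'   `ref_aa`, `alt_aa`, `aa_change`, `effect_class`. Non-coding positions
#'   have `effect_class == "non-coding"` and `NA` codon fields.
#' @export
annotate_codon_effect <- function(variant, alt_index = 1L, model, reference) {
  reference <- toupper(as.character(reference))
  alt <- variant$alts[alt_index]
  ref_base <- substr(reference, variant$pos, variant$pos)
  if (ref_base != variant$ref)
    stop("reference mismatch at ", variant$chrom, ":", variant$pos,
         ": reference has ", ref_base, ", variant.ref is ", variant$ref)
  cds_pos <- .cds_coord(variant$pos, model)
  if (is.na(cds_pos)) {
    return(data.frame(transcript_id = model$transcript_id,
                      codon_number = NA_integer_, ref_aa = NA_character_,
                      alt_aa = NA_character_, aa_change = NA_character_,
                      effect_class = "non-coding",
                      stringsAsFactors = FALSE))
  }
  codon_number <- (cds_pos - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
  codon_bases <- vapply((codon_number - 1L) * 3L + 1:3, function(cp) {
    gp <- .genomic_coord(cp, model)
    b <- substr(reference, gp, gp)
    if (model$strand == "-") .COMPLEMENT[[b]] else b
  }, character(1))
  ref_codon <- paste(codon_bases, collapse = "")
  alt_strand <- if (model$strand == "-") .COMPLEMENT[[alt]] else alt
  alt_bases <- codon_bases
  alt_bases[pos_in_codon] <- alt_strand
  alt_codon <- paste(alt_bases, collapse = "")
  ref_aa <- .translate_codon(ref_codon)
  alt_aa <- .translate_codon(alt_codon)
  effect_class <-
    if (alt_aa == "*" && ref_aa != "*") "nonsense"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  data.frame(transcript_id = model$transcript_id,
             codon_number = codon_number, ref_aa = ref_aa, alt_aa = alt_aa,
             aa_change = paste0(ref_aa, codon_number, alt_aa),
             effect_class = effect_class, stringsAsFactors = FALSE)
}

#' Annotate a variant against several transcripts
#'
#' Runs [annotate_codon_effect()] for each supplied gene model and flags
#' variants whose effect class differs between transcripts (e.g. synonymous
#' in the analysis transcript but missense in an alternative one).
#'
#' @inheritParams annotate_codon_effect
#' @param models List of [gene_model()] objects.
#' @return A data.frame with one row per transcript and a logical
#'   `discordant` column (identical across rows).
#' @export
effects_across_transcripts <- function(variant, alt_index = 1L, models,
                                       reference) {
  stopifnot(length(models) >= 1L)
  rows <- lapply(models, function(m)
    annotate_codon_effect(variant, alt_index, m, reference))
  out <- do.call(rbind, rows)
  out$discordant <- length(unique(out$effect_class)) > 1L
  rownames(out) <- NULL
  out
}

#' Map codon numbers between two species by global protein alignment
#'
#' Aligns two protein sequences end-to-end (Needleman-Wunsch with a BLOSUM62
#' matrix and affine gap penalties, as provided by
#' `Biostrings::pairwiseAlignment`) and reads off equivalent codon numbers
#' from the aligned columns, e.g. to convert An. gambiae VGSC codon numbers
#' to the Musca domestica numbering used in the resistance literature.
#'
#' @param protein_a,protein_b Amino-acid sequences (character strings).
#' @param substitution_matrix Name of the scoring matrix (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return A list of class `codon_map` with `pairs` (data.frame `a`, `b` of
#'   aligned codon numbers, strictly increasing in both), `unmapped_a` and
#'   `unmapped_b` (codon numbers falling in gaps).
#' @export
build_codon_map <- function(protein_a, protein_b,
                            substitution_matrix = "BLOSUM62",
                            gap_opening = 10, gap_extension = 1) {
  protein_a <- toupper(protein_a); protein_b <- toupper(protein_b)
  if (nchar(protein_a) == 0L || nchar(protein_b) == 0L)
    stop("build_codon_map: empty sequence")
  ok <- "^[ACDEFGHIKLMNPQRSTVWY*]+$"
  if (!grepl(ok, protein_a) || !grepl(ok, protein_b))
    stop("build_codon_map: non-amino-acid symbols in input")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  a_idx <- integer(0); b_idx <- integer(0)
  gap_a <- integer(0); gap_b <- integer(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      a_idx <- c(a_idx, ia); b_idx <- c(b_idx, ib)
    } else if (pa[k] != "-") {
      gap_a <- c(gap_a, ia)
    } else {
      gap_b <- c(gap_b, ib)
    }
  }
  structure(list(pairs = data.frame(a = a_idx, b = b_idx),
                 unmapped_a = gap_a, unmapped_b = gap_b,
                 score = Biostrings::score(aln)),
            class = "codon_map")
}

#' Look up the codon number of species B equivalent to a species-A codon
#'
#' @param map A `codon_map` from [build_codon_map()].
#' @param codon_a Codon number(s) in species A.
#' @return Integer vector of species-B codon numbers (`NA` where unmapped).
#' @export
map_codon <- function(map, codon_a) {
  map$pairs$b[match(codon_a, map$pairs$a)]
}

#' Read CDS features for one or more transcripts from a GFF3 file
#'
#' Parses `CDS` lines and groups them into [gene_model()] objects by the
#' `Parent` (fallback `ID`) attribute.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, 1L) == 9L]
  cds <- Filter(function(f) f[3] == "CDS", fields)
  if (length(cds) == 0L) stop("read_gene_models: no CDS features in ", path)
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))[[1]]
    if (length(m) == 0L) NA_character_ else m[3]
  }
  df <- do.call(rbind, lapply(cds, function(f) {
    tid <- attr_val(f[9], "Parent")
    if (is.na(tid)) tid <- attr_val(f[9], "ID")
    data.frame(chrom = f[1], start = as.integer(f[4]), end = as.integer(f[5]),
               strand = f[7], transcript = tid, stringsAsFactors = FALSE)
  }))
  models <- lapply(split(df, df$transcript), function(d)
    gene_model(d$transcript[1], d$chrom[1], d$strand[1],
               d[, c("start", "end")]))
  models
}

#' Read a reference sequence from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read phased haplotypes from a VCF and a sample metadata table
#'
#' Requires every genotype to be phased (`|` separator); unphased or missing
#' genotypes are an error, since all downstream statistics operate on
#' haplotypes. Each diploid sample contributes two haplotype columns,
#' `<sample>_a` and `<sample>_b`.
#'
#' @param vcf_path Path to a VCF file with a GT field.
#' @param meta_path Path to a TSV with columns `sample_id`, `population`,
#'   `species`, `year`.
#' @return A `haplotype_matrix`: list with `geno` (integer matrix, sites x
#'   haplotypes, 0 = ref), `sites` (data.frame `chrom`, `pos`, `ref`, `alts`
#'   comma-separated, `n_alleles`), and `meta` (one row per haplotype:
#'   `hap_id`, `sample_id`, `population`, `species`, `year`).
#' @export
read_phased_vcf <- function(vcf_path, meta_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(is.na(gt)) || any(grepl("/", gt, fixed = TRUE)))
    stop("read_phased_vcf: unphased or missing genotypes; ",
         "phased GT ('|' separator) is required")
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alts = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  sites$n_alleles <- 1L + vapply(strsplit(sites$alts, ","), length, 1L)
  a <- sub("\\|.*$", "", gt)
  b <- sub("^.*\\|", "", gt)
  geno <- cbind(matrix(as.integer(a), nrow = nrow(gt)),
                matrix(as.integer(b), nrow = nrow(gt)))
  samples <- colnames(gt)
  colnames(geno) <- c(paste0(samples, "_a"), paste0(samples, "_b"))
  ord <- order(rep(seq_along(samples), 2L), rep(1:2, each = length(samples)))
  geno <- geno[, ord, drop = FALSE]
  meta_tbl <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "population", "species", "year")
  if (!all(needed %in% names(meta_tbl)))
    stop("metadata must have columns ", paste(needed, collapse = ", "))
  idx <- match(samples, meta_tbl$sample_id)
  if (any(is.na(idx)))
    stop("metadata missing samples: ",
         paste(samples[is.na(idx)], collapse = ", "))
  meta <- data.frame(
    hap_id = colnames(geno),
    sample_id = rep(samples, each = 2L),
    population = rep(meta_tbl$population[idx], each = 2L),
    species = rep(meta_tbl$species[idx], each = 2L),
    year = rep(meta_tbl$year[idx], each = 2L),
    stringsAsFactors = FALSE)
  haplotype_matrix(geno, sites, meta)
}

#' Construct a haplotype matrix
#'
#' @param geno Integer matrix, sites x haplotypes; 0 codes the reference
#'   allele, k >= 1 the k-th alternate.
#' @param sites Data.frame with `chrom`, `pos`, `ref`, `alts` (comma
#'   separated) and optionally `n_alleles`.
#' @param meta Data.frame with one row per haplotype column: `hap_id`,
#'   `sample_id`, `population`, `species`, `year`.
#' @return Object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(geno, sites, meta) {
  geno <- as.matrix(geno); storage.mode(geno) <- "integer"
  stopifnot(nrow(geno) == nrow(sites), ncol(geno) == nrow(meta))
  if (is.null(sites$n_alleles))
    sites$n_alleles <- 1L + vapply(strsplit(sites$alts, ","), length, 1L)
  if (any(geno >= sites$n_alleles))
    stop("haplotype_matrix: allele code exceeds number of alleles at a site")
  structure(list(geno = geno, sites = sites, meta = meta),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$geno), "sites x", ncol(x$geno),
      "haplotypes (", length(unique(x$meta$population)), "populations )\n")
  invisible(x)
}

#' Number of haplotypes
#' @param haps A `haplotype_matrix`.
#' @export
n_haplotypes <- function(haps) ncol(haps$geno)

#' Write a codon-effect annotation table as TSV
#'
#' One row per (site, alternate allele): chrom, pos, ref, alt, transcript,
#' codon, aa_change, effect_class.
#'
#' @param annotations Data.frame as produced by annotating each allele with
#'   [annotate_codon_effect()] plus `chrom`, `pos`, `ref`, `alt` columns.
#' @param path Output path.
#' @export
write_annotation_tsv <- function(annotations, path) {
  cols <- c("chrom", "pos", "ref", "alt", "transcript_id", "codon_number",
            "aa_change", "effect_class")
  utils::write.table(annotations[, intersect(cols, names(annotations))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate every alternate allele of every site in a haplotype matrix
#'
#' Decomposes multi-allelic sites into one record per (site, alt) pair and
#' annotates each against the gene model.
#'
#' @param haps A `haplotype_matrix`.
#' @param model A [gene_model()].
#' @param reference Plus-strand chromosome sequence.
#' @return Data.frame with one row per allele: `site_index`, `chrom`, `pos`,
#'   `ref`, `alt`, `alt_index` and the [annotate_codon_effect()] columns.
#' @export
annotate_all_sites <- function(haps, model, reference) {
  rows <- list()
  for (i in seq_len(nrow(haps$sites))) {
    s <- haps$sites[i, ]
    alts <- strsplit(s$alts, ",")[[1]]
    for (j in seq_along(alts)) {
      v <- variant_site(s$chrom, s$pos, s$ref, alts)
      eff <- annotate_codon_effect(v, j, model, reference)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(site_index = i, chrom = s$chrom, pos = s$pos,
                   ref = s$ref, alt = alts[j], alt_index = j,
                   stringsAsFactors = FALSE),
        eff)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
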