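.entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.gini <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Information gain of a binary SNP feature about group labels
#'
#' `IG = H(labels) - sum_v (n_v / n) H(labels | feature = v)` with entropies
#' in bits: how much knowing the SNP allele reduces uncertainty about which
#' haplotype group a haplotype belongs to.
#'
#' @param feature Binary (0/1) vector.
#' @param labels Label vector of the same length.
#' @return Information gain in bits (>= 0).
#' @export
information_gain <- function(feature, labels) {
  stopifnot(length(feature) == length(labels))
  h0 <- .entropy_bits(labels)
  cond <- 0
  for (v in unique(feature)) {
    sel <- feature == v
    cond <- cond + mean(sel) * .entropy_bits(labels[sel])
  }
  h0 - cond
}

# criterion gain of a split for build_tree
.split_gain <- function(feature, labels, criterion) {
  if (criterion == "information_gain") return(information_gain(feature, labels))
  sel <- feature == 1L
  .gini(labels) - mean(sel) * .gini(labels[sel]) -
    mean(!sel) * .gini(labels[!sel])
}

.majority <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]      # which.max takes the first = lowest label
}

#' Build a decision tree over binary SNP features
#'
#' Greedy top-down induction: at each node the SNP with the largest
#' criterion gain is chosen (information gain = ID3; Gini decrease = CART
#' restricted to binary features), ties broken by lowest SNP index; leaves
#' predict the majority class (ties to the alphabetically lowest label).
#' Growth stops on purity, `max_depth`, or when no split has positive gain.
#'
#' @param X Binary matrix, haplotypes x SNPs (column names = SNP ids).
#' @param labels Class label per haplotype.
#' @param criterion `"information_gain"` (default) or `"gini"`.
#' @param max_depth Maximum tree depth (root splits at depth 1).
#' @return Object of class `decision_tree` (nested list of nodes).
#' @export
build_tree <- function(X, labels,
                       criterion = c("information_gain", "gini"),
                       max_depth = 5L) {
  criterion <- match.arg(criterion)
  if (max_depth < 1L) stop("build_tree: max_depth must be >= 1")
  X <- as.matrix(X)
  labels <- as.character(labels)
  node_gains <- function(rows) {
    labs <- labels[rows]
    vapply(seq_len(ncol(X)), function(j) {
      f <- X[rows, j]
      if (length(unique(f)) < 2L) return(-Inf)
      .split_gain(f, labs, criterion)
    }, numeric(1))
  }
  grow <- function(rows, depth) {
    labs <- labels[rows]
    if (length(unique(labs)) == 1L || depth > max_depth)
      return(list(leaf = TRUE, class = .majority(labs), n = length(rows)))
    gains <- node_gains(rows)
    best <- which.max(gains)          # lowest index wins ties
    if (!is.finite(gains[best]))
      return(list(leaf = TRUE, class = .majority(labs), n = length(rows)))
    if (gains[best] <= 0) {
      # zero-gain splits are accepted only with one step of lookahead:
      # some feature must pay off in a child (e.g. XOR-patterned pairs);
      # otherwise the node becomes a majority leaf
      best <- 0L
      if (depth < max_depth) {
        for (j in which(gains == 0)) {
          sel_j <- X[rows, j] == 1L
          child_pay <- any(node_gains(rows[sel_j]) > 0) ||
                       any(node_gains(rows[!sel_j]) > 0)
          if (child_pay) { best <- j; break }
        }
      }
      if (best == 0L)
        return(list(leaf = TRUE, class = .majority(labs), n = length(rows)))
    }
    sel <- X[rows, best] == 1L
    list(leaf = FALSE, snp = best,
         snp_id = colnames(X)[best],
         gain = gains[best], n = length(rows),
         left = grow(rows[!sel], depth + 1L),    # allele 0
         right = grow(rows[sel], depth + 1L))    # allele 1
  }
  structure(list(root = grow(seq_len(nrow(X)), 1L),
                 criterion = criterion, max_depth = max_depth),
            class = "decision_tree")
}

#' Predict classes with a decision tree
#'
#' @param object A `decision_tree`.
#' @param newdata Binary matrix with the same SNP columns as training.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.decision_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  one <- function(node, x) {
    while (!node$leaf)
      node <- if (x[node$snp] == 1L) node$right else node$left
    node$class
  }
  vapply(seq_len(nrow(newdata)), function(i)
    one(object$root, newdata[i, ]), character(1))
}

#' SNPs used by a decision tree
#'
#' @param tree A `decision_tree`.
#' @return Sorted integer vector of distinct SNP column indices.
#' @export
tree_snps <- function(tree) {
  rec <- function(node) {
    if (node$leaf) return(integer(0))
    c(node$snp, rec(node$left), rec(node$right))
  }
  sort(unique(rec(tree$root)))
}

#' Render a decision tree as indented text
#'
#' @param tree A `decision_tree`.
#' @return Character vector of lines.
#' @export
format_tree <- function(tree) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf)
      return(sprintf("%s-> %s (n=%d)", pad, node$class, node$n))
    c(sprintf("%s[%s] (gain=%.3f, n=%d)", pad,
              if (is.null(node$snp_id)) paste0("snp", node$snp)
              else node$snp_id, node$gain, node$n),
      sprintf("%s allele 0:", pad), rec(node$left, indent + 1L),
      sprintf("%s allele 1:", pad), rec(node$right, indent + 1L))
  }
  rec(tree$root, 0L)
}

# stratified fold assignment preserving class proportions
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated tree accuracy
#'
#' Classes with fewer members than `k_folds` are merged into the wild-type
#' class (with a warning) so every class appears in every fold. Folds are
#' stratified to preserve class proportions; the procedure is repeated with
#' fresh fold assignments, all driven by a single seed, and the number of
#' distinct SNPs used by each trained tree is reported alongside accuracy.
#'
#' @param X Binary feature matrix (haplotypes x SNPs).
#' @param labels Class labels.
#' @param criterion Split criterion, see [build_tree()].
#' @param max_depth Maximum tree depth.
#' @param k_folds Number of folds (default 5).
#' @param repeats Number of repeats (default 10).
#' @param seed Random seed.
#' @param wt_label Label absorbing rare classes (default `"wt"`).
#' @return Data.frame: `repeat_`, `fold`, `accuracy`, `n_snps_used`.
#' @export
stratified_cv_accuracy <- function(X, labels,
                                   criterion = c("information_gain", "gini"),
                                   max_depth = 5L, k_folds = 5L,
                                   repeats = 10L, seed = 1L,
                                   wt_label = "wt") {
  criterion <- match.arg(criterion)
  if (k_folds < 2L) stop("stratified_cv_accuracy: k_folds must be >= 2")
  labels <- as.character(labels)
  tab <- table(labels)
  rare <- names(tab)[tab < k_folds]
  if (length(rare)) {
    warning("classes merged into ", wt_label, " (fewer than k_folds members): ",
            paste(rare, collapse = ", "))
    labels[labels %in% rare] <- wt_label
  }
  set.seed(seed)
  out <- list()
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(labels, k_folds)
    for (f in seq_len(k_folds)) {
      train <- fold != f
      tree <- build_tree(X[train, , drop = FALSE], labels[train],
                         criterion, max_depth)
      pred <- predict(tree, X[!train, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        accuracy = mean(pred == labels[!train]),
        n_snps_used = length(tree_snps(tree)))
    }
  }
  do.call(rbind, out)
}

#' Per-group allele frequency table for panel design
#'
#' For every biallelic SNP within the gene plus `flank` bp on each side,
#' the alternate-allele frequency within each haplotype group, the SNP's
#' information gain about the group labels, and a flag for panel-candidate
#' SNPs whose maximum between-group frequency difference reaches
#' `diff_threshold`.
#'
#' @param haps A `haplotype_matrix`.
#' @param labels Group label per haplotype (wild-type cores merged to
#'   `"wt"`).
#' @param gene_interval `c(start, end)` of the gene (1-based inclusive).
#' @param flank Flanking distance in bp (default 10000).
#' @param diff_threshold Between-group frequency-difference flag threshold
#'   (default 0.9).
#' @return Data.frame of class `panel_report`: `site_index`, `pos`, `ref`,
#'   `alt`, per-group frequency columns, `info_gain`, `candidate`.
#' @export
group_frequency_table <- function(haps, labels, gene_interval,
                                  flank = 10000L, diff_threshold = 0.9) {
  stopifnot(flank >= 0)
  win <- c(gene_interval[1L] - flank, gene_interval[2L] + flank)
  sel <- which(haps$sites$pos >= win[1L] & haps$sites$pos <= win[2L] &
               haps$sites$n_alleles == 2L)
  groups <- sort(unique(labels))
  rows <- lapply(sel, function(i) {
    g <- haps$geno[i, ]
    freqs <- vapply(groups, function(k) mean(g[labels == k] == 1L),
                    numeric(1))
    data.frame(site_index = i, pos = haps$sites$pos[i],
               ref = haps$sites$ref[i], alt = haps$sites$alts[i],
               as.list(freqs), info_gain = information_gain(g, labels),
               candidate = max(freqs) - min(freqs) >= diff_threshold,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("panel_report", "data.frame")
  out
}

#' Binary feature matrix for tree induction
#'
#' Biallelic SNPs in the gene plus flank as 0/1 columns named by position.
#'
#' @inheritParams group_frequency_table
#' @return Binary matrix, haplotypes x SNPs.
#' @export
feature_matrix <- function(haps, gene_interval, flank = 10000L) {
  win <- c(gene_interval[1L] - flank, gene_interval[2L] + flank)
  sel <- which(haps$sites$pos >= win[1L] & haps$sites$pos <= win[2L] &
               haps$sites$n_alleles == 2L)
  X <- t(haps$geno[sel, , drop = FALSE])
  colnames(X) <- paste0("pos", haps$sites$pos[sel])
  attr(X, "site_index") <- sel
  X
}
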