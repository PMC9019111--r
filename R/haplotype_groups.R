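#' Pairwise Hamming distance matrix over a genomic window
#'
#' Exact integer SNP-difference counts between all haplotype pairs, using
#' sites inside `window` (optionally restricted to biallelic sites, the
#' convention used for clustering and network construction).
#'
#' @param haps A `haplotype_matrix`.
#' @param window `c(start, end)` 1-based inclusive; `NULL` for all sites.
#' @param biallelic_only Drop sites with more than two alleles (default
#'   TRUE).
#' @param subset Optional haplotype indices.
#' @return Integer matrix (haplotypes x haplotypes), zero diagonal,
#'   with attribute `site_index` giving the sites used.
#' @export
pairwise_hamming <- function(haps, window = NULL, biallelic_only = TRUE,
                             subset = NULL) {
  keep <- rep(TRUE, nrow(haps$sites))
  if (!is.null(window))
    keep <- keep & haps$sites$pos >= window[1L] & haps$sites$pos <= window[2L]
  if (biallelic_only) keep <- keep & haps$sites$n_alleles == 2L
  g <- haps$geno[keep, , drop = FALSE]
  if (!is.null(subset)) g <- g[, subset, drop = FALSE]
  d <- .hamming_mat(g)
  dimnames(d) <- list(colnames(g), colnames(g))
  attr(d, "site_index") <- which(keep)
  d
}

# Hamming distances between columns of a small-integer matrix.
.hamming_mat <- function(g) {
  n <- ncol(g)
  if (nrow(g) == 0L) return(matrix(0L, n, n))
  codes <- sort(unique(as.vector(g)))
  d <- matrix(0, n, n)
  # matches = sum over codes of (g==c)'(g==c); distance = sites - matches
  matches <- matrix(0, n, n)
  for (cc in codes) {
    m <- g == cc
    storage.mode(m) <- "double"
    matches <- matches + crossprod(m)
  }
  d <- nrow(g) - matches
  storage.mode(d) <- "integer"
  d
}

#' Haplotype groups by hierarchical clustering
#'
#' Agglomerative clustering of the pairwise-distance matrix; the tree is cut
#' at `cut_height` (in SNP differences) so clusters of near-identical
#' haplotypes become groups. Clusters are labelled by their focal-allele
#' content and decreasing size (largest cluster carrying the first focal
#' allele gets label `<name>1`, etc.). Clusters smaller than
#' `min_group_size` are merged into `OR` (carries some focal allele) or
#' `wt` (carries none).
#'
#' @param dist Square distance matrix from [pairwise_hamming()].
#' @param focal_alleles Named list of logical carrier vectors (one per focal
#'   allele class, e.g. `list(F = ..., S = ..., L = ...)`), each of length
#'   `nrow(dist)`.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param cut_height Tree cut height in SNP differences.
#' @param min_group_size Minimum cluster size to receive its own label.
#' @return Character vector of group labels per haplotype, with the integer
#'   cluster ids as attribute `cluster`.
#' @export
hierarchical_groups <- function(dist, focal_alleles,
                                linkage = c("average", "single", "complete"),
                                cut_height, min_group_size = 3L) {
  linkage <- match.arg(linkage)
  if (cut_height < 0) stop("hierarchical_groups: cut_height must be >= 0")
  hc <- stats::hclust(stats::as.dist(dist), method = linkage)
  cl <- stats::cutree(hc, h = cut_height)
  label_clusters(cl, focal_alleles, min_group_size)
}

#' Label integer clusters by focal-allele content and size
#'
#' Shared labelling rule for hierarchical clusters and network components:
#' a cluster is assigned to the focal class of the majority allele among
#' its members; classes are numbered by decreasing cluster size. Clusters
#' below `min_group_size` collapse to `OR` / `wt`.
#'
#' @param cl Integer cluster id per haplotype.
#' @param focal_alleles Named list of logical carrier vectors.
#' @param min_group_size Minimum size for an own label.
#' @return Character label vector (attribute `cluster` = `cl`).
#' @export
label_clusters <- function(cl, focal_alleles, min_group_size = 3L) {
  stopifnot(all(lengths(focal_alleles) == length(cl)))
  ids <- unique(cl)
  # per cluster, carriers of each focal class; the cluster belongs to the
  # class with the most carriers, and group size = that carrier count (a
  # cluster may also contain wild-type haplotypes sharing the background)
  carr_n <- vapply(ids, function(i) {
    vapply(focal_alleles, function(f) sum(f[cl == i]), numeric(1))
  }, numeric(length(focal_alleles)))
  carr_n <- matrix(carr_n, nrow = length(focal_alleles),
                   dimnames = list(names(focal_alleles), NULL))
  cls <- apply(carr_n, 2, function(x) {
    if (all(x == 0)) NA_character_ else names(focal_alleles)[which.max(x)]
  })
  gsize <- apply(carr_n, 2, max)
  labels <- character(length(ids))
  for (k in names(focal_alleles)) {
    members <- which(cls == k & gsize >= min_group_size)
    members <- members[order(-gsize[members], ids[members])]
    labels[members] <- paste0(k, seq_along(members))
  }
  any_focal <- Reduce(`|`, focal_alleles)
  out <- character(length(cl))
  for (j in seq_along(ids)) {
    i <- ids[j]
    sel <- cl == i
    if (nzchar(labels[j])) {
      k <- cls[j]
      # the group label applies only to carriers of the cluster's focal
      # class; other members fall back to OR / wt
      out[sel] <- ifelse(focal_alleles[[k]][sel], labels[j],
                         ifelse(any_focal[sel], "OR", "wt"))
    } else {
      out[sel] <- ifelse(any_focal[sel], "OR", "wt")
    }
  }
  attr(out, "cluster") <- cl
  out
}

# ---- median-joining network ----------------------------------------------

# epsilon-relaxed minimum spanning network: include the pair (x, y) iff
# d(x, y) <= s(x, y) + epsilon, where s is the minimax (bottleneck) path
# distance — the largest edge on the MST path between x and y. With
# epsilon = 0 this is the union of all minimum spanning trees.
.msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  empty <- data.frame(from = integer(0), to = integer(0), dist = numeric(0))
  if (n <= 1L) return(empty)
  dimnames(d) <- NULL
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mt <- igraph::mst(g)
  el <- igraph::as_edgelist(mt, names = FALSE)
  wt <- igraph::E(mt)$weight
  nbr <- vector("list", n)
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1L]; b <- el[k, 2L]
    nbr[[a]] <- rbind(nbr[[a]], c(b, wt[k]))
    nbr[[b]] <- rbind(nbr[[b]], c(a, wt[k]))
  }
  s <- matrix(0, n, n)
  for (root in seq_len(n)) {          # BFS over the MST tracking max edge
    seen <- rep(FALSE, n); seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      x <- queue[1L]; queue <- queue[-1L]
      for (r in seq_len(NROW(nbr[[x]]))) {
        y <- nbr[[x]][r, 1L]
        if (!seen[y]) {
          seen[y] <- TRUE
          s[root, y] <- max(s[root, x], nbr[[x]][r, 2L])
          queue <- c(queue, y)
        }
      }
    }
  }
  sel <- which(upper.tri(d) & d <= s + epsilon, arr.ind = TRUE)
  data.frame(from = sel[, 1L], to = sel[, 2L], dist = d[sel])
}

.mst_length <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(0)
  dimnames(d) <- NULL
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

#' Median-joining haplotype network
#'
#' Bandelt's median-joining construction over binary-coded haplotypes in a
#' window: iteratively build the epsilon-relaxed minimum spanning network
#' over the current node set; for node triples that are mutually connected,
#' propose the per-site majority-consensus (median) vector as an inferred
#' node and add it when it shortens the network (reduces minimum
#' spanning length); repeat to fixation; finally drop unused median nodes
#' and prune edges longer than `max_edge_dist`. Components smaller than
#' `min_component_size` are flagged (`display = FALSE`) but never removed
#' from the data structure.
#'
#' @param haps A `haplotype_matrix`.
#' @param window `c(start, end)` or `NULL` for all sites.
#' @param subset Optional haplotype indices.
#' @param epsilon MSN relaxation parameter (default 0).
#' @param max_edge_dist Edges longer than this (SNP differences) are pruned
#'   after construction (default 2; `Inf` disables pruning).
#' @param min_component_size Components below this size are flagged for
#'   exclusion from display output (default 3).
#' @return Object of class `haplotype_network`: `nodes` (data.frame `id`,
#'   `seq`, `multiplicity`, `observed`, `display`, `component`), `edges`
#'   (`from`, `to`, `dist`, `sites` list-column of distinguishing site
#'   indices in `haps`), `membership` (haplotype -> node id, NA for
#'   non-subset haplotypes), `site_index` (window sites used).
#' @export
median_joining_network <- function(haps, window = NULL, subset = NULL,
                                   epsilon = 0L, max_edge_dist = 2L,
                                   min_component_size = 3L) {
  keep <- rep(TRUE, nrow(haps$sites))
  if (!is.null(window))
    keep <- keep & haps$sites$pos >= window[1L] & haps$sites$pos <= window[2L]
  site_index <- which(keep)
  if (any(haps$sites$n_alleles[keep] > 2L))
    stop("median_joining_network: non-binary site in window; ",
         "restrict to biallelic sites first")
  g <- haps$geno[keep, , drop = FALSE]
  if (!is.null(subset)) g <- g[, subset, drop = FALSE] else
    subset <- seq_len(ncol(haps$geno))
  if (ncol(g) < 1L) stop("median_joining_network: no haplotypes")
  seqs <- apply(g, 2, paste, collapse = "")
  # deterministic lexicographic node order
  useq <- sort(unique(seqs))
  mult <- as.integer(table(seqs)[useq])
  node_mat <- if (length(site_index))
    vapply(strsplit(useq, ""), as.integer, integer(length(site_index)))
  else matrix(integer(0), 0, length(useq))
  node_mat <- matrix(node_mat, nrow = length(site_index))
  observed <- rep(TRUE, length(useq))

  repeat {
    d <- .hamming_mat(node_mat)
    msn <- .msn_edges(d, epsilon)
    if (nrow(msn) == 0L) break
    adj <- matrix(FALSE, ncol(node_mat), ncol(node_mat))
    adj[cbind(msn$from, msn$to)] <- TRUE
    adj <- adj | t(adj)
    base_len <- .mst_length(d)
    # candidate medians from mutually connected triples: for each MSN edge
    # (u, v) with u < v, every common neighbour w > v closes a triangle
    cand <- list()
    for (k in seq_len(nrow(msn))) {
      u <- msn$from[k]; v <- msn$to[k]
      ws <- which(adj[u, ] & adj[v, ])
      for (w in ws[ws > v]) {
        med <- as.integer(rowSums(node_mat[, c(u, v, w), drop = FALSE]) >= 2L)
        cand[[length(cand) + 1L]] <- med
      }
    }
    if (length(cand) == 0L) break
    keyed <- vapply(cand, paste, character(1), collapse = "")
    existing <- apply(node_mat, 2, paste, collapse = "")
    new <- !duplicated(keyed) & !(keyed %in% existing)
    cand <- cand[new]; keyed <- keyed[new]
    if (length(cand) == 0L) break
    ord <- order(keyed)
    cand <- cand[ord]
    best_delta <- 0; best <- NULL
    for (m in cand) {
      dm <- colSums(node_mat != m)
      d2 <- unname(rbind(cbind(d, dm), c(dm, 0)))
      delta <- .mst_length(d2) - base_len
      if (delta < best_delta) { best_delta <- delta; best <- m }
    }
    if (is.null(best)) break
    node_mat <- cbind(node_mat, best)
    observed <- c(observed, FALSE)
    mult <- c(mult, 0L)
  }

  # drop median nodes that do not shorten the network (degree <= 1, or
  # removable without increasing MST length), iteratively
  repeat {
    d <- .hamming_mat(node_mat)
    msn <- .msn_edges(d, epsilon)
    deg <- tabulate(c(msn$from, msn$to), nbins = ncol(node_mat))
    drop <- which(!observed & deg <= 1L)
    if (length(drop) == 0L) break
    node_mat <- node_mat[, -drop, drop = FALSE]
    observed <- observed[-drop]; mult <- mult[-drop]
  }

  d <- .hamming_mat(node_mat)
  msn <- .msn_edges(d, epsilon)
  pruned <- msn[msn$dist <= max_edge_dist, , drop = FALSE]
  gg <- igraph::graph_from_data_frame(
    pruned, directed = FALSE,
    vertices = data.frame(name = seq_len(ncol(node_mat))))
  comp <- igraph::components(gg)$membership
  node_seqs <- apply(node_mat, 2, paste, collapse = "")
  if (length(node_seqs) == 0L) node_seqs <- character(0)
  nodes <- data.frame(id = seq_len(ncol(node_mat)), seq = node_seqs,
                      multiplicity = mult, observed = observed,
                      component = as.integer(comp[as.character(
                        seq_len(ncol(node_mat)))]),
                      stringsAsFactors = FALSE)
  comp_sizes <- tapply(nodes$multiplicity, nodes$component, sum)
  nodes$display <- comp_sizes[as.character(nodes$component)] >=
    min_component_size
  edges <- pruned
  edges$sites <- lapply(seq_len(nrow(edges)), function(i)
    site_index[which(node_mat[, edges$from[i]] != node_mat[, edges$to[i]])])
  membership <- rep(NA_integer_, ncol(haps$geno))
  membership[subset] <- match(seqs, node_seqs)
  structure(list(nodes = nodes, edges = edges, membership = membership,
                 site_index = site_index, max_edge_dist = max_edge_dist),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes (",
      sum(!x$nodes$observed), "median ),", nrow(x$edges), "edges,",
      length(unique(x$nodes$component)), "components\n")
  invisible(x)
}

#' Group labels from network components
#'
#' Labels each observed haplotype by the component of its network node,
#' using the same focal-allele / size rule as [hierarchical_groups()].
#'
#' @param net A `haplotype_network`.
#' @param focal_alleles Named list of logical carrier vectors over the full
#'   haplotype set of the matrix the network was built from.
#' @param min_group_size Minimum component haplotype count for an own label.
#' @return Character label vector over the haplotypes in the network's
#'   subset (NA membership rows excluded).
#' @export
network_groups <- function(net, focal_alleles, min_group_size = 3L) {
  in_net <- !is.na(net$membership)
  comp <- net$nodes$component[net$membership[in_net]]
  fa <- lapply(focal_alleles, function(f) f[in_net])
  out <- rep(NA_character_, length(net$membership))
  out[in_net] <- label_clusters(comp, fa, min_group_size)
  out
}

#' Flag and label non-synonymous edges of a network
#'
#' Marks every edge whose distinguishing sites include at least one
#' missense (or nonsense) site and labels it with the codon change(s),
#' oriented away from the reference allele.
#'
#' @param net A `haplotype_network`.
#' @param effects Annotation table from [annotate_all_sites()] (uses
#'   `site_index`, `effect_class`, `aa_change`).
#' @return The network with edge columns `nonsyn` (logical) and
#'   `codon_changes` (comma-separated labels, "" when none).
#' @export
annotate_nonsynonymous_edges <- function(net, effects) {
  ns <- effects[effects$effect_class %in% c("missense", "nonsense"), ]
  lab <- function(sites) {
    hit <- ns[ns$site_index %in% sites, ]
    paste(unique(hit$aa_change), collapse = ",")
  }
  net$edges$codon_changes <- vapply(net$edges$sites, lab, character(1))
  net$edges$nonsyn <- nzchar(net$edges$codon_changes)
  net
}

# ---- concordance ----------------------------------------------------------

# Hungarian algorithm for the square assignment problem, minimizing cost.
# Shortest-augmenting-path formulation with dual potentials, O(n^3);
# column index 0 is a sentinel. Sufficient for small label sets.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)                    # row potentials
  v <- numeric(n + 1)                # col potentials (index 1 = sentinel)
  p <- integer(n + 1)                # p[j+1] = row matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) if (!used[j + 1L]) {
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

#' Concordance between two group assignments
#'
#' Fraction of haplotypes identically assigned after the best one-to-one
#' matching between the two label sets (maximum-agreement bipartite
#' matching on the confusion table), so that assignments identical up to a
#' label permutation score 1.
#'
#' @param a,b Character label vectors over the same haplotypes.
#' @return Fraction in `[0, 1]`; the matched label pairs are attached as
#'   attribute `matching`.
#' @export
concordance <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  la <- sort(unique(a)); lb <- sort(unique(b))
  k <- max(length(la), length(lb))
  conf <- matrix(0, k, k)
  conf[seq_along(la), seq_along(lb)] <-
    as.matrix(table(factor(a, la), factor(b, lb)))
  assign <- .hungarian(max(conf) - conf)   # maximize agreement
  agree <- sum(conf[cbind(seq_len(k), assign)])
  matching <- data.frame(
    a = c(la, rep(NA, k - length(la))),
    b = c(lb, rep(NA, k - length(lb)))[assign])
  structure(agree / length(a), matching = matching)
}

#' Group frequency table per population
#'
#' Cross-tabulates haplotype group labels against populations, as counts
#' and frequencies — the per-population composition of each sweep group.
#'
#' @param labels Character group labels per haplotype.
#' @param populations Population per haplotype.
#' @return List with `counts` and `freq` matrices (population x group).
#' @export
population_group_table <- function(labels, populations) {
  counts <- table(population = populations, group = labels)
  freq <- counts / rowSums(counts)
  list(counts = unclass(counts), freq = unclass(freq))
}

#' Export a haplotype network as GraphViz DOT
#'
#' Node size encodes multiplicity; non-synonymous edges are red and
#' labelled with their codon changes.
#'
#' @param net A `haplotype_network` (optionally after
#'   [annotate_nonsynonymous_edges()]).
#' @param path Output path.
#' @param display_only Drop components flagged `display = FALSE`.
#' @export
write_network_dot <- function(net, path, display_only = TRUE) {
  nodes <- net$nodes
  if (display_only) nodes <- nodes[nodes$display, , drop = FALSE]
  keep_ids <- nodes$id
  edges <- net$edges[net$edges$from %in% keep_ids &
                     net$edges$to %in% keep_ids, , drop = FALSE]
  lines <- c("graph haplotype_network {", "  node [shape=circle];")
  for (i in seq_len(nrow(nodes))) {
    sz <- 0.3 + 0.1 * sqrt(nodes$multiplicity[i])
    lines <- c(lines, sprintf(
      "  n%d [width=%.2f, label=\"%d\", style=%s];", nodes$id[i], sz,
      nodes$multiplicity[i],
      if (nodes$observed[i]) "solid" else "dotted"))
  }
  for (i in seq_len(nrow(edges))) {
    ns <- !is.null(edges$nonsyn) && isTRUE(edges$nonsyn[i])
    lab <- if (ns) edges$codon_changes[i] else ""
    lines <- c(lines, sprintf(
      "  n%d -- n%d [label=\"%s\", color=%s];", edges$from[i], edges$to[i],
      lab, if (ns) "red" else "black"))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
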