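# Distance-based phylogeny: JTT maximum-likelihood pairwise distances
# (optionally with a discrete-Gamma rate mixture), classical Saitou-Nei
# neighbor joining with a deterministic tie rule, column bootstrap, and
# midpoint rooting. ape's "phylo" is the tree container throughout.

#' Configuration for distance-tree construction
#'
#' @param gamma_shape Positive Gamma shape for among-site rate
#'   heterogeneity, or `NULL` for uniform rates.
#' @param n_rate_categories Number of discrete-Gamma categories (default 5).
#' @param n_bootstrap Number of bootstrap pseudo-replicates (default 1000).
#' @param seed Integer seed; replicate `r` uses `seed + r`.
#' @param deletion Gap treatment before distances; only `"complete"` is
#'   supported.
#' @return An object of class `phylo_config`.
#' @export
phylo_config <- function(gamma_shape = NULL, n_rate_categories = 5L,
                         n_bootstrap = 1000L, seed = NULL,
                         deletion = "complete") {
  stopifnot(is.null(gamma_shape) || (is.numeric(gamma_shape) && gamma_shape > 0),
            n_rate_categories >= 1L, n_bootstrap >= 1L)
  deletion <- match.arg(deletion, "complete")
  structure(list(gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = seed, deletion = deletion),
            class = "phylo_config")
}

.rates_from <- function(gamma_shape, k) {
  if (is.null(gamma_shape)) 1 else discrete_gamma_rates(gamma_shape, k)
}

# 20x20 table of aligned residue-pair counts from two encoded sequences
.pair_counts <- function(ia, ib) {
  matrix(tabulate((ia - 1L) * 20L + ib, nbins = 400L),
         nrow = 20L, byrow = TRUE)
}

#' JTT maximum-likelihood distance between two aligned sequences
#'
#' Maximizes the likelihood of the aligned residue pairs under the JTT
#' model (mixed over discrete-Gamma rate categories when `gamma_shape` is
#' set) over branch lengths in `[1e-9, 10]` to tolerance `1e-6`.
#'
#' @param a,b Equal-length protein strings containing only the 20
#'   standard residues (apply [complete_deletion()] first).
#' @param gamma_shape Optional Gamma shape parameter.
#' @param k Number of rate categories when `gamma_shape` is set.
#' @return Distance in substitutions/site, with attribute `saturated`
#'   `TRUE` when the optimizer ran into the upper bound.
#' @export
jtt_distance <- function(a, b, gamma_shape = NULL, k = 5L) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) == 0L) stop("zero overlapping sites")
  ia <- aa_index(a); ib <- aa_index(b)
  counts <- .pair_counts(ia, ib)
  e <- jtt_eigen()
  rates <- .rates_from(gamma_shape, k)
  t_hat <- jtt_fit_cpp(counts, e$values, e$vectors, e$sqrtpi, rates,
                       1e-9, 10, 1e-6)
  structure(t_hat, saturated = (t_hat > 10 - 1e-3))
}

#' Pairwise JTT distance matrix for an alignment
#'
#' Applies complete deletion, then estimates every pairwise distance with
#' [jtt_distance()].
#'
#' @param aln A [alignment()] (or named character vector).
#' @param gamma_shape,k As in [jtt_distance()].
#' @param deletion `"complete"` (gapped/missing columns removed first) or
#'   `"none"` (the alignment must already be gap-free).
#' @return Symmetric numeric matrix of substitutions/site with taxon
#'   dimnames.
#' @export
jtt_distance_matrix <- function(aln, gamma_shape = NULL, k = 5L,
                                deletion = c("complete", "none")) {
  aln <- as_alignment(aln)
  deletion <- match.arg(deletion)
  if (deletion == "complete") aln <- complete_deletion(aln)
  if (aln$n_cols == 0L) stop("zero overlapping sites after complete deletion")
  ids <- names(aln$seqs)
  enc <- lapply(aln$seqs, aa_index)
  n <- length(ids)
  e <- jtt_eigen()
  rates <- .rates_from(gamma_shape, k)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      counts <- .pair_counts(enc[[i]], enc[[j]])
      d[i, j] <- d[j, i] <- jtt_fit_cpp(counts, e$values, e$vectors,
                                        e$sqrtpi, rates, 1e-9, 10, 1e-6)
    }
  }
  d
}

#' Neighbor joining (Saitou & Nei)
#'
#' Classical NJ on a distance matrix: iteratively joins the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`.
#' Q-ties are broken toward the lowest (row, column) index pair, so the
#' output is deterministic. Negative branch-length estimates are clamped
#' to 0 (the number clamped is reported in attribute `n_clamped`).
#'
#' @param d Symmetric distance matrix with taxon dimnames (or `dist`).
#' @return An unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("non-finite distances")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(d)))
  labels <- ids              # current newick fragment per active cluster
  n_clamped <- 0L
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i, j) among minima, scanning rows then columns
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (q[i, j] < qmin) { qmin <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0 || lj < 0) n_clamped <- n_clamped + sum(c(li, lj) < 0)
    new_label <- paste0("(", labels[i], ":", fmt(li), ",",
                        labels[j], ":", fmt(lj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    labels <- c(labels[keep], new_label)
    rownames(d2) <- colnames(d2) <- seq_len(n - 1L)
    d <- d2
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(l1, l2, l3) < 0)) n_clamped <- n_clamped + sum(c(l1, l2, l3) < 0)
  nwk <- paste0("(", labels[1], ":", fmt(l1), ",", labels[2], ":", fmt(l2),
                ",", labels[3], ":", fmt(l3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; the bipartition is
#' represented canonically as the sorted label set on the side *not*
#' containing the alphabetically first leaf, so representations are
#' comparable across trees and rootings.
#'
#' @param tree A `"phylo"` object.
#' @return Character vector of canonical bipartition keys; names give the
#'   child node number of the corresponding edge.
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    tips <- labs[parts[[k]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    if (length(side) <= 1L) next
    out <- c(out, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ntip + k)
  }
  names(out) <- nodes
  out
}

#' Robinson-Foulds distance
#'
#' Count of non-trivial bipartitions present in exactly one of the two
#' trees.
#'
#' @param t1,t2 `"phylo"` trees on the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Builds the NJ tree from JTT distances on the complete-deletion
#' alignment, then resamples alignment columns with replacement
#' (`config$n_bootstrap` times; replicate `r` is seeded with
#' `config$seed + r`), rebuilds the tree per replicate, and reports for
#' every internal edge of the original tree the percentage of replicates
#' containing its bipartition. Replicates in which all rows are identical
#' carry no signal; they are skipped with a warning but still counted in
#' the denominator.
#'
#' @param aln A [alignment()].
#' @param config A [phylo_config()] with a non-`NULL` seed.
#' @return The unrooted NJ `"phylo"` tree with support percentages in
#'   `node.label` (empty for the root and leaves' trivial edges).
#' @export
bootstrap_support <- function(aln, config) {
  stopifnot(inherits(config, "phylo_config"))
  if (is.null(config$seed)) stop("config$seed must be set for bootstrap")
  aln <- complete_deletion(as_alignment(aln))
  if (aln$n_cols == 0L) stop("zero columns after complete deletion")
  enc <- do.call(rbind, lapply(aln$seqs, aa_index))  # rows x columns
  ids <- names(aln$seqs)
  e <- jtt_eigen()
  rates <- .rates_from(config$gamma_shape, config$n_rate_categories)
  dist_from <- function(cols) {
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      counts <- .pair_counts(enc[i, cols], enc[j, cols])
      d[i, j] <- d[j, i] <- jtt_fit_cpp(counts, e$values, e$vectors,
                                        e$sqrtpi, rates, 1e-9, 10, 1e-6)
    }
    d
  }
  tree0 <- neighbor_joining(dist_from(seq_len(aln$n_cols)))
  bip0 <- tree_bipartitions(tree0)
  hits <- setNames(numeric(length(bip0)), bip0)
  skipped <- 0L
  for (r in seq_len(config$n_bootstrap)) {
    set.seed((config$seed + r) %% 2147483647L)
    cols <- sample.int(aln$n_cols, aln$n_cols, replace = TRUE)
    sub <- enc[, cols, drop = FALSE]
    if (all(apply(sub, 2L, function(col) length(unique(col)) == 1L))) {
      skipped <- skipped + 1L
      next
    }
    bip_r <- tree_bipartitions(neighbor_joining(dist_from(cols)))
    found <- bip0 %in% bip_r
    hits[found] <- hits[found] + 1
  }
  if (skipped > 0L)
    warning(skipped, " degenerate replicate(s) skipped (all rows identical)")
  support <- 100 * hits / config$n_bootstrap
  ntip <- length(tree0$tip.label)
  node.label <- rep("", tree0$Nnode)
  for (k in seq_along(bip0)) {
    node <- as.integer(names(bip0)[k])
    node.label[node - ntip] <- sprintf("%.10g", support[k])
  }
  tree0$node.label <- node.label
  attr(tree0, "support") <- support
  attr(tree0, "skipped_replicates") <- skipped
  tree0
}

# undirected adjacency list from a phylo: per node, matrix of (neighbor, length)
.tree_adjacency <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n_nodes)
  len <- tree$edge.length
  if (is.null(len)) stop("tree has no branch lengths")
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, len[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, len[k]))
  }
  adj
}

# single-source distances + parent pointers over the unrooted tree
.tree_bfs <- function(adj, from) {
  n <- length(adj)
  dist <- rep(NA_real_, n); parent <- rep(NA_integer_, n)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      u <- nb[k, 1]
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + nb[k, 2]
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Longest leaf-to-leaf path of a tree
#'
#' Two-pass farthest-leaf search: the farthest leaf from an arbitrary
#' start, then the farthest leaf from that one; the connecting path is a
#' tree diameter.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @return List with `leaves` (two tip labels), `length` (path length)
#'   and `path` (node numbers along the path).
#' @export
longest_leaf_path <- function(tree) {
  ntip <- length(tree$tip.label)
  adj <- .tree_adjacency(tree)
  far_leaf <- function(from) {
    b <- .tree_bfs(adj, from)
    dl <- b$dist[seq_len(ntip)]
    list(leaf = which.max(dl), res = b)
  }
  u <- far_leaf(1L)$leaf
  second <- far_leaf(u)
  v <- which.max(second$res$dist[seq_len(ntip)])
  path <- v
  while (path[1] != u) path <- c(second$res$parent[path[1]], path)
  list(leaves = tree$tip.label[c(u, v)],
       length = second$res$dist[v], path = path)
}

# serialize the tree re-rooted at `root_node` (with optional extra node
# splitting edge a-b at distance x from a) back into a phylo
.rebuild_rooted <- function(tree, adj, root_at, split = NULL) {
  ntip <- length(tree$tip.label)
  node_name <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label[v - ntip]
      if (!is.na(lab) && nzchar(lab)) return(lab)
    }
    ""
  }
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  emit <- function(v, from) {
    nb <- adj[[v]]
    kids <- character(0)
    for (k in seq_len(nrow(nb))) {
      u <- nb[k, 1]
      if (!is.na(from) && u == from) next
      kids <- c(kids, paste0(emit(u, v), ":", fmt(nb[k, 2])))
    }
    if (length(kids) == 0L) return(node_name(v))
    paste0("(", paste(kids, collapse = ","), ")", node_name(v))
  }
  if (!is.null(split)) {
    a <- split$a; b <- split$b; x <- split$x
    root_id <- length(adj) + 1L
    drop_edge <- function(m, u) m[m[, 1] != u, , drop = FALSE]
    adj[[a]] <- rbind(drop_edge(adj[[a]], b), c(root_id, x))
    adj[[b]] <- rbind(drop_edge(adj[[b]], a), c(root_id, split$len - x))
    adj[[root_id]] <- rbind(c(a, x), c(b, split$len - x))
    root_at <- root_id
  }
  nwk <- paste0(emit(root_at, NA), ";")
  ape::read.tree(text = nwk)
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the midpoint of its longest leaf-to-leaf
#' path, so the two deepest root-to-leaf distances are equal.
#'
#' @param tree An unrooted `"phylo"` with branch lengths.
#' @return A rooted `"phylo"`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    stop("midpoint undefined: tree has no positive branch lengths")
  adj <- .tree_adjacency(tree)
  lp <- longest_leaf_path(tree)
  half <- lp$length / 2
  path <- lp$path
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    nb <- adj[[a]]
    len <- nb[nb[, 1] == b, 2][1]
    if (cum + len >= half - 1e-12) {
      x <- half - cum
      if (x <= 1e-12)       # midpoint sits on node a
        return(.rebuild_rooted(tree, adj, root_at = a))
      if (len - x <= 1e-12) # midpoint sits on node b
        return(.rebuild_rooted(tree, adj, root_at = b))
      return(.rebuild_rooted(tree, adj, root_at = NA,
                             split = list(a = a, b = b, x = x, len = len)))
    }
    cum <- cum + len
  }
  stop("midpoint not found on the longest path")  # unreachable
}

#' Write a distance matrix as TSV
#'
#' @param d Symmetric matrix with dimnames.
#' @param path Output path (header line starts `#`).
#' @export
write_distance_tsv <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#id\t", paste(colnames(d), collapse = "\t")), con)
  write.table(cbind(rownames(d), format(d, digits = 10, trim = TRUE)),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
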