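# Distance-based tree building and clade/motif concordance. Trees are
# returned as ape "phylo" objects; Newick I/O goes through ape.

validate_dist_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (anyNA(D) || any(!is.finite(D)))
    stop("distance matrix contains NA/non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining with the standard Q criterion and
#' branch-length formulas. Deterministic: ties in Q are broken by the
#' lexicographically smallest label pair. Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling edge, so Newick
#' output is always valid.
#'
#' On an additive (tree-like) matrix NJ recovers the generating topology
#' and branch lengths exactly.
#'
#' @param D Symmetric distance matrix with zero diagonal and row names.
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
neighbor_joining <- function(D) {
  D <- validate_dist_matrix(D)
  labs <- rownames(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 labels")
  if (n == 2) {
    d <- D[1, 2]
    return(ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g);",
                                         labs[1], d / 2, labs[2], d / 2)))
  }
  frag <- labs            # newick fragment per active node
  tielab <- labs          # label used for deterministic tie-breaking
  Dm <- D
  clamp_pair <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    c(vi, vj)
  }
  while (nrow(Dm) > 3) {
    r <- nrow(Dm)
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    key1 <- pmin(tielab[idx[, 1]], tielab[idx[, 2]])
    key2 <- pmax(tielab[idx[, 1]], tielab[idx[, 2]])
    pick <- order(key1, key2)[1]
    i <- idx[pick, 1]; j <- idx[pick, 2]
    vi <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- Dm[i, j] - vi
    v <- clamp_pair(vi, vj); vi <- v[1]; vj <- v[2]
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], vi, frag[j], vj)
    newlab <- min(tielab[i], tielab[j])
    dk <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dk[keep]),
                 c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    tielab <- c(tielab[keep], newlab)
    Dm <- Dm2
  }
  if (nrow(Dm) == 3) {
    va <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
    vb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
    vc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
    va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
    txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                   frag[1], va, frag[2], vb, frag[3], vc)
  } else {
    txt <- sprintf("(%s:%.15g,%s:%.15g);", frag[1], Dm[1, 2] / 2,
                   frag[2], Dm[1, 2] / 2)
  }
  ape::read.tree(text = txt)
}

#' Cut a tree into k clades
#'
#' Midpoint-roots the tree, then repeatedly splits the cluster whose
#' connecting edge is longest until `k` clusters remain. Internal edges
#' are preferred over pendant edges; remaining ties go to the deeper node
#' and then to the smallest descendant leaf label, so the partition is
#' deterministic. Clades are numbered by their smallest leaf label.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param k Number of clades, `1 <= k <=` number of leaves.
#' @return Named integer vector mapping each leaf label to a clade index.
#' @export
cut_tree_clades <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k < 1 || k > ntip) stop("k must be in [1, ", ntip, "]")
  if (ntip == 1 || k == 1)
    return(setNames(rep(1L, ntip), tree$tip.label))
  tr <- tree
  if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
  edges <- data.frame(parent = tr$edge[, 1], child = tr$edge[, 2],
                      length = tr$edge.length)
  nnode <- max(tr$edge)

  # node depths and smallest descendant leaf label per edge child
  depth <- rep(NA_integer_, nnode)
  root <- setdiff(edges$parent, edges$child)[1]
  depth[root] <- 0L
  ord <- order(edges$parent)  # parents precede children in ape's numbering
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      if (is.na(depth[edges$child[e]]) && !is.na(depth[edges$parent[e]])) {
        depth[edges$child[e]] <- depth[edges$parent[e]] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  children <- split(edges$child, edges$parent)
  minleaf <- rep(NA_character_, nnode)
  minleaf[seq_len(ntip)] <- tr$tip.label
  fill_minleaf <- function(node) {
    if (!is.na(minleaf[node])) return(minleaf[node])
    kids <- children[[as.character(node)]]
    vals <- vapply(kids, fill_minleaf, "")
    minleaf[node] <<- min(vals)
    minleaf[node]
  }
  fill_minleaf(root)

  cut <- rep(FALSE, nrow(edges))
  comp_of <- function() {
    # union-find over uncut edges
    parent <- seq_len(nnode)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in seq_len(nrow(edges))) if (!cut[e]) {
      a <- find(edges$parent[e]); b <- find(edges$child[e])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(nnode), find, 0L)
  }
  subtree_leaves <- function(node) {
    # leaves of the rooted subtree below `node`
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[[1]]; stack <- stack[-1]
      if (nd <= ntip) out <- c(out, nd)
      stack <- c(stack, children[[as.character(nd)]])
    }
    out
  }
  sub_leaf_cache <- lapply(seq_len(nnode), subtree_leaves)

  ncomp_leafful <- function(comp) length(unique(comp[seq_len(ntip)]))
  comp <- comp_of()
  while (ncomp_leafful(comp) < k) {
    cand <- which(!cut)
    # a cut is valid only if both resulting parts of its component keep a leaf
    valid <- vapply(cand, function(e) {
      cc <- comp[edges$child[e]]
      below <- intersect(sub_leaf_cache[[edges$child[e]]],
                         which(comp[seq_len(ntip)] == cc))
      total <- sum(comp[seq_len(ntip)] == cc)
      length(below) >= 1 && total - length(below) >= 1
    }, TRUE)
    cand <- cand[valid]
    if (!length(cand)) stop("cannot split tree further")
    internal <- edges$child[cand] > ntip
    key <- order(!internal,                      # internal edges first
                 -edges$length[cand],            # longest first
                 -depth[edges$child[cand]],      # deeper node first
                 minleaf[edges$child[cand]])     # then label order
    e <- cand[key[1]]
    cut[e] <- TRUE
    comp <- comp_of()
  }
  leafcomp <- comp[seq_len(ntip)]
  # number clades by smallest leaf label
  comp_min <- tapply(tr$tip.label, leafcomp, min)
  lev <- names(sort(comp_min))
  setNames(match(as.character(leafcomp), lev), tr$tip.label)
}

#' Concordance between a clade partition and group labels
#'
#' Computes the clade-by-group contingency table, clade purity
#' (fraction of leaves whose clade's majority group matches their own),
#' and the adjusted Rand index. Invariant to relabeling of clade indices.
#'
#' @param partition Named integer vector (leaf -> clade index), e.g. from
#'   [cut_tree_clades()].
#' @param groups Named vector (leaf -> group label) over the same leaves.
#' @return An object of class `concordance_report` with fields
#'   `purity`, `adjusted_rand`, `contingency`.
#' @export
clade_concordance <- function(partition, groups) {
  if (is.null(names(partition)) || is.null(names(groups)))
    stop("partition and groups must be named by leaf label")
  sd1 <- setdiff(names(partition), names(groups))
  sd2 <- setdiff(names(groups), names(partition))
  if (length(sd1) || length(sd2))
    stop("leaf sets differ: ", paste(c(sd1, sd2), collapse = ", "))
  groups <- groups[names(partition)]
  tab <- table(clade = partition, group = as.character(groups))
  n <- sum(tab)
  purity <- sum(apply(tab, 1, max)) / n

  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  ari <- if (abs(max_index - expected) < 1e-12) 1 else
    (sum_ij - expected) / (max_index - expected)

  structure(list(purity = purity, adjusted_rand = ari, contingency = tab),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance> purity %.3f, adjusted Rand %.3f\n",
              x$purity, x$adjusted_rand))
  print(x$contingency)
  invisible(x)
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept at 6 significant digits.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  tree$edge.length <- signif(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
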