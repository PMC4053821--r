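#' Gene-tree collections with window provenance
#'
#' A `tree_set` pairs an `ape::multiPhylo` with a data frame giving the
#' genomic window each tree was estimated from, and records the shared
#' taxon universe.
#'
#' @param trees an `ape::multiPhylo` (or list of `phylo`).
#' @param windows optional data frame `chrom`, `start`, `end`, one row per
#'   tree.
#' @return an object of class `tree_set`.
#' @export
tree_set <- function(trees, windows = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- structure(trees, class = "multiPhylo")
  taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  if (!is.null(windows)) {
    stopifnot(is.data.frame(windows), nrow(windows) == length(trees),
              all(c("chrom", "start", "end") %in% names(windows)))
  }
  structure(list(trees = trees, windows = windows, taxa = taxa),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("Tree set: %d trees over %d taxa%s\n", length(x$trees),
              length(x$taxa),
              if (is.null(x$windows)) "" else " (window provenance attached)"))
  invisible(x)
}

#' @export
length.tree_set <- function(x) length(x$trees)

#' Neighbor-joining gene tree with Jukes-Cantor distances
#'
#' A deterministic per-window tree builder: pairwise p-distances are
#' Jukes-Cantor corrected (`d = -3/4 * log(1 - 4p/3)`) and passed to
#' neighbor joining. Taxa are sorted lexicographically first so that ties
#' inside the NJ joins resolve identically for identical input; on additive
#' distance matrices NJ recovers the generating tree exactly. Externally
#' inferred trees in Newick form can be used everywhere downstream instead
#' (see [read_tree_set()]).
#'
#' @param x either a site-by-taxon (or taxon-by-site) character/integer
#'   alignment matrix with taxa as *rows* and named rows, or a square
#'   symmetric distance matrix / `dist` object.
#' @param correct apply the Jukes-Cantor correction to alignment-derived
#'   p-distances (default TRUE; ignored for distance input).
#' @param n_invariant number of invariant alignment columns not stored in
#'   `x` (compressed variable-sites-only alignments, as produced by the
#'   simulator, record only segregating columns; the invariant count
#'   restores the correct per-bp denominator).
#' @return an unrooted [ape::phylo].
#' @export
nj_tree <- function(x, correct = TRUE, n_invariant = 0) {
  d <- NULL
  if (inherits(x, "dist")) {
    d <- as.matrix(x)
  } else if (is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x) &&
             !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
             all(abs(diag(x)) < 1e-12) && isTRUE(all.equal(x, t(x)))) {
    d <- x
  }
  if (is.null(d)) {
    stopifnot(is.matrix(x), !is.null(rownames(x)))
    taxa <- rownames(x)
    n <- length(taxa)
    if (n < 3) stop("need at least 3 taxa")
    d <- matrix(0, n, n, dimnames = list(taxa, taxa))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      p <- if (any(ok) || n_invariant > 0)
        sum(x[i, ok] != x[j, ok]) / (sum(ok) + n_invariant) else 0
      if (correct) {
        if (p >= 0.75)
          stop("Jukes-Cantor correction undefined for pair ", taxa[i], " - ",
               taxa[j], " (p-distance ", signif(p, 3), " >= 0.75)")
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (n == 3) {
    # three-point formulas give the unique star resolution
    lab <- rownames(d)
    v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                         lab[1], v[1], lab[2], v[2], lab[3], v[3])))
  }
  ape::nj(stats::as.dist(d))
}

#' Bootstrap gene trees from a window alignment
#'
#' Draws `B` site-resampled replicates of the alignment and rebuilds a
#' neighbor-joining tree for each.
#'
#' @param aln taxon-by-site alignment matrix (taxa as named rows).
#' @param B number of replicates (default 100); `B = 0` gives an empty set.
#' @param seed optional integer seed.
#' @param correct,n_invariant passed to [nj_tree()]; with a compressed
#'   alignment, each replicate resamples the full column set (variable plus
#'   invariant) so that bootstrap distances stay on the per-bp scale.
#' @return a [tree_set()] of `B` trees.
#' @export
bootstrap_trees <- function(aln, B = 100, seed = NULL, correct = TRUE,
                            n_invariant = 0) {
  stopifnot(is.matrix(aln), ncol(aln) >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(aln) + n_invariant
  trees <- vector("list", B)
  for (b in seq_len(B)) {
    k <- if (n_invariant > 0) stats::rbinom(1, m, ncol(aln) / m) else ncol(aln)
    idx <- sample.int(ncol(aln), k, replace = TRUE)
    trees[[b]] <- nj_tree(aln[, idx, drop = FALSE], correct = correct,
                          n_invariant = m - k)
  }
  tree_set(trees)
}

# Non-trivial bipartitions of a tree, canonicalized as the side that does
# not contain the first taxon of the (sorted) universe; comma-joined keys.
.bipartitions <- function(tree, universe = NULL) {
  if (is.null(universe)) universe <- sort(tree$tip.label)
  n <- length(tree$tip.label)
  ref <- universe[1]
  below <- .tips_below(tree)
  out <- character(0)
  for (v in (n + 1):(n + tree$Nnode)) {
    tips <- tree$tip.label[below[[v]]]
    side <- if (ref %in% tips) setdiff(universe, tips) else tips
    if (length(side) >= 2 && length(side) <= n - 2)
      out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

# Rooted clades (tip-label sets below each node, including the full set)
.clades <- function(tree) {
  n <- length(tree$tip.label)
  below <- .tips_below(tree)
  unique(vapply((n + 1):(n + tree$Nnode), function(v)
    paste(sort(tree$tip.label[below[[v]]]), collapse = ","), character(1)))
}

#' Robinson-Foulds distance
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' (unrooted) trees. Requires identical leaf sets.
#'
#' @param t1,t2 [ape::phylo] trees on the same taxa.
#' @return a non-negative integer; 0 iff the unrooted topologies agree, at
#'   most `2 * (n - 3)` for binary trees on `n` leaves.
#' @export
rf_distance <- function(t1, t2) {
  u1 <- sort(t1$tip.label); u2 <- sort(t2$tip.label)
  if (!identical(u1, u2)) stop("trees have different leaf sets")
  b1 <- .bipartitions(t1, u1)
  b2 <- .bipartitions(t2, u1)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Clade / bipartition relative frequencies
#'
#' For each clade (rooted mode) or non-trivial bipartition (unrooted mode)
#' observed anywhere in the collection, the proportion of trees containing
#' it.
#'
#' @param trees a [tree_set()] or `multiPhylo`.
#' @param rooted treat trees as rooted and tabulate clades (default FALSE:
#'   unrooted bipartitions).
#' @return a data frame `clade` (comma-joined sorted members), `count`,
#'   `freq`, sorted by decreasing frequency.
#' @export
clade_frequencies <- function(trees, rooted = FALSE) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  stopifnot(length(trees) >= 1)
  universe <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  items <- unlist(lapply(trees, function(t)
    if (rooted) .clades(t) else .bipartitions(t, universe)))
  tab <- sort(table(items), decreasing = TRUE)
  out <- data.frame(clade = names(tab), count = as.integer(tab),
                    freq = as.numeric(tab) / length(trees),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$clade), ]
  rownames(out) <- NULL
  out
}

#' Extended majority-rule consensus tree
#'
#' Greedy frequency consensus: bipartitions observed across the collection
#' are sorted by decreasing frequency (ties broken lexicographically) and
#' added whenever compatible with those already accepted; node labels carry
#' the bipartition frequencies as support values.
#'
#' @param trees a [tree_set()] or `multiPhylo` on identical taxon sets.
#' @return an [ape::phylo] with `node.label` support values in `[0, 1]`.
#' @export
consensus_tree <- function(trees) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  stopifnot(length(trees) >= 1)
  universe <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  cf <- clade_frequencies(trees, rooted = FALSE)
  accepted <- list()
  for (i in seq_len(nrow(cf))) {
    cl <- strsplit(cf$clade[i], ",", fixed = TRUE)[[1]]
    compatible <- all(vapply(accepted, function(a) {
      ov <- length(intersect(a$members, cl))
      ov == 0 || ov == length(cl) || ov == length(a$members)
    }, logical(1)))
    if (compatible)
      accepted[[length(accepted) + 1L]] <- list(members = cl, freq = cf$freq[i])
  }
  .tree_from_clades(accepted, universe)
}

# Build a phylo from a compatible clade list (sides excluding universe[1])
.tree_from_clades <- function(accepted, universe) {
  ref <- universe[1]
  rest <- setdiff(universe, ref)
  if (length(accepted))
    accepted <- accepted[order(-lengths(lapply(accepted, `[[`, "members")))]
  build <- function(members) {
    used <- character(0)
    parts <- character(0)
    for (a in accepted) {
      cl <- a$members
      if (length(cl) < length(members) && all(cl %in% members) && !any(cl %in% used)) {
        parts <- c(parts, paste0(build(cl), signif(a$freq, 6)))
        used <- c(used, cl)
      }
    }
    parts <- c(parts, setdiff(members, used))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0("(", ref, ",", substring(build(rest), 2))
  # substring removed the opening "(" of the rest-group; re-close correctly
  nwk <- paste0(nwk, ";")
  ape::read.tree(text = nwk)
}

#' STAR species tree from gene trees
#'
#' Species-tree reconstruction from average coalescence ranks: each gene
#' tree is rooted on the outgroup; the root gets rank `n` (the taxon
#' count), every node one less than its parent; the distance between two
#' taxa in a gene tree is twice the rank of their most recent common
#' ancestor. Ranks are averaged across gene trees and the species topology
#' is read off the resulting matrix with neighbor joining. The result is
#' invariant to the input order of the gene trees. Gene trees missing the
#' outgroup are skipped (count reported as an attribute).
#'
#' @param trees a [tree_set()] or `multiPhylo`.
#' @param outgroup outgroup tip label used to root every gene tree.
#' @return a rooted [ape::phylo] species-tree topology with attribute
#'   `n_skipped`.
#' @export
star_species_tree <- function(trees, outgroup) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  stopifnot(length(trees) >= 1)
  taxa <- sort(unique(unlist(lapply(trees, function(t) t$tip.label))))
  n <- length(taxa)
  acc <- matrix(0, n, n, dimnames = list(taxa, taxa))
  cnt <- matrix(0, n, n, dimnames = list(taxa, taxa))
  skipped <- 0L
  for (tr in trees) {
    if (!outgroup %in% tr$tip.label) { skipped <- skipped + 1L; next }
    rt <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    nt <- length(rt$tip.label)
    root <- nt + 1L
    depth <- integer(nt + rt$Nnode)
    pre <- rt$edge[order(rt$edge[, 1]), , drop = FALSE]
    # breadth of traversal: edges of a phylo are parent-before-child when
    # taken from the root; compute depth by repeated sweeps
    repeat {
      d_old <- depth
      depth[rt$edge[, 2]] <- depth[rt$edge[, 1]] + 1L
      if (identical(d_old, depth)) break
    }
    rank <- nt - depth
    mr <- ape::mrca(rt)
    labs <- rt$tip.label
    dmat <- 2 * matrix(rank[mr], nt, nt, dimnames = list(labs, labs))
    diag(dmat) <- 0
    acc[labs, labs] <- acc[labs, labs] + dmat
    cnt[labs, labs] <- cnt[labs, labs] + 1
  }
  if (all(cnt == 0)) stop("no gene tree contains the outgroup '", outgroup, "'")
  avg <- acc / pmax(cnt, 1)
  diag(avg) <- 0
  sp <- nj_tree(avg)
  sp <- ape::root(sp, outgroup = outgroup, resolve.root = TRUE)
  attr(sp, "n_skipped") <- skipped
  sp
}
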