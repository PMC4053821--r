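#' Polarize genotypes against an outgroup
#'
#' Recodes a site-by-taxon matrix of allele codes into derived-allele
#' indicators: the outgroup's allele defines the ancestral state A, any
#' other allele the derived state B. Sites where the outgroup is missing
#' are dropped.
#'
#' @param geno matrix with one column per taxon (columns named), any atomic
#'   allele coding (0/1 integers, bases, ...). One allele per taxon
#'   (pseudo-haploid representation).
#' @param outgroup column name of the outgroup.
#' @return an integer 0/1 matrix (outgroup column all 0) with attributes
#'   `kept` (row indices retained) and `n_dropped`.
#' @export
polarize <- function(geno, outgroup) {
  stopifnot(is.matrix(geno), outgroup %in% colnames(geno))
  og <- geno[, outgroup]
  keep <- !is.na(og)
  out <- matrix(0L, sum(keep), ncol(geno), dimnames = list(NULL, colnames(geno)))
  ogk <- og[keep]
  for (j in seq_len(ncol(geno))) {
    v <- geno[keep, j]
    out[, j] <- ifelse(is.na(v), NA_integer_, as.integer(v != ogk))
  }
  attr(out, "kept") <- which(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Enumerate quartet configurations
#'
#' Lists the `(((P1,P2),P3),O)` configurations to test. Without a guide
#' tree, every ordered choice of `P3` from each ingroup triple is emitted
#' (one configuration per unordered `(P1,P2)` pair, since swapping P1 and
#' P2 only flips the sign of D), giving `3 * choose(n, 3)` configurations
#' for `n` ingroup taxa. With a guide species tree, only the configuration
#' consistent with the tree is kept for each triple (`P1`,`P2` the pair
#' with the most recent common ancestor), giving `choose(n, 3)`.
#'
#' @param taxa ingroup taxon labels (the outgroup, if present, is removed).
#' @param outgroup outgroup label; never appears as P1/P2/P3.
#' @param tree optional guide topology: an [ape::phylo] or a
#'   [species_tree_model()].
#' @return a data frame with columns `P1`, `P2`, `P3`, `O`.
#' @export
all_quartets <- function(taxa, outgroup, tree = NULL) {
  taxa <- setdiff(taxa, outgroup)
  if (length(taxa) < 3) stop("need at least 3 ingroup taxa")
  trips <- utils::combn(sort(taxa), 3)
  node_time <- NULL
  phy <- NULL
  if (!is.null(tree)) {
    if (inherits(tree, "species_tree_model")) tree <- tree$tree
    stopifnot(inherits(tree, "phylo"))
    phy <- tree
    depth <- ape::node.depth.edgelength(phy)
    node_time <- max(depth) - depth
  }
  rows <- list()
  for (k in seq_len(ncol(trips))) {
    tr <- trips[, k]
    if (is.null(phy)) {
      for (i in 1:3) {
        pair <- sort(tr[-i])
        rows[[length(rows) + 1L]] <- c(pair[1], pair[2], tr[i])
      }
    } else {
      mr <- ape::mrca(phy)
      tt <- c(node_time[mr[tr[1], tr[2]]], node_time[mr[tr[1], tr[3]]],
              node_time[mr[tr[2], tr[3]]])
      i3 <- c(3L, 2L, 1L)[which.min(tt)]  # taxon excluded from the closest pair
      pair <- sort(tr[-i3])
      rows[[length(rows) + 1L]] <- c(pair[1], pair[2], tr[i3])
    }
  }
  m <- do.call(rbind, rows)
  data.frame(P1 = m[, 1], P2 = m[, 2], P3 = m[, 3], O = outgroup,
             stringsAsFactors = FALSE)
}

#' Count ABBA/BABA site patterns for one quartet
#'
#' Counts, over a derived-allele matrix polarized against the outgroup, the
#' sites where P2 and P3 share the derived allele (ABBA) and where P1 and
#' P3 share it (BABA), keeping per-block tallies for the jackknife. Sites
#' with a missing genotype in any of the four taxa are skipped.
#'
#' @param derived site-by-taxon matrix of 0/1 derived indicators (or raw
#'   allele codes; states are compared to the outgroup column).
#' @param quartet character vector `c(P1, P2, P3, O)` of column names, or a
#'   one-row data frame as produced by [all_quartets()].
#' @param block integer vector assigning every site to a jackknife block
#'   (`1..n_block`); must cover all sites (no `NA`).
#' @return an object of class `site_pattern_counts`: totals `nABBA`,
#'   `nBABA`, a per-block data frame, and the quartet.
#' @export
count_patterns <- function(derived, quartet, block) {
  if (is.data.frame(quartet)) quartet <- unlist(quartet[1, c("P1", "P2", "P3", "O")])
  quartet <- as.character(quartet)
  stopifnot(length(quartet) == 4, all(quartet %in% colnames(derived)),
            length(block) == nrow(derived))
  if (anyNA(block)) stop("block partition must be exhaustive: NA block for some sites")
  block <- as.integer(block)
  nb <- max(block, 1L)
  q <- matrix(match(quartet, colnames(derived)), 1)
  res <- cpp_count_patterns(.as_int_matrix(derived), block, nb, q)
  blocks <- data.frame(block = seq_len(nb), abba = res$abba[, 1], baba = res$baba[, 1],
                       n_sites = tabulate(block, nb))
  structure(list(nABBA = sum(blocks$abba), nBABA = sum(blocks$baba),
                 blocks = blocks, quartet = quartet),
            class = "site_pattern_counts")
}

.as_int_matrix <- function(m) {
  if (is.integer(m)) return(m)
  if (is.numeric(m)) { storage.mode(m) <- "integer"; return(m) }
  # factor-code character alleles
  lev <- sort(unique(as.vector(m[!is.na(m)])))
  out <- matrix(match(as.vector(m), lev), nrow(m), ncol(m),
                dimnames = dimnames(m))
  storage.mode(out) <- "integer"
  out
}

#' @export
print.site_pattern_counts <- function(x, ...) {
  cat(sprintf("Site patterns for (((%s,%s),%s),%s): ABBA = %g, BABA = %g over %d blocks\n",
              x$quartet[1], x$quartet[2], x$quartet[3], x$quartet[4],
              x$nABBA, x$nBABA, nrow(x$blocks)))
  invisible(x)
}

#' The D statistic
#'
#' `D = (nABBA - nBABA) / (nABBA + nBABA)`. Returns `NA` (not 0) when there
#' are no informative sites.
#'
#' @param counts a `site_pattern_counts` object, or a numeric vector
#'   `c(nABBA, nBABA)`.
#' @return a single number in `[-1, 1]`, or `NA`.
#' @export
d_statistic <- function(counts) {
  if (inherits(counts, "site_pattern_counts"))
    counts <- c(counts$nABBA, counts$nBABA)
  tot <- counts[1] + counts[2]
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  unname((counts[1] - counts[2]) / tot)
}

# Weighted delete-one block jackknife over per-block ABBA/BABA matrices
# (blocks x quartets). Busing-style estimator with block weights `w`
# proportional to each block's genomic span; with the equal-span blocks
# used throughout the package this is exactly the unweighted delete-one
# formula over all blocks. Weights are deliberately *fixed* quantities
# (spans), never informative-site counts: random, outcome-correlated
# weights demonstrably deflate the variance estimate, and fixed weights
# keep D and SE pure functions of the pattern counts (so singleton
# perturbations cannot move a call). A quartet whose informative sites
# all fall in one block gets SE = NA (flagged).
.weighted_jackknife <- function(abba, baba, w = NULL) {
  K <- ncol(abba); nB <- nrow(abba)
  if (is.null(w)) w <- rep(1, nB)
  stopifnot(length(w) == nB)
  A <- colSums(abba); Bc <- colSums(baba); tot <- A + Bc
  D <- ifelse(tot > 0, (A - Bc) / tot, NA_real_)
  nb <- abba + baba
  totm <- matrix(tot, nB, K, byrow = TRUE)
  num <- matrix(A - Bc, nB, K, byrow = TRUE) - (abba - baba)
  den <- totm - nb
  wm <- matrix(w, nB, K)
  valid <- wm > 0 & den > 0
  Dm <- matrix(NA_real_, nB, K)
  Dm[valid] <- num[valid] / den[valid]
  N <- colSums(valid)
  n <- colSums(wm * valid)
  h <- matrix(n, nB, K, byrow = TRUE) / wm
  w1 <- 1 - wm / matrix(n, nB, K, byrow = TRUE)
  sum1 <- colSums(ifelse(valid, w1 * Dm, 0))
  thetaJ <- N * D - sum1
  Dmat <- matrix(D, nB, K, byrow = TRUE)
  tJm <- matrix(thetaJ, nB, K, byrow = TRUE)
  term <- (h * Dmat - (h - 1) * Dm - tJm)^2 / (h - 1)
  varJ <- colSums(ifelse(valid, term, 0)) / N
  SE <- sqrt(pmax(varJ, 0))
  SE[N < 2] <- NA_real_
  Z <- D / SE
  p <- 2 * stats::pnorm(-abs(Z))
  list(D = D, SE = SE, Z = Z, p = p, n_blocks = N, n_sites = tot)
}

#' Weighted block-jackknife standard error for D
#'
#' Delete-one-block jackknife over contiguous genomic blocks, with blocks
#' weighted by their informative-site counts; `Z = D / SE` and a two-sided
#' p-value from the standard normal. With equal per-block counts this
#' reduces exactly to the unweighted delete-one jackknife.
#'
#' @param counts a `site_pattern_counts` object (see [count_patterns()]).
#' @return a list `D`, `SE`, `Z`, `p`, `n_blocks` (blocks with informative
#'   sites), `n_sites`. `SE` is `NA` when fewer than two blocks carry
#'   informative sites.
#' @export
block_jackknife <- function(counts) {
  stopifnot(inherits(counts, "site_pattern_counts"))
  r <- .weighted_jackknife(cbind(counts$blocks$abba), cbind(counts$blocks$baba))
  lapply(r, `[[`, 1)
}

#' Bonferroni correction
#'
#' Multiplies p-values by the number of tests and caps at 1 — the simple
#' family-wise control used when scanning every quartet configuration.
#'
#' @param p numeric vector of raw p-values.
#' @param m number of tests (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' Fit D statistics over quartet configurations
#'
#' The central fitting function of the package: counts ABBA/BABA site
#' patterns for a set of quartet configurations against a designated
#' outgroup, computes `D = (ABBA - BABA)/(ABBA + BABA)` per quartet, a
#' weighted block-jackknife standard error, `Z = D/SE`, a two-sided normal
#' p-value, and Bonferroni-adjusted p-values over all configurations
#' tested. Significant positive D indicates excess derived-allele sharing
#' between P2 and P3 (and negative between P1 and P3) beyond what
#' incomplete lineage sorting alone can produce.
#'
#' @param x a `genome_sim` object (see [simulate_genome()]) or a
#'   site-by-taxon genotype matrix with named columns.
#' @param outgroup outgroup label (defaults to the simulation outgroup).
#' @param quartets data frame `P1,P2,P3,O` (default: [all_quartets()] over
#'   the ingroup, constrained by `tree` if given).
#' @param tree optional guide topology passed to [all_quartets()].
#' @param blocks jackknife block assignment: `"window"` (one block per
#'   simulated window; the windows are unlinked by construction) or
#'   `"size"` to cut blocks of `block_size` bp from the coordinates.
#' @param block_size block length in bp when `blocks = "size"` (default
#'   5 Mb, comfortably above typical linkage scales).
#' @param mode `"pseudohaploid"` (one sampled allele per taxon per site;
#'   deterministic under `seed`) or `"frequency"` (sites contribute
#'   fractional pattern weights from derived-allele frequencies).
#' @param alpha significance level applied to the Bonferroni-adjusted
#'   p-values (default 0.01).
#' @param seed optional integer seed (governs pseudo-haploid sampling).
#' @param pos,chrom site coordinates (matrix method only; `pos` required
#'   when `blocks = "size"`).
#' @param ... passed between methods.
#' @return an object of class `dstat` with a `results` data frame
#'   (`P1,P2,P3,O,nABBA,nBABA,D,SE,Z,p,p_bonf,n_blocks,n_sites`) and
#'   metadata; see [print.dstat()], [summary.dstat()], [coef.dstat()],
#'   [plot.dstat()].
#' @examples
#' m <- example_species_tree(4)
#' g <- simulate_genome(m, n_windows = 200, window_len = 5000, seed = 1)
#' fit <- dstat(g, tree = m)
#' fit
#' @export
dstat <- function(x, ...) UseMethod("dstat")

#' @rdname dstat
#' @export
dstat.genome_sim <- function(x, outgroup = x$outgroup, quartets = NULL,
                             tree = NULL, blocks = c("window", "size"),
                             block_size = 5e6,
                             mode = c("pseudohaploid", "frequency"),
                             alpha = 0.01, seed = NULL, ...) {
  blocks <- match.arg(blocks)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(quartets)) quartets <- all_quartets(x$taxa, outgroup, tree)
  if (blocks == "window") {
    block <- as.integer(x$window)
    n_block <- x$n_windows
  } else {
    block <- as.integer(x$pos %/% block_size) + 1L
    n_block <- max(block)
  }
  if (mode == "pseudohaploid") {
    geno <- pseudo_haploid(x)
    .dstat_fit(geno, block, n_block, quartets, alpha, mode, match.call())
  } else {
    ploidy_n <- if (x$ploidy == "diploid") 2 else 1
    freq <- genotypes(x) / ploidy_n
    .dstat_fit_freq(freq, block, n_block, quartets, alpha, match.call())
  }
}

#' @rdname dstat
#' @export
dstat.matrix <- function(x, outgroup, quartets = NULL, tree = NULL,
                         blocks = c("size", "window"), block_size = 5e6,
                         mode = c("pseudohaploid", "frequency"),
                         alpha = 0.01, seed = NULL, pos = NULL, chrom = NULL, ...) {
  blocks <- match.arg(blocks)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(quartets))
    quartets <- all_quartets(colnames(x), outgroup, tree)
  if (is.null(pos)) {
    block <- rep(1L, nrow(x))
    n_block <- 1L
  } else {
    if (is.null(chrom)) chrom <- rep("chr", nrow(x))
    key <- paste(chrom, pos %/% block_size)
    block <- as.integer(factor(key, levels = unique(key)))
    n_block <- max(block)
  }
  if (mode == "frequency") {
    .dstat_fit_freq(x, block, n_block, quartets, alpha, match.call())
  } else {
    .dstat_fit(x, block, n_block, quartets, alpha, mode, match.call())
  }
}

.quartet_index <- function(quartets, taxa) {
  q <- cbind(match(quartets$P1, taxa), match(quartets$P2, taxa),
             match(quartets$P3, taxa), match(quartets$O, taxa))
  if (anyNA(q)) stop("quartet references a taxon absent from the genotype matrix")
  storage.mode(q) <- "integer"
  q
}

.dstat_fit <- function(geno, block, n_block, quartets, alpha, mode, call) {
  q <- .quartet_index(quartets, colnames(geno))
  res <- cpp_count_patterns(.as_int_matrix(geno), block, n_block, q)
  .dstat_finish(res, quartets, alpha, mode, call, n_block)
}

.dstat_fit_freq <- function(freq, block, n_block, quartets, alpha, call) {
  # polarize frequencies so the outgroup column is (near) ancestral:
  # fold any site where the outgroup derived frequency exceeds 1/2
  q <- .quartet_index(quartets, colnames(freq))
  og_cols <- unique(q[, 4])
  f <- freq
  for (oc in og_cols) {
    flip <- !is.na(f[, oc]) & f[, oc] > 0.5
    if (any(flip)) f[flip, ] <- 1 - f[flip, ]
  }
  res <- cpp_count_patterns_freq(f, block, n_block, q)
  .dstat_finish(res, quartets, alpha, "frequency", call, n_block)
}

.dstat_finish <- function(res, quartets, alpha, mode, call, n_block, w = NULL) {
  jk <- .weighted_jackknife(res$abba, res$baba, w)
  m <- nrow(quartets)
  results <- data.frame(
    quartets[, c("P1", "P2", "P3", "O")],
    nABBA = colSums(res$abba), nBABA = colSums(res$baba),
    D = jk$D, SE = jk$SE, Z = jk$Z, p = jk$p,
    p_bonf = bonferroni(jk$p, m), n_blocks = jk$n_blocks, n_sites = jk$n_sites,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = results, m = m, alpha = alpha, mode = mode,
                 n_block = n_block, call = call,
                 block_abba = res$abba, block_baba = res$baba),
            class = "dstat")
}

#' Admixture-fraction estimate from derived-allele excess
#'
#' Estimates the fraction of the recipient genome contributed by the donor
#' as the ratio of two derived-allele excess sums,
#' `f = S(P1, P2, D1, O) / S(P1, D2, D1, O)` with `S = nABBA - nBABA`:
#' the observed excess sharing of the recipient `P2` with one donor
#' lineage, normalized by the excess a full donor (the donor's second
#' lineage standing in for `P2`) would show. The standard error comes from
#' the same weighted block jackknife applied to the ratio.
#'
#' @param x a `genome_sim` (diploid simulations supply the two donor
#'   lineages automatically) or a haplotype matrix with named columns.
#' @param p1 sister taxon of the recipient (no gene flow assumed into it).
#' @param p2 recipient taxon.
#' @param donor donor taxon; in a diploid `genome_sim` its two lineages are
#'   used as `D1`/`D2`, otherwise supply `donor2`.
#' @param outgroup outgroup label.
#' @param donor2 optional second donor-lineage column (matrix input, or
#'   haploid simulations with a duplicated donor population).
#' @param seed optional integer seed (pseudo-haploid sampling of non-donor
#'   taxa in diploid simulations).
#' @return an object of class `admixture_fraction`: `f`, `SE`, the two
#'   excess sums, and block bookkeeping. `f` is `NA` (flagged in `$note`)
#'   when the denominator excess is not positive.
#' @export
admixture_fraction <- function(x, p1, p2, donor, outgroup = NULL, donor2 = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "genome_sim")) {
    if (is.null(outgroup)) outgroup <- x$outgroup
    if (x$ploidy == "diploid") {
      geno <- pseudo_haploid(x)
      hap <- haplotypes(x)
      d1 <- paste0(donor, "_1"); d2 <- paste0(donor, "_2")
      geno <- cbind(geno[, c(p1, p2, outgroup), drop = FALSE],
                    hap[, c(d1, d2), drop = FALSE])
    } else {
      if (is.null(donor2)) stop("haploid simulation: supply 'donor2' (a second donor-lineage taxon)")
      d1 <- donor; d2 <- donor2
      geno <- haplotypes(x)[, c(p1, p2, outgroup, d1, d2), drop = FALSE]
    }
    block <- as.integer(x$window); n_block <- x$n_windows
  } else {
    stopifnot(is.matrix(x))
    if (is.null(outgroup)) stop("'outgroup' is required for matrix input")
    if (is.null(donor2)) stop("matrix input: supply 'donor2'")
    d1 <- donor; d2 <- donor2
    geno <- x
    block <- rep(1L, nrow(x)); n_block <- 1L
  }
  quart <- rbind(c(p1, p2, d1, outgroup), c(p1, d2, d1, outgroup))
  q <- .quartet_index(data.frame(P1 = quart[, 1], P2 = quart[, 2],
                                 P3 = quart[, 3], O = quart[, 4]),
                      colnames(geno))
  res <- cpp_count_patterns(.as_int_matrix(geno), block, n_block, q)
  s1b <- res$abba[, 1] - res$baba[, 1]
  s2b <- res$abba[, 2] - res$baba[, 2]
  S1 <- sum(s1b); S2 <- sum(s2b)
  wb <- rep(1, n_block)  # equal-span blocks
  note <- NULL
  N <- NA_integer_
  if (S2 <= 0) {
    f <- NA_real_; SE <- NA_real_
    note <- "denominator excess S(P1,D2,D1,O) is not positive; no usable donor signal"
  } else {
    f <- S1 / S2
    den <- S2 - s2b
    valid <- wb > 0 & den > 0
    N <- sum(valid)
    if (N < 2) {
      SE <- NA_real_
      note <- "fewer than two usable jackknife blocks"
    } else {
      n <- sum(wb[valid])
      fm <- (S1 - s1b[valid]) / den[valid]
      h <- n / wb[valid]
      thetaJ <- N * f - sum((1 - wb[valid] / n) * fm)
      varJ <- mean((h * f - (h - 1) * fm - thetaJ)^2 / (h - 1))
      SE <- sqrt(max(varJ, 0))
    }
  }
  structure(list(f = f, SE = SE, S_num = S1, S_den = S2,
                 p1 = p1, p2 = p2, donor = donor, outgroup = outgroup,
                 n_blocks = N, note = note),
            class = "admixture_fraction")
}

#' @export
print.admixture_fraction <- function(x, ...) {
  cat(sprintf("Admixture fraction %s -> %s (sister %s, outgroup %s)\n",
              x$donor, x$p2, x$p1, x$outgroup))
  if (is.na(x$f)) {
    cat("  f undefined:", x$note, "\n")
  } else {
    cat(sprintf("  f = %.4f (SE %.4f); excess sums %g / %g\n",
                x$f, x$SE, x$S_num, x$S_den))
  }
  invisible(x)
}
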