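#' Sample one gene tree under the multispecies coalescent
#'
#' Draws a single gene genealogy from the structured coalescent defined by a
#' species-tree model, optionally with directed admixture pulses. Lineages
#' within a population coalesce pairwise at rate `1/(2*Ne)` per generation;
#' at a pulse, each lineage currently on the recipient branch relocates to
#' the donor branch independently with probability `gamma`; at a speciation
#' (looking backwards), the two daughter populations merge.
#'
#' @param model a [species_tree_model()].
#' @param pulses a list of [admixture_pulse()] objects (or a single pulse).
#' @param ploidy `"haploid"` (one lineage per taxon) or `"diploid"` (two).
#' @param seed optional integer; when given, `set.seed(seed)` is called.
#' @return an [ape::phylo] gene tree, rooted, branch lengths in generations.
#' @examples
#' m <- example_species_tree(4)
#' tr <- sample_gene_tree(m, seed = 1)
#' @export
sample_gene_tree <- function(model, pulses = list(), ploidy = c("haploid", "diploid"),
                             seed = NULL) {
  ploidy <- match.arg(ploidy)
  if (!is.null(seed)) set.seed(seed)
  pl <- .encode_pulses(model, pulses)
  lin <- .lineages(model, ploidy)
  res <- cpp_simulate_genome(
    model$parent - 1L, model$node_time, model$Ne, lin$branch - 1L,
    pl$time, pl$from - 1L, pl$to - 1L, pl$gamma,
    lin$labels, 1L, 1, 0, 1L, 0, TRUE, FALSE)
  ape::read.tree(text = res$newick[1])
}

#' @rdname sample_gene_tree
#' @param object a [species_tree_model()] (for the `simulate` method).
#' @param nsim number of independent gene trees to draw.
#' @param ... passed on (`pulses`, `ploidy`).
#' @return `simulate()` returns an `ape::multiPhylo` of `nsim` gene trees.
#' @export
simulate.species_tree_model <- function(object, nsim = 1, seed = NULL, ...) {
  args <- list(...)
  pulses <- if (is.null(args$pulses)) list() else args$pulses
  ploidy <- if (is.null(args$ploidy)) "haploid" else args$ploidy
  if (!is.null(seed)) set.seed(seed)
  pl <- .encode_pulses(object, pulses)
  lin <- .lineages(object, ploidy)
  res <- cpp_simulate_genome(
    object$parent - 1L, object$node_time, object$Ne, lin$branch - 1L,
    pl$time, pl$from - 1L, pl$to - 1L, pl$gamma,
    lin$labels, as.integer(nsim), 1, 0, 1L, 0, TRUE, FALSE)
  trees <- ape::read.tree(text = paste(res$newick, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  trees
}

#' Drop infinite-sites mutations on a gene tree
#'
#' Places `Poisson(mu * length * branch_length)` mutations on each branch of
#' a gene tree; every mutation creates one biallelic site whose derived
#' allele is carried by exactly the leaves below it, at a distinct position
#' within the window.
#'
#' @param tree an [ape::phylo] with branch lengths in generations.
#' @param mu mutation rate per site per generation.
#' @param length window length in bp.
#' @param seed optional integer seed.
#' @return a list with `geno` (site x leaf 0/1 matrix, derived = 1, columns
#'   named by tip label) and `pos` (sorted 0-based positions).
#' @export
drop_mutations <- function(tree, mu, length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!is.null(seed)) set.seed(seed)
  ntip <- base::length(tree$tip.label)
  L <- as.integer(length)
  expected <- mu * L * sum(tree$edge.length)
  if (expected > L)
    stop("infinite-sites model exhausted: expected mutation count (",
         signif(expected, 4), ") exceeds window length ", L)
  nmut <- stats::rpois(nrow(tree$edge), mu * L * tree$edge.length)
  total <- sum(nmut)
  if (total > L) stop("infinite-sites model exhausted: drew more mutations than positions")
  geno <- matrix(0L, nrow = total, ncol = ntip,
                 dimnames = list(NULL, tree$tip.label))
  if (total > 0) {
    below <- .tips_below(tree)
    row <- 1L
    for (e in seq_len(nrow(tree$edge))) {
      if (nmut[e] == 0) next
      tips <- below[[tree$edge[e, 2]]]
      for (k in seq_len(nmut[e])) {
        geno[row, tips] <- 1L
        row <- row + 1L
      }
    }
    pos <- sort(sample.int(L, total) - 1L)
  } else pos <- integer(0)
  list(geno = geno, pos = pos)
}

# tip indices below each node (tips and internals), postorder accumulation
.tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- i
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge)))
    out[[tr$edge[e, 1]]] <- c(out[[tr$edge[e, 1]]], out[[tr$edge[e, 2]]])
  out
}

#' Simulate a windowed genome under the multispecies coalescent
#'
#' Generates `n_windows` genomic windows on one synthetic chromosome. Each
#' window carries an independent gene tree (free recombination between
#' windows, none within, unless sub-window recombination is enabled) and
#' infinite-sites mutations, concatenated into a haplotype matrix with
#' window provenance. Optionally records the gene trees and a per-window
#' recombination-rate covariate whose only role is to drive the number of
#' distinct gene trees per window through a monotone link, so that
#' recombination-vs-discordance correlation scans can be exercised.
#'
#' @inheritParams sample_gene_tree
#' @param n_windows number of windows.
#' @param window_len window length in bp.
#' @param trees record gene trees (as a [tree_set()]) with window provenance.
#' @param recomb `NULL` for one tree per window, or a list with elements
#'   `segments` (sub-windows per window, default 4), `rates` (per-window
#'   rates; default drawn log-normal with `meanlog`/`sdlog`) and `scale`:
#'   the gene tree is redrawn between consecutive sub-windows with
#'   probability `1 - exp(-scale * rate)`.
#' @return an object of class `genome_sim`: haplotype matrix (`$geno`, sites
#'   x lineages, 0 ancestral / 1 derived), site positions and window ids,
#'   window intervals (`$windows`), optional `$trees` and `$recomb` track,
#'   plus taxon bookkeeping.
#' @examples
#' m <- example_species_tree(4)
#' g <- simulate_genome(m, n_windows = 20, window_len = 5000, seed = 1)
#' g
#' @export
simulate_genome <- function(model, pulses = list(), n_windows = 100,
                            window_len = 5000, ploidy = c("haploid", "diploid"),
                            seed = NULL, trees = FALSE, recomb = NULL) {
  ploidy <- match.arg(ploidy)
  stopifnot(n_windows >= 1, window_len >= 1)
  if (!is.null(seed)) set.seed(seed)
  pl <- .encode_pulses(model, pulses)
  lin <- .lineages(model, ploidy)

  segments <- 1L
  change_p <- 0
  rates <- NULL
  if (!is.null(recomb)) {
    segments <- if (is.null(recomb$segments)) 4L else as.integer(recomb$segments)
    if (window_len %% segments != 0)
      stop("window_len must be divisible by recomb$segments")
    rates <- recomb$rates
    if (is.null(rates)) {
      meanlog <- if (is.null(recomb$meanlog)) 0 else recomb$meanlog
      sdlog <- if (is.null(recomb$sdlog)) 1 else recomb$sdlog
      rates <- stats::rlnorm(n_windows, meanlog, sdlog)
    }
    if (length(rates) != n_windows) stop("recomb$rates must have one value per window")
    scale <- if (is.null(recomb$scale)) 1 else recomb$scale
    change_p <- 1 - exp(-scale * rates)
  }

  res <- cpp_simulate_genome(
    model$parent - 1L, model$node_time, model$Ne, lin$branch - 1L,
    pl$time, pl$from - 1L, pl$to - 1L, pl$gamma,
    lin$labels, as.integer(n_windows), as.numeric(window_len), model$mu,
    segments, change_p, trees, TRUE)

  windows <- interval_set(data.frame(
    chrom = "sim1",
    start = (seq_len(n_windows) - 1) * window_len,
    end = seq_len(n_windows) * window_len))

  ts <- NULL
  if (trees) {
    phy <- ape::read.tree(text = paste(res$newick, collapse = "\n"))
    if (inherits(phy, "phylo")) phy <- structure(list(phy), class = "multiPhylo")
    ts <- tree_set(phy, data.frame(chrom = "sim1", start = res$tree_start,
                                   end = res$tree_end))
  }
  rtrack <- NULL
  if (!is.null(rates))
    rtrack <- data.frame(chrom = "sim1",
                         start = (seq_len(n_windows) - 1) * window_len,
                         end = seq_len(n_windows) * window_len,
                         rate = rates, n_trees = res$n_distinct)

  structure(
    list(geno = res$geno, pos = res$site_pos, window = res$site_window,
         windows = windows, trees = ts, recomb = rtrack,
         taxa = model$taxa, outgroup = model$outgroup, ploidy = ploidy,
         lineage_taxon = stats::setNames(lin$taxon, lin$labels),
         chrom = "sim1", length = n_windows * window_len,
         n_windows = n_windows, window_len = window_len),
    class = "genome_sim")
}

#' @export
print.genome_sim <- function(x, ...) {
  cat("Simulated genome (multispecies coalescent)\n")
  cat(sprintf("  %d taxa (%s ploidy%s), outgroup %s\n", length(x$taxa), x$ploidy,
              if (x$ploidy == "diploid") ", 2 lineages each" else "", x$outgroup))
  cat(sprintf("  %d windows x %s bp, %d segregating sites\n",
              x$n_windows, format(x$window_len, big.mark = ","), nrow(x$geno)))
  if (!is.null(x$trees)) cat(sprintf("  %d gene trees recorded\n", length(x$trees$trees)))
  if (!is.null(x$recomb)) cat("  recombination covariate attached\n")
  invisible(x)
}

#' Haplotype and genotype views of a simulated genome
#'
#' `haplotypes()` returns the site-by-lineage 0/1 matrix. `genotypes()`
#' collapses lineages to taxa: derived-allele dosage per site (0/1 for
#' haploid simulations, 0/1/2 for diploid; heterozygous sites are exactly
#' those where an individual's two lineages differ).
#'
#' @param x a `genome_sim`.
#' @return an integer matrix, sites in rows.
#' @export
haplotypes <- function(x) {
  stopifnot(inherits(x, "genome_sim"))
  x$geno
}

#' @rdname haplotypes
#' @export
genotypes <- function(x) {
  stopifnot(inherits(x, "genome_sim"))
  if (x$ploidy == "haploid") return(x$geno)
  taxa <- x$taxa
  out <- vapply(taxa, function(tx) {
    cols <- which(x$lineage_taxon == tx)
    as.integer(rowSums(x$geno[, cols, drop = FALSE]))
  }, integer(nrow(x$geno)))
  rownames(out) <- NULL
  out
}

#' Pseudo-haploid view of a simulated genome
#'
#' Samples one allele per taxon per site (relevant for diploid simulations;
#' a haploid genome is returned unchanged). This mirrors the common
#' practice of representing each sequenced individual by a single sampled
#' allele so that site-pattern counts are unambiguous.
#'
#' @param x a `genome_sim`.
#' @param seed optional integer seed.
#' @return a sites-by-taxa 0/1 integer matrix.
#' @export
pseudo_haploid <- function(x, seed = NULL) {
  stopifnot(inherits(x, "genome_sim"))
  if (x$ploidy == "haploid") return(x$geno)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x$geno)
  out <- vapply(x$taxa, function(tx) {
    cols <- which(x$lineage_taxon == tx)
    pick <- sample(cols, n, replace = TRUE)
    x$geno[cbind(seq_len(n), pick)]
  }, integer(n))
  rownames(out) <- NULL
  out
}

#' Inject independent singleton sequencing errors
#'
#' Adds per-taxon base-calling errors at a fixed per-site rate. Errors at
#' monomorphic positions create new singleton sites (one taxon derived, all
#' others ancestral) — the kind of error the ABBA-BABA counts are immune to
#' by construction, since an informative pattern needs the derived allele
#' in two taxa. With `where = "everywhere"` errors additionally hit
#' existing segregating sites and flip that taxon's allele there, modelling
#' a fully independent error process. Used to probe the robustness of
#' D-statistic significance calls to non-systematic sequencing error.
#'
#' @param x a `genome_sim` (haploid).
#' @param rate per-taxon per-site error rate.
#' @param where `"monomorphic"` (default: errors create singletons only) or
#'   `"everywhere"`.
#' @param seed optional integer seed.
#' @return a modified `genome_sim` with extra (and possibly flipped) sites.
#' @export
inject_singletons <- function(x, rate = 1e-4,
                              where = c("monomorphic", "everywhere"),
                              seed = NULL) {
  stopifnot(inherits(x, "genome_sim"))
  where <- match.arg(where)
  if (!is.null(seed)) set.seed(seed)
  geno <- x$geno
  n_lin <- ncol(geno)
  n_sites <- nrow(geno)
  if (where == "everywhere") {
    flips <- matrix(stats::runif(n_sites * n_lin) < rate, n_sites, n_lin)
    geno[flips] <- 1L - geno[flips]
  }
  # errors at monomorphic positions: new singletons
  n_mono <- x$length - n_sites
  new_pos <- integer(0); new_col <- integer(0)
  for (j in seq_len(n_lin)) {
    k <- stats::rbinom(1, max(n_mono, 0), rate)
    if (k > 0) {
      new_pos <- c(new_pos, sample.int(x$length, k) - 1L)
      new_col <- c(new_col, rep(j, k))
    }
  }
  if (length(new_pos)) {
    add <- matrix(0L, length(new_pos), n_lin, dimnames = list(NULL, colnames(geno)))
    add[cbind(seq_along(new_pos), new_col)] <- 1L
    geno <- rbind(geno, add)
    pos <- c(x$pos, new_pos)
    win <- c(x$window, pmin(x$n_windows, new_pos %/% x$window_len + 1L))
    ord <- order(pos)
    x$geno <- geno[ord, , drop = FALSE]
    x$pos <- pos[ord]
    x$window <- win[ord]
  } else {
    x$geno <- geno
  }
  x
}
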