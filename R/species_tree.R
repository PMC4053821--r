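#' Species-tree demographic model
#'
#' Bundles a rooted, ultrametric species tree (branch lengths in
#' generations), per-branch diploid effective population sizes, a per-site
#' per-generation mutation rate, and the designated outgroup into the model
#' object that drives all coalescent simulation in the package.
#'
#' Internally time runs backwards from the present in generations; a branch
#' of duration `t` over a population of size `Ne` spans `t / (2 * Ne)`
#' coalescent units. The outgroup must be a tip attached directly at the
#' root, mirroring the usual design of quartet-based introgression panels.
#'
#' @param tree an [ape::phylo] object (or a Newick string), rooted, binary,
#'   ultrametric, with branch lengths in generations.
#' @param Ne diploid effective population size; either a single number used
#'   for every branch, or a vector with one entry per node of `tree` (in ape
#'   node order, tips first) giving the size of the population on the branch
#'   above that node. The root entry is the size of the ancestral population
#'   extending beyond the root.
#' @param mu mutation rate per site per generation.
#' @param outgroup tip label of the outgroup.
#' @return an object of class `species_tree_model`.
#' @examples
#' tr <- ape::read.tree(text = "(((P1:20000,P2:20000):20000,P3:40000):160000,O:200000);")
#' m <- species_tree_model(tr, Ne = 10000, mu = 1e-8, outgroup = "O")
#' m
#' @seealso [admixture_pulse()], [sample_gene_tree()], [simulate_genome()]
#' @export
species_tree_model <- function(tree, Ne, mu, outgroup) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object or Newick string")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths (generations)")
  if (anyDuplicated(tree$tip.label)) stop("taxon labels must be unique")
  ntip <- length(tree$tip.label)
  if (!ape::is.ultrametric(tree, tol = 1e-6)) stop("species tree must be ultrametric in time")
  if (!outgroup %in% tree$tip.label) stop("outgroup '", outgroup, "' is not a tip of the tree")
  root <- ntip + 1L
  og_tip <- match(outgroup, tree$tip.label)
  og_parent <- tree$edge[tree$edge[, 2] == og_tip, 1]
  if (og_parent != root) stop("the outgroup must attach directly at the root")

  n_node <- ntip + tree$Nnode
  if (length(Ne) == 1L) Ne <- rep(Ne, n_node)
  if (length(Ne) != n_node) stop("'Ne' must be scalar or one value per node (", n_node, ")")
  if (any(!is.finite(Ne)) || any(Ne <= 0)) stop("all Ne must be positive and finite")
  if (!is.finite(mu) || mu < 0) stop("'mu' must be a non-negative number")

  # node times, backwards from the present (tips at 0)
  depth <- ape::node.depth.edgelength(tree)
  node_time <- max(depth) - depth
  node_time[node_time < 1e-9 * max(node_time)] <- 0
  parent <- rep(NA_integer_, n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  structure(
    list(tree = tree, Ne = Ne, mu = mu, outgroup = outgroup,
         taxa = tree$tip.label, ingroup = setdiff(tree$tip.label, outgroup),
         node_time = node_time, parent = parent),
    class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("Species-tree coalescent model\n")
  cat("  taxa:    ", length(x$taxa), " (outgroup: ", x$outgroup, ")\n", sep = "")
  cat("  root age:", format(max(x$node_time), big.mark = ","), "generations\n")
  rng <- range(x$Ne)
  cat("  Ne:      ", if (rng[1] == rng[2]) format(rng[1]) else paste(rng, collapse = " - "), "\n")
  cat("  mu:      ", format(x$mu), "per site per generation\n")
  invisible(x)
}

#' Directed admixture pulse
#'
#' A single instantaneous gene-flow event of proportion `gamma` from a donor
#' lineage into a recipient lineage at a given time before present. In the
#' backwards-in-time coalescent, each ancestral lineage found on the
#' recipient branch at the pulse time traces back to the donor branch
#' independently with probability `gamma`.
#'
#' @param donor,recipient taxon labels; the pulse acts on the branch
#'   ancestral to each label that spans `time`.
#' @param time generations before present.
#' @param gamma admixture proportion in `[0, 1]`.
#' @return an object of class `admixture_pulse`.
#' @export
admixture_pulse <- function(donor, recipient, time, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop("'gamma' must be a single number in [0, 1]")
  if (!is.numeric(time) || length(time) != 1L || time < 0)
    stop("'time' must be a single non-negative number of generations")
  structure(list(donor = donor, recipient = recipient, time = time, gamma = gamma),
            class = "admixture_pulse")
}

#' @export
print.admixture_pulse <- function(x, ...) {
  cat(sprintf("Admixture pulse: %s -> %s, gamma = %g, at %s generations BP\n",
              x$donor, x$recipient, x$gamma, format(x$time, big.mark = ",")))
  invisible(x)
}

# Find the species-tree branch (identified by the node below it) ancestral
# to `taxon` that spans `time`. Errors if the time reaches the root branch
# only when allow_root = FALSE.
.spanning_branch <- function(model, taxon, time) {
  tip <- match(taxon, model$taxa)
  if (is.na(tip)) stop("pulse references unknown taxon '", taxon, "'")
  node <- tip
  while (!is.na(model$parent[node]) && model$node_time[model$parent[node]] <= time)
    node <- model$parent[node]
  if (is.na(model$parent[node]))
    stop("pulse time ", time, " predates the root of the species tree")
  node
}

# Resolve pulses to the flat arrays the C++ sampler consumes. Recipient
# lineages move to the donor branch backwards in time.
.encode_pulses <- function(model, pulses) {
  if (inherits(pulses, "admixture_pulse")) pulses <- list(pulses)
  if (length(pulses) == 0L)
    return(list(time = numeric(0), from = integer(0), to = integer(0), gamma = numeric(0)))
  for (p in pulses)
    if (!inherits(p, "admixture_pulse")) stop("each pulse must be an admixture_pulse object")
  tm <- vapply(pulses, `[[`, numeric(1), "time")
  if (any(tm %in% model$node_time[model$node_time > 0]))
    stop("pulse times must not coincide exactly with a speciation time")
  list(
    time = tm,
    from = vapply(seq_along(pulses), function(i)
      .spanning_branch(model, pulses[[i]]$recipient, tm[i]), integer(1)),
    to = vapply(seq_along(pulses), function(i)
      .spanning_branch(model, pulses[[i]]$donor, tm[i]), integer(1)),
    gamma = vapply(pulses, `[[`, numeric(1), "gamma"))
}

# Lineage bookkeeping: haploid samples one lineage per taxon, diploid two.
.lineages <- function(model, ploidy) {
  if (ploidy == "haploid") {
    list(labels = model$taxa, branch = seq_along(model$taxa),
         taxon = model$taxa)
  } else {
    n <- length(model$taxa)
    list(labels = paste0(rep(model$taxa, each = 2), c("_1", "_2")),
         branch = rep(seq_len(n), each = 2),
         taxon = rep(model$taxa, each = 2))
  }
}

#' Example species-tree model
#'
#' A ready-made model for demonstrations and simulation studies: a
#' ladder-with-cherries topology over `n` ingroup taxa plus an outgroup
#' attached at the root, with split times spread between one and several
#' coalescent units so that incomplete lineage sorting is present but the
#' species topology remains recoverable.
#'
#' @param n_ingroup number of ingroup taxa (labelled `P1`..`Pn`).
#' @param Ne diploid effective population size on every branch.
#' @param mu mutation rate per site per generation.
#' @param depth_units root age of the ingroup clade in coalescent units
#'   (`2 * Ne` generations each); the outgroup attaches at twice that age.
#' @return a [species_tree_model()].
#' @export
example_species_tree <- function(n_ingroup = 10, Ne = 10000, mu = 5e-9,
                                 depth_units = 6) {
  stopifnot(n_ingroup >= 2)
  unit <- 2 * Ne
  # ladder of splits, evenly spaced from 1 unit (shallowest) to depth_units
  times <- seq(1, depth_units, length.out = n_ingroup - 1) * unit
  labs <- paste0("P", seq_len(n_ingroup))
  nwk <- labs[1]
  h <- 0
  for (i in 2:n_ingroup) {
    t_i <- times[i - 1]
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, t_i - h, labs[i], t_i)
    h <- t_i
  }
  root_t <- 2 * depth_units * unit
  nwk <- sprintf("(%s:%g,O:%g);", nwk, root_t - h, root_t)
  species_tree_model(nwk, Ne = Ne, mu = mu, outgroup = "O")
}
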