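# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the package's own internals.

# positionwise interval membership over a small genome
oracle_positions <- function(iv, genome_len) {
  x <- logical(genome_len)  # position p covered <=> x[p + 1]
  for (i in seq_len(nrow(iv))) x[(iv$start[i] + 1):iv$end[i]] <- TRUE
  x
}

oracle_intersection <- function(sets, genome_len) {
  acc <- rep(TRUE, genome_len)
  for (s in sets) acc <- acc & oracle_positions(s, genome_len)
  acc
}

# per-site ABBA/BABA classification by direct pattern matching
oracle_patterns <- function(geno, p1, p2, p3, o) {
  nA <- nB <- 0L
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, c(p1, p2, p3, o)]
    if (anyNA(g)) next
    d <- g != g[4]
    if (d[3] && d[2] && !d[1]) nA <- nA + 1L
    if (d[3] && d[1] && !d[2]) nB <- nB + 1L
  }
  c(abba = nA, baba = nB)
}

# O(n^2) Kendall tau-b with tie correction, straight from the definition
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) { tx <- tx + 1; next }
    if (dy == 0) { ty <- ty + 1; next }
    if (dx == dy) conc <- conc + 1 else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# descendant tip sets per node from the edge matrix alone
oracle_descendants <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- vector("list", nn)
  grab <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    if (!is.null(out[[v]])) return(out[[v]])
    r <- unlist(lapply(kids[[as.character(v)]], grab))
    out[[v]] <<- r
    r
  }
  for (v in (n + 1):nn) grab(v)
  out
}

# non-trivial unrooted splits as canonical keys (side without the first
# taxon of the sorted universe)
oracle_splits <- function(tree, universe = sort(tree$tip.label)) {
  n <- length(universe)
  desc <- oracle_descendants(tree)
  keys <- character(0)
  for (v in (length(tree$tip.label) + 1):(length(tree$tip.label) + tree$Nnode)) {
    side <- desc[[v]]
    if (universe[1] %in% side) side <- setdiff(universe, side)
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  u <- sort(t1$tip.label)
  s1 <- oracle_splits(t1, u); s2 <- oracle_splits(t2, u)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# small species-tree models used across tests
quartet_model <- function(T_units = 1, Ne = 10000, mu = 5e-9, t12_units = 1,
                          og_units = 4) {
  u <- 2 * Ne
  t12 <- t12_units * u
  t123 <- t12 + T_units * u
  tO <- t123 + og_units * u
  nwk <- sprintf("(((P1:%.10g,P2:%.10g):%.10g,P3:%.10g):%.10g,O:%.10g);",
                 t12, t12, t123 - t12, t123, tO - t123, tO)
  species_tree_model(nwk, Ne = Ne, mu = mu, outgroup = "O")
}

# is the (P1,P2) cherry present in a rooted gene tree?
pair_is_clade <- function(tree, pair) {
  mr <- ape::getMRCA(tree, pair)
  length(ape::extract.clade(tree, mr)$tip.label) == 2
}

# minimal pileup row constructor
pileup_row <- function(pos, bases, bq, mq, ref = "A", chrom = "mt") {
  data.frame(chrom = chrom, pos = pos, ref = ref, depth = nchar(bases),
             bases = bases, bquals = intToUtf8(bq + 33L),
             mquals = paste(mq, collapse = ","), stringsAsFactors = FALSE)
}

random_interval_set <- function(genome_len, n = 30, max_gap = 1500,
                                chrom = "c1") {
  # callable-track-like: the genome minus n random gaps, so that even an
  # 11-way intersection keeps a workable fraction of positions
  gs <- sort(sample.int(genome_len - max_gap - 1, n))
  ge <- gs + sample.int(max_gap, n)
  covered <- rep(TRUE, genome_len)
  for (i in seq_len(n)) covered[(gs[i] + 1):ge[i]] <- FALSE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  interval_set(data.frame(chrom = chrom, start = starts[r$values],
                          end = ends[r$values]))
}

# canonical split keys of a tree, via the oracle enumerator
.bip_keys_for_test <- function(tree) {
  sort(gsub("\\|", ",", oracle_splits(tree)))
}
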