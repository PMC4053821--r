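---
title: "Models and methods behind dscan"
author: "dscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscan)
```

dscan asks a single scientific question in several forms: given whole-genome
data from a handful of closely related species plus an outgroup, how much of
the genome's history departs from a strictly bifurcating species tree, and
can that departure be attributed to gene flow rather than to incomplete
lineage sorting (ILS)? The package provides the estimator that answers it
(the ABBA-BABA D statistic with a block-jackknife error), the admixture
proportion that quantifies it, the site filters that make the input
trustworthy, and the gene-tree analytics that display the same discordance
from the phylogenetic side. Because the real sequencing data behind such
studies are large and external, every stage is also exercisable end to end
on genomes drawn from a bundled multispecies-coalescent (MSC) simulator
whose behaviour is checked against closed-form theory.

## The coalescent simulator

### Model

A `species_tree_model()` is a rooted, binary, ultrametric species tree with
branch lengths in *generations*, a diploid effective population size
$N_e$ on every branch (one value or one per branch), a per-site
per-generation mutation rate $\mu$, and a designated outgroup attached at
the root. Gene genealogies are drawn backwards in time under the structured
coalescent: within a population, each pair of lineages coalesces at rate
$1/(2N_e)$ per generation; at a speciation time the daughter populations
merge; the ancestral population above the root extends indefinitely. Time
conversions are explicit throughout: a branch of duration $t$ generations
spans $T = t/(2N_e)$ coalescent units.

An `admixture_pulse(donor, recipient, time, gamma)` is a single directed
gene-flow event: looking backwards, every lineage found on the recipient
branch at the pulse time relocates to the donor branch independently with
probability $\gamma \in [0,1]$. A pulse with $\gamma = 0$ consumes no
random numbers, so it is bit-for-bit a no-op under the same seed. Pulse
times may not coincide exactly with a speciation time (the ordering would
be ambiguous); the constructor rejects that configuration.

For the canonical four-taxon tree $(((P_1,P_2),P_3),O)$ with an internal
branch of $T$ coalescent units, MSC theory gives the probability that a
gene tree is discordant with the species tree as $\tfrac{2}{3}e^{-T}$.
The test suite and the acceptance script draw $10^4$ genealogies at
$T \in \{0.5, 1, 2\}$ and require agreement within three Monte-Carlo
standard errors — this closed form is the external yardstick for the
simulator's correctness.

### Mutations, windows, recombination

`simulate_genome()` tiles one synthetic chromosome with `n_windows` windows
of `window_len` bp. Windows are *unlinked*: each carries an independent
genealogy, and there is no recombination within a window unless sub-window
recombination is switched on. This mirrors the per-window tree model used
in windowed genome scans, and rests on the observation that topologies are
strongly autocorrelated over short physical distances, so intra-window
recombination mainly adds noise rather than bias. Mutations follow the
infinite-sites model — $\mathrm{Poisson}(\mu \cdot L \cdot b)$ mutations on
a branch of length $b$ generations, each creating one biallelic site at a
distinct position whose derived allele is carried by exactly the leaves
below it. Infinite sites is the right companion for D statistics, whose
site-pattern logic presumes single-origin biallelic variants; the simulator
refuses configurations whose expected mutation count exceeds the window
length. Ploidy is `"haploid"` (one lineage per taxon) or `"diploid"` (two
lineages; a genotype is heterozygous exactly when the two lineages
disagree).

The optional recombination covariate is generated, not mechanistic: each
window receives a rate $r_w$ (log-normal by default), each window is cut
into `segments` sub-windows, and the genealogy is redrawn between
consecutive sub-windows with probability $1 - e^{-c\,r_w}$. The only
purpose of this device is to give the correlation scans something real to
detect: windows with higher $r_w$ contain more distinct trees, hence a
larger mean pairwise Robinson-Foulds (RF) distance, so the rank correlation
between the rate track and the RF track must come out positive. The
covariate makes no claim about recombination biology beyond that monotone
link.

### What the simulator does and does not emulate

It reproduces the statistical structure the analysis relies on — ILS
controlled by branch lengths in coalescent units, directed introgression
of known proportion, windowed block structure, diploid heterozygosity, and
(at the pileup level) depth and quality noise with plantable artifacts. It
does not emulate read alignment, reference bias, CpG or repeat content,
selection, continuous migration, or intra-window linkage maps. Green tests
therefore certify the *estimators* under the model's assumptions; they do
not certify robustness to alignment artifacts in real data, which is
precisely why the site-filter module exists.

## Site filters

The filter chain reproduces a classic pileup-era workflow, with each
threshold's boundary semantics pinned by a test:

* **Genotype calls** (`call_genotypes()`): reads below base quality 20 or
  mapping quality 20 are discarded; a site with fewer than 3 passing reads
  is missing. The published workflows of this era leave the diploid
  decision rule unstated, so the package fixes a concrete one: a site is
  heterozygous if the minor allele has at least 2 passing reads *and* at
  least 20% of them, otherwise homozygous for the majority allele (ties
  broken alphabetically). The thresholds are arguments, the rule is
  documented, and the boundary case — exactly three passing reads — calls.
* **SNP clusters** (`filter_snp_artifacts()`): any window of 10 consecutive
  bp containing 3 or more called SNPs flags them all (a sliding, inclusive
  span: positions 100/105/109 span 10 bp and are all removed; 100/105/110
  survive). The conservative sliding reading was chosen because an anchored
  reading would depend on an arbitrary grid.
* **Indel proximity**: any SNP within 3 bp of an indel position, in either
  direction, is flagged; distance 3 is removed, distance 4 kept.
* **Bin acceptance** (`accept_bins()`): 1-kbp bins pass iff mean raw depth
  is *strictly under* twice the genome-wide average and at least 90% of
  positions carry a usable call. 899/1000 callable fails; depth exactly at
  the threshold fails. The genome-wide mean is computed per sample (whether
  the original workflow pooled samples is not recoverable from its
  description; per-sample is the reproducible choice and is exposed via
  `genome_mean`). A final partial bin is excluded: fixed-size bin
  statistics are not comparable on truncated bins.
* **Chaining** (`chain_bins()`): bins merge only when exactly adjacent
  (`end == start`); a 1-bp gap is not adjacency. The operation is
  idempotent.
* **Intersection and spans** (`intersect_samples()`, `select_spans()`):
  standard interval intersection across all samples (validated against a
  positionwise brute force), then regions of at least 5 kbp with strictly
  less than 10% missing data in every sample.
* **Effective coverage** (`effective_coverage()`, `filter_mt_sites()`):
  for organellar data with wildly variable depth, each read contributes
  $(1 - 10^{-mq/10})(1 - 10^{-bq/10})$ to its allele's effective coverage;
  a site is kept iff the major allele holds at least 70% of the total
  (inclusive). Worked values — one read at $q = mq = 20$ gives
  $0.99^2 = 0.9801$; a base quality of 0 nullifies a read — are asserted
  to $10^{-9}$.

The cluster and indel filters are pure predicates on the call set, so they
commute; flags accumulate across applications rather than being reset.

## The D statistic engine

### Counting and the fit object

`dstat()` is the package's central fitting function. Sites are polarized
against the outgroup (ancestral A = the outgroup allele; sites with a
missing outgroup are dropped), and for a quartet $(((P_1,P_2),P_3),O)$ the
engine counts ABBA sites ($P_2$ and $P_3$ share the derived allele) and
BABA sites ($P_1$ and $P_3$ share it). Under ILS alone the two patterns
are exchangeable — both require the $P_3$ lineage to meet $P_1$ or $P_2$
in their common ancestral population, where the two are symmetric — so

$$D = \frac{n_{ABBA} - n_{BABA}}{n_{ABBA} + n_{BABA}}$$

has expectation 0; a significant excess in either direction indicates gene
flow or cryptic structure. $D$ is reported as `NA`, never 0, when no
informative sites exist. Heterozygous genotypes are handled by
pseudo-haploid sampling (one seeded random allele per taxon per site,
deterministic under `seed`) or, optionally, by frequency weighting
($(1-p_1)p_2p_3(1-p_4)$ and $p_1(1-p_2)p_3(1-p_4)$); the two agree exactly
on haploid data.

`all_quartets()` enumerates one configuration per unordered $(P_1,P_2)$
pair per ingroup triple — $3\binom{n}{3}$ configurations for $n$ ingroup
taxa (360 for 10), since swapping $P_1$ and $P_2$ only flips the sign of
$D$. With a guide species tree it keeps only the tree-consistent
configuration per triple ($P_1,P_2$ = the pair with the most recent
common ancestor; $\binom{n}{3}$ configurations). The distinction matters
for calibration studies: the null expectation $E[D] = 0$ holds only for
tree-consistent configurations — orderings that contradict the species
tree have $D \ne 0$ under pure ILS by construction — so the package's null
calibration checks (and any user replicating them) must use the
tree-constrained enumeration. Scans of *all* configurations remain the
right tool for data where the species tree itself is in doubt.

### The block jackknife

Neighbouring sites share genealogies, so site-wise binomial errors would be
badly anticonservative. The engine divides the genome into contiguous
blocks — by default one block per simulated window (the windows are
unlinked by construction), or fixed 5-Mb blocks when fitting a coordinate
matrix (comfortably above typical linkage scales; the size is exposed
because no universal value exists) — and uses a delete-one block jackknife:

$$\hat\theta_J = N\hat\theta - \sum_b (1 - w_b/n)\,\hat\theta_{(-b)},\qquad
\widehat{\mathrm{var}} = \frac{1}{N}\sum_b
\frac{(h_b\hat\theta - (h_b - 1)\hat\theta_{(-b)} - \hat\theta_J)^2}{h_b - 1},$$

with $h_b = n / w_b$ and block weights $w_b$ proportional to each block's
*genomic span*. With the equal-span blocks used throughout this reduces
exactly to the unweighted delete-one formula over all blocks. The choice
of span weights over informative-site-count weights is deliberate and was
settled empirically during development: informative-site counts are random
and positively correlated with a block's contribution to $D$, and using
them as weights deflates the standard error (the suite's calibration
study, 500 replicate null genomes of 5000 windows with 10 ingroup taxa,
is the check: the raw $|Z| > 1.96$ rate must land in $[0.025, 0.085]$ and
the $Z$ standard deviation in $[0.85, 1.15]$, which span weights achieve
and count weights did not). Fixed weights have a second virtue: $D$ and
its SE become pure functions of the pattern counts, so singleton
perturbations cannot move a call (below). A quartet whose informative
sites all fall in one block gets `SE = NA`, flagged rather than invented.
`Z = D/SE` and the two-sided normal p-value follow; a companion check
requires the mean jackknife SE to track the empirical standard deviation
of $D$ across 200 replicate genomes within a factor of $[0.8, 1.25]$.

### Multiple testing

Scanning every configuration multiplies opportunities for false positives,
and the correction used is the simplest one: each raw p-value is multiplied
by the number of D computations and capped at 1 (`bonferroni()`).
Significance calls apply the $\alpha = 0.01$ threshold to the *adjusted*
p-values — composing the stated correction with the stated threshold is the
only consistent reading, and it is what `print`, `summary` and `plot`
report. A family-wise property test confirms the expected conservatism on
null simulations.

### Robustness to singleton errors

An ABBA or BABA pattern needs the derived allele in two taxa, so a
sequencing error that creates a *singleton* (one taxon derived, all others
ancestral) can never contribute. `inject_singletons()` makes this claim
testable: at rate $10^{-4}$ per taxon per site it adds singleton sites at
monomorphic positions (the literal reading of "errors resulting in
singletons"), and the engine's counts, $D$, SE and Z are provably — and
the suite asserts, exactly — unchanged. A stricter variant
(`where = "everywhere"`) also flips alleles at existing segregating sites,
modelling a fully independent error process; such errors perturb $Z$ by
far less than the distance of any confident call from the $|Z| = 3$
threshold.

### Admixture fractions

`admixture_fraction()` estimates the proportion of the recipient genome
contributed by the donor as a ratio of derived-allele excesses,

$$\hat f = \frac{S(P_1, P_2, D_1, O)}{S(P_1, D_2, D_1, O)},\qquad
S = n_{ABBA} - n_{BABA},$$

where $D_1, D_2$ are the donor's two lineages (its phased pseudo-haplotypes
in a diploid simulation, or an explicit second donor taxon). The numerator
measures the recipient's observed excess sharing with the donor; the
denominator measures the excess a 100%-donor individual would show, so the
ratio estimates the admixed proportion $\gamma$. The standard error comes
from the same span-weighted delete-one jackknife applied to the ratio. A
non-positive denominator (no usable donor signal — e.g. the degenerate call
in which the donor also serves as the reference sister) is flagged
undefined rather than reported as 0. One caveat the interface cannot
enforce: if the *reference* taxon $P_1$ is chosen badly (a deep taxon as
reference with the recipient's true sister as "donor"), the ratio is a
well-defined shared-drift fraction, not an admixture proportion — choosing
$P_1$ as the recipient's non-admixed sister is the user's modelling
responsibility. Under the intended design the suite requires the mean
$\hat f$ over 100 replicate genomes with a $\gamma = 0.10$ pulse to land
in $[0.07, 0.13]$, and the mean $D$ to increase strictly over
$\gamma \in \{0, 0.05, 0.1, 0.2\}$.

## Gene-tree analytics

* **`nj_tree()`** is the deterministic per-window tree builder: pairwise
  p-distances, Jukes-Cantor corrected ($d = -\tfrac34\log(1 - \tfrac43 p)$,
  with an error naming the pair when $p \ge 0.75$), neighbor joining, taxa
  pre-sorted lexicographically so ties resolve identically. Maximum
  likelihood search is out of scope by design — the downstream statistics
  (frequencies, consensus, STAR, RF) are agnostic to the tree source, and
  externally inferred Newick trees drop in via `read_tree_set()`. Windowed
  alignments are usually stored variable-sites-only; the `n_invariant`
  argument restores the per-bp denominator, and `bootstrap_trees()`
  resamples the full column multiset (variable plus invariant) so
  bootstrap distances stay on the same scale.
* **`clade_frequencies()`** tabulates, for every clade (rooted) or
  non-trivial bipartition (unrooted) observed anywhere in a collection,
  the fraction of trees containing it.
* **`consensus_tree()`** is the extended majority-rule (greedy) frequency
  consensus: bipartitions sorted by decreasing frequency (ties broken
  lexicographically for determinism) are added when compatible with those
  already accepted; supports are the bipartition frequencies. The greedy
  flavour was chosen over strict majority rule because it yields a resolved
  tree whose node supports remain exactly the clade frequencies — the suite
  asserts the consensus bipartition set equals the greedy compatible prefix
  of the sorted list, and that regenerating frequencies from the inputs
  reproduces the supports.
* **`star_species_tree()`** implements the average-ranks species-tree
  method: each gene tree is rooted on the outgroup; the root receives rank
  $n$ (the taxon count) and every node one less than its parent; the
  distance between two taxa is twice the rank of their MRCA; ranks are
  averaged across gene trees and the topology read off by neighbor
  joining. Gene trees missing the outgroup are skipped with a count. The
  procedure is invariant to input order, and the suite requires it to
  recover the true topology in at least 95% of 50 replicates of 1000 gene
  trees at one-coalescent-unit internal branches.
* **`rf_distance()`** counts non-trivial bipartitions present in exactly
  one tree. Trees are treated as unrooted for RF and bipartition
  frequencies, rooted (by the outgroup) for clade tables and STAR —
  matching each procedure's mathematical requirement. The implementation
  is validated against an independent brute-force split enumeration on all
  pairs of 500 random six-taxon trees and cross-checked against
  phangorn's implementation.

One supermatrix-style utility question was left open by the original
windowed workflows: whether bins are drawn with or without replacement when
concatenating random bins into fixed-size alignments. Without replacement
is implemented (each bin used once), as "unique alignments" is most
naturally read that way.

## Genome scans

`divergence_track()` computes, per fixed-size window (1 Mb nominal), each
ingroup sample's divergence to the outgroup — differing sites over callable
sites, heterozygous genotypes counting $\tfrac12$ (the unbiased expectation
for a sampled allele; the convention is stated here because published
descriptions rarely state theirs) — averaged across samples. Windows with
no callable sites are `NA`, never 0. `rf_track()` averages the pairwise RF
distance over all tree pairs whose provenance falls in the window; windows
with fewer than two trees are `NA`. A final partial window is kept in each
track but flagged, and `kendall_tau()` excludes flagged and missing
windows before computing Kendall's $\tau_b$ (tie-corrected, p-value from
the tie-adjusted normal approximation, via R's own `cor.test`); an
all-tied track yields a flagged `NA` rather than a number. p-values here
are reported raw — these are single planned correlations, not a scanned
family. The suite checks $\tau_b$ exactly against an $O(n^2)$
concordant/discordant pair count and requires the churn-linked simulation
to produce $\tau > 0$ with $p < 0.01$ at 200 windows — the direction, not
the magnitude, is the assertion, since the magnitude depends on simulator
settings.

## Pipeline and reproducibility

`run_pipeline()` drives simulate → D statistics → tree analytics → scans
from one YAML configuration with one global seed. Per-stage seeds derive
deterministically from the global seed and the stage name (`stage_seed()`,
always below $2^{31}$); unknown configuration keys are rejected before any
stage runs; a failing stage aborts with its name and renames its partial
outputs `.partial`. The JSON manifest records parameters, seeds, package
version and an MD5 checksum per output, and a rerun with the same
configuration reproduces every checksum — the suite asserts this literally.
All randomness in the package flows through R's RNG, so `set.seed()` (or
the `seed` arguments) makes any result, including the C++ coalescent core,
bit-reproducible.

## Problem sizes used in validation

The validation studies run at: 500 replicate genomes × 5000 windows × 5 kbp
with 10 ingroup taxa for null calibration; 200 replicates for the SE/SD
comparison; 100 replicates × 10,000 windows (diploid) for admixture-fraction
recovery and 100 × 5000 per $\gamma$ for monotonicity; $10^4$ genealogies
per branch length for the discordance check; a 100-kbp pileup for the
filters; 500 (tests) / 200 (acceptance script) random six-taxon trees for
the RF cross-check; and 50 × 1000 gene trees for STAR. These sizes give
Monte-Carlo errors comfortably inside the asserted bands while keeping a
full run on one CPU in the minutes range.

## Known limitations

The simulator's free-recombination-between / no-recombination-within window
structure is an idealization; real windows are mosaics. The recombination
covariate is a generative device for correlation tests, not a recombination
model. Pseudo-haploid sampling discards within-individual information that
a genotype-likelihood treatment would keep. The $\hat f$ ratio assumes the
reference taxon is unadmixed and the donor's two lineages are exchangeable;
population-level panels (multiple individuals per taxon) are not modelled.
The filters operate on a simplified pileup text schema (explicit base
columns) rather than raw alignment formats, and no reference-bias or
mappability correction is attempted.
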