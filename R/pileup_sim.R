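#' Simulate a pileup with injected artifacts
#'
#' Generates a single-sample pileup over one synthetic chromosome: per-site
#' read depth is Poisson around the target coverage, read bases follow the
#' truth genotype with a per-read substitution error rate, and base and
#' mapping qualities are drawn from rounded normal distributions. Three
#' kinds of artifacts are injected with exact ground-truth labels so that
#' filter recall and precision are computable: clusters of three spurious
#' SNPs within 10 bp, spurious SNPs within 3 bp of an indel, and
#' high-depth (copy-number-like) segments whose depth is multiplied.
#' Injected SNP sites are planted cleanly (pure alternate-allele reads,
#' qualities at least 25, depth at least 5) so that their labels are exact
#' rather than probabilistic.
#'
#' @param length chromosome length in bp.
#' @param coverage target mean read depth.
#' @param error_rate per-read substitution error probability.
#' @param q_mean,q_sd,mq_mean,mq_sd base/mapping quality distributions.
#' @param snp_rate per-site probability of a true SNP.
#' @param het_frac fraction of true SNPs that are heterozygous.
#' @param n_clusters number of injected 3-SNP clusters.
#' @param n_indel_snps number of injected indel-adjacent SNPs.
#' @param n_high_depth,high_depth_mult,high_depth_len high-depth segments.
#' @param chrom chromosome name.
#' @param seed optional integer seed.
#' @return an object of class `pileup_sim`: `pileup` (data frame `chrom`,
#'   `pos`, `ref`, `depth`, `bases`, `bquals`, `mquals`), and `truth` with
#'   `snps`, `cluster_snps`, `indels`, `indel_snps`, `high_depth`.
#' @export
simulate_pileup <- function(length = 100000, coverage = 12, error_rate = 0.005,
                            q_mean = 32, q_sd = 4, mq_mean = 50, mq_sd = 8,
                            snp_rate = 5e-4, het_frac = 0.5,
                            n_clusters = 5, n_indel_snps = 5,
                            n_high_depth = 2, high_depth_mult = 2.2,
                            high_depth_len = 3000, chrom = "sim1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  bases4 <- c("A", "C", "G", "T")
  ref <- sample(bases4, L, replace = TRUE)

  # --- artifact placement, keeping anchors well separated -----------------
  n_anchor <- n_clusters + n_indel_snps + n_high_depth
  anchors <- integer(0)
  guard <- max(60, if (n_high_depth > 0) high_depth_len + 20 else 0)
  tries <- 0
  while (length(anchors) < n_anchor && tries < 10000) {
    cand <- sample.int(L - guard - 20L, 1) + 20L
    if (!length(anchors) || all(abs(cand - anchors) > guard))
      anchors <- c(anchors, cand)
    tries <- tries + 1
  }
  if (length(anchors) < n_anchor) stop("chromosome too short for the requested artifacts")
  cl_anchor <- anchors[seq_len(n_clusters)]
  id_anchor <- anchors[n_clusters + seq_len(n_indel_snps)]
  hd_anchor <- anchors[n_clusters + n_indel_snps + seq_len(n_high_depth)]

  cluster_snps <- sort(unlist(lapply(cl_anchor, function(p) p + c(0L, 4L, 9L))))
  indels <- sort(id_anchor)
  indel_snps <- sort(id_anchor + vapply(seq_along(id_anchor), function(i)
    sample(c(-3:-1, 1:3), 1), integer(1)))
  hd <- if (n_high_depth > 0)
    interval_set(data.frame(chrom = chrom, start = sort(hd_anchor) - 1L,
                            end = sort(hd_anchor) - 1L + high_depth_len))
  else interval_set(data.frame(chrom = character(0), start = integer(0), end = integer(0)))

  injected <- c(cluster_snps, indel_snps)

  # --- true SNPs, away from the injected machinery ------------------------
  snp_pos <- which(stats::runif(L) < snp_rate)
  near_inject <- vapply(snp_pos, function(p)
    any(abs(p - c(injected, indels)) <= 15), logical(1))
  snp_pos <- snp_pos[!near_inject]
  alt_of <- function(r) vapply(r, function(b) sample(setdiff(bases4, b), 1), "")
  snp_alt <- alt_of(ref[snp_pos])
  snp_het <- stats::runif(length(snp_pos)) < het_frac
  truth_snps <- data.frame(pos = snp_pos,
                           a1 = ifelse(snp_het, ref[snp_pos], snp_alt),
                           a2 = snp_alt)

  # --- depths -------------------------------------------------------------
  mult <- rep(1, L)
  if (nrow(hd)) for (i in seq_len(nrow(hd)))
    mult[(hd$start[i] + 1L):hd$end[i]] <- high_depth_mult
  depth <- stats::rpois(L, coverage * mult)
  depth[injected] <- pmax(depth[injected], 5L)

  # --- per-read data ------------------------------------------------------
  covered <- which(depth > 0)
  site_of <- rep.int(covered, depth[covered])
  nread <- length(site_of)
  # truth allele per site
  a1 <- ref; a2 <- ref
  a1[truth_snps$pos] <- truth_snps$a1; a2[truth_snps$pos] <- truth_snps$a2
  inj_alt <- alt_of(ref[injected])
  a1[injected] <- inj_alt; a2[injected] <- inj_alt
  pick2 <- stats::runif(nread) < 0.5
  base <- ifelse(pick2, a1[site_of], a2[site_of])
  err <- stats::runif(nread) < error_rate
  is_inj_read <- site_of %in% injected
  err[is_inj_read] <- FALSE
  if (any(err)) base[err] <- alt_of(base[err])
  bq <- pmin(pmax(as.integer(round(stats::rnorm(nread, q_mean, q_sd))), 2L), 41L)
  mq <- pmin(pmax(as.integer(round(stats::rnorm(nread, mq_mean, mq_sd))), 0L), 60L)
  bq[is_inj_read] <- pmax(bq[is_inj_read], 25L)
  mq[is_inj_read] <- pmax(mq[is_inj_read], 25L)

  sp <- factor(site_of, levels = covered)
  bases_str <- vapply(split(base, sp), paste, "", collapse = "")
  bq_str <- vapply(split(bq, sp), function(q) intToUtf8(q + 33L), "")
  mq_str <- vapply(split(mq, sp), paste, "", collapse = ",")

  pileup <- data.frame(chrom = chrom, pos = covered, ref = ref[covered],
                       depth = depth[covered], bases = unname(bases_str),
                       bquals = unname(bq_str), mquals = unname(mq_str),
                       stringsAsFactors = FALSE)
  structure(list(
    pileup = pileup,
    truth = list(snps = truth_snps, cluster_snps = cluster_snps,
                 indels = indels, indel_snps = indel_snps, high_depth = hd),
    params = list(length = L, coverage = coverage, error_rate = error_rate,
                  chrom = chrom)),
    class = "pileup_sim")
}

#' @export
print.pileup_sim <- function(x, ...) {
  cat(sprintf("Simulated pileup: %s bp at %gx, %d covered positions\n",
              format(x$params$length, big.mark = ","), x$params$coverage,
              nrow(x$pileup)))
  cat(sprintf("  truth: %d SNPs; injected: %d cluster SNPs, %d indel-adjacent SNPs, %d high-depth segment(s)\n",
              nrow(x$truth$snps), length(x$truth$cluster_snps),
              length(x$truth$indel_snps), nrow(x$truth$high_depth)))
  invisible(x)
}
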