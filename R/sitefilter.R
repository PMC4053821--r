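#' Call genotypes from pileup records
#'
#' Applies the classic pileup-era calling rule: reads with base quality
#' below `min_q` or mapping quality below `min_mq` are discarded; a site
#' with fewer than `min_depth` remaining reads is missing. Among passing
#' reads the site is called heterozygous when the minor allele is seen in
#' at least `het_frac` of reads and at least `het_min_reads` reads,
#' otherwise homozygous for the majority allele (ties broken
#' alphabetically).
#'
#' @param pileup a data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `depth`, `bases` (string of read base calls), `bquals` (phred+33
#'   string), `mquals` (comma-separated integers) — the layout written by
#'   [simulate_pileup()] and [write_pileup()].
#' @param min_depth minimum passing reads to call (default 3).
#' @param min_q,min_mq minimum base and mapping quality (default 20).
#' @param het_frac,het_min_reads heterozygote decision rule (defaults 0.2
#'   and 2).
#' @return a data frame of class `genotype_calls`: `chrom`, `pos`, `ref`,
#'   `a1`, `a2` (NA when missing), `depth_pass`, `flag_lowdepth`.
#' @export
call_genotypes <- function(pileup, min_depth = 3, min_q = 20, min_mq = 20,
                           het_frac = 0.2, het_min_reads = 2) {
  req <- c("chrom", "pos", "ref", "depth", "bases", "bquals", "mquals")
  stopifnot(is.data.frame(pileup), all(req %in% names(pileup)))
  n <- nrow(pileup)
  if (n > 1 && any(order(pileup$chrom, pileup$pos) != seq_len(n)))
    stop("pileup must be sorted by (chrom, pos)")
  if (any(nchar(pileup$bases) != pileup$depth) ||
      any(nchar(pileup$bquals) != pileup$depth) ||
      any(lengths(strsplit(pileup$mquals, ",", fixed = TRUE)) != pileup$depth))
    stop("depth does not match per-read vectors")
  base <- unlist(strsplit(pileup$bases, "", fixed = TRUE), use.names = FALSE)
  bq <- unlist(lapply(pileup$bquals, utf8ToInt), use.names = FALSE) - 33L
  mq <- as.integer(unlist(strsplit(pileup$mquals, ",", fixed = TRUE),
                          use.names = FALSE))
  if (any(bq < 0) || any(mq < 0)) stop("negative qualities in pileup")
  site <- rep.int(seq_len(n), pileup$depth)
  pass <- bq >= min_q & mq >= min_mq
  cnt <- table(factor(site[pass], levels = seq_len(n)), base[pass])
  cnt <- matrix(as.integer(cnt), n, ncol(cnt),
                dimnames = list(NULL, colnames(cnt)))
  alleles <- colnames(cnt)
  dp <- as.integer(rowSums(cnt))
  a1 <- a2 <- rep(NA_character_, n)
  called <- dp >= min_depth
  if (any(called) && length(alleles)) {
    top <- max.col(cnt, ties.method = "first")
    m1 <- cnt[cbind(seq_len(n), top)]
    tmp <- cnt
    tmp[cbind(seq_len(n), top)] <- -1L
    sec <- max.col(tmp, ties.method = "first")
    m2 <- tmp[cbind(seq_len(n), sec)]
    m2[m2 < 0] <- 0L
    het <- called & m2 >= het_min_reads & m2 / pmax(dp, 1L) >= het_frac
    hom <- called & !het
    a1[hom] <- a2[hom] <- alleles[top[hom]]
    if (any(het)) {
      pa <- alleles[top[het]]; pb <- alleles[sec[het]]
      a1[het] <- pmin(pa, pb); a2[het] <- pmax(pa, pb)
    }
  }
  out <- data.frame(chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
                    a1 = a1, a2 = a2, depth_pass = dp,
                    flag_lowdepth = dp < min_depth)
  class(out) <- c("genotype_calls", class(out))
  out
}

#' Flag SNP clusters and indel-proximal SNPs
#'
#' Implements the two positional artifact filters: any SNP belonging to a
#' run of `cluster_n` or more SNPs spanning at most `cluster_bp` bp
#' (sliding, inclusive span) is flagged `snpcluster`; any SNP within
#' `indel_bp` bp of an indel position (symmetric) is flagged `nearindel`.
#' A SNP here is any non-missing call with an allele differing from the
#' reference. The two flags are independent predicates on the call set, so
#' applying the filters in either order gives the same result.
#'
#' @param calls a `genotype_calls` data frame (see [call_genotypes()]).
#' @param indels integer vector of indel positions (leftmost affected
#'   position, same coordinate system as `calls$pos`).
#' @param cluster_n,cluster_bp cluster rule (defaults 3 SNPs within 10 bp).
#' @param indel_bp indel proximity (default 3 bp).
#' @return `calls` with logical columns `flag_snpcluster`, `flag_nearindel`
#'   added, and `is_snp` for reference.
#' @export
filter_snp_artifacts <- function(calls, indels = integer(0), cluster_n = 3,
                                 cluster_bp = 10, indel_bp = 3) {
  stopifnot(is.data.frame(calls))
  is_snp <- !is.na(calls$a1) & (calls$a1 != calls$ref | calls$a2 != calls$ref)
  flag_cluster <- logical(nrow(calls))
  flag_indel <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch & is_snp)
    pos <- calls$pos[idx]
    if (length(pos) >= cluster_n) {
      # any window of cluster_n consecutive SNPs with inclusive span <= cluster_bp
      for (i in seq_len(length(pos) - cluster_n + 1)) {
        j <- i + cluster_n - 1
        if (pos[j] - pos[i] <= cluster_bp - 1)
          flag_cluster[idx[i:j]] <- TRUE
      }
    }
    if (length(indels) && length(idx)) {
      near <- vapply(calls$pos[idx], function(p) any(abs(p - indels) <= indel_bp),
                     logical(1))
      flag_indel[idx[near]] <- TRUE
    }
  }
  # flags accumulate across applications: each filter is a pure predicate on
  # the call set, so applying them in any order gives the same result
  calls$is_snp <- is_snp
  calls$flag_snpcluster <- flag_cluster |
    (if (is.null(calls$flag_snpcluster)) FALSE else calls$flag_snpcluster)
  calls$flag_nearindel <- flag_indel |
    (if (is.null(calls$flag_nearindel)) FALSE else calls$flag_nearindel)
  calls
}

#' Accept fixed-size genomic bins
#'
#' Tiles each chromosome with `bin_size`-bp bins (the final partial bin is
#' excluded) and keeps a bin iff its mean raw read depth is strictly under
#' `max_depth_mult` times the genome-wide average and at least
#' `min_callable` of its positions carry a usable genotype call (non-missing
#' and not artifact-flagged).
#'
#' @param calls a `genotype_calls` data frame, ideally after
#'   [filter_snp_artifacts()]; positions absent from `calls` count as
#'   uncallable.
#' @param depths data frame `chrom`, `pos`, `depth` of raw per-position read
#'   depth; absent positions count as depth 0.
#' @param chrom_len named vector of chromosome lengths in bp.
#' @param bin_size bin width (default 1000).
#' @param max_depth_mult depth threshold multiplier (default 2; strict `<`).
#' @param min_callable minimum callable fraction (default 0.90; `>=`).
#' @param genome_mean optionally override the genome-wide mean depth
#'   (computed over all positions of `chrom_len` otherwise).
#' @return an [interval_set()] of accepted bins with metadata columns
#'   `mean_depth` and `callable_frac`.
#' @export
accept_bins <- function(calls, depths, chrom_len, bin_size = 1000,
                        max_depth_mult = 2, min_callable = 0.90,
                        genome_mean = NULL) {
  stopifnot(!is.null(names(chrom_len)))
  if (is.null(genome_mean))
    genome_mean <- sum(as.numeric(depths$depth)) / sum(as.numeric(chrom_len))
  callable <- !is.na(calls$a1)
  for (fl in c("flag_snpcluster", "flag_nearindel"))
    if (fl %in% names(calls)) callable <- callable & !calls[[fl]]
  out <- list()
  for (ch in names(chrom_len)) {
    n_bins <- chrom_len[[ch]] %/% bin_size
    if (n_bins < 1) next
    starts <- (seq_len(n_bins) - 1) * bin_size
    dsub <- depths[depths$chrom == ch & depths$pos <= n_bins * bin_size, ]
    bin_of_d <- (dsub$pos - 1) %/% bin_size + 1
    dsum <- numeric(n_bins)
    if (nrow(dsub)) {
      agg <- tapply(dsub$depth, bin_of_d, sum)
      dsum[as.integer(names(agg))] <- as.numeric(agg)
    }
    csub_pos <- calls$pos[calls$chrom == ch & callable & calls$pos <= n_bins * bin_size]
    csum <- numeric(n_bins)
    if (length(csub_pos)) {
      agg <- table((csub_pos - 1) %/% bin_size + 1)
      csum[as.integer(names(agg))] <- as.numeric(agg)
    }
    mean_depth <- dsum / bin_size
    callable_frac <- csum / bin_size
    keep <- mean_depth < max_depth_mult * genome_mean & callable_frac >= min_callable
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = starts[keep] + bin_size,
                              mean_depth = mean_depth[keep],
                              callable_frac = callable_frac[keep])
  }
  if (!length(out))
    return(interval_set(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0))))
  interval_set(do.call(rbind, out))
}

#' Per-allele effective coverage
#'
#' For each read the probability that both its mapping and its base call
#' are correct is `(1 - 10^(-mq/10)) * (1 - 10^(-bq/10))`; the effective
#' coverage of an allele at a position is the sum of that product over the
#' reads carrying the allele. Raising any read's quality never decreases
#' any allele's effective coverage.
#'
#' @param pileup a pileup data frame (see [call_genotypes()] for layout).
#' @return a data frame with one row per position: `chrom`, `pos`, one
#'   `C_<base>` column per observed allele, `major`, `major_frac`,
#'   `total_C`, `no_data`.
#' @export
effective_coverage <- function(pileup) {
  bases <- strsplit(pileup$bases, "", fixed = TRUE)
  bq <- lapply(pileup$bquals, function(s) utf8ToInt(s) - 33L)
  mq <- lapply(strsplit(pileup$mquals, ",", fixed = TRUE), as.integer)
  alleles <- sort(unique(unlist(bases)))
  n <- nrow(pileup)
  C <- matrix(0, n, length(alleles), dimnames = list(NULL, alleles))
  for (i in seq_len(n)) {
    if (!length(bases[[i]])) next
    w <- (1 - 10^(-mq[[i]] / 10)) * (1 - 10^(-bq[[i]] / 10))
    agg <- tapply(w, bases[[i]], sum)
    C[i, names(agg)] <- as.numeric(agg)
  }
  total <- rowSums(C)
  major <- rep(NA_character_, n)
  frac <- rep(NA_real_, n)
  pos_data <- total > 0
  if (any(pos_data)) {
    major[pos_data] <- alleles[max.col(C[pos_data, , drop = FALSE], ties.method = "first")]
    frac[pos_data] <- apply(C[pos_data, , drop = FALSE], 1, max) / total[pos_data]
  }
  out <- data.frame(chrom = pileup$chrom, pos = pileup$pos)
  for (a in alleles) out[[paste0("C_", a)]] <- C[, a]
  out$major <- major
  out$major_frac <- frac
  out$total_C <- total
  out$no_data <- !pos_data
  out
}

#' Filter sites by major-allele effective coverage
#'
#' Keeps a site iff the major allele's effective coverage represents at
#' least `min_major_frac` of the total effective coverage at the position
#' (default 70%). Sites with zero total effective coverage are filtered and
#' flagged as no-data. Designed for organellar data whose raw depth is too
#' variable for fixed depth cutoffs.
#'
#' @param pileup a pileup data frame.
#' @param min_major_frac threshold on the major-allele fraction (default
#'   0.70, inclusive).
#' @return the [effective_coverage()] table with a logical `kept` column.
#' @export
filter_mt_sites <- function(pileup, min_major_frac = 0.70) {
  ec <- effective_coverage(pileup)
  ec$kept <- !ec$no_data & ec$major_frac >= min_major_frac
  ec
}
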