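#' Windowed divergence to the outgroup
#'
#' Tiles the genome in fixed-size windows and computes, per window, each
#' ingroup sample's divergence to the outgroup (differing sites over
#' callable sites) and averages across samples. Heterozygous genotypes
#' count as half a difference in diploid data. Windows without callable
#' sites are missing (`NA`, never 0); a final partial window is kept in the
#' track but flagged so correlation scans can drop it.
#'
#' @param x a `genome_sim` object or a site-by-taxon dosage matrix.
#' @param outgroup outgroup column (defaults to the simulation outgroup).
#' @param window window size in bp (default 1 Mb).
#' @param pos,chrom_len site coordinates and total length (matrix input).
#' @param callable optional [interval_set()] restricting the denominator;
#'   by default every position of the genome is callable.
#' @param ploidy 1 or 2 alleles per genotype value (matrix input).
#' @return a `window_track` data frame: `chrom`, `start`, `end`, `value`,
#'   `n` (callable sites) and `partial`.
#' @export
divergence_track <- function(x, outgroup = NULL, window = 1e6, pos = NULL,
                             chrom_len = NULL, callable = NULL, ploidy = NULL) {
  if (inherits(x, "genome_sim")) {
    if (is.null(outgroup)) outgroup <- x$outgroup
    geno <- genotypes(x)
    pos <- x$pos
    chrom_len <- x$length
    if (is.null(ploidy)) ploidy <- if (x$ploidy == "diploid") 2 else 1
  } else {
    stopifnot(is.matrix(x), !is.null(pos), !is.null(chrom_len))
    geno <- x
    if (is.null(ploidy)) ploidy <- 1
  }
  stopifnot(outgroup %in% colnames(geno))
  samples <- setdiff(colnames(geno), outgroup)
  n_win <- ceiling(chrom_len / window)
  starts <- (seq_len(n_win) - 1) * window
  ends <- pmin(starts + window, chrom_len)
  win_of <- pmin(as.integer(pos %/% window) + 1L, n_win)
  # callable positions per window
  if (is.null(callable)) {
    n_call <- ends - starts
    site_ok <- rep(TRUE, length(pos))
  } else {
    callable <- interval_set(as.data.frame(callable)[c("chrom", "start", "end")])
    n_call <- numeric(n_win)
    for (i in seq_len(nrow(callable))) {
      s <- callable$start[i]; e <- callable$end[i]
      w1 <- as.integer(s %/% window) + 1L; w2 <- as.integer((e - 1) %/% window) + 1L
      for (w in w1:w2)
        n_call[w] <- n_call[w] + min(e, starts[w] + window) - max(s, starts[w])
    }
    site_ok <- vapply(pos, function(p) any(callable$start <= p & p < callable$end),
                      logical(1))
  }
  # per-sample differences to the outgroup: |dosage - dosage_out| / ploidy
  diff_sum <- numeric(n_win)
  for (sm in samples) {
    d <- abs(geno[site_ok, sm] - geno[site_ok, outgroup]) / ploidy
    agg <- tapply(d, win_of[site_ok], sum)
    tmp <- numeric(n_win)
    tmp[as.integer(names(agg))] <- as.numeric(agg)
    diff_sum <- diff_sum + tmp / length(samples)
  }
  value <- ifelse(n_call > 0, diff_sum / n_call, NA_real_)
  out <- data.frame(chrom = if (inherits(x, "genome_sim")) x$chrom else "chr",
                    start = starts, end = ends, value = value, n = n_call,
                    partial = ends - starts < window)
  class(out) <- c("window_track", class(out))
  out
}

#' Mean pairwise Robinson-Foulds distance per window
#'
#' For each fixed-size window, the mean [rf_distance()] over all unordered
#' pairs of gene trees whose provenance interval starts within the window.
#' Windows with fewer than two trees are missing.
#'
#' @param trees a [tree_set()] with window provenance.
#' @param window window size in bp (default 1 Mb).
#' @param chrom_len total length (defaults to the largest provenance end).
#' @return a `window_track` data frame (`value` = mean pairwise RF, `n` =
#'   number of trees in the window).
#' @export
rf_track <- function(trees, window = 1e6, chrom_len = NULL) {
  stopifnot(inherits(trees, "tree_set"), !is.null(trees$windows))
  prov <- trees$windows
  if (is.null(chrom_len)) chrom_len <- max(prov$end)
  n_win <- ceiling(chrom_len / window)
  starts <- (seq_len(n_win) - 1) * window
  ends <- pmin(starts + window, chrom_len)
  win_of <- pmin(as.integer(prov$start %/% window) + 1L, n_win)
  value <- rep(NA_real_, n_win)
  count <- integer(n_win)
  universe <- trees$taxa
  bip <- lapply(trees$trees, .bipartitions, universe = universe)
  for (w in seq_len(n_win)) {
    idx <- which(win_of == w)
    count[w] <- length(idx)
    if (length(idx) < 2) next
    tot <- 0; np <- 0
    for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1):length(idx)) {
      b1 <- bip[[idx[i]]]; b2 <- bip[[idx[j]]]
      tot <- tot + length(setdiff(b1, b2)) + length(setdiff(b2, b1))
      np <- np + 1
    }
    value[w] <- tot / np
  }
  out <- data.frame(chrom = prov$chrom[1], start = starts, end = ends,
                    value = value, n = count, partial = ends - starts < window)
  class(out) <- c("window_track", class(out))
  out
}

#' Aggregate a fine-grained track into scan windows
#'
#' Averages per-interval values (for example the simulator's per-window
#' recombination rates) over fixed-size windows, matching the layout of
#' [divergence_track()] / [rf_track()] so tracks can be correlated.
#'
#' @param track a data frame `chrom`, `start`, `end`, and a value column.
#' @param window window size in bp.
#' @param value name of the value column (default `"rate"`).
#' @param chrom_len total length (defaults to the largest `end`).
#' @return a `window_track`.
#' @export
aggregate_track <- function(track, window = 1e6, value = "rate",
                            chrom_len = NULL) {
  stopifnot(is.data.frame(track), value %in% names(track))
  if (is.null(chrom_len)) chrom_len <- max(track$end)
  n_win <- ceiling(chrom_len / window)
  starts <- (seq_len(n_win) - 1) * window
  ends <- pmin(starts + window, chrom_len)
  win_of <- pmin(as.integer(track$start %/% window) + 1L, n_win)
  agg <- tapply(track[[value]], win_of, mean)
  v <- rep(NA_real_, n_win)
  v[as.integer(names(agg))] <- as.numeric(agg)
  cnt <- integer(n_win)
  tab <- table(win_of)
  cnt[as.integer(names(tab))] <- as.integer(tab)
  out <- data.frame(chrom = track$chrom[1], start = starts, end = ends,
                    value = v, n = cnt, partial = ends - starts < window)
  class(out) <- c("window_track", class(out))
  out
}

#' Kendall rank correlation between two window tracks
#'
#' Kendall's tau-b (tie-corrected) between the values of two tracks over
#' the windows where both are non-missing, with the p-value from R's
#' tie-adjusted normal approximation. Partial windows are excluded, so the
#' correlation only compares windows of equal size.
#'
#' @param x,y `window_track` data frames on the same window grid.
#' @return an object of class `track_correlation`: `tau`, `p`, `n`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(inherits(x, "data.frame"), inherits(y, "data.frame"),
            nrow(x) == nrow(y))
  ok <- !is.na(x$value) & !is.na(y$value)
  if ("partial" %in% names(x)) ok <- ok & !x$partial
  if ("partial" %in% names(y)) ok <- ok & !y$partial
  if (sum(ok) < 2) stop("need at least 2 windows with both tracks non-missing")
  xv <- x$value[ok]; yv <- y$value[ok]
  if (length(unique(xv)) < 2 || length(unique(yv)) < 2)
    return(structure(list(tau = NA_real_, p = NA_real_, n = sum(ok),
                          note = "all values tied in one track"),
                     class = "track_correlation"))
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = "kendall"))
  structure(list(tau = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 note = NULL),
            class = "track_correlation")
}

#' @export
print.track_correlation <- function(x, ...) {
  if (is.na(x$tau)) {
    cat("Kendall correlation undefined:", x$note, "\n")
  } else {
    cat(sprintf("Kendall tau = %.3f, p = %.3g (n = %d windows)\n",
                x$tau, x$p, x$n))
  }
  invisible(x)
}
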