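#' Genomic interval sets (BED semantics)
#'
#' A thin validated container for 0-based half-open genomic intervals:
#' a data frame with columns `chrom`, `start`, `end` (plus optional
#' metadata columns), sorted and non-overlapping within each chromosome.
#'
#' @param x a data frame with columns `chrom`, `start`, `end`.
#' @return an object of class `interval_set` (still a data frame).
#' @export
interval_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (nrow(x)) {
    if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
    if (any(x$start < 0)) stop("intervals must have non-negative start")
    x <- x[order(x$chrom, x$start), , drop = FALSE]
    rownames(x) <- NULL
    for (ch in unique(x$chrom)) {
      s <- x[x$chrom == ch, ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("intervals overlap on chromosome ", ch)
    }
  }
  class(x) <- unique(c("interval_set", class(x)))
  x
}

# 0-based half-open -> IRanges (1-based closed) and back
.to_ir <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)
.from_ir <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = as.numeric(IRanges::start(ir) - 1L),
             end = as.numeric(IRanges::end(ir)))
}

#' Chain adjacent genomic bins
#'
#' Merges runs of exactly adjacent intervals (`end[i] == start[i+1]` on the
#' same chromosome) into single intervals; intervals separated by any gap
#' are left untouched. Idempotent.
#'
#' @param bins an [interval_set()].
#' @return an `interval_set` of chained intervals.
#' @export
chain_bins <- function(bins) {
  bins <- interval_set(as.data.frame(bins)[c("chrom", "start", "end")])
  if (!nrow(bins)) return(bins)
  out <- do.call(rbind, lapply(unique(bins$chrom), function(ch) {
    s <- bins[bins$chrom == ch, ]
    .from_ir(IRanges::reduce(.to_ir(s)), ch)
  }))
  interval_set(out)
}

#' Intersect callable regions across samples
#'
#' Positions retained are exactly those present in every sample's interval
#' set (standard multi-sample interval intersection). Commutative and
#' associative; the total retained length never exceeds the smallest input.
#'
#' @param sets a list of [interval_set()] objects, one per sample.
#' @return an `interval_set`.
#' @export
intersect_samples <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L || inherits(sets, "data.frame"))
    stop("'sets' must be a non-empty list of interval sets")
  sets <- lapply(sets, function(s) interval_set(as.data.frame(s)[c("chrom", "start", "end")]))
  acc <- sets[[1]]
  for (s in sets[-1]) {
    chroms <- intersect(unique(acc$chrom), unique(s$chrom))
    acc <- interval_set(do.call(rbind, c(list(data.frame(
      chrom = character(0), start = integer(0), end = integer(0))),
      lapply(chroms, function(ch) {
        ir <- IRanges::intersect(.to_ir(acc[acc$chrom == ch, ]),
                                 .to_ir(s[s$chrom == ch, ]))
        .from_ir(ir, ch)
      }))))
  }
  acc
}

#' Select long, well-covered spans
#'
#' Keeps regions at least `min_span` bp long whose missing-data fraction is
#' below `max_missing` in every sample. Missingness is supplied per sample
#' as interval sets of *callable* positions; the missing fraction of a
#' region for a sample is `1 - callable_overlap / width`.
#'
#' @param regions an [interval_set()] of candidate regions.
#' @param callable a list of per-sample `interval_set`s of callable positions.
#' @param min_span minimum region length in bp (default 5000).
#' @param max_missing strict upper bound on the per-sample missing fraction
#'   (default 0.10; a region with exactly 10% missing in some sample is
#'   dropped).
#' @return an `interval_set` of selected regions.
#' @export
select_spans <- function(regions, callable, min_span = 5000, max_missing = 0.10) {
  regions <- interval_set(as.data.frame(regions)[c("chrom", "start", "end")])
  if (!nrow(regions)) return(regions)
  width <- regions$end - regions$start
  keep <- width >= min_span
  for (s in callable) {
    s <- interval_set(as.data.frame(s)[c("chrom", "start", "end")])
    ov <- numeric(nrow(regions))
    for (ch in unique(regions$chrom)) {
      idx <- which(regions$chrom == ch)
      if (!length(idx)) next
      sc <- s[s$chrom == ch, ]
      ir_r <- .to_ir(regions[idx, ])
      ir_c <- .to_ir(sc)
      hits <- IRanges::findOverlaps(ir_r, ir_c)
      if (length(hits)) {
        w <- IRanges::width(IRanges::pintersect(
          ir_r[S4Vectors::queryHits(hits)], ir_c[S4Vectors::subjectHits(hits)]))
        agg <- tapply(w, S4Vectors::queryHits(hits), sum)
        tmp <- numeric(length(idx))
        tmp[as.integer(names(agg))] <- as.numeric(agg)
        ov[idx] <- tmp
      }
    }
    missing_frac <- (width - ov) / width
    keep <- keep & (missing_frac < max_missing)
  }
  interval_set(regions[keep, , drop = FALSE])
}
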