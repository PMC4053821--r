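#' Methods for fitted D-statistic objects
#'
#' `print` shows a compact overview; `summary` returns the full result
#' table together with the subset significant after Bonferroni control;
#' `coef` extracts the named vector of D values; `plot` draws D with
#' 2-standard-error bars, marking significant quartets.
#'
#' @param x,object a `dstat` fit (see [dstat()]).
#' @param ... unused.
#' @name dstat-methods
NULL

#' @rdname dstat-methods
#' @export
print.dstat <- function(x, ...) {
  r <- x$results
  sig <- !is.na(r$p_bonf) & r$p_bonf < x$alpha
  cat(sprintf("D-statistic fit: %d quartet configuration%s, %s counting, %d jackknife blocks\n",
              x$m, if (x$m == 1) "" else "s", x$mode, x$n_block))
  cat(sprintf("  significant at Bonferroni-adjusted p < %g: %d of %d\n",
              x$alpha, sum(sig), x$m))
  show <- utils::head(r[order(r$p_bonf, -abs(r$Z)), ], 8)
  show$D <- round(show$D, 4); show$SE <- round(show$SE, 4)
  show$Z <- round(show$Z, 2)
  show$p <- signif(show$p, 3); show$p_bonf <- signif(show$p_bonf, 3)
  print(show, row.names = FALSE)
  if (nrow(r) > 8) cat("  ... (", nrow(r) - 8, " more rows; see summary())\n", sep = "")
  invisible(x)
}

#' @rdname dstat-methods
#' @export
summary.dstat <- function(object, ...) {
  r <- object$results
  sig <- r[!is.na(r$p_bonf) & r$p_bonf < object$alpha, ]
  structure(list(results = r, significant = sig, alpha = object$alpha,
                 m = object$m, mode = object$mode), class = "summary.dstat")
}

#' @export
print.summary.dstat <- function(x, ...) {
  cat(sprintf("D statistics over %d quartet configurations (%s counting)\n", x$m, x$mode))
  print(x$results, row.names = FALSE, digits = 4)
  cat(sprintf("\n%d configuration(s) significant at Bonferroni-adjusted p < %g\n",
              nrow(x$significant), x$alpha))
  invisible(x)
}

#' @rdname dstat-methods
#' @export
coef.dstat <- function(object, ...) {
  r <- object$results
  stats::setNames(r$D, paste0("D(", r$P1, ",", r$P2, ";", r$P3, ")"))
}

#' @rdname dstat-methods
#' @export
plot.dstat <- function(x, ...) {
  r <- x$results
  ord <- order(r$D)
  r <- r[ord, ]
  sig <- !is.na(r$p_bonf) & r$p_bonf < x$alpha
  n <- nrow(r)
  graphics::plot(r$D, seq_len(n), xlim = range(c(r$D - 2 * r$SE, r$D + 2 * r$SE),
                                               na.rm = TRUE),
                 pch = ifelse(sig, 19, 1), col = ifelse(sig, "firebrick", "grey30"),
                 xlab = "D (ABBA - BABA excess)", ylab = "quartet rank",
                 main = "D statistics with 2 SE", ...)
  graphics::segments(r$D - 2 * r$SE, seq_len(n), r$D + 2 * r$SE, seq_len(n),
                     col = ifelse(sig, "firebrick", "grey60"))
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
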