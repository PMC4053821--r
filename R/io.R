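#' Read and write the package's plain-text interchange formats
#'
#' BED intervals (0-based half-open), genotype matrices as TSV or minimal
#' VCF, pileup TSV, and Newick tree sets with window-provenance comments.
#'
#' @name dscan-io
NULL

#' @rdname dscan-io
#' @param x object to write (see individual functions).
#' @param file path.
#' @export
write_bed <- function(x, file) {
  df <- as.data.frame(x)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname dscan-io
#' @param extra_cols names for columns beyond chrom/start/end.
#' @export
read_bed <- function(file, extra_cols = NULL) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols) && ncol(df) >= 3 + length(extra_cols))
    names(df)[4:(3 + length(extra_cols))] <- extra_cols
  interval_set(df)
}

#' @rdname dscan-io
#' @param geno site-by-taxon matrix.
#' @param pos,chrom site coordinates.
#' @export
write_geno_tsv <- function(geno, pos, file, chrom = "sim1") {
  df <- data.frame(chrom = chrom, pos = pos, geno, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname dscan-io
#' @export
read_geno_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  geno <- as.matrix(df[, setdiff(names(df), c("chrom", "pos")), drop = FALSE])
  list(geno = geno, pos = df$pos, chrom = df$chrom)
}

#' @rdname dscan-io
#' @param ref,alt reference and alternate allele labels used in the VCF.
#' @export
write_vcf <- function(geno, pos, file, chrom = "sim1", ref = "A", alt = "T") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=dscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(geno)), collapse = "\t")), con)
  gt <- matrix("0", nrow(geno), ncol(geno))
  gt[geno == 1] <- "1"
  gt[is.na(geno)] <- "."
  lines <- paste(chrom, pos + 1L, ".", ref, alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(file)
}

#' @rdname dscan-io
#' @details `read_vcf_geno()` imports biallelic SNPs from a VCF into a
#'   pseudo-haploid 0/1 matrix (heterozygous genotypes are sampled to one
#'   allele with the current RNG; multiallelic records are dropped with a
#'   message). Requires the `vcfR` package.
#' @export
read_vcf_geno <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) message("dropped ", sum(multi), " multiallelic site(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  first <- substr(gt, 1, 1)
  second <- substr(gt, nchar(gt), nchar(gt))
  pick <- matrix(stats::runif(length(gt)) < 0.5, nrow(gt), ncol(gt))
  chosen <- ifelse(pick, first, second)
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  geno[chosen == "0"] <- 0L
  geno[chosen == "1"] <- 1L
  list(geno = geno, pos = as.integer(fix[, "POS"]) - 1L, chrom = fix[, "CHROM"])
}

#' @rdname dscan-io
#' @param pileup pileup data frame (see [call_genotypes()]).
#' @export
write_pileup <- function(pileup, file) {
  utils::write.table(pileup, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname dscan-io
#' @export
read_pileup <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", bases = "character",
                                   bquals = "character", mquals = "character"))
}

#' @rdname dscan-io
#' @param ts a [tree_set()].
#' @export
write_tree_set <- function(ts, file) {
  stopifnot(inherits(ts, "tree_set"))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(ts$trees)) {
    if (!is.null(ts$windows))
      writeLines(sprintf("#window=%s:%d-%d", ts$windows$chrom[i],
                         as.integer(ts$windows$start[i]),
                         as.integer(ts$windows$end[i])), con)
    writeLines(ape::write.tree(ts$trees[[i]]), con)
  }
  invisible(file)
}

#' @rdname dscan-io
#' @export
read_tree_set <- function(file) {
  lines <- readLines(file)
  is_comment <- startsWith(lines, "#")
  nwk <- lines[!is_comment]
  trees <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  windows <- NULL
  wl <- lines[is_comment & startsWith(lines, "#window=")]
  if (length(wl) == length(trees)) {
    m <- regmatches(wl, regexec("#window=([^:]+):([0-9]+)-([0-9]+)", wl))
    windows <- data.frame(chrom = vapply(m, `[`, "", 2),
                          start = as.integer(vapply(m, `[`, "", 3)),
                          end = as.integer(vapply(m, `[`, "", 4)))
  }
  tree_set(trees, windows)
}
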