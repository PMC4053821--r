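# Genotype calling ----------------------------------------------------------

test_that("calling respects depth and quality thresholds", {
  # two reads, both excellent: still below the 3-read floor
  p <- pileup_row(10, "AA", c(40, 40), c(60, 60))
  expect_true(is.na(call_genotypes(p)$a1))
  # five clean reads of A
  p <- pileup_row(10, "AAAAA", rep(30, 5), rep(30, 5))
  cc <- call_genotypes(p)
  expect_equal(cc$a1, "A"); expect_equal(cc$a2, "A")
  # qualities (19,20,20,20): exactly three reads pass, so the site is called
  p <- pileup_row(10, "AAAA", c(19, 20, 20, 20), rep(60, 4))
  cc <- call_genotypes(p)
  expect_equal(cc$depth_pass, 3)
  expect_equal(cc$a1, "A")
  # low mapping quality excludes reads the same way
  p <- pileup_row(10, "AAAA", rep(40, 4), c(19, 19, 20, 20))
  expect_true(is.na(call_genotypes(p)$a1))
  # heterozygote rule: minor needs >= 2 reads and >= 20%
  p <- pileup_row(10, "AAAAAAAAAG", rep(30, 10), rep(30, 10))
  expect_equal(call_genotypes(p)$a2, "A")  # 1 read, 10% -> hom
  p <- pileup_row(10, "AAAAAAAAGG", rep(30, 10), rep(30, 10))
  cc <- call_genotypes(p)
  expect_equal(c(cc$a1, cc$a2), c("A", "G"))  # 2 reads, 20% -> het
  expect_error(call_genotypes(pileup_row(10, "AA", c(-1, 30), c(30, 30))),
               "negative")
  p2 <- rbind(pileup_row(10, "AAA", rep(30, 3), rep(30, 3)),
              pileup_row(5, "AAA", rep(30, 3), rep(30, 3)))
  expect_error(call_genotypes(p2), "sorted")
})

# Artifact filters -----------------------------------------------------------

test_that("SNP clusters and indel-proximal SNPs are flagged per the rules", {
  mk_calls <- function(pos) {
    data.frame(chrom = "c1", pos = pos, ref = "A",
               a1 = "G", a2 = "G", depth_pass = 10, flag_lowdepth = FALSE)
  }
  # three SNPs spanning positions 100..109 (10 bp inclusive): all removed
  f <- filter_snp_artifacts(mk_calls(c(100, 105, 109)))
  expect_true(all(f$flag_snpcluster))
  # two SNPs are never a cluster
  f <- filter_snp_artifacts(mk_calls(c(100, 109)))
  expect_false(any(f$flag_snpcluster))
  # three SNPs spanning 11 bp: kept
  f <- filter_snp_artifacts(mk_calls(c(100, 105, 110)))
  expect_false(any(f$flag_snpcluster))
  # four SNPs where only a sub-triple is tight: whole run inside the window
  f <- filter_snp_artifacts(mk_calls(c(100, 101, 102, 150)))
  expect_equal(f$flag_snpcluster, c(TRUE, TRUE, TRUE, FALSE))
  # indel proximity is symmetric and inclusive at 3 bp
  f <- filter_snp_artifacts(mk_calls(c(203, 204)), indels = 200)
  expect_equal(f$flag_nearindel, c(TRUE, FALSE))
  f <- filter_snp_artifacts(mk_calls(c(197, 196)), indels = 200)
  expect_equal(f$flag_nearindel, c(TRUE, FALSE))
  # non-SNP (hom-ref) sites are untouched
  calls <- mk_calls(c(100, 105, 109))
  calls$a1 <- calls$a2 <- "A"
  f <- filter_snp_artifacts(calls, indels = 101)
  expect_false(any(f$flag_snpcluster | f$flag_nearindel))
})

test_that("cluster and indel filters commute", {
  set.seed(31)
  pos <- sort(sample.int(5000, 120))
  calls <- data.frame(chrom = "c1", pos = pos, ref = "A",
                      a1 = sample(c("A", "G"), 120, TRUE), a2 = "G",
                      depth_pass = 10, flag_lowdepth = FALSE)
  indels <- sort(sample.int(5000, 10))
  a <- filter_snp_artifacts(filter_snp_artifacts(calls, integer(0)), indels)
  b <- filter_snp_artifacts(filter_snp_artifacts(calls, indels), integer(0))
  expect_identical(a$flag_snpcluster, b$flag_snpcluster)
  expect_identical(a$flag_nearindel, b$flag_nearindel)
})

# Bin acceptance -------------------------------------------------------------

test_that("bin acceptance applies the strict depth and callable thresholds", {
  len <- 3000L
  mk <- function(n_callable_bin1) {
    pos <- 1:len
    a1 <- rep("A", len)
    a1[seq_len(1000 - n_callable_bin1)] <- NA  # knock out callable in bin 1
    data.frame(chrom = "c1", pos = pos, ref = "A", a1 = a1, a2 = a1,
               depth_pass = 10, flag_lowdepth = is.na(a1))
  }
  depths <- data.frame(chrom = "c1", pos = 1:len, depth = 10)
  # 900/1000 callable at 1x mean: bin passes
  b <- accept_bins(mk(900), depths, c(c1 = len), genome_mean = 10)
  expect_true(0 %in% b$start)
  # 899/1000: fails the 90% rule
  b <- accept_bins(mk(899), depths, c(c1 = len), genome_mean = 10)
  expect_false(0 %in% b$start)
  # mean depth exactly at 2x the genome mean: strict "under" fails
  depths2 <- depths; depths2$depth[1:1000] <- 20
  b <- accept_bins(mk(1000), depths2, c(c1 = len), genome_mean = 10)
  expect_false(0 %in% b$start)
  depths2$depth[1:1000] <- 19.99
  b <- accept_bins(mk(1000), depths2, c(c1 = len), genome_mean = 10)
  expect_true(0 %in% b$start)
  # final partial bin is excluded
  b <- accept_bins(mk(1000), depths, c(c1 = 2500L), genome_mean = 10)
  expect_true(all(b$end <= 2000))
})

# Interval algebra -----------------------------------------------------------

test_that("chaining merges exactly adjacent bins and is idempotent", {
  iv <- interval_set(data.frame(chrom = "c1", start = c(0, 1000),
                                end = c(1000, 2000)))
  expect_equal(as.data.frame(chain_bins(iv))[, 1:3],
               data.frame(chrom = "c1", start = 0, end = 2000))
  iv <- interval_set(data.frame(chrom = "c1", start = c(0, 2000),
                                end = c(1000, 3000)))
  expect_equal(nrow(chain_bins(iv)), 2)
  iv <- interval_set(data.frame(chrom = "c1", start = (0:4) * 1000,
                                end = (1:5) * 1000))
  ch <- chain_bins(iv)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$end - ch$start, 5000)
  expect_identical(as.data.frame(chain_bins(ch)), as.data.frame(ch))
  # 1-bp gaps are not adjacency
  iv <- interval_set(data.frame(chrom = "c1", start = c(0, 1001),
                                end = c(1000, 2000)))
  expect_equal(nrow(chain_bins(iv)), 2)
})

test_that("multi-sample intersection matches positionwise brute force", {
  expect_error(intersect_samples(list()), "non-empty")
  a <- interval_set(data.frame(chrom = "c1", start = 0, end = 100))
  b <- interval_set(data.frame(chrom = "c1", start = 50, end = 150))
  r <- intersect_samples(list(a, b))
  expect_equal(c(r$start, r$end), c(50, 100))
  expect_identical(as.data.frame(intersect_samples(list(a, a, a))),
                   as.data.frame(a))
  # 11 random sets over a 100-kbp toy genome
  set.seed(17)
  L <- 100000L
  sets <- lapply(1:11, function(i) random_interval_set(L, n = 60))
  r <- intersect_samples(sets)
  expect_identical(oracle_positions(r, L), oracle_intersection(sets, L))
  # commutative and bounded by the smallest input
  r2 <- intersect_samples(rev(sets))
  expect_identical(as.data.frame(r), as.data.frame(r2))
  width <- function(s) sum(s$end - s$start)
  expect_lte(width(r), min(vapply(sets, width, numeric(1))))
})

test_that("span selection applies the length and missingness bounds", {
  regions <- interval_set(data.frame(
    chrom = "c1", start = c(0, 10000, 20000), end = c(5000, 14999, 25000)))
  # sample callable sets: region 1 has 9% missing, region 3 exactly 10%
  callable <- list(interval_set(data.frame(
    chrom = "c1",
    start = c(450, 10000, 20500),
    end   = c(5000, 14999, 25000))))
  keep <- select_spans(regions, callable, min_span = 5000, max_missing = 0.10)
  expect_equal(keep$start, 0)   # 9% missing, 5000 bp: kept
  # region 2 is 4999 bp: dropped regardless of completeness
  # region 3 has exactly 10% missing: dropped by the strict rule
})

# Effective coverage ---------------------------------------------------------

test_that("effective coverage reproduces the per-read error products", {
  # one read with base and mapping quality 20: (1 - 10^-2)^2
  ec <- effective_coverage(pileup_row(1, "A", 20, 20))
  expect_equal(ec$C_A, 0.99^2, tolerance = 1e-12)
  expect_equal(ec$C_A, 0.9801, tolerance = 1e-9)
  # base quality 0 nullifies the read regardless of mapping quality
  ec <- effective_coverage(pileup_row(1, "A", 0, 60))
  expect_equal(ec$C_A, 0, tolerance = 1e-12)
  # 3 A reads + 1 G read at q = mq = 30
  ec <- effective_coverage(pileup_row(1, "AAAG", rep(30, 4), rep(30, 4)))
  expect_equal(ec$C_A, 3 * 0.999^2, tolerance = 1e-9)
  expect_equal(ec$major, "A")
  expect_equal(ec$major_frac, 0.75, tolerance = 1e-12)
  # monotonicity: raising one read's quality never lowers any C
  ec1 <- effective_coverage(pileup_row(1, "AG", c(20, 20), c(20, 20)))
  ec2 <- effective_coverage(pileup_row(1, "AG", c(30, 20), c(20, 20)))
  expect_gte(ec2$C_A, ec1$C_A)
  expect_equal(ec2$C_G, ec1$C_G)
})

test_that("the 70% major-allele rule is inclusive and flags no-data sites", {
  # 7 + 3 reads with equal qualities: exactly 0.70, kept
  p <- pileup_row(1, paste0(strrep("A", 7), strrep("G", 3)),
                  rep(30, 10), rep(30, 10))
  expect_true(filter_mt_sites(p)$kept)
  # 3 + 2: 0.60, filtered
  p <- pileup_row(2, "AAAGG", rep(30, 5), rep(30, 5))
  expect_false(filter_mt_sites(p)$kept)
  # mixed qualities: 2 A (40) + 1 G (10)
  p <- pileup_row(3, "AAG", c(40, 40, 10), c(40, 40, 10))
  ec <- filter_mt_sites(p)
  frac <- 2 * 0.9999^2 / (2 * 0.9999^2 + 0.9^2)
  expect_equal(ec$major_frac, frac, tolerance = 1e-9)
  expect_true(ec$kept)   # ~= 0.712 >= 0.70
  # zero effective coverage: filtered and flagged
  p <- pileup_row(4, "A", 0, 0)
  ec <- filter_mt_sites(p)
  expect_true(ec$no_data)
  expect_false(ec$kept)
})

test_that("filters recover injected pileup artifacts exactly", {
  ps <- simulate_pileup(length = 30000, n_clusters = 3, n_indel_snps = 3,
                        n_high_depth = 1, seed = 77)
  calls <- filter_snp_artifacts(call_genotypes(ps$pileup),
                                indels = ps$truth$indels)
  expect_true(all(ps$truth$cluster_snps %in% calls$pos[calls$flag_snpcluster]))
  expect_true(all(ps$truth$indel_snps %in% calls$pos[calls$flag_nearindel]))
  # false positives among clean truth SNPs stay rare
  clean <- ps$truth$snps$pos
  flagged <- calls$pos[calls$flag_snpcluster | calls$flag_nearindel]
  expect_lt(mean(clean %in% flagged), 0.05)
})
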