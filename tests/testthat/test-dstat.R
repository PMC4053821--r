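# Pattern counting -----------------------------------------------------------

test_that("polarization encodes derived states against the outgroup", {
  geno <- rbind(c("A", "A", "B", "B"),  # ABBA given O = last column
                c("B", "A", "B", "A"),  # BABA
                c("A", "A", "A", "A"),  # uninformative
                c("B", "B", "B", "B"))  # all derived? no: equal to outgroup
  colnames(geno) <- c("P1", "P2", "P3", "O")
  geno[1:3, 4] <- "A"; geno[4, 4] <- "B"
  d <- polarize(geno, "O")
  expect_equal(unname(d[1, ]), c(0L, 0L, 1L, 0L))
  expect_equal(unname(d[2, ]), c(1L, 0L, 1L, 0L))
  expect_equal(sum(d[3, ]), 0)
  expect_equal(sum(d[4, ]), 0)
  # missing outgroup drops the site
  geno[2, 4] <- NA
  d <- polarize(geno, "O")
  expect_equal(nrow(d), 3)
  expect_equal(attr(d, "n_dropped"), 1)
})

test_that("pattern counts match the per-site brute-force classifier", {
  set.seed(23)
  geno <- matrix(sample(c(0L, 1L, NA), 1000 * 5, TRUE, prob = c(.45, .45, .1)),
                 1000, 5, dimnames = list(NULL, c("P1", "P2", "P3", "P4", "O")))
  block <- sample.int(10, 1000, TRUE)
  cnt <- count_patterns(geno, c("P1", "P2", "P3", "O"), block)
  oracle <- oracle_patterns(geno, "P1", "P2", "P3", "O")
  expect_equal(cnt$nABBA, unname(oracle["abba"]))
  expect_equal(cnt$nBABA, unname(oracle["baba"]))
  expect_equal(sum(cnt$blocks$abba), cnt$nABBA)
  # swapping P1 and P2 swaps the counts exactly
  cnt2 <- count_patterns(geno, c("P2", "P1", "P3", "O"), block)
  expect_equal(cnt2$nABBA, cnt$nBABA)
  expect_equal(cnt2$nBABA, cnt$nABBA)
  # constructed input: 10 ABBA, 0 BABA
  g <- matrix(0L, 10, 4, dimnames = list(NULL, c("P1", "P2", "P3", "O")))
  g[, c("P2", "P3")] <- 1L
  cnt3 <- count_patterns(g, c("P1", "P2", "P3", "O"), rep(1L, 10))
  expect_equal(c(cnt3$nABBA, cnt3$nBABA), c(10, 0))
  expect_error(count_patterns(g, c("P1", "P2", "P3", "O"),
                              c(rep(1L, 9), NA)), "exhaustive")
})

test_that("D arithmetic and degenerate cases", {
  expect_equal(d_statistic(c(30, 10)), 0.5)
  expect_equal(d_statistic(c(7, 7)), 0)
  expect_equal(d_statistic(c(0, 17)), -1)
  expect_true(is.na(d_statistic(c(0, 0))))  # undefined, not 0
})

test_that("quartet enumeration covers all configurations exactly once", {
  q3 <- all_quartets(c("A", "B", "C"), "O")
  expect_equal(nrow(q3), 3)
  q10 <- all_quartets(paste0("P", 1:10), "O")
  expect_equal(nrow(q10), 360)
  expect_false(any(q10$O %in% c(q10$P1, q10$P2, q10$P3)))
  expect_false("O" %in% unlist(q10[, 1:3]))
  # no duplicated unordered configuration
  key <- apply(q10, 1, function(r) paste(sort(r[1:2]), r[3], collapse = "|"))
  expect_equal(anyDuplicated(key), 0)
  # guide tree keeps one consistent configuration per triple
  m <- quartet_model()
  tr5 <- example_species_tree(5)
  qt <- all_quartets(tr5$taxa, "O", tree = tr5)
  expect_equal(nrow(qt), choose(5, 3))
  row <- qt[qt$P3 == "P3" & qt$P1 == "P1", ]
  expect_equal(unname(unlist(row[1, 1:2])), c("P1", "P2"))
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.001, 10), 0.01)
  expect_equal(bonferroni(0.5, 360), 1)
  expect_equal(bonferroni(c(0.001, 0.5), 360), c(0.36, 1))
})

# Jackknife -------------------------------------------------------------------

test_that("equal block weights reduce to the unweighted delete-one formula", {
  set.seed(41)
  B <- 40
  ab <- rpois(B, 5); ba <- rpois(B, 5)
  counts <- structure(list(
    nABBA = sum(ab), nBABA = sum(ba),
    blocks = data.frame(block = 1:B, abba = ab, baba = ba, n_sites = 100),
    quartet = c("P1", "P2", "P3", "O")), class = "site_pattern_counts")
  jk <- block_jackknife(counts)
  D <- (sum(ab) - sum(ba)) / (sum(ab) + sum(ba))
  Dm <- ((sum(ab) - ab) - (sum(ba) - ba)) / ((sum(ab) - ab) + (sum(ba) - ba))
  se_unw <- sqrt((B - 1) / B * sum((Dm - mean(Dm))^2))
  expect_equal(jk$D, D)
  expect_equal(jk$SE, se_unw, tolerance = 1e-12)
  expect_equal(jk$Z, D / se_unw, tolerance = 1e-10)
  expect_equal(jk$p, 2 * pnorm(-abs(jk$Z)))
})

test_that("single-block data yields a flagged, undefined SE", {
  counts <- structure(list(
    nABBA = 5, nBABA = 3,
    blocks = data.frame(block = 1:2, abba = c(5, 0), baba = c(3, 0),
                        n_sites = c(8, 0)),
    quartet = c("P1", "P2", "P3", "O")), class = "site_pattern_counts")
  jk <- block_jackknife(counts)
  expect_true(is.na(jk$SE))
})

test_that("D is antisymmetric in (P1, P2) with invariant SE", {
  m <- quartet_model()
  g <- simulate_genome(m, n_windows = 150, window_len = 5000, seed = 19)
  q <- rbind(data.frame(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"),
             data.frame(P1 = "P2", P2 = "P1", P3 = "P3", O = "O"))
  fit <- dstat(g, quartets = q)
  expect_equal(fit$results$D[1], -fit$results$D[2])
  expect_equal(fit$results$SE[1], fit$results$SE[2])
  expect_true(all(abs(fit$results$D) <= 1))
})

test_that("pseudo-haploid and frequency modes agree on haploid data", {
  m <- quartet_model()
  g <- simulate_genome(m, n_windows = 100, window_len = 5000, seed = 29)
  f1 <- dstat(g, mode = "pseudohaploid")
  f2 <- dstat(g, mode = "frequency")
  expect_equal(f1$results$nABBA, f2$results$nABBA)
  expect_equal(f1$results$D, f2$results$D)
})

test_that("fit object methods expose the results coherently", {
  m <- quartet_model()
  g <- simulate_genome(m, n_windows = 100, window_len = 5000, seed = 31)
  fit <- dstat(g)
  expect_s3_class(fit, "dstat")
  expect_named(fit$results,
               c("P1", "P2", "P3", "O", "nABBA", "nBABA", "D", "SE", "Z", "p",
                 "p_bonf", "n_blocks", "n_sites"))
  expect_equal(fit$results$p_bonf, pmin(1, fit$results$p * nrow(fit$results)))
  expect_length(coef(fit), nrow(fit$results))
  expect_output(print(fit), "quartet configuration")
  s <- summary(fit)
  expect_s3_class(s, "summary.dstat")
  expect_equal(nrow(s$results), nrow(fit$results))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("a known pulse produces a significant, sign-correct D", {
  m <- quartet_model()
  pl <- admixture_pulse("P3", "P2", time = 5000, gamma = 0.15)
  g <- simulate_genome(m, pulses = list(pl), n_windows = 1500,
                       window_len = 5000, seed = 37)
  fit <- dstat(g, quartets = data.frame(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"))
  expect_gt(fit$results$Z, 3)       # P2 shares excess derived alleles with P3
  expect_lt(fit$results$p_bonf, 0.01)
})

# Admixture fraction ----------------------------------------------------------

test_that("admixture fraction is near zero without gene flow and flagged when undefined", {
  nwk <- "(((P1:20000,P2:20000):40000,P3:60000):140000,O:200000);"
  m <- species_tree_model(nwk, Ne = 10000, mu = 1e-8, outgroup = "O")
  g <- simulate_genome(m, n_windows = 3000, window_len = 2000,
                       ploidy = "diploid", seed = 43)
  af <- admixture_fraction(g, "P1", "P2", "P3")
  expect_lt(abs(af$f), 2 * af$SE + 0.02)
  # donor = recipient's sister with no pulse: no usable excess, flagged
  af2 <- admixture_fraction(g, "P1", "P2", "P1")
  expect_true(is.na(af2$f))
  expect_match(af2$note, "denominator")
})

test_that("admixture fraction recovers the pulse proportion", {
  nwk <- "(((P1:20000,P2:20000):40000,P3:60000):140000,O:200000);"
  m <- species_tree_model(nwk, Ne = 10000, mu = 1e-8, outgroup = "O")
  pl <- admixture_pulse("P3", "P2", time = 5000, gamma = 0.1)
  set.seed(47)
  fh <- vapply(1:10, function(i) {
    g <- simulate_genome(m, pulses = list(pl), n_windows = 4000,
                         window_len = 2000, ploidy = "diploid")
    admixture_fraction(g, "P1", "P2", "P3")$f
  }, numeric(1))
  expect_gt(mean(fh), 0.06)
  expect_lt(mean(fh), 0.14)
})
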