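test_that("allele frequencies match hand enumeration", {
  g <- make_geno(matrix(c(0, 0, 2, 1), ncol = 1), rep("P1", 4))
  expect_equal(allele_frequencies(g, "P1")$p, 5 / 8)
  # fixation and full heterozygosity
  expect_equal(allele_frequencies(make_geno(matrix(0, 3, 1), rep("P", 3)))$p, 1)
  expect_equal(allele_frequencies(make_geno(matrix(2, 3, 1), rep("P", 3)))$p, 0.5)
  expect_error(allele_frequencies(g, "nope"), "unknown population")
})

test_that("population summary reproduces the single-locus hand calculation", {
  g <- make_geno(matrix(c(0, 0, 2, 1), ncol = 1), rep("P1", 4))
  s <- population_summary(g)
  row <- s[s$population == "P1", ]
  expect_equal(row$na, 2)
  expect_equal(row$ne, 1 / (0.625^2 + 0.375^2), tolerance = 1e-12)
  expect_equal(row$ho, 25)
  expect_equal(row$he, 100 * 2 * 0.625 * 0.375) # 46.875
  expect_equal(row$f, (46.875 - 25) / 46.875, tolerance = 1e-12)
})

test_that("monomorphic loci degrade gracefully and are excluded from F", {
  codes <- cbind(rep(0, 4), c(0, 0, 2, 1)) # L1 monomorphic, L2 polymorphic
  s <- population_summary(make_geno(codes, rep("P1", 4)))
  row <- s[s$population == "P1", ]
  expect_equal(row$na, 1.5)
  expect_equal(row$ne, (1 + 1 / (0.625^2 + 0.375^2)) / 2, tolerance = 1e-12)
  expect_equal(row$pl_pct, 50)
  # F averaged only over the polymorphic locus
  expect_equal(row$f, (46.875 - 25) / 46.875, tolerance = 1e-12)
})

test_that("the mean row is the unweighted mean of per-population values", {
  set.seed(2)
  codes <- matrix(sample(0:2, 24 * 50, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)), nrow = 24)
  g <- make_geno(codes, rep(c("A", "B", "C"), each = 8))
  s <- population_summary(g)
  per_pop <- s[s$population != "Mean", ]
  mean_row <- s[s$population == "Mean", ]
  for (col in c("n", "na", "ne", "ho", "he", "f", "pl_pct")) {
    expect_equal(mean_row[[col]], mean(per_pop[[col]]),
                 tolerance = 1e-12, label = col)
  }
})

test_that("private alleles are alleles seen in exactly one population", {
  # L1: B only in pop A (via het); L2: A everywhere, B nowhere; L3: B only in B
  codes <- rbind(
    c(2, 0, 0), c(0, 0, 0),  # pop A
    c(0, 0, 1), c(0, 0, 1)   # pop B
  )
  s <- population_summary(make_geno(codes, c("A", "A", "B", "B")))
  # pop A privately holds allele B at L1 and allele A at L3 (pop B is fixed
  # for B there); pop B privately holds allele B at L3
  expect_equal(s$pa_count[s$population == "A"], 2)
  expect_equal(s$pa_count[s$population == "B"], 1)
  # pa_pct uses alleles observed in that population as denominator (A sees
  # 2 + 1 + 1 = 4 alleles over the three loci)
  expect_equal(s$pa_pct[s$population == "A"], 100 * 2 / 4)
})

test_that("F-statistics match the two-population hand calculation", {
  # pop1 p = 0.2 (genotypes 2,2,1,1,1), pop2 p = 0.8 (mirrored)
  codes <- matrix(c(2, 2, 1, 1, 1, 2, 2, 0, 0, 0), ncol = 1)
  g <- make_geno(codes, rep(c("P1", "P2"), each = 5))
  fs <- glance(f_statistics(g))
  expect_equal(fs$hs, 0.32, tolerance = 1e-12)
  expect_equal(fs$ht, 0.5, tolerance = 1e-12)
  expect_equal(fs$fst, 0.36, tolerance = 1e-12)
  expect_equal(fs$nm, 0.25 * (1 - 0.36) / 0.36, tolerance = 1e-12)
})

test_that("F-statistics handle the extremes of differentiation", {
  # opposite fixation: Hs = 0, Ht = 0.5, Fst = 1, Nm = 0
  g <- make_geno(matrix(c(0, 0, 1, 1), ncol = 1), rep(c("A", "B"), each = 2))
  fs <- glance(f_statistics(g))
  expect_equal(fs$hs, 0)
  expect_equal(fs$ht, 0.5)
  expect_equal(fs$fst, 1)
  expect_equal(fs$nm, 0)
  # identical frequencies: Fst = 0, Nm infinite
  g2 <- make_geno(matrix(c(2, 2, 2, 2), ncol = 1), rep(c("A", "B"), each = 2))
  fs2 <- glance(f_statistics(g2))
  expect_equal(fs2$fst, 0)
  expect_true(is.infinite(fs2$nm))
  expect_error(f_statistics(make_geno(matrix(0, 2, 1), c("A", "A"))),
               "two populations")
})

test_that("effective cannot exceed observed allele number, Hs <= Ht", {
  d <- small_cohort(seed = 11, n_loci = 150)
  pl <- population_summary(d)
  expect_true(all(pl$ne <= pl$na + 1e-12))
  expect_true(all(pl$na >= 1 & pl$na <= 2))
  fs <- f_statistics(d)
  expect_true(all(fs$per_locus$hs <= fs$per_locus$ht + 1e-12))
})

test_that("expected heterozygosity matches 2pq under Hardy-Weinberg draws", {
  set.seed(31)
  p <- 0.3; n <- 4000
  dos <- stats::rbinom(n, 2, p)
  codes <- ifelse(dos == 2, 0L, ifelse(dos == 0, 1L, 2L))
  g <- make_geno(matrix(codes, ncol = 1), rep("P", n))
  s <- population_summary(g)
  # He = 2 p-hat q-hat; close to 2pq at this sample size
  expect_equal(s$he[1] / 100, 2 * p * (1 - p), tolerance = 0.02)
})

test_that("Evanno delta-K finds a constructed likelihood elbow", {
  mean_l <- c(-500, -400, -300, -200, -190, -180) # slope break at K = 4
  tab <- tidyr::expand_grid(k = 1:6, replicate = 1:2) %>%
    dplyr::mutate(lnp = mean_l[k] + ifelse(replicate == 1, 1, -1))
  dk <- evanno_delta_k(tab)
  expect_equal(attr(dk, "best_k"), 4)
  expect_true(all(is.na(dk$delta_k[dk$k %in% c(1, 6)])))
  # |L''|(4) = |(-190) - 2(-200) + (-300)| = 90, sd = sd(c(+1,-1))
  expect_equal(dk$delta_k[dk$k == 4], 90 / stats::sd(c(1, -1)))
  expect_equal(dk$lprime[dk$k == 2], 100)
})

test_that("delta-K edge rules: zero spread, endpoints, non-consecutive K", {
  const <- tidyr::expand_grid(k = 1:3, replicate = 1:2) %>%
    dplyr::mutate(lnp = c(-10, -10, -5, -5, -4, -4)[2 * (k - 1) + replicate])
  dk <- evanno_delta_k(const)
  expect_false(any(dk$defined)) # sd = 0 everywhere
  # K in 1..3 leaves only K = 2 as interior
  jit <- tidyr::expand_grid(k = 1:3, replicate = 1:2) %>%
    dplyr::mutate(lnp = -10 * k + ifelse(replicate == 1, 0.5, -0.5))
  dk2 <- evanno_delta_k(jit)
  expect_equal(dk2$k[dk2$defined], 2)
  bad <- tidyr::expand_grid(k = c(1, 2, 4), replicate = 1:2) %>%
    dplyr::mutate(lnp = -k)
  expect_error(evanno_delta_k(bad), "consecutive")
})

test_that("lnP tables read back from TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("K\treplicate\tlnP", "1\t1\t-100.5", "1\t2\t-101"), f)
  tab <- read_lnp_table(f)
  expect_equal(names(tab), c("k", "replicate", "lnp"))
  expect_equal(tab$lnp, c(-100.5, -101))
})
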