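test_that("per-locus progeny heterozygosity follows Mendelian expectation", {
  # genotype x genotype table: identical homozygotes 0, opposite 1, any het 0.5
  expect_equal(expected_progeny_het_locus(0, 0), 0)
  expect_equal(expected_progeny_het_locus(1, 1), 0)
  expect_equal(expected_progeny_het_locus(0, 1), 1)
  expect_equal(expected_progeny_het_locus(1, 0), 1)
  expect_equal(expected_progeny_het_locus(c(0, 1, 2), c(2, 2, 2)),
               c(0.5, 0.5, 0.5))
  # Aa x Aa -> 1/4 AA, 1/2 Aa, 1/4 aa by direct enumeration
  gametes <- expand.grid(a = c(0, 1), b = c(0, 1))
  expect_equal(mean(gametes$a != gametes$b), 0.5)
  expect_error(expected_progeny_het_locus(NA, 0), "missing")
  expect_error(expected_progeny_het_locus(3, 0), "0, 1 or 2")
})

test_that("cross-level expectation averages loci; extremes behave", {
  g <- make_geno(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(0, 1, 2)),
                 rep("P", 4))
  # classic F1: opposite homozygotes at every locus
  expect_equal(expected_progeny_heterozygosity(g, "s1", "s2"), 1)
  # selfing a fully homozygous / fully heterozygous parent
  expect_equal(expected_progeny_heterozygosity(g, "s1", "s1"), 0)
  expect_equal(expected_progeny_heterozygosity(g, "s3", "s3"), 0.5)
  # mixed pair: (0,0)->0, (0,1)->1, (0,2)->0.5
  expect_equal(expected_progeny_heterozygosity(g, "s1", "s4"), mean(c(0, 1, 0.5)))
  expect_error(expected_progeny_heterozygosity(g, "s1", "zz"), "unknown sample")
})

test_that("selfing expectation is exactly half the parent heterozygosity", {
  d <- small_cohort(seed = 17, n_loci = 120)
  hom <- observed_homozygosity(d)
  for (i in sample(nrow(d), 8)) {
    expect_equal(
      expected_progeny_heterozygosity(d, d$sample[i], d$sample[i]),
      (1 - hom$obs_hom[i]) / 2, tolerance = 1e-12
    )
  }
})

test_that("cross prediction is symmetric and matches Monte-Carlo offspring", {
  set.seed(55)
  d <- small_cohort(seed = 31, n_loci = 100)
  m <- as.matrix(d[locus_names(d)])
  for (rep in 1:4) {
    pair <- sample(nrow(d), 2)
    pred <- expected_progeny_heterozygosity(d, d$sample[pair[1]],
                                            d$sample[pair[2]])
    expect_equal(pred, expected_progeny_heterozygosity(
      d, d$sample[pair[2]], d$sample[pair[1]]))
    sim <- simulate_offspring_het(m[pair[1], ], m[pair[2], ],
                                  n_offspring = 4000)
    se <- sqrt(pred * (1 - pred) / (4000 * ncol(m)))
    expect_lt(abs(sim - pred), max(3 * se, 5e-3))
  }
})

test_that("parent selection is greedy on homozygosity with GS cohesion", {
  # 12 individuals: a tight block of 10 plus 2 divergent ones, one of which
  # has the 2nd-highest homozygosity and must still be excluded
  set.seed(77)
  base <- sample(0:1, 60, replace = TRUE)
  block <- t(vapply(1:10, function(i) {
    v <- base
    flip <- sample(60, 2) # ~97% GS within the block
    v[flip] <- 2L
    v
  }, integer(60)))
  block[1, ] <- base # highest homozygosity seed
  far1 <- 1L - base; far2 <- 1L - base; far2[1:6] <- 2L
  codes <- rbind(block, far1, far2)
  g <- make_geno(codes, rep("P", 12))
  sel <- select_parents(g, k = 10, gs_threshold = 0.9)
  expect_equal(nrow(sel), 10)
  expect_setequal(sel$sample, paste0("s", 1:10))
  expect_false(any(sel$relaxed))
  expect_equal(sel$sample[1], "s1")
})

test_that("parent selection tie-breaks, shortfalls and relaxation", {
  # all identical: first k in input order, nothing relaxed
  g <- make_geno(matrix(0L, 6, 10), rep("P", 6))
  sel <- select_parents(g, k = 3)
  expect_equal(sel$sample, paste0("s", 1:3))
  expect_false(any(sel$relaxed))
  # population smaller than k: everyone selected
  suppressMessages(sel2 <- select_parents(g, k = 10))
  expect_equal(nrow(sel2), 6)
  # two mutually exclusive clusters force relaxation beyond cluster size
  codes <- rbind(matrix(0L, 3, 8), matrix(1L, 3, 8))
  g3 <- make_geno(codes, rep("P", 6))
  sel3 <- select_parents(g3, k = 5, gs_threshold = 0.9)
  expect_equal(nrow(sel3), 5)
  expect_true(any(sel3$relaxed))
  expect_error(select_parents(g, k = 0), ">= 1")
})

test_that("cross-prediction matrix composes GS, prediction and strategy", {
  codes <- rbind(c(0, 0), c(0, 2), c(1, 1), c(1, 2))
  g <- make_geno(codes, c("A", "A", "B", "B"))
  cp <- cross_prediction_matrix(g, g$sample)
  gs <- simple_matching_gs(g)
  m <- genotype_matrix(g)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(cp$matrix[i, j],
                   mean(expected_progeny_het_locus(m[i, ], m[j, ])))
      expect_equal(cp$matrix[j, i], gs[i, j])
    }
  }
  expect_equal(diag(cp$matrix), setNames(observed_homozygosity(g)$obs_hom,
                                         g$sample))
  expect_equal(sum(cp$strategy == "FS"), 4)  # 2 within-pop pairs, both triangles
  expect_equal(sum(cp$strategy == "F1"), 8)  # 4 cross-pop pairs
  expect_equal(unname(diag(cp$strategy)), rep("S", 4))
  # extreme cell: opposite homozygotes
  cp2 <- cross_prediction_matrix(
    make_geno(rbind(c(0, 0), c(1, 1)), c("A", "B")), c("s1", "s2"))
  expect_equal(cp2$matrix[1, 2], 1)
  expect_equal(cp2$matrix[2, 1], 0)
  expect_error(cross_prediction_matrix(g, c("s1", "s1")), "duplicate")
})

test_that("strategy summary orders S <= FS <= F1 on divergent inbred pops", {
  d <- small_cohort(seed = 37, n_loci = 300)
  sel <- select_parents(d, k = 5)
  cp <- cross_prediction_matrix(d, sel)
  ss <- strategy_summary(cp)
  means <- tapply(ss$mean, ss$strategy, mean)
  expect_lte(means[["S"]], means[["FS"]])
  expect_lte(means[["FS"]], means[["F1"]])
  # selfing values are half the parent heterozygosity
  s_rows <- ss[ss$strategy == "S", ]
  hom <- observed_homozygosity(d)
  for (pop in unique(sel$population)) {
    sel_pop <- sel$sample[sel$population == pop]
    expect_equal(s_rows$mean[s_rows$group == pop],
                 mean((1 - hom$obs_hom[match(sel_pop, hom$sample)]) / 2),
                 tolerance = 1e-12)
  }
})

test_that("closely related populations give overlapping FS and F1 ranges", {
  # population 2 generated as an offshoot of population 1 (shared founders)
  freqs <- simulate_ancestral_freqs(200, seed = 5)
  sim <- simulate_populations(freqs, fst = 0.5, pop_sizes = c(10, 10, 10),
                              seed = 5)
  d <- simulate_admixture(sim$data, "Pop2", c("Pop1", "Pop1"), 1, seed = 6)
  sel <- select_parents(d, k = 4)
  cp <- cross_prediction_matrix(d, sel)
  ss <- strategy_summary(cp)
  f1_close <- ss[ss$strategy == "F1" & ss$group == "Pop1 x Pop2", ]
  f1_far <- ss[ss$strategy == "F1" & ss$group == "Pop1 x Pop3", ]
  # sibling-derived pair predicts far less progeny heterozygosity than a
  # cross between truly divergent populations
  expect_lt(f1_close$mean, f1_far$mean)
})
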