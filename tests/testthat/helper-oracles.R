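# fixtures and independent oracles used across the suite

# genotype tibble from a plain code matrix (rows = samples)
make_geno <- function(codes, pops, samples = NULL) {
  codes <- as.matrix(codes)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(codes)))
  out <- tibble::tibble(sample = samples, population = pops)
  call_df <- as.data.frame(codes)
  names(call_df) <- paste0("L", seq_len(ncol(codes)))
  dplyr::bind_cols(out, tibble::as_tibble(call_df))
}

# Rohlf simple matching via explicit binary allele-presence expansion:
# 0 -> (1,0), 1 -> (0,1), 2 -> (1,1); GS = matching characters / characters
gs_binary_oracle <- function(codes) {
  expand <- function(row) {
    as.vector(vapply(row, function(g) switch(as.character(g),
      "0" = c(1L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L)), integer(2)))
  }
  n <- nrow(codes)
  out <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        a <- expand(codes[i, ]); b <- expand(codes[j, ])
        out[i, j] <- out[j, i] <- mean(a == b)
      }
    }
  }
  out
}

# per-locus 0/1/4 squared distance by direct case enumeration
d2_oracle <- function(codes) {
  per_locus <- function(g1, g2) {
    if (g1 == g2) 0
    else if (g1 != 2 && g2 != 2) 4
    else 1
  }
  n <- nrow(codes)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        out[i, j] <- out[j, i] <-
          sum(mapply(per_locus, codes[i, ], codes[j, ]))
      }
    }
  }
  out
}

# AMOVA sums of squares / components straight from the partition formulas
amova_oracle <- function(d2, pops) {
  n <- nrow(d2)
  k <- length(unique(pops))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (p in unique(pops)) {
    idx <- which(pops == p)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (k - 1)
  ms_within <- ss_within / (n - k)
  sizes <- as.numeric(table(pops))
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  var_among <- max((ms_among - ms_within) / n0, 0)
  list(ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       var_among = var_among, var_within = ms_within,
       phi = var_among / (var_among + ms_within))
}

# probability that a gamete from a genotype code carries allele A
gamete_p_a <- function(code) c("0" = 1, "1" = 0, "2" = 0.5)[as.character(code)]

# direct Mendelian offspring simulation for one parent pair:
# fraction of heterozygous (locus, offspring) calls
simulate_offspring_het <- function(g1, g2, n_offspring) {
  p1 <- unname(gamete_p_a(g1))
  p2 <- unname(gamete_p_a(g2))
  n_loci <- length(g1)
  a1 <- matrix(stats::runif(n_offspring * n_loci) <
                 rep(p1, each = n_offspring), n_offspring)
  a2 <- matrix(stats::runif(n_offspring * n_loci) <
                 rep(p2, each = n_offspring), n_offspring)
  mean(a1 != a2)
}

# small divergent cohort reused by several files (cheap, deterministic)
small_cohort <- function(seed = 42, n_loci = 400, missing = 0) {
  co <- synth_cohort(
    n_loci = n_loci, pop_sizes = c(8, 8, 10, 9), fst = 0.5,
    sib_generations = 2, admixture = NULL, missing_rate = missing,
    seed = seed
  )
  co$data
}
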