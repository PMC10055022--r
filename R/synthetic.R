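#' Ancestral allele frequencies
#'
#' Draws ancestral allele-A frequencies from Uniform(`min_p`, `max_p`)
#' (bounded away from fixation so every locus is potentially informative).
#' Deterministic given the seed.
#'
#' @param n_loci Number of loci (>= 1).
#' @param seed Integer seed.
#' @param min_p,max_p Support bounds (default 0.1 and 0.9).
#' @return Numeric vector of length `n_loci`.
#' @export
simulate_ancestral_freqs <- function(n_loci, seed = 1, min_p = 0.1,
                                     max_p = 0.9) {
  if (n_loci < 1) abort("`n_loci` must be >= 1")
  set.seed(derive_seed(seed, "ancestral"))
  stats::runif(n_loci, min_p, max_p)
}

# dosage (copies of allele A, 0/1/2) -> genotype code (1/2/0)
dosage_to_code <- function(dos) {
  code <- matrix(NA_integer_, nrow(dos), ncol(dos))
  code[dos == 2] <- 0L
  code[dos == 0] <- 1L
  code[dos == 1] <- 2L
  code
}

code_to_tibble <- function(code, samples, populations, loci) {
  out <- tibble(sample = samples, population = populations)
  call_df <- as.data.frame(code)
  names(call_df) <- loci
  dplyr::bind_cols(out, as_tibble(call_df))
}

#' Simulate divergent founder populations
#'
#' Balding-Nichols divergence: per population and locus, the founder allele
#' frequency is drawn from `Beta(p (1 - theta) / theta, (1 - p)(1 - theta) /
#' theta)` around the ancestral frequency `p`, with `theta = fst`; founder
#' genotypes are then drawn in Hardy-Weinberg proportions. Ancestral
#' frequencies of exactly 0 or 1 stay fixed.
#'
#' @param freqs Ancestral allele-A frequencies
#'   (e.g. [simulate_ancestral_freqs()]).
#' @param fst Divergence parameter strictly inside (0, 1).
#' @param pop_sizes Integer vector of founder counts per population.
#' @param seed Integer seed.
#' @param pop_names Optional population labels (default `Pop1..Popk`).
#' @return A list with `data` (genotype tibble) and `truth` (list with the
#'   ancestral and realised per-population founder frequencies).
#' @export
simulate_populations <- function(freqs, fst, pop_sizes, seed = 1,
                                 pop_names = NULL) {
  if (fst <= 0 || fst >= 1) abort("`fst` must be strictly inside (0, 1)")
  if (any(pop_sizes < 1)) abort("population sizes must be >= 1")
  k <- length(pop_sizes)
  if (is.null(pop_names)) pop_names <- paste0("Pop", seq_len(k))
  set.seed(derive_seed(seed, "populations"))
  n_loci <- length(freqs)
  a <- freqs * (1 - fst) / fst
  b <- (1 - freqs) * (1 - fst) / fst
  founder_freqs <- matrix(NA_real_, k, n_loci,
                          dimnames = list(pop_names, NULL))
  for (i in seq_len(k)) {
    pf <- stats::rbeta(n_loci, a, b)
    fixed <- freqs %in% c(0, 1)
    pf[fixed] <- freqs[fixed]
    founder_freqs[i, ] <- pf
  }
  dosage <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rbinom(pop_sizes[i] * n_loci, 2,
                         rep(founder_freqs[i, ], each = pop_sizes[i])),
           nrow = pop_sizes[i])
  }))
  samples <- unlist(lapply(seq_len(k), function(i) {
    sprintf("%s-%02d", pop_names[i], seq_len(pop_sizes[i]))
  }))
  populations <- rep(pop_names, pop_sizes)
  list(
    data = code_to_tibble(dosage_to_code(dosage), samples, populations,
                          paste0("L", seq_len(n_loci))),
    truth = list(ancestral = freqs, founder_freqs = founder_freqs,
                 fst = fst, pop_sizes = pop_sizes, pop_names = pop_names)
  )
}

# one gamete per locus from a genotype-code vector (returns 0/1 copies of A)
draw_gametes <- function(code) {
  g <- integer(length(code))
  g[code == 0L] <- 1L
  g[code == 1L] <- 0L
  het <- code == 2L
  g[het] <- stats::rbinom(sum(het), 1, 0.5)
  g
}

#' Advance populations by sib-mating or selfing
#'
#' Per population and generation, draws two parents (full-sib regime) or one
#' (selfing regime) at random from the current generation and produces
#' `family_size` offspring by independent Mendelian gamete draws per locus,
#' which become the next generation. This is the in-silico analogue of
#' advancing inbred lines where self-incompatibility forces sib-mating.
#'
#' @param df Genotype tibble (complete calls).
#' @param generations Number of generations (>= 0; 0 returns `df`).
#' @param family_size Offspring per family; default keeps each population at
#'   its current size. Must be >= 2 under the full-sib regime.
#' @param seed Integer seed.
#' @param regime `"full-sib"` (default) or `"selfing"`.
#' @return A genotype tibble of the final generation, with a `pedigree`
#'   attribute recording the parent picks per population and generation.
#' @export
sib_mate <- function(df, generations, family_size = NULL, seed = 1,
                     regime = c("full-sib", "selfing")) {
  regime <- match.arg(regime)
  validate_genotypes(df)
  if (generations < 0) abort("`generations` must be >= 0")
  set.seed(derive_seed(seed, paste0("sibmate-", regime)))
  pops <- unique(df$population)
  loci <- locus_names(df)
  pedigree <- list()
  cur <- split(df, factor(df$population, levels = pops))
  for (gen in seq_len(generations)) {
    cur <- lapply(cur, function(sub) {
      n_off <- if (is.null(family_size)) nrow(sub) else family_size
      if (regime == "full-sib") {
        if (n_off < 2) abort("`family_size` must be >= 2 under full-sib mating")
        if (nrow(sub) < 2) abort("full-sib mating needs >= 2 individuals per population")
        par_idx <- sample(nrow(sub), 2)
      } else {
        par_idx <- rep(sample(nrow(sub), 1), 2)
      }
      pedigree[[length(pedigree) + 1]] <<- list(
        population = sub$population[1], generation = gen,
        parents = sub$sample[unique(par_idx)]
      )
      m <- genotype_matrix(sub)
      p1 <- m[par_idx[1], ]; p2 <- m[par_idx[2], ]
      dosage <- t(vapply(seq_len(n_off), function(i) {
        draw_gametes(p1) + draw_gametes(p2)
      }, numeric(length(loci))))
      code_to_tibble(dosage_to_code(dosage),
                     sprintf("%s-g%d-%02d", sub$population[1], gen,
                             seq_len(n_off)),
                     rep(sub$population[1], n_off), loci)
    })
  }
  out <- dplyr::bind_rows(cur)
  attr(out, "pedigree") <- pedigree
  out
}

#' Admix one population from two source populations
#'
#' Replaces each individual of the target population by one whose two
#' gametes are drawn, independently, from a random individual of source
#' population A with probability `proportion` and from source population B
#' otherwise (gamete-level admixture; `proportion = 0.5` emulates an F1-like
#' 50:50 ancestry).
#'
#' @param df Genotype tibble.
#' @param target Population label to replace.
#' @param sources Length-2 character vector of source population labels.
#' @param proportion Probability of drawing each gamete from `sources[1]`.
#' @param seed Integer seed.
#' @return The genotype tibble with the target population regenerated.
#' @export
simulate_admixture <- function(df, target, sources, proportion = 0.5,
                               seed = 1) {
  validate_genotypes(df)
  if (proportion < 0 || proportion > 1) abort("`proportion` must be in [0, 1]")
  if (length(sources) != 2) abort("`sources` must name two populations")
  if (!all(c(target, sources) %in% df$population)) {
    abort("target and source populations must exist in the dataset")
  }
  set.seed(derive_seed(seed, "admixture"))
  m <- genotype_matrix(df)
  tgt_rows <- which(df$population == target)
  src_rows <- lapply(sources, function(p) which(df$population == p))
  new_dosage <- t(vapply(tgt_rows, function(i) {
    gam <- lapply(1:2, function(g) {
      from <- if (stats::runif(1) < proportion) 1 else 2
      donor <- sample(src_rows[[from]], 1)
      draw_gametes(m[donor, ])
    })
    gam[[1]] + gam[[2]]
  }, numeric(ncol(m))))
  code <- dosage_to_code(new_dosage)
  out <- df
  out[tgt_rows, locus_names(df)] <- as.data.frame(code)
  out
}

#' Inject missing calls at random
#'
#' Sets each call to missing independently with probability `rate` and
#' returns the mask used, so the completeness filter can be tested against
#' ground truth.
#'
#' @param df Genotype tibble.
#' @param rate Per-call missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The genotype tibble with a logical `missing_mask` attribute
#'   (samples x loci).
#' @export
inject_missing <- function(df, rate, seed = 1) {
  validate_genotypes(df)
  if (rate < 0 || rate >= 1) abort("`rate` must be in [0, 1)")
  set.seed(derive_seed(seed, "missing"))
  loci <- locus_names(df)
  mask <- matrix(stats::runif(nrow(df) * length(loci)) < rate,
                 nrow = nrow(df),
                 dimnames = list(df$sample, loci))
  m <- genotype_matrix(df)
  m[mask] <- NA_integer_
  out <- code_to_tibble(m, df$sample, df$population, loci)
  attr(out, "missing_mask") <- mask
  out
}

# random ACGT string of length n using the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthetic male-sterility locus (myb80-like) for the CAPS assay
#'
#' Builds, deterministically given the seed, a pair of allele sequences for
#' the nuclear male-sterility locus: a fertile (wild-type) allele whose
#' amplicon between the assay primers is 298 bp and contains no Tru1I site,
#' and a sterile allele identical except for a 4-nt `AATT` insertion placed
#' immediately after a `TT` dinucleotide — creating exactly one `TTAA`
#' recognition site — positioned so the 302-bp sterile amplicon digests into
#' 230 + 72 bp fragments. Synthetic stand-ins for the deposited reference
#' alleles; the primer pair is the published assay pair.
#'
#' @param seed Integer seed.
#' @param flank Length of random flanking sequence on each side of the
#'   amplicon (default 50).
#' @return A list: `fertile_allele`, `sterile_allele` (full templates with
#'   flanks), `fwd`, `rev` ([primer()]s), `site` ([restriction_site()]),
#'   `truth` (tibble of the three diploid genotypes with their allele
#'   pairs).
#' @export
synth_myb80_locus <- function(seed = 1, flank = 50) {
  set.seed(derive_seed(seed, "myb80"))
  fwd <- primer("CiMyb80_for", "ACTGCGGTTGCTGGTCA")
  rev <- primer("CiMyb80_rev", "CCCTGCTCATGCTCCTG")
  site <- restriction_site("TTAA", 1)
  amp_len <- 298L
  cut_pos <- 230L # 5' fragment length after insertion-induced cut
  forbidden <- c("TTAA", "AATT", fwd$sequence, rc(fwd$sequence),
                 rev$sequence, rc(rev$sequence))
  repeat {
    mid <- random_dna(amp_len - nchar(fwd$sequence) - nchar(rev$sequence))
    fertile_amp <- paste0(fwd$sequence, mid, rc(rev$sequence))
    # force a TT dinucleotide at the cut position, guarded against
    # accidentally completing a motif
    substr(fertile_amp, cut_pos, cut_pos + 2L) <- "TTG"
    left <- random_dna(flank)
    right <- random_dna(flank)
    fertile <- paste0(left, fertile_amp, right)
    sterile_amp <- paste0(substr(fertile_amp, 1, cut_pos + 1L), "AATT",
                          substr(fertile_amp, cut_pos + 2L, amp_len))
    sterile <- paste0(left, sterile_amp, right)
    count_hits <- function(s, p) {
      h <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
      sum(h > 0)
    }
    ok_fertile <- all(vapply(forbidden[1:2], count_hits, numeric(1),
                             s = fertile) == 0) &&
      count_hits(fertile, fwd$sequence) == 1 &&
      count_hits(fertile, rc(rev$sequence)) == 1 &&
      count_hits(fertile, rev$sequence) == 0 &&
      count_hits(fertile, rc(fwd$sequence)) == 0
    ok_sterile <- count_hits(sterile, "TTAA") == 1 &&
      count_hits(sterile, "AATT") == 1
    if (ok_fertile && ok_sterile) break
  }
  truth <- tibble(
    sample = c("MsMs-1", "Msms-1", "msms-1"),
    genotype = c("MsMs", "Msms", "msms"),
    allele1 = c("fertile", "fertile", "sterile"),
    allele2 = c("fertile", "sterile", "sterile")
  )
  list(fertile_allele = fertile, sterile_allele = sterile,
       fwd = fwd, rev = rev, site = site, truth = truth)
}

#' Synthetic breeding cohort
#'
#' Composes the generators into a full study-like cohort: divergent founder
#' populations (Balding-Nichols), optional gamete-level admixture of one
#' population, several generations of full-sib mating, and random missing
#' calls. The defaults emulate a four-population full-sib breeding core
#' collection: sizes 15/17/37/25, 9351 raw loci of which roughly 2950
#' survive complete-call filtering at the default missing rate, strong
#' divergence (`fst = 0.5`), three sib-mating generations, and the first
#' population admixed 50:50 with the second.
#'
#' @param n_loci Number of simulated loci.
#' @param pop_sizes Population sizes.
#' @param fst Balding-Nichols divergence parameter.
#' @param sib_generations Generations of full-sib mating.
#' @param admixture `NULL`, or a list with `target`, `sources` (length 2)
#'   and `proportion`, applied to the founders before sib-mating.
#' @param missing_rate Per-call missingness probability.
#' @param seed Master seed; component generators derive their own streams
#'   from it.
#' @return A list with `data` (genotype tibble, missing injected) and
#'   `truth` (ancestral/founder frequencies, pedigree, missing mask, and the
#'   configuration).
#' @export
synth_cohort <- function(n_loci = 9351,
                         pop_sizes = c(15, 17, 37, 25),
                         fst = 0.5,
                         sib_generations = 3,
                         admixture = list(target = "Pop1",
                                          sources = c("Pop1", "Pop2"),
                                          proportion = 0.5),
                         missing_rate = 0.0122,
                         seed = 1) {
  freqs <- simulate_ancestral_freqs(n_loci, seed = seed)
  founders <- simulate_populations(freqs, fst, pop_sizes, seed = seed)
  dat <- founders$data
  if (!is.null(admixture)) {
    dat <- simulate_admixture(dat, admixture$target, admixture$sources,
                              admixture$proportion, seed = seed)
  }
  if (sib_generations > 0) {
    dat <- sib_mate(dat, sib_generations, seed = seed)
  }
  pedigree <- attr(dat, "pedigree")
  if (missing_rate > 0) {
    dat <- inject_missing(dat, missing_rate, seed = seed)
  }
  list(
    data = dat,
    truth = list(
      ancestral = freqs,
      founder_freqs = founders$truth$founder_freqs,
      pedigree = pedigree,
      missing_mask = attr(dat, "missing_mask"),
      config = list(n_loci = n_loci, pop_sizes = pop_sizes, fst = fst,
                    sib_generations = sib_generations, admixture = admixture,
                    missing_rate = missing_rate, seed = seed)
    )
  )
}
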