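#' Per-population allele frequencies
#'
#' Frequency of allele A per locus, overall or split by population.
#'
#' @param df Genotype tibble (see [validate_genotypes()]).
#' @param population Optional population label; `NULL` computes frequencies
#'   in every population.
#' @return A tibble with columns `population`, `locus`, `p` (frequency of
#'   allele A; `NA` where no sample was genotyped) and `n`.
#' @export
allele_frequencies <- function(df, population = NULL) {
  validate_genotypes(df)
  pops <- if (is.null(population)) unique(df$population) else population
  if (!all(pops %in% df$population)) {
    abort(sprintf("unknown population '%s'",
                  paste(setdiff(pops, df$population), collapse = ", ")))
  }
  purrr::map_dfr(pops, function(pop) {
    ac <- allele_counts(df, population = pop)
    tibble(
      population = pop,
      locus = ac$locus,
      p = ifelse(ac$n > 0, ac$count_a / (2 * ac$n), NA_real_),
      n = ac$n
    )
  })
}

# per-population, per-locus building blocks shared by the summary tables:
# p, q, observed-het fraction, na (alleles seen), ne = 1/(p^2+q^2), he = 2pq
per_locus_pop_stats <- function(df) {
  validate_genotypes(df)
  loci <- locus_names(df)
  m <- genotype_matrix(df)
  pops <- unique(df$population)
  purrr::map_dfr(pops, function(pop) {
    sub <- m[df$population == pop, , drop = FALSE]
    n <- colSums(!is.na(sub))
    a <- colSums(sub == 0L, na.rm = TRUE) * 2 + colSums(sub == 2L, na.rm = TRUE)
    p <- ifelse(n > 0, a / (2 * n), NA_real_)
    q <- 1 - p
    ho <- ifelse(n > 0, colSums(sub == 2L, na.rm = TRUE) / n, NA_real_)
    tibble(
      population = pop, locus = loci, n = unname(n), p = unname(p),
      na = unname((p > 0) + (q > 0)),
      ne = unname(1 / (p^2 + q^2)),
      ho = unname(ho),
      he = unname(2 * p * q)
    )
  })
}

#' Population diversity summary
#'
#' Per-population means over loci of the standard SNP diversity statistics:
#' observed (`na`) and effective (`ne`) alleles, observed and expected
#' heterozygosity (`ho`, `he`, in percent), fixation index
#' `f = (he - ho) / he` averaged over loci with `he > 0`, percentage of
#' polymorphic loci (`pl_pct`), and private alleles (`pa_count`, with
#' `pa_pct` expressed relative to all alleles observed in that population).
#' A final `Mean` row holds the unweighted mean of the per-population values.
#'
#' @param df Genotype tibble with at least one population; loci are expected
#'   to be complete (see [filter_complete_loci()]).
#' @return A tibble with one row per population plus a `Mean` row.
#' @export
population_summary <- function(df) {
  validate_genotypes(df)
  if (!length(locus_names(df))) abort("no loci in dataset")
  if (!nrow(df)) abort("no samples in dataset")
  pl <- per_locus_pop_stats(df)
  pops <- unique(df$population)

  # private alleles: allele (A or B) present in exactly one population
  pres <- pl %>%
    dplyr::mutate(has_a = .data$p > 0, has_b = .data$p < 1) %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::mutate(
      private_a = .data$has_a & sum(.data$has_a) == 1L,
      private_b = .data$has_b & sum(.data$has_b) == 1L
    ) %>%
    dplyr::ungroup()

  sizes <- df %>% dplyr::count(.data$population, name = "n_samples")
  per_pop <- pres %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(
      na_mean = mean(.data$na, na.rm = TRUE),
      ne = mean(.data$ne, na.rm = TRUE),
      ho_mean = 100 * mean(.data$ho, na.rm = TRUE),
      he_mean = 100 * mean(.data$he, na.rm = TRUE),
      f = mean(((.data$he - .data$ho) / .data$he)[.data$he > 0], na.rm = TRUE),
      pl_pct = 100 * mean(.data$na == 2, na.rm = TRUE),
      pa_count = sum(.data$private_a) + sum(.data$private_b),
      alleles_observed = sum(.data$na, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::left_join(sizes, by = "population") %>%
    dplyr::mutate(pa_pct = 100 * .data$pa_count / .data$alleles_observed) %>%
    dplyr::select("population", n = "n_samples", na = "na_mean", "ne",
                  ho = "ho_mean", he = "he_mean", "f", "pl_pct",
                  "pa_count", "pa_pct") %>%
    dplyr::arrange(match(.data$population, pops))

  mean_row <- per_pop %>%
    dplyr::summarise(dplyr::across(-"population", mean)) %>%
    dplyr::mutate(population = "Mean", .before = 1)
  dplyr::bind_rows(per_pop, mean_row)
}

#' Wright's F-statistics and gene flow
#'
#' Computes, per locus across populations, the mean within-population
#' expected heterozygosity `Hs` (unweighted mean of `2pq`), the total
#' expected heterozygosity `Ht = 2 p-bar q-bar` from the unweighted mean
#' allele frequency, and the fixation indices
#' `Fis = (Hs - Ho-bar)/Hs`, `Fit = (Ht - Ho-bar)/Ht`,
#' `Fst = (Ht - Hs)/Ht`, each averaged over loci with a positive
#' denominator (the spreadsheet-convention estimator commonly reported for
#' codominant SNP panels). Island-model gene flow is
#' `Nm = 0.25 (1 - Fst) / Fst` from the mean Fst (infinite when `Fst = 0`).
#' Standard errors are sd across loci divided by the square root of the
#' locus count.
#'
#' @param df Genotype tibble with at least two populations.
#' @return An object of class `fstat`; use [tidy()] for the per-statistic
#'   table (estimate and SE) and [glance()] for a one-row summary.
#' @export
f_statistics <- function(df) {
  validate_genotypes(df)
  pops <- unique(df$population)
  if (length(pops) < 2) abort("F-statistics need at least two populations")
  pl <- per_locus_pop_stats(df)
  by_locus <- pl %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(
      hs = mean(.data$he, na.rm = TRUE),
      pbar = mean(.data$p, na.rm = TRUE),
      hobar = mean(.data$ho, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      ht = 2 * .data$pbar * (1 - .data$pbar),
      fis = ifelse(.data$hs > 0, (.data$hs - .data$hobar) / .data$hs, NA_real_),
      fit = ifelse(.data$ht > 0, (.data$ht - .data$hobar) / .data$ht, NA_real_),
      fst = ifelse(.data$ht > 0, (.data$ht - .data$hs) / .data$ht, NA_real_)
    )
  est <- function(x) mean(x, na.rm = TRUE)
  fst <- est(by_locus$fst)
  out <- list(
    summary = tibble(
      statistic = c("Hs", "Ht", "Fis", "Fit", "Fst", "Nm"),
      estimate = c(est(by_locus$hs), est(by_locus$ht), est(by_locus$fis),
                   est(by_locus$fit), fst,
                   if (isTRUE(fst > 0)) 0.25 * (1 - fst) / fst else Inf),
      se = c(se_of(by_locus$hs), se_of(by_locus$ht), se_of(by_locus$fis),
             se_of(by_locus$fit), se_of(by_locus$fst), NA_real_)
    ),
    per_locus = by_locus,
    n_populations = length(pops),
    n_loci = nrow(by_locus)
  )
  class(out) <- "fstat"
  out
}

#' @export
print.fstat <- function(x, ...) {
  cat(sprintf("Wright's F-statistics over %d loci, %d populations\n",
              x$n_loci, x$n_populations))
  print(x$summary, ...)
  invisible(x)
}

#' @rdname f_statistics
#' @param x An `fstat` object.
#' @param ... Unused.
#' @method tidy fstat
#' @export
tidy.fstat <- function(x, ...) x$summary

#' @rdname f_statistics
#' @method glance fstat
#' @export
glance.fstat <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$estimate),
                          tolower(x$summary$statistic))
  dplyr::bind_cols(as_tibble(wide),
                   tibble(n_loci = x$n_loci, n_populations = x$n_populations))
}

#' Evanno delta-K from admixture-run log-likelihoods
#'
#' Given replicate log-likelihoods `L(K)` of an admixture/structure model at
#' consecutive K, computes the second-order rate of change
#' `deltaK(K) = mean over replicates |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`.
#' Endpoint K values and K with zero replicate spread have no defined deltaK.
#'
#' @param lnp Data frame with columns `k`, `replicate`, `lnp` (one row per
#'   replicate run). K values must be consecutive integers, with the same
#'   number (at least 2) of replicates at every K.
#' @return A tibble with one row per K: `k`, `n_rep`, `mean_lnp`, `sd_lnp`,
#'   `lprime` (first difference of mean L), `ldoubleprime_abs`, `delta_k`,
#'   `defined`. The K maximising delta-K is attached as attribute `best_k`.
#' @export
evanno_delta_k <- function(lnp) {
  lnp <- as_tibble(lnp)
  names(lnp) <- tolower(names(lnp))
  if (!all(c("k", "lnp") %in% names(lnp))) {
    abort("`lnp` needs columns k, replicate, lnp")
  }
  if (!"replicate" %in% names(lnp)) lnp$replicate <- seq_len(nrow(lnp))
  ks <- sort(unique(lnp$k))
  if (length(ks) < 3) abort("need at least 3 consecutive K values")
  if (!all(diff(ks) == 1)) abort("K values must be consecutive integers")
  counts <- table(lnp$k)
  if (length(unique(counts)) != 1 || any(counts < 2)) {
    abort("every K needs the same number (>= 2) of replicate runs")
  }
  # replicate-matched matrix: rows = replicates (by order within K), cols = K
  L <- lnp %>%
    dplyr::arrange(.data$k, .data$replicate) %>%
    dplyr::group_by(.data$k) %>%
    dplyr::mutate(.rep = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    tidyr::pivot_wider(id_cols = ".rep", names_from = "k",
                       values_from = "lnp") %>%
    dplyr::select(-".rep") %>%
    as.matrix()
  mean_l <- colMeans(L)
  sd_l <- apply(L, 2, stats::sd)
  nk <- length(ks)
  lpp <- rep(NA_real_, nk)
  for (i in seq(2, nk - 1)) {
    lpp[i] <- mean(abs(L[, i + 1] - 2 * L[, i] + L[, i - 1]))
  }
  delta <- ifelse(!is.na(lpp) & sd_l > 0, lpp / sd_l, NA_real_)
  out <- tibble(
    k = ks,
    n_rep = unname(as.integer(counts)),
    mean_lnp = unname(mean_l),
    sd_lnp = unname(sd_l),
    lprime = unname(c(NA_real_, diff(mean_l))),
    ldoubleprime_abs = lpp,
    delta_k = unname(delta),
    defined = unname(!is.na(delta))
  )
  attr(out, "best_k") <-
    if (any(out$defined)) out$k[which.max(out$delta_k)] else NA_integer_
  out
}

#' Read a replicate log-likelihood table for delta-K
#'
#' Parses a TSV with columns `K`, `replicate`, `lnP` (case-insensitive;
#' tolerant of extra columns) as exported from admixture-software summaries.
#'
#' @param path File path.
#' @return A tibble suitable for [evanno_delta_k()].
#' @export
read_lnp_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  names(tab) <- tolower(names(tab))
  names(tab)[names(tab) == "lnp"] <- "lnp"
  if (!all(c("k", "replicate", "lnp") %in% names(tab))) {
    abort("expected TSV columns K, replicate, lnP")
  }
  as_tibble(tab[c("k", "replicate", "lnp")])
}
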