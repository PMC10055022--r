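#' Pairwise squared genetic distances for codominant SNPs
#'
#' The codominant genotypic squared distance: per locus, identical genotypes
#' score 0, homozygote vs heterozygote 1, opposite homozygotes 4 (the squared
#' Euclidean distance between allele-dosage vectors), summed over loci. This
#' is the distance basis of the distance-based AMOVA.
#'
#' @param df Genotype tibble with complete loci (no missing calls).
#' @return A symmetric numeric matrix (samples x samples) with zero diagonal;
#'   population labels attached as attribute `populations`.
#' @export
squared_distance_matrix <- function(df) {
  validate_genotypes(df)
  d <- allele_dosage_matrix(df)
  if (anyNA(d)) abort("missing calls present; run filter_complete_loci() first")
  m <- as.matrix(stats::dist(d, method = "euclidean"))^2
  dimnames(m) <- list(df$sample, df$sample)
  attr(m, "populations") <- stats::setNames(df$population, df$sample)
  m
}

# variance-component estimation shared by amova() and amova_from_summaries()
amova_components <- function(ss_among, ss_within, df_among, df_within,
                             pop_sizes) {
  n_total <- sum(pop_sizes)
  k <- length(pop_sizes)
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n_total - sum(pop_sizes^2) / n_total) / (k - 1)
  var_within <- ms_within
  var_among_raw <- (ms_among - ms_within) / n0
  floored <- var_among_raw < 0
  var_among <- max(var_among_raw, 0)
  var_total <- var_among + var_within
  list(
    table = tibble(
      source = c("Among Pops", "Within Pops", "Total"),
      df = unname(c(df_among, df_within, df_among + df_within)),
      ss = unname(c(ss_among, ss_within, ss_among + ss_within)),
      ms = unname(c(ms_among, ms_within, NA_real_)),
      est_var = unname(c(var_among, var_within, var_total)),
      pct = unname(100 * c(var_among, var_within, var_total) /
        ifelse(var_total > 0, var_total, NA_real_))
    ),
    n0 = unname(n0),
    phi_pt = unname(if (var_total > 0) var_among / var_total else 0),
    degenerate = unname(var_total <= 0),
    floored = unname(floored)
  )
}

# sums of squares from a squared-distance matrix and a label vector
amova_ss <- function(d2, pops) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(unique(pops), function(p) {
    idx <- which(pops == p)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Distance-based AMOVA partitioning molecular variance among and within
#' populations, with a whole-individual label-permutation test of PhiPT
#' (the among-population fraction of total variance). Sums of squares come
#' from the squared-distance partition
#' `SS_total = sum_{i<j} d2_ij / N` and
#' `SS_within = sum_pops sum_{i<j in pop} d2_ij / n_pop`;
#' variance components use the unequal-sample-size coefficient
#' `n0 = (N - sum(n_pop^2)/N) / (k - 1)`, with a negative among-population
#' component floored at zero. The permutation p-value uses the `+1`
#' correction, so its floor is `1 / (n_permutations + 1)`.
#'
#' @param df Genotype tibble with >= 2 populations, each with >= 2 samples,
#'   and complete loci.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `amova`: use [tidy()] for the
#'   df/SS/MS/variance table and [glance()] for PhiPT, p-value and n0.
#' @export
amova <- function(df, n_permutations = 999, seed = 1) {
  validate_genotypes(df)
  sizes <- table(df$population)
  if (length(sizes) < 2) abort("AMOVA needs at least two populations")
  if (any(sizes < 2)) abort("every population needs at least two samples")
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  d2 <- squared_distance_matrix(df)
  pops <- df$population
  ss <- amova_ss(d2, pops)
  k <- length(sizes)
  n <- nrow(df)
  comp <- amova_components(ss["among"], ss["within"], k - 1, n - k,
                           as.numeric(sizes))
  obs_phi <- comp$phi_pt

  set.seed(seed)
  perm_phi <- vapply(seq_len(n_permutations), function(i) {
    pp <- sample(pops)
    pss <- amova_ss(d2, pp)
    amova_components(pss["among"], pss["within"], k - 1, n - k,
                     as.numeric(table(pp)))$phi_pt
  }, numeric(1))
  p <- (sum(perm_phi >= obs_phi) + 1) / (n_permutations + 1)

  out <- c(comp, list(
    p_value = p, n_permutations = n_permutations,
    perm_phi = perm_phi, n_samples = n, n_populations = k
  ))
  class(out) <- "amova"
  out
}

#' AMOVA variance components from printed summaries
#'
#' Recovers estimated variance components, percentages and PhiPT from
#' already-computed sums of squares, degrees of freedom and population sizes
#' (e.g. the rows of a published AMOVA table), using the same estimation
#' equations as [amova()]. No permutation test is possible at this level.
#'
#' @param ss_among,ss_within Sums of squares among/within populations.
#' @param df_among,df_within Degrees of freedom (`k - 1` and `N - k`).
#' @param pop_sizes Integer vector of population sample sizes.
#' @return An object of class `amova` with `p_value = NA`.
#' @examples
#' fit <- amova_from_summaries(104231, 50439, 3, 90, c(15, 17, 37, 25))
#' tidy(fit)
#' @export
amova_from_summaries <- function(ss_among, ss_within, df_among, df_within,
                                 pop_sizes) {
  k <- length(pop_sizes)
  n <- sum(pop_sizes)
  if (df_among != k - 1 || df_within != n - k) {
    abort(sprintf(
      "degrees of freedom inconsistent with %d populations of %d samples (expected %d and %d)",
      k, n, k - 1, n - k
    ))
  }
  if (ss_among < 0 || ss_within < 0) abort("sums of squares must be >= 0")
  comp <- amova_components(ss_among, ss_within, df_among, df_within, pop_sizes)
  out <- c(comp, list(
    p_value = NA_real_, n_permutations = 0L,
    perm_phi = numeric(0), n_samples = n, n_populations = k
  ))
  class(out) <- "amova"
  out
}

#' @export
print.amova <- function(x, ...) {
  cat(sprintf("AMOVA: %d samples, %d populations\n",
              x$n_samples, x$n_populations))
  print(x$table, ...)
  cat(sprintf("PhiPT = %.4f", x$phi_pt))
  if (!is.na(x$p_value)) {
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_permutations))
  }
  cat("\n")
  if (x$floored) cat("note: negative among-population component floored at 0\n")
  if (x$degenerate) cat("note: zero total variance (degenerate input)\n")
  invisible(x)
}

#' @rdname amova
#' @param x An `amova` object.
#' @param ... Unused.
#' @method tidy amova
#' @export
tidy.amova <- function(x, ...) x$table

#' @rdname amova
#' @method glance amova
#' @export
glance.amova <- function(x, ...) {
  tibble(
    phi_pt = x$phi_pt, p_value = x$p_value,
    n_permutations = x$n_permutations, n0 = x$n0,
    n_samples = x$n_samples, n_populations = x$n_populations,
    degenerate = x$degenerate, floored = x$floored
  )
}
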