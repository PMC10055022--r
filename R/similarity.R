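#' Simple-matching genetic similarity
#'
#' Rohlf's simple-matching coefficient on allele-presence-coded genotypes:
#' each biallelic locus expands to two binary allele-presence characters
#' (`0 -> (1,0)`, `1 -> (0,1)`, `2 -> (1,1)`), and GS is the fraction of
#' matching characters. Equivalently, per-locus scores of 1 (identical
#' genotype), 0.5 (homozygote vs heterozygote) and 0 (opposite homozygotes)
#' averaged over loci.
#'
#' @param df Genotype tibble with complete loci.
#' @return A symmetric matrix of class `gs_matrix` with unit diagonal and
#'   entries in `[0, 1]`; population labels attached as attribute
#'   `populations`. Use [tidy()] for a long pairwise tibble.
#' @export
simple_matching_gs <- function(df) {
  validate_genotypes(df)
  d <- allele_dosage_matrix(df)
  if (anyNA(d)) abort("missing calls present; run filter_complete_loci() first")
  n_loci <- ncol(d)
  if (!n_loci) abort("no loci in dataset")
  # |dosage difference| is 0 / 1 / 2 for identical / hom-vs-het / opposite hom,
  # so GS = 1 - manhattan / (2 L)
  gs <- 1 - as.matrix(stats::dist(d, method = "manhattan")) / (2 * n_loci)
  dimnames(gs) <- list(df$sample, df$sample)
  attr(gs, "populations") <- stats::setNames(df$population, df$sample)
  class(gs) <- c("gs_matrix", class(gs))
  gs
}

#' @export
print.gs_matrix <- function(x, ...) {
  cat(sprintf("simple-matching genetic similarity, %d samples\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @rdname simple_matching_gs
#' @param x A `gs_matrix`.
#' @param ... Unused.
#' @return `tidy.gs_matrix()` returns one row per unordered sample pair with
#'   columns `sample_a`, `sample_b`, `pop_a`, `pop_b`, `gs`.
#' @method tidy gs_matrix
#' @export
tidy.gs_matrix <- function(x, ...) {
  pops <- attr(x, "populations")
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    sample_a = rownames(x)[idx[, 1]],
    sample_b = colnames(x)[idx[, 2]],
    pop_a = unname(pops[rownames(x)[idx[, 1]]]),
    pop_b = unname(pops[colnames(x)[idx[, 2]]]),
    gs = x[idx]
  )
}

#' Per-sample observed homozygosity
#'
#' Fraction of loci at which each sample is homozygous (call 0 or 1);
#' homozygosity and heterozygosity sum to 1 per sample.
#'
#' @param df Genotype tibble with complete loci.
#' @return A tibble with columns `sample`, `population`, `obs_hom`.
#' @export
observed_homozygosity <- function(df) {
  validate_genotypes(df)
  m <- genotype_matrix(df)
  if (anyNA(m)) abort("missing calls present; run filter_complete_loci() first")
  tibble(
    sample = df$sample,
    population = df$population,
    obs_hom = unname(rowMeans(m != 2L))
  )
}

#' Within- and among-population similarity summary
#'
#' Mean simple-matching GS within each population (self-pairs excluded;
#' `n (n - 1) / 2` pairs) and among each population pair (`n1 * n2` pairs),
#' with standard errors over pairs, plus per-population mean observed
#' homozygosity (reported on the within rows).
#'
#' @param df Genotype tibble with complete loci.
#' @param gs Optional precomputed [simple_matching_gs()] matrix.
#' @return A tibble with columns `pop_a`, `pop_b`, `type`
#'   (`"within"`/`"among"`), `n_pairs`, `mean_gs`, `se_gs`, `mean_obs_hom`,
#'   `se_obs_hom`. Populations of size 1 yield `NA` within-GS (flagged by
#'   `n_pairs = 0`).
#' @export
group_similarity_summary <- function(df, gs = NULL) {
  validate_genotypes(df)
  if (is.null(gs)) gs <- simple_matching_gs(df)
  hom <- observed_homozygosity(df)
  pops <- unique(df$population)
  pairs <- tidy(gs)
  hom_sum <- hom %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(mean_obs_hom = mean(.data$obs_hom),
                     se_obs_hom = se_of(.data$obs_hom), .groups = "drop")

  combos <- tidyr::expand_grid(
    a = seq_along(pops), b = seq_along(pops)
  ) %>% dplyr::filter(.data$a <= .data$b)

  purrr::pmap_dfr(combos, function(a, b) {
    pa <- pops[a]; pb <- pops[b]
    vals <- pairs %>%
      dplyr::filter((.data$pop_a == pa & .data$pop_b == pb) |
                      (.data$pop_a == pb & .data$pop_b == pa)) %>%
      dplyr::pull("gs")
    within <- identical(pa, pb)
    tibble(
      pop_a = pa, pop_b = pb,
      type = if (within) "within" else "among",
      n_pairs = length(vals),
      mean_gs = if (length(vals)) mean(vals) else NA_real_,
      se_gs = if (length(vals) == 1) 0 else se_of(vals),
      mean_obs_hom = if (within) hom_sum$mean_obs_hom[hom_sum$population == pa]
                     else NA_real_,
      se_obs_hom = if (within) hom_sum$se_obs_hom[hom_sum$population == pa]
                   else NA_real_
    )
  })
}

#' UPGMA dendrogram from a similarity or distance matrix
#'
#' Average-linkage agglomerative clustering on `D = 1 - GS` (or on a distance
#' matrix directly). Cluster-to-cluster distance is the arithmetic mean of
#' all cross pairs of original distances; the resulting tree is ultrametric
#' with node height equal to half the merge distance.
#'
#' @param x A `gs_matrix`, a symmetric distance matrix, or a [stats::dist].
#' @param is_similarity Treat `x` as a similarity matrix (default guesses
#'   from class and diagonal).
#' @return An [ape::phylo] tree with branch lengths in distance units; write
#'   with [ape::write.tree()].
#' @export
upgma <- function(x, is_similarity = NULL) {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    m <- unclass(x)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12))) {
      abort("matrix must be symmetric")
    }
    if (is.null(is_similarity)) {
      is_similarity <- inherits(x, "gs_matrix") ||
        isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m))))
    }
    d <- stats::as.dist(if (is_similarity) 1 - m else m)
  }
  if (attr(d, "Size") < 2) abort("need at least 2 samples")
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' Principal coordinate analysis of a similarity matrix
#'
#' Classical metric multidimensional scaling: the distance `D = 1 - GS`
#' (optionally its square root) is squared, double-centered (Gower) and
#' eigendecomposed; coordinates are eigenvectors scaled by the square root
#' of their eigenvalues. Axis percentages are relative to the sum of
#' positive eigenvalues only; each axis is oriented so its largest-magnitude
#' coordinate is positive.
#'
#' @param x A `gs_matrix` or symmetric distance matrix.
#' @param n_axes Number of axes to retain (default 2; truncated with a
#'   warning if it exceeds the rank).
#' @param sqrt_dist Use `sqrt(1 - GS)` instead of `1 - GS`.
#' @return An object of class `pcoa_result` with elements `scores` (tibble:
#'   sample, population, `axis1..axisn`), `eigenvalues`, `pct_variance`,
#'   `n_negative_eigenvalues`, `degenerate`. [tidy()] returns the scores.
#' @export
pcoa <- function(x, n_axes = 2, sqrt_dist = FALSE) {
  m <- unclass(x)
  pops <- attr(x, "populations")
  is_sim <- inherits(x, "gs_matrix") ||
    isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m))))
  d <- if (is_sim) 1 - m else m
  if (sqrt_dist) d <- sqrt(d)
  n <- nrow(d)
  # Gower double-centering of -0.5 * D^2, full eigendecomposition
  b <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% b %*% ctr
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- eg$values
  pos <- ev > max(ev, 0) * 1e-9
  degenerate <- !any(pos)
  n_pos <- sum(pos)
  if (n_axes > n_pos && !degenerate) {
    warn(sprintf("n_axes = %d exceeds rank %d; truncated", n_axes, n_pos))
  }
  k <- if (degenerate) min(n_axes, n - 1) else min(n_axes, n_pos)
  scores <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- eg$vectors[, j] * sqrt(max(ev[j], 0))
    if (length(v) && v[which.max(abs(v))] < 0) v <- -v
    scores[, j] <- v
  }
  colnames(scores) <- paste0("axis", seq_len(k))
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  out <- list(
    scores = dplyr::bind_cols(
      tibble(sample = ids,
             population = if (!is.null(pops)) unname(pops[ids]) else NA_character_),
      as_tibble(scores)
    ),
    eigenvalues = ev,
    pct_variance = if (degenerate) rep(NA_real_, k) else
      100 * ev[seq_len(k)] / sum(ev[pos]),
    n_negative_eigenvalues = sum(ev < -max(abs(ev)) * 1e-9),
    degenerate = degenerate
  )
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes retained", nrow(x$scores),
              ncol(x$scores) - 2))
  if (x$degenerate) cat(" (degenerate: all eigenvalues ~ 0)")
  cat("\n")
  if (!x$degenerate) {
    cat("percent variance per axis:",
        paste(sprintf("%.1f", x$pct_variance), collapse = ", "), "\n")
  }
  print(x$scores, ...)
  invisible(x)
}

#' @rdname pcoa
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$scores

#' @rdname pcoa
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_axes = ncol(x$scores) - 2,
    pct_axis1 = x$pct_variance[1],
    pct_axis2 = if (length(x$pct_variance) >= 2) x$pct_variance[2] else NA_real_,
    n_negative_eigenvalues = x$n_negative_eigenvalues,
    degenerate = x$degenerate
  )
}
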