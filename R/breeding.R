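#' Expected progeny heterozygosity at a single locus
#'
#' Mendelian expectation of the heterozygote frequency among progeny of a
#' cross between two parental genotypes at one biallelic locus: two identical
#' homozygotes give 0, opposite homozygotes give 1, and any pairing that
#' involves a heterozygote gives 0.5 (e.g. Aa x Aa -> 1/4 AA, 1/2 Aa,
#' 1/4 aa).
#'
#' @param g1,g2 Integer genotype codes in `{0, 1, 2}` (vectorised).
#' @return Numeric vector of expected heterozygote frequencies.
#' @examples
#' expected_progeny_het_locus(0, 1) # 1
#' expected_progeny_het_locus(2, 2) # 0.5
#' @export
expected_progeny_het_locus <- function(g1, g2) {
  if (length(g1) != length(g2)) {
    if (length(g1) == 1) g1 <- rep(g1, length(g2))
    else if (length(g2) == 1) g2 <- rep(g2, length(g1))
    else abort("g1 and g2 must have matching lengths")
  }
  if (anyNA(g1) || anyNA(g2)) abort("missing genotype in cross prediction")
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) {
    abort("genotype codes must be 0, 1 or 2")
  }
  ifelse(g1 == 2L | g2 == 2L, 0.5, ifelse(g1 == g2, 0, 1))
}

#' Expected mean progeny heterozygosity for a cross
#'
#' Mean over loci of [expected_progeny_het_locus()] for a specific parent
#' pair; `parent1 == parent2` encodes selfing, for which the expectation is
#' exactly half the parent's own heterozygosity. Loci are treated as
#' independent, which is exact for single-generation means regardless of
#' linkage.
#'
#' @param df Genotype tibble with complete loci.
#' @param parent1,parent2 Sample ids present in `df`.
#' @return A single expected progeny heterozygosity in `[0, 1]`.
#' @export
expected_progeny_heterozygosity <- function(df, parent1, parent2) {
  validate_genotypes(df)
  m <- genotype_matrix(df)
  for (p in c(parent1, parent2)) {
    if (!p %in% rownames(m)) abort(sprintf("unknown sample '%s'", p))
  }
  mean(expected_progeny_het_locus(m[parent1, ], m[parent2, ]))
}

#' Select elite parents per population
#'
#' Greedy per-population selection of candidate parents for inbred-line
#' maintenance: rank individuals by observed homozygosity (ties broken by
#' input order), seed the selection with the top-ranked individual, then
#' iteratively add the highest-homozygosity candidate whose GS to every
#' already-selected individual exceeds `gs_threshold`. If fewer than `k`
#' individuals qualify, the remaining slots are filled in homozygosity order
#' with `relaxed = TRUE` ("within GS > 90 percent, when possible"). Exactly
#' `min(k, population size)` parents are returned per population.
#'
#' @param df Genotype tibble with complete loci.
#' @param k Number of parents to select per population (default 10).
#' @param gs_threshold Within-population GS cohesion threshold (default 0.90).
#' @param gs Optional precomputed [simple_matching_gs()] matrix.
#' @return A tibble with columns `population`, `sample`, `obs_hom`, `rank`
#'   (selection order within population), `relaxed`.
#' @export
select_parents <- function(df, k = 10, gs_threshold = 0.90, gs = NULL) {
  validate_genotypes(df)
  if (k < 1) abort("`k` must be >= 1")
  if (is.null(gs)) gs <- simple_matching_gs(df)
  hom <- observed_homozygosity(df)
  pops <- unique(df$population)
  purrr::map_dfr(pops, function(pop) {
    cand <- hom %>%
      dplyr::filter(.data$population == pop) %>%
      dplyr::mutate(.ord = dplyr::row_number()) %>%
      dplyr::arrange(dplyr::desc(.data$obs_hom), .data$.ord)
    target <- min(k, nrow(cand))
    sel <- cand$sample[1]
    remaining <- cand$sample[-1]
    while (length(sel) < target && length(remaining)) {
      ok <- vapply(remaining,
                   function(s) all(gs[s, sel] > gs_threshold), logical(1))
      pick <- if (any(ok)) remaining[which(ok)[1]] else remaining[1]
      sel <- c(sel, pick)
      remaining <- setdiff(remaining, pick)
    }
    if (length(sel) < k) {
      inform(sprintf("population '%s': only %d of %d requested parents available",
                     pop, length(sel), k))
    }
    cohesive <- c(TRUE, vapply(seq_along(sel)[-1], function(i) {
      all(gs[sel[i], sel[seq_len(i - 1)]] > gs_threshold)
    }, logical(1)))
    tibble(
      population = pop,
      sample = sel,
      obs_hom = cand$obs_hom[match(sel, cand$sample)],
      rank = seq_along(sel),
      relaxed = !cohesive
    )
  })
}

#' Cross-prediction matrix over selected parents
#'
#' Square matrix over the selected parents (population blocks in input
#' order): expected mean progeny heterozygosity above the diagonal, pairwise
#' GS below the diagonal, and each parent's observed homozygosity on the
#' diagonal. Every cell carries a strategy label: `S` (selfing, diagonal),
#' `FS` (full-sibling, same population) or `F1` (pairwise crossing, different
#' populations).
#'
#' @param df Genotype tibble with complete loci.
#' @param parents Output of [select_parents()], or a character vector of
#'   sample ids.
#' @param gs Optional precomputed [simple_matching_gs()] matrix.
#' @return An object of class `cross_prediction` with elements `matrix`,
#'   `strategy` (label matrix), `parents` (tibble), `self_het` (expected
#'   selfing-progeny heterozygosity per parent). [tidy()] returns one row per
#'   parent pair.
#' @export
cross_prediction_matrix <- function(df, parents, gs = NULL) {
  validate_genotypes(df)
  if (is.data.frame(parents)) parents <- parents$sample
  if (anyDuplicated(parents)) abort("duplicate parent ids")
  if (!all(parents %in% df$sample)) {
    abort(sprintf("unknown sample(s): %s",
                  paste(setdiff(parents, df$sample), collapse = ", ")))
  }
  if (is.null(gs)) gs <- simple_matching_gs(df)
  sub <- df[match(parents, df$sample), , drop = FALSE]
  m <- genotype_matrix(sub)
  pops <- sub$population
  n <- length(parents)
  hom <- observed_homozygosity(sub)$obs_hom
  het <- 1 - hom
  out <- matrix(NA_real_, n, n, dimnames = list(parents, parents))
  strat <- matrix("", n, n, dimnames = list(parents, parents))
  diag(out) <- hom
  diag(strat) <- "S"
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      out[i, j] <- mean(expected_progeny_het_locus(m[i, ], m[j, ]))
      out[j, i] <- gs[parents[i], parents[j]]
      strat[i, j] <- strat[j, i] <- if (pops[i] == pops[j]) "FS" else "F1"
    }
  }
  res <- list(
    matrix = out,
    strategy = strat,
    parents = tibble(sample = parents, population = pops, obs_hom = hom),
    self_het = stats::setNames(het / 2, parents)
  )
  class(res) <- "cross_prediction"
  res
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat(sprintf(
    "cross-prediction matrix: %d parents from %d population(s)\n(GS below diagonal, expected progeny heterozygosity above, parent homozygosity on diagonal)\n",
    nrow(x$parents), dplyr::n_distinct(x$parents$population)
  ))
  k <- min(8, nrow(x$matrix))
  print(round(x$matrix[seq_len(k), seq_len(k)], 3), ...)
  if (nrow(x$matrix) > k) cat("...\n")
  invisible(x)
}

#' @rdname cross_prediction_matrix
#' @param x A `cross_prediction` object.
#' @param ... Unused.
#' @method tidy cross_prediction
#' @export
tidy.cross_prediction <- function(x, ...) {
  n <- nrow(x$matrix)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  ids <- rownames(x$matrix)
  tibble(
    parent1 = ids[idx[, 1]],
    parent2 = ids[idx[, 2]],
    pop1 = x$parents$population[idx[, 1]],
    pop2 = x$parents$population[idx[, 2]],
    strategy = x$strategy[idx],
    gs = x$matrix[cbind(idx[, 2], idx[, 1])],
    expected_het = x$matrix[idx]
  )
}

#' Distribution of expected progeny heterozygosity by breeding strategy
#'
#' Summarises expected progeny heterozygosity for the three strategies:
#' selfing (`S`, one value per selected parent: half its heterozygosity),
#' full-sibling (`FS`, within-population parent pairs) and pairwise crossing
#' (`F1`, between-population pairs, grouped by population pair). Quartiles
#' use linear interpolation.
#'
#' @param x A [cross_prediction_matrix()] result.
#' @return A tibble with columns `strategy`, `group`, `n`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`. Empty categories are omitted.
#' @export
strategy_summary <- function(x) {
  if (!inherits(x, "cross_prediction")) {
    abort("`x` must be a cross_prediction object")
  }
  pairs <- tidy(x)
  five <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble(n = length(v), min = min(v), q1 = q[1], median = q[2],
           mean = mean(v), q3 = q[3], max = max(v))
  }
  s_rows <- x$parents %>%
    dplyr::mutate(self_het = unname(x$self_het)) %>%
    dplyr::group_by(.data$population) %>%
    dplyr::group_modify(~ five(.x$self_het)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(strategy = "S", group = .data$population) %>%
    dplyr::select("strategy", "group", "n", "min", "q1", "median", "mean",
                  "q3", "max")
  fs_rows <- pairs %>%
    dplyr::filter(.data$strategy == "FS") %>%
    dplyr::group_by(group = .data$pop1) %>%
    dplyr::group_modify(~ five(.x$expected_het)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(strategy = "FS") %>%
    dplyr::select("strategy", "group", dplyr::everything())
  f1_rows <- pairs %>%
    dplyr::filter(.data$strategy == "F1") %>%
    dplyr::mutate(group = paste(pmin(.data$pop1, .data$pop2),
                                pmax(.data$pop1, .data$pop2), sep = " x ")) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::group_modify(~ five(.x$expected_het)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(strategy = "F1") %>%
    dplyr::select("strategy", "group", dplyr::everything())
  dplyr::bind_rows(s_rows, fs_rows, f1_rows)
}
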