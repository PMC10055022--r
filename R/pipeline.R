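#' Run the full breeding-design analysis pipeline
#'
#' Sequences the whole analysis on one genotype table: sample missingness
#' filter, complete-call locus filter, per-population diversity summary,
#' F-statistics, AMOVA with permutation test, simple-matching GS with group
#' summary, UPGMA tree, PCoA, parental selection, cross prediction and
#' strategy summary; optionally the in-silico CAPS assay when allele
#' sequences are supplied. All artifacts are written to `out_dir` as
#' delimited text (percentage tables formatted to 2 decimals, half-up),
#' plus a JSON manifest with the configuration, package version and MD5
#' checksums of every output, so a rerun with identical inputs is
#' verifiable.
#'
#' @param df Genotype tibble, or path to a genotype table readable by
#'   [read_genotype_table()].
#' @param out_dir Output directory (created if absent).
#' @param max_missing Per-sample missing-call threshold.
#' @param n_permutations AMOVA permutations.
#' @param k Parents per population for [select_parents()].
#' @param gs_threshold GS cohesion threshold for parental selection.
#' @param caps_alleles Optional named list of length-2 allele sequences per
#'   sample for [in_silico_caps()].
#' @param caps_fwd,caps_rev,caps_site CAPS assay primers/site (defaults are
#'   the male-sterility assay of [synth_myb80_locus()]).
#' @param pcoa_axes PCoA axes to retain.
#' @param seed Seed for the AMOVA permutation stream.
#' @return Invisibly, a named list of all in-memory results (plus
#'   `manifest`).
#' @export
run_pipeline <- function(df, out_dir,
                         max_missing = 0.2,
                         n_permutations = 999,
                         k = 10,
                         gs_threshold = 0.90,
                         caps_alleles = NULL,
                         caps_fwd = primer("CiMyb80_for", "ACTGCGGTTGCTGGTCA"),
                         caps_rev = primer("CiMyb80_rev", "CCCTGCTCATGCTCCTG"),
                         caps_site = restriction_site("TTAA", 1),
                         pcoa_axes = 2,
                         seed = 1) {
  if (is.character(df)) df <- read_genotype_table(df)
  validate_genotypes(df)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  fmt_pct <- function(x) sprintf("%.2f", round_half_up(x, 2))

  filtered <- stage("filter", {
    df %>% drop_high_missing_samples(max_missing) %>% filter_complete_loci()
  })
  if (!length(locus_names(filtered))) {
    abort("pipeline stage 'filter' failed: no complete loci remain")
  }

  pop_stats <- stage("stats", population_summary(filtered))
  fstat <- stage("fstat", f_statistics(filtered))
  am <- stage("amova", amova(filtered, n_permutations = n_permutations,
                             seed = seed))
  gs <- stage("similarity", simple_matching_gs(filtered))
  hom <- stage("similarity", observed_homozygosity(filtered))
  gs_groups <- stage("similarity", group_similarity_summary(filtered, gs))
  tree <- stage("tree", upgma(gs))
  pc <- stage("pcoa", pcoa(gs, n_axes = pcoa_axes))
  parents <- stage("select-parents",
                   select_parents(filtered, k = k,
                                  gs_threshold = gs_threshold, gs = gs))
  cross <- stage("predict-cross",
                 cross_prediction_matrix(filtered, parents, gs = gs))
  strat <- stage("strategy-summary", strategy_summary(cross))
  caps <- if (!is.null(caps_alleles)) {
    stage("caps", in_silico_caps(caps_alleles, caps_fwd, caps_rev, caps_site))
  } else NULL

  paths <- c(
    population_stats = "population_stats.csv",
    f_statistics = "f_statistics.csv",
    amova = "amova.csv",
    gs_matrix = "gs_matrix.csv",
    group_similarity = "group_similarity.csv",
    homozygosity = "homozygosity.csv",
    tree = "upgma_tree.nwk",
    pcoa = "pcoa_coordinates.csv",
    parents = "selected_parents.csv",
    cross_matrix = "cross_prediction_matrix.csv",
    strategy = "strategy_summary.csv"
  )
  paths <- vapply(paths, function(p) file.path(out_dir, p), character(1))

  readr::write_csv(
    pop_stats %>% dplyr::mutate(dplyr::across(
      c("ho", "he", "pl_pct", "pa_pct"), ~ round_half_up(.x, 2))),
    paths["population_stats"])
  readr::write_csv(tidy(fstat), paths["f_statistics"])
  readr::write_csv(
    dplyr::bind_cols(tidy(am),
                     glance(am)[rep(1, 3), c("phi_pt", "p_value")]),
    paths["amova"])
  utils::write.csv(round(unclass(gs), 6), paths["gs_matrix"])
  readr::write_csv(
    gs_groups %>% dplyr::mutate(dplyr::across(
      c("mean_gs", "se_gs", "mean_obs_hom", "se_obs_hom"),
      ~ round_half_up(100 * .x, 2))),
    paths["group_similarity"])
  readr::write_csv(hom, paths["homozygosity"])
  ape::write.tree(tree, paths["tree"])
  readr::write_csv(tidy(pc), paths["pcoa"])
  readr::write_csv(parents, paths["parents"])
  utils::write.csv(round(cross$matrix, 6), paths["cross_matrix"])
  readr::write_csv(strat, paths["strategy"])
  if (!is.null(caps)) {
    caps_path <- file.path(out_dir, "caps_calls.csv")
    readr::write_csv(
      caps %>% dplyr::mutate(bands = vapply(
        .data$bands, paste, character(1), collapse = ";")),
      caps_path)
    paths <- c(paths, caps = caps_path)
  }

  manifest <- list(
    package = "hybridplan",
    version = as.character(utils::packageVersion("hybridplan")),
    seed = seed,
    config = list(max_missing = max_missing,
                  n_permutations = n_permutations, k = k,
                  gs_threshold = gs_threshold, pcoa_axes = pcoa_axes),
    n_samples_input = nrow(df),
    n_samples_retained = nrow(filtered),
    n_loci_retained = length(locus_names(filtered)),
    input_checksum = digest_tibble(df),
    outputs = lapply(stats::setNames(as.list(paths), names(paths)),
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    data = filtered, population_stats = pop_stats, f_statistics = fstat,
    amova = am, gs = gs, homozygosity = hom,
    group_similarity = gs_groups, tree = tree, pcoa = pc,
    parents = parents, cross_prediction = cross,
    strategy_summary = strat, caps = caps,
    manifest = manifest, manifest_path = manifest_path
  ))
}

# order-sensitive checksum of a genotype tibble via its canonical text form
digest_tibble <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_genotype_table(df, tmp)
  unname(tools::md5sum(tmp))
}
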