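#' Biallelic SNP genotype tables
#'
#' Throughout the package a genotype dataset is an ordinary tibble with one
#' row per sample, a `sample` column (unique ids), a `population` column
#' (labels partitioning the samples) and one integer column per SNP locus.
#' Calls are coded `0` (homozygous for allele A), `1` (homozygous for allele
#' B), `2` (heterozygous) and `NA` (no call). All analysis functions take
#' this tibble as their first argument so pipelines compose with the pipe.
#'
#' @param df A data frame to validate as a genotype table.
#' @return `validate_genotypes()` returns `df` invisibly after checking the
#'   container invariants; it aborts with an informative message otherwise.
#' @examples
#' g <- tibble::tibble(
#'   sample = c("a", "b"), population = c("P1", "P1"),
#'   L1 = c(0L, 2L), L2 = c(1L, 1L)
#' )
#' validate_genotypes(g)
#' @export
validate_genotypes <- function(df) {
  if (!is.data.frame(df)) abort("genotype data must be a data frame")
  if (!all(c("sample", "population") %in% names(df))) {
    abort("genotype data needs `sample` and `population` columns")
  }
  if (anyDuplicated(df$sample)) abort("sample ids must be unique")
  if (any(is.na(df$population))) abort("every sample needs a population label")
  loci <- locus_names(df)
  if (length(loci)) {
    m <- as.matrix(df[loci])
    bad <- !(m %in% c(0L, 1L, 2L) | is.na(m))
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "invalid genotype call %s at sample '%s', locus '%s' (allowed: 0, 1, 2, NA)",
        m[idx[1], idx[2]], df$sample[idx[1]], loci[idx[2]]
      ))
    }
  }
  invisible(df)
}

#' @rdname validate_genotypes
#' @return `locus_names()` returns the character vector of locus column names.
#' @export
locus_names <- function(df) {
  setdiff(names(df), c("sample", "population"))
}

# integer call matrix (samples x loci) with sample rownames
genotype_matrix <- function(df) {
  loci <- locus_names(df)
  m <- as.matrix(df[loci])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  m
}

# copies of allele A per genotype: 0 -> 2 copies, 1 -> 0, 2 -> 1, NA -> NA
allele_dosage_matrix <- function(df) {
  m <- genotype_matrix(df)
  d <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  d[m == 0L] <- 2
  d[m == 1L] <- 0
  d[m == 2L] <- 1
  d
}

#' Read and write delimited genotype tables
#'
#' The canonical on-disk dialect is a UTF-8 delimited text file with header
#' `sample,population,<locus ids...>`, one row per sample, and calls coded
#' `0`/`1`/`2`/`NA`. Both comma and tab delimiters are supported; the reader
#' sniffs the delimiter from the header when `delim` is `NULL`.
#'
#' @param path File path.
#' @param delim Field delimiter, `","` or `"\t"`; `NULL` to auto-detect.
#' @return `read_genotype_table()` returns a genotype tibble (see
#'   [validate_genotypes()]); `write_genotype_table()` returns `path`
#'   invisibly. A write/read/write round trip is byte-identical.
#' @export
read_genotype_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("genotype table needs a header and at least one sample row")
  if (is.null(delim)) {
    delim <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2 || header[1] != "sample" || header[2] != "population") {
    abort("header must start with `sample<delim>population`")
  }
  n_col <- length(header)
  len <- lengths(fields[-1])
  if (any(len != n_col)) {
    bad <- which(len != n_col)[1]
    abort(sprintf(
      "row %d has %d fields, expected %d (sample line '%s')",
      bad + 1, len[bad], n_col, fields[-1][[bad]][1]
    ))
  }
  rows <- do.call(rbind, fields[-1])
  loci <- header[-(1:2)]
  calls <- rows[, -(1:2), drop = FALSE]
  ok <- calls %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    idx <- which(matrix(!ok, nrow(calls)), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "unknown call symbol '%s' at sample '%s', locus '%s'",
      calls[idx[1], idx[2]], rows[idx[1], 1], loci[idx[2]]
    ))
  }
  out <- tibble(sample = rows[, 1], population = rows[, 2])
  call_df <- as.data.frame(
    matrix(suppressWarnings(as.integer(calls)), nrow = nrow(calls))
  )
  names(call_df) <- loci
  out <- dplyr::bind_cols(out, as_tibble(call_df))
  validate_genotypes(out)
  out
}

#' @rdname read_genotype_table
#' @param df Genotype tibble.
#' @export
write_genotype_table <- function(df, path, delim = ",") {
  validate_genotypes(df)
  m <- genotype_matrix(df)
  chr <- matrix(as.character(m), nrow(m))
  chr[is.na(chr)] <- "NA"
  lines <- c(
    paste(c("sample", "population", locus_names(df)), collapse = delim),
    vapply(
      seq_len(nrow(df)),
      function(i) paste(c(df$sample[i], df$population[i], chr[i, ]), collapse = delim),
      character(1)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Import biallelic SNP genotypes from a VCF
#'
#' Reads GT fields from a VCF, keeps only biallelic SNP records, and maps
#' diploid calls to the package coding: `0/0 -> 0`, `1/1 -> 1`, `0/1` or
#' `1/0 -> 2`, `./. -> NA`. Multiallelic records are skipped and counted.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param popmap Path to a two-column TSV `sample<TAB>population` (a header
#'   line `sample\tpopulation` is tolerated), or a data frame with those
#'   columns.
#' @return A genotype tibble. The number of excluded non-biallelic records is
#'   attached as attribute `n_excluded` and reported via a message.
#' @export
read_vcf_biallelic <- function(path, popmap) {
  if (is.character(popmap)) {
    pm <- utils::read.table(popmap, sep = "\t", header = FALSE,
                            col.names = c("sample", "population"),
                            colClasses = "character")
    if (nrow(pm) && pm$sample[1] == "sample") pm <- pm[-1, , drop = FALSE]
  } else {
    pm <- as.data.frame(popmap)[c("sample", "population")]
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  keep <- vcfR::is.biallelic(vcf) &
    nchar(vcf@fix[, "REF"]) == 1 & nchar(vcf@fix[, "ALT"]) == 1
  n_excluded <- sum(!keep)
  if (n_excluded) inform(sprintf("skipped %d non-biallelic-SNP record(s)", n_excluded))
  vcf <- vcf[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  missing_pm <- setdiff(samples, pm$sample)
  if (length(missing_pm)) {
    abort(sprintf("sample(s) absent from popmap: %s",
                  paste(missing_pm, collapse = ", ")))
  }
  id <- vcf@fix[, "ID"]
  locus_ids <- ifelse(is.na(id) | id == ".",
                      paste0(vcf@fix[, "CHROM"], "_", vcf@fix[, "POS"]), id)
  locus_ids <- make.unique(locus_ids)
  core <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[core == "0/0"] <- 0L
  code[core == "1/1"] <- 1L
  code[core %in% c("0/1", "1/0")] <- 2L
  out <- tibble(
    sample = samples,
    population = pm$population[match(samples, pm$sample)]
  )
  call_df <- as.data.frame(t(code))
  names(call_df) <- locus_ids
  out <- dplyr::bind_cols(out, as_tibble(call_df))
  loci_meta <- tibble(
    locus = locus_ids,
    allele_a = vcf@fix[, "REF"],
    allele_b = vcf@fix[, "ALT"]
  )
  attr(out, "loci") <- loci_meta
  attr(out, "n_excluded") <- n_excluded
  validate_genotypes(out)
  out
}

#' Drop samples with excessive missing calls
#'
#' Samples whose fraction of missing calls exceeds `max_missing` are removed
#' (sequencing dropouts are excluded before locus filtering so that a few bad
#' samples do not erase the locus panel).
#'
#' @param df Genotype tibble.
#' @param max_missing Maximum tolerated missing-call fraction in `[0, 1]`.
#' @return The filtered tibble; removed sample ids (with their missing
#'   fractions) are attached as attribute `removed` and reported.
#' @export
drop_high_missing_samples <- function(df, max_missing = 0.2) {
  validate_genotypes(df)
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1) {
    abort("`max_missing` must be in [0, 1]")
  }
  m <- genotype_matrix(df)
  frac <- rowMeans(is.na(m))
  drop <- frac > max_missing
  removed <- tibble(sample = df$sample[drop], missing_fraction = frac[drop])
  if (nrow(removed)) {
    inform(sprintf(
      "removed %d sample(s) above missing-call threshold %.2f: %s",
      nrow(removed), max_missing, paste(removed$sample, collapse = ", ")
    ))
  }
  out <- df[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Keep only loci with complete calls
#'
#' Retains loci with zero missing calls across all samples (complete-call
#' filtering); locus order is preserved and the operation is idempotent.
#'
#' @param df Genotype tibble.
#' @return The filtered tibble; dropped locus names are attached as attribute
#'   `dropped_loci`.
#' @export
filter_complete_loci <- function(df) {
  validate_genotypes(df)
  loci <- locus_names(df)
  if (!length(loci)) return(df)
  m <- genotype_matrix(df)
  complete <- colSums(is.na(m)) == 0L
  out <- df[c("sample", "population", loci[complete])]
  attr(out, "dropped_loci") <- loci[!complete]
  out
}

#' Allele counts per locus and population
#'
#' Counts copies of allele A and allele B at each locus, overall or within
#' one population. `count_a + count_b = 2 * n` at every locus.
#'
#' @param df Genotype tibble.
#' @param locus Optional locus id (default: all loci).
#' @param population Optional population label (default: all samples).
#' @return A tibble with columns `locus`, `count_a`, `count_b`, `n`
#'   (genotyped sample count).
#' @examples
#' g <- tibble::tibble(
#'   sample = letters[1:4], population = "P1",
#'   L1 = c(0L, 0L, 2L, 1L)
#' )
#' allele_counts(g) # count_a 5, count_b 3, n 4
#' @export
allele_counts <- function(df, locus = NULL, population = NULL) {
  validate_genotypes(df)
  if (!is.null(population)) {
    if (!population %in% df$population) {
      abort(sprintf("unknown population '%s'", population))
    }
    df <- df[df$population == population, , drop = FALSE]
  }
  loci <- locus_names(df)
  if (!is.null(locus)) {
    if (!all(locus %in% loci)) {
      abort(sprintf("unknown locus: %s",
                    paste(setdiff(locus, loci), collapse = ", ")))
    }
    loci <- locus
  }
  d <- allele_dosage_matrix(df)[, loci, drop = FALSE]
  n <- colSums(!is.na(d))
  count_a <- colSums(d, na.rm = TRUE)
  tibble(
    locus = loci,
    count_a = unname(count_a),
    count_b = unname(2 * n - count_a),
    n = unname(n)
  )
}
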