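#' PCR primers and restriction sites
#'
#' `primer()` builds a validated primer (5'->3', strict ACGT alphabet —
#' ambiguity codes are rejected). `restriction_site()` describes a
#' restriction enzyme by its recognition motif and the cut offset within the
#' motif; the default `TTAA` with offset 1 is the canonical Tru1I site
#' (T^TAA, an MseI isoschizomer).
#'
#' @param name Primer name.
#' @param sequence Primer sequence, 5' to 3'.
#' @return `primer()` returns a `primer` object; `restriction_site()` a
#'   `restriction_site` object.
#' @examples
#' primer("CiMyb80_for", "ACTGCGGTTGCTGGTCA")
#' restriction_site("TTAA", 1)
#' @export
primer <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) abort("primer sequence must be nonempty")
  if (grepl("[^ACGT]", sequence)) {
    abort(sprintf("primer '%s' contains non-ACGT (ambiguous?) bases", name))
  }
  structure(list(name = name, sequence = sequence), class = "primer")
}

#' @rdname primer
#' @param motif Recognition motif (ACGT).
#' @param cut_offset Cut position within the motif: the cut falls after
#'   `cut_offset` bases of the motif (0 = before it, `nchar(motif)` = after).
#' @export
restriction_site <- function(motif = "TTAA", cut_offset = 1) {
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    abort("recognition motif must be a nonempty ACGT string")
  }
  if (cut_offset < 0 || cut_offset > nchar(motif)) {
    abort("`cut_offset` must be between 0 and the motif length")
  }
  structure(list(motif = motif, cut_offset = as.integer(cut_offset)),
            class = "restriction_site")
}

rc <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# all match start positions of `pattern` in `subject`, with mismatch budget;
# a mismatch at the pattern's 3'-terminal base always disqualifies
primer_matches <- function(subject, pattern, max_mismatch, terminal_is_last) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                   max.mismatch = max_mismatch)
  starts <- Biostrings::start(hits)
  if (max_mismatch > 0 && length(starts)) {
    keep <- vapply(seq_along(starts), function(i) {
      frag <- substr(subject, starts[i], starts[i] + nchar(pattern) - 1)
      pos <- if (terminal_is_last) nchar(pattern) else 1L
      substr(frag, pos, pos) == substr(pattern, pos, pos)
    }, logical(1))
    starts <- starts[keep]
  }
  starts
}

#' In-silico PCR
#'
#' Finds plus-strand matches of the forward primer and matches of the
#' reverse-complemented reverse primer downstream of them, and emits every
#' resulting amplicon up to `max_length`. Coordinates are 1-based inclusive
#' on the plus strand. Primer matching is exact by default; when mismatches
#' are allowed, a 3'-terminal mismatch still disqualifies a site (no
#' extension from a mispaired 3' end).
#'
#' @param template Template sequence (character) or a named element of a
#'   [Biostrings::DNAStringSet].
#' @param fwd,rev [primer()] objects (plain sequences are accepted).
#' @param max_mismatch Allowed mismatches per primer (default 0).
#' @param max_length Maximum amplicon length (default 5000).
#' @return A tibble with columns `start`, `end`, `length`, `sequence`; zero
#'   rows when no productive primer pair exists.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatch = 0,
                          max_length = 5000) {
  template <- toupper(as.character(template))
  if (!nzchar(template)) abort("template must be nonempty")
  if (!inherits(fwd, "primer")) fwd <- primer("fwd", fwd)
  if (!inherits(rev, "primer")) rev <- primer("rev", rev)
  f_starts <- primer_matches(template, fwd$sequence, max_mismatch,
                             terminal_is_last = TRUE)
  # the reverse primer binds the minus strand; on the plus strand its
  # reverse complement appears with the primer's 3' end at the match START
  r_rc <- rc(rev$sequence)
  r_starts <- primer_matches(template, r_rc, max_mismatch,
                             terminal_is_last = FALSE)
  r_ends <- r_starts + nchar(r_rc) - 1L
  empty <- tibble(start = integer(0), end = integer(0),
                  length = integer(0), sequence = character(0))
  if (!length(f_starts) || !length(r_ends)) return(empty)
  out <- tidyr::expand_grid(start = as.integer(f_starts),
                            end = as.integer(r_ends)) %>%
    dplyr::filter(.data$end >= .data$start + nchar(fwd$sequence) - 1L,
                  .data$end - .data$start + 1L <= max_length)
  if (!nrow(out)) return(empty)
  out %>%
    dplyr::mutate(
      length = .data$end - .data$start + 1L,
      sequence = substr(rep(template, dplyr::n()), .data$start, .data$end)
    )
}

#' Restriction digestion of a linear sequence
#'
#' Cuts at every occurrence of the recognition motif (overlapping
#' occurrences each cut once at their own position) and returns fragment
#' lengths ordered 5' to 3'. Fragment lengths always sum to the input
#' length.
#'
#' @param seq Sequence to digest (character).
#' @param site A [restriction_site()].
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @examples
#' digest("AATTAAG", restriction_site("TTAA", 1)) # 3 4
#' @export
digest <- function(seq, site = restriction_site()) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) abort("cannot digest an empty sequence")
  if (!inherits(site, "restriction_site")) abort("`site` must be a restriction_site")
  # lookahead finds overlapping motif occurrences
  hits <- gregexpr(paste0("(?=", site$motif, ")"), seq, perl = TRUE)[[1]]
  hits <- hits[hits > 0]
  cuts <- sort(unique(hits + site$cut_offset - 1L))
  cuts <- cuts[cuts >= 1 & cuts < nchar(seq)]
  as.integer(diff(c(0L, cuts, nchar(seq))))
}

#' Merged band pattern of a diploid sample
#'
#' Digests both alleles and merges the fragment-length sets (equal sizes
#' collapse into one gel band). Symmetric in its allele arguments.
#'
#' @param allele1,allele2 Allele sequences (e.g. amplicons of the two
#'   haplotypes).
#' @param site A [restriction_site()].
#' @return Integer vector of distinct band sizes, largest first.
#' @export
diploid_band_pattern <- function(allele1, allele2,
                                 site = restriction_site()) {
  sort(unique(c(digest(allele1, site), digest(allele2, site))),
       decreasing = TRUE)
}

#' Call the male-sterility genotype from a CAPS band pattern
#'
#' Classifies a gel band pattern against the reference sizes of the
#' male-sterility CAPS assay: an undigested band near 300 bp, and digestion
#' products near 230 and 70 bp. `{300} -> MsMs` (homozygous fertile),
#' `{300, 230, 70} -> Msms` (heterozygous, partial restriction; fertile),
#' `{230, 70} -> msms` (fully restricted; sterile, full penetrance).
#' Anything else is an explicit no-call. Because the small ~70 bp product
#' can be hard to resolve on agarose, `allow_low_band_dropout = TRUE`
#' additionally accepts `{300, 230}` as `Msms`.
#'
#' @param bands Integer vector of observed band sizes (bp).
#' @param tolerance_bp Band-size matching tolerance (default 15 bp, a gel
#'   resolution proxy).
#' @param allow_low_band_dropout Accept a missing ~70 bp band in the
#'   heterozygote pattern.
#' @param ref_sizes Named vector `c(uncut =, cut_long =, cut_short =)`.
#' @return A one-row tibble: `genotype` (`"MsMs"`, `"Msms"`, `"msms"` or
#'   `"no-call"`), `phenotype` (`"fertile"`, `"sterile"` or `NA`), `bands`
#'   (list column).
#' @export
call_ms_genotype <- function(bands, tolerance_bp = 15,
                             allow_low_band_dropout = FALSE,
                             ref_sizes = c(uncut = 300, cut_long = 230,
                                           cut_short = 70)) {
  bands <- sort(unique(as.integer(bands)), decreasing = TRUE)
  near <- function(ref) any(abs(bands - ref) <= tolerance_bp)
  unmatched <- !vapply(bands, function(b) {
    any(abs(b - ref_sizes) <= tolerance_bp)
  }, logical(1))
  has_uncut <- near(ref_sizes[["uncut"]])
  has_long <- near(ref_sizes[["cut_long"]])
  has_short <- near(ref_sizes[["cut_short"]])
  genotype <- "no-call"
  if (!any(unmatched) && length(bands)) {
    if (has_uncut && !has_long && !has_short) genotype <- "MsMs"
    else if (has_uncut && has_long && (has_short || allow_low_band_dropout)) {
      genotype <- "Msms"
    } else if (!has_uncut && has_long && has_short) genotype <- "msms"
  }
  phenotype <- switch(genotype,
    MsMs = "fertile", Msms = "fertile", msms = "sterile", NA_character_)
  tibble(genotype = genotype, phenotype = phenotype, bands = list(bands))
}

#' Full in-silico CAPS assay over diploid samples
#'
#' Runs virtual PCR on each allele of each sample, digests the amplicons,
#' merges band patterns and calls the male-sterility genotype.
#'
#' @param alleles A list (one element per sample) of length-2 character
#'   vectors with the two allele/template sequences.
#' @param fwd,rev [primer()] objects.
#' @param site A [restriction_site()].
#' @param ... Passed to [call_ms_genotype()].
#' @return A tibble with one row per sample: `sample`, `genotype`,
#'   `phenotype`, `bands` (list column), `n_amplicons`.
#' @export
in_silico_caps <- function(alleles, fwd, rev, site = restriction_site(),
                           ...) {
  ids <- names(alleles)
  if (is.null(ids)) ids <- paste0("sample", seq_along(alleles))
  purrr::map2_dfr(alleles, ids, function(al, id) {
    stopifnot(length(al) == 2)
    amps <- lapply(al, function(a) in_silico_pcr(a, fwd, rev))
    n_amp <- sum(vapply(amps, nrow, integer(1)))
    if (any(vapply(amps, nrow, integer(1)) == 0)) {
      return(tibble(sample = id, genotype = "no-call",
                    phenotype = NA_character_, bands = list(integer(0)),
                    n_amplicons = n_amp))
    }
    bands <- diploid_band_pattern(amps[[1]]$sequence[1],
                                  amps[[2]]$sequence[1], site)
    call <- call_ms_genotype(bands, ...)
    dplyr::bind_cols(tibble(sample = id), call, tibble(n_amplicons = n_amp))
  })
}

#' Concordance between two genotype-call vectors
#'
#' Positional comparison of paired calls from two markers on the same
#' samples. Pairs where either call is a no-call (or `NA`) are excluded from
#' the percentage and counted separately.
#'
#' @param calls_a,calls_b Character vectors of equal length, paired by
#'   sample. `"no-call"` and `NA` mark failed calls.
#' @return A one-row tibble: `n`, `n_valid`, `n_excluded`, `matches`,
#'   `mismatches`, `mismatch_pct` (percent of valid pairs, 2 decimals,
#'   half-up).
#' @examples
#' a <- rep("msms", 94); b <- a; b[5] <- "Msms"
#' marker_concordance(a, b)$mismatch_pct # 1.06
#' @export
marker_concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    abort("call vectors must have equal length (paired by sample)")
  }
  valid <- !is.na(calls_a) & !is.na(calls_b) &
    calls_a != "no-call" & calls_b != "no-call"
  a <- calls_a[valid]; b <- calls_b[valid]
  mism <- sum(a != b)
  tibble(
    n = length(calls_a),
    n_valid = sum(valid),
    n_excluded = sum(!valid),
    matches = sum(a == b),
    mismatches = mism,
    mismatch_pct = if (sum(valid)) round_half_up(100 * mism / sum(valid), 2)
                   else NA_real_
  )
}
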