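# Base call of each record at a reference position, honouring soft-trim
# masks and coverage gaps. Returns NA for records not spanning the site,
# "masked" for soft-trimmed positions, "gap" for '-'.
call_at_site <- function(records, locus, position) {
  span <- records$locus == locus &
    records$fragment_start <= position &
    records$fragment_end > position
  out <- rep(NA_character_, nrow(records))
  if (!any(span)) return(out)
  off <- position - records$fragment_start[span] + 1L
  len <- records$fragment_end[span] - records$fragment_start[span]
  t5 <- records$trim5[span] %||% rep(0L, sum(span))
  t3 <- records$trim3[span] %||% rep(0L, sum(span))
  base <- substr(records$seq[span], off, off)
  base[off <= t5 | off > len - t3] <- "masked"
  base[base == "-"] <- "gap"
  out[span] <- base
  out
}

#' Pile up consensus records over targeted sites
#'
#' Each record spanning a site contributes one molecule count: the
#' reference allele, the targeted alternate, any third allele (`n_other`),
#' or `n_ambiguous` for positions with no concrete call (consensus `N`,
#' coverage gap, or a soft-trim mask). The four counts sum to the number of
#' spanning records.
#'
#' @param records Tibble with `locus`, `fragment_start`, `fragment_end`,
#'   `seq`, and optional `trim5`/`trim3` (SSCS, duplex-consensus, or merged
#'   aligned reads).
#' @param sites Tibble with `locus`, `position` (0-based), `ref`, `alt`.
#' @param level Label stored in the output (`"sscs"`, `"duplex"`, ...).
#' @param reference Optional named reference; when given, a site outside
#'   every locus is an error (a site merely uncovered by `records` is not).
#' @return Tibble: one row per site with `level`, `n_ref`, `n_alt`,
#'   `n_other`, `n_ambiguous`, `vaf` (alt over concrete calls; `NA` when no
#'   concrete call covers the site).
#' @export
pileup_sites <- function(records, sites, level = "sscs", reference = NULL) {
  if (!is.null(reference)) {
    bad <- !sites$locus %in% names(reference) |
      sites$position < 0 |
      sites$position >= nchar(reference)[match(sites$locus, names(reference))]
    if (any(bad, na.rm = TRUE)) {
      abort(sprintf("site %s:%d lies outside the reference",
                    sites$locus[bad][1], sites$position[bad][1]))
    }
  }
  rows <- purrr::map(seq_len(nrow(sites)), function(k) {
    calls <- call_at_site(records, sites$locus[k], sites$position[k])
    calls <- calls[!is.na(calls)]
    concrete <- calls %in% c("A", "C", "G", "T")
    n_ref <- sum(calls == sites$ref[k])
    n_alt <- sum(calls == sites$alt[k])
    n_other <- sum(concrete) - n_ref - n_alt
    n_amb <- sum(!concrete)
    denom <- n_ref + n_alt + n_other
    tibble(
      locus = sites$locus[k], position = sites$position[k],
      ref = sites$ref[k], alt = sites$alt[k], level = level,
      n_ref = n_ref, n_alt = n_alt, n_other = n_other, n_ambiguous = n_amb,
      vaf = if (denom > 0) n_alt / denom else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Call variants with duplex-support flags
#'
#' Combines single-strand and duplex pileups at the targeted sites. A site
#' has duplex support when at least one duplex consensus carries the
#' alternate allele; only duplex-supported calls are flagged high
#' confidence (a variant must be seen independently on both parental
#' strands).
#'
#' @param sscs_pileup,duplex_pileup Outputs of [pileup_sites()] at the two
#'   levels.
#' @param min_molecules Minimum single-strand alternate molecules for a
#'   detection.
#' @return Tibble: one row per site with per-level counts, `vaf_sscs`,
#'   `vaf_duplex`, `detected`, `duplex_support`, `high_confidence`.
#' @export
call_variants <- function(sscs_pileup, duplex_pileup, min_molecules = 1) {
  s <- dplyr::rename_with(
    sscs_pileup, \(x) paste0(x, "_sscs"),
    dplyr::all_of(c("n_ref", "n_alt", "n_other", "n_ambiguous", "vaf"))
  )
  d <- dplyr::rename_with(
    duplex_pileup, \(x) paste0(x, "_duplex"),
    dplyr::all_of(c("n_ref", "n_alt", "n_other", "n_ambiguous", "vaf"))
  )
  out <- dplyr::left_join(
    dplyr::select(s, -"level"),
    dplyr::select(d, -"level"),
    by = c("locus", "position", "ref", "alt")
  )
  out |>
    dplyr::mutate(
      detected = .data$n_alt_sscs >= min_molecules,
      duplex_support = dplyr::coalesce(.data$n_alt_duplex >= 1, FALSE),
      high_confidence = .data$detected & .data$duplex_support
    )
}

SUBSTITUTION_CLASSES <- c(
  "A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T", "T>A", "T>C", "T>G"
)

#' Background error profile by substitution class
#'
#' Fraction of non-reference calls out of all evaluated consensus bases,
#' split into the 12 substitution classes oriented by the reference strand
#' (C>A and its reciprocal G>T are tracked separately, which exposes the
#' strand asymmetry of oxidative damage). Soft-trimmed, ambiguous and gap
#' positions and a-priori known variant sites are excluded from both
#' numerator and denominator.
#'
#' @param records Consensus (or merged-read) tibble with `locus`,
#'   `fragment_start`, `fragment_end`, `seq`, optional `trim5`/`trim3`.
#' @param reference Named character vector of locus sequences.
#' @param exclude_sites Tibble with `locus`, `position` (0-based) of known
#'   SNPs / targeted somatic sites to exclude.
#' @param level Label stored in the output.
#' @return List of class `error_profile`: `by_class` (tibble `class`,
#'   `n_errors`, `rate`), `total_bases`, `n_errors`, `overall_rate`,
#'   `level`.
#' @export
background_error_profile <- function(records, reference,
                                     exclude_sites = NULL,
                                     level = "sscs") {
  class_counts <- stats::setNames(integer(12), SUBSTITUTION_CLASSES)
  total <- 0L
  excl <- if (is.null(exclude_sites)) character(0) else
    paste(exclude_sites$locus, exclude_sites$position)

  for (i in seq_len(nrow(records))) {
    rec_seq <- split1(records$seq[i])
    L <- length(rec_seq)
    ref_seq <- split1(substr(reference[[records$locus[i]]],
                             records$fragment_start[i] + 1,
                             records$fragment_end[i]))
    t5 <- records$trim5[i] %||% 0L
    t3 <- records$trim3[i] %||% 0L
    keep <- rep(TRUE, L)
    if (t5 > 0) keep[seq_len(min(t5, L))] <- FALSE
    if (t3 > 0) keep[seq.int(max(1L, L - t3 + 1L), L)] <- FALSE
    keep <- keep & rec_seq %in% c("A", "C", "G", "T")
    if (length(excl) > 0) {
      pos0 <- records$fragment_start[i] + seq_len(L) - 1L
      keep <- keep & !(paste(records$locus[i], pos0) %in% excl)
    }
    total <- total + sum(keep)
    mm <- keep & rec_seq != ref_seq
    if (any(mm)) {
      cls <- paste0(ref_seq[mm], ">", rec_seq[mm])
      tt <- table(cls)
      class_counts[names(tt)] <- class_counts[names(tt)] + as.integer(tt)
    }
  }

  structure(
    list(
      by_class = tibble(
        class = SUBSTITUTION_CLASSES,
        n_errors = as.integer(class_counts),
        rate = if (total > 0) as.integer(class_counts) / total else NA_real_
      ),
      total_bases = total,
      n_errors = sum(class_counts),
      overall_rate = if (total > 0) sum(class_counts) / total else NA_real_,
      level = level
    ),
    class = "error_profile"
  )
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> level %s: %d non-reference calls / %d bases (rate %.3g)\n",
              x$level, x$n_errors, x$total_bases, x$overall_rate))
  invisible(x)
}

#' Expected genome copies from input mass
#'
#' @param input_mass_ng DNA input in nanograms.
#' @param pg_per_haploid Mass of one haploid genome in picograms (3.3 for
#'   human).
#' @return Integer number of haploid copies (e.g. 2.3 ng gives 697).
#' @export
copies_from_mass <- function(input_mass_ng, pg_per_haploid = 3.3) {
  round(input_mass_ng * 1000 / pg_per_haploid)
}

#' Per-site unique-molecule accounting and recovery efficiency
#'
#' Compares per-site unique molecule counts against the copies expected
#' from the DNA input mass, and summarises counts across sites/replicates
#' with mean and sample (n-1) standard deviation.
#'
#' @param counts Tibble with a `unique_molecules` column (one row per site
#'   and replicate; any id columns are carried through).
#' @param input_mass_ng,pg_per_haploid Passed to [copies_from_mass()].
#' @return List of class `molecule_accounting`: `per_site` (counts with
#'   `expected_copies` and `efficiency`), `expected_copies`,
#'   `mean_molecules`, `sd_molecules`.
#' @export
unique_molecule_table <- function(counts, input_mass_ng,
                                  pg_per_haploid = 3.3) {
  expected <- copies_from_mass(input_mass_ng, pg_per_haploid)
  per_site <- counts |>
    dplyr::mutate(
      expected_copies = expected,
      efficiency = .data$unique_molecules / expected
    )
  structure(
    list(
      per_site = per_site,
      expected_copies = expected,
      mean_molecules = mean(counts$unique_molecules),
      sd_molecules = stats::sd(counts$unique_molecules)
    ),
    class = "molecule_accounting"
  )
}

#' @export
print.molecule_accounting <- function(x, ...) {
  cat(sprintf("<molecule_accounting> %d expected copies; %.1f +/- %.1f unique molecules per site\n",
              x$expected_copies, x$mean_molecules, x$sd_molecules))
  invisible(x)
}
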