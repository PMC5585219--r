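#' Pipeline stage parameters
#'
#' Validated bundle of the tunable thresholds of the calling workflow.
#' Unknown names are rejected.
#'
#' @param ... Overrides for: `min_overlap` (30), `max_mismatch_frac` (0.1),
#'   `soft_trim` (2), `min_reads` (3), `max_key_mismatches` (2),
#'   `spurious_threshold` (5), `mismatch_frac` (0.01), `max_edit_frac`
#'   (0.05), `min_molecules` (1), `keep_unknown_orientation` (TRUE: reads
#'   with undecidable strand tags still feed single-strand analyses; they
#'   are never duplexed).
#' @return Named list of class `run_params`.
#' @export
run_params <- function(...) {
  defaults <- list(
    min_overlap = 30, max_mismatch_frac = 0.1, soft_trim = 2,
    min_reads = 3, max_key_mismatches = 2, spurious_threshold = 5,
    mismatch_frac = 0.01, max_edit_frac = 0.05, min_molecules = 1,
    keep_unknown_orientation = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(defaults, over)
  stopifnot(p$min_overlap >= 1, p$min_reads >= 1,
            p$max_mismatch_frac >= 0, p$max_mismatch_frac <= 1,
            p$soft_trim >= 0, p$max_key_mismatches >= 0,
            p$spurious_threshold >= 0)
  structure(p, class = "run_params")
}

#' Simulate a library and write it to disk
#'
#' Wraps [simulate_reads()]: writes gzipped paired FASTQ, the truth table
#' as TSV, the reference as FASTA and an echo of the configuration, all
#' under `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `sim_result`.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_reads(config)
  write_fastq(sim$reads,
              file.path(out_dir, "reads_R1.fastq.gz"),
              file.path(out_dir, "reads_R2.fastq.gz"))
  truth <- sim$truth
  truth$mispair_left <- vapply(truth$mispair_left, paste, character(1),
                               collapse = ",")
  truth$mispair_right <- vapply(truth$mispair_right, paste, character(1),
                                collapse = ",")
  truth$damage_positions <- vapply(truth$damage_positions, paste,
                                   character(1), collapse = ",")
  utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", names(config$reference), "\n", config$reference),
             file.path(out_dir, "reference.fa"))
  echo <- config[c("n_molecules", "fragment_length_mean",
                   "fragment_length_sd", "polymerase_error_rate",
                   "damage_rate_c_to_a", "damaged_strand", "seq_error_rate",
                   "read_length", "seed")]
  echo$design <- config$adapter$design_version
  yaml::write_yaml(echo, file.path(out_dir, "config_echo.yaml"))
  invisible(sim)
}

#' Run the calling workflow end to end
#'
#' Executes read preparation, alignment, family grouping, single-strand
#' consensus, duplex matching and variant quantification, and collects the
#' stage outputs plus a mutually consistent run summary.
#'
#' @param pairs Read-pair tibble ([simulate_reads()]`$reads` or
#'   [read_fastq_pairs()]).
#' @param reference Named character vector of locus sequences.
#' @param sites Targeted sites tibble (`locus`, `position`, `ref`, `alt`).
#' @param adapter An [adapter_spec()].
#' @param params A [run_params()].
#' @return Object of class `dbc_run` with elements `reads`, `sscs`,
#'   `duplex_match`, `duplexes`, `calls`, `recovery`, `error_profiles`
#'   (raw/sscs/duplex), `mispair_profile`, `family_stats`, `summary`.
#' @export
run_call <- function(pairs, reference, sites, adapter = adapter_spec(),
                     params = run_params()) {
  if (nrow(pairs) == 0) {
    empty_pile <- pileup_sites(
      tibble(locus = character(0), fragment_start = integer(0),
             fragment_end = integer(0), seq = character(0)),
      sites, level = "sscs", reference = reference)
    return(structure(list(
      reads = pairs, sscs = NULL, duplex_match = NULL,
      duplexes = NULL,
      calls = call_variants(empty_pile,
                            dplyr::mutate(empty_pile, level = "duplex")),
      recovery = duplex_recovery(0, 0, 0),
      error_profiles = NULL, mispair_profile = NULL, family_stats = NULL,
      summary = tibble(reads_in = 0L, merged = 0L, unmerged = 0L,
                       rejected = 0L, families = 0L, sscs = 0L,
                       duplexes = 0L, recovery_rate = NA_real_)
    ), class = "dbc_run"))
  }

  prepped <- prep_reads(pairs, adapter, params$min_overlap,
                        params$max_mismatch_frac, params$soft_trim)
  if (!params$keep_unknown_orientation) {
    drop <- !is.na(prepped$orientation) & prepped$orientation == "unknown"
    prepped$status[drop] <- "rejected"
    prepped$reject_reason[drop] <- "unknown_orientation"
  }
  aligned <- align_reads(prepped, reference, params$max_edit_frac)
  grouped <- group_families(aligned, adapter, params$mismatch_frac)
  sscs <- build_sscs(grouped, params$min_reads)
  matched <- match_duplexes(sscs, adapter, params$max_key_mismatches,
                            params$spurious_threshold)
  duplexes <- build_duplex_consensus(matched, sscs)

  n_fwd <- sum(sscs$orientation == "plus")
  n_rev <- sum(sscs$orientation == "minus")
  recovery <- duplex_recovery(n_fwd, n_rev, nrow(duplexes))

  sscs_pile <- pileup_sites(sscs, sites, "sscs", reference)
  dup_pile <- pileup_sites(duplexes, sites, "duplex", reference)
  calls <- call_variants(sscs_pile, dup_pile, params$min_molecules)

  usable <- grouped[!is.na(grouped$family_id), ]
  profiles <- list(
    raw = background_error_profile(usable, reference, sites, "raw"),
    sscs = background_error_profile(sscs, reference, sites, "sscs"),
    duplex = background_error_profile(duplexes, reference, sites, "duplex")
  )

  summary <- tibble(
    reads_in = nrow(pairs),
    merged = sum(grouped$status == "merged"),
    unmerged = sum(grouped$status == "unmerged"),
    rejected = sum(grouped$status == "rejected"),
    families = dplyr::n_distinct(grouped$family_id, na.rm = TRUE),
    sscs = nrow(sscs),
    duplexes = nrow(duplexes),
    recovery_rate = recovery$recovery_rate
  )

  structure(list(
    reads = grouped, sscs = sscs, duplex_match = matched,
    duplexes = duplexes, calls = calls, recovery = recovery,
    error_profiles = profiles,
    mispair_profile = mispairing_profile(duplexes, adapter),
    family_stats = family_size_stats(grouped),
    summary = summary
  ), class = "dbc_run")
}

#' @export
print.dbc_run <- function(x, ...) {
  cat("<dbc_run>\n")
  print(x$summary)
  invisible(x)
}

#' Summary tables of a finished run
#'
#' Reproduces the library-characterisation tables: UID diversity over the
#' single-strand consensus set, the family-size histogram, the duplex
#' recovery line and the mispairing histograms.
#'
#' @param run A `dbc_run` from [run_call()].
#' @return Named list of tibbles: `uid_diversity`, `family_sizes`,
#'   `recovery`, `mispairing_per_position`, `mispairing_histogram`.
#' @export
run_stats <- function(run) {
  uid_div <- if (!is.null(run$sscs) && nrow(run$sscs) >= 2) {
    uid_diversity_stats(run$sscs$uid)
  } else NULL
  list(
    uid_diversity = uid_div,
    family_sizes = if (!is.null(run$family_stats)) run$family_stats$histogram,
    recovery = run$recovery,
    mispairing_per_position =
      if (!is.null(run$mispair_profile)) run$mispair_profile$per_position,
    mispairing_histogram =
      if (!is.null(run$mispair_profile)) run$mispair_profile$histogram_full
  )
}

# --- broom-style methods ----------------------------------------------------

#' Tidy the variant calls of a run
#'
#' @param x A `dbc_run`.
#' @param ... Unused.
#' @return The per-site call tibble.
#' @export
tidy.dbc_run <- function(x, ...) {
  x$calls
}

#' One-row summary of a run
#'
#' @param x A `dbc_run`.
#' @param ... Unused.
#' @return One-row tibble of run-level counts and rates, including the
#'   per-level background error rates.
#' @export
glance.dbc_run <- function(x, ...) {
  out <- x$summary
  if (!is.null(x$error_profiles)) {
    out$error_rate_raw <- x$error_profiles$raw$overall_rate
    out$error_rate_sscs <- x$error_profiles$sscs$overall_rate
    out$error_rate_duplex <- x$error_profiles$duplex$overall_rate
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# --- config file ------------------------------------------------------------

#' Read a run configuration file
#'
#' YAML file with two optional blocks: `simulate` (passed to
#' [sim_config()], except that `reference` may be a FASTA path) and `call`
#' (passed to [run_params()]). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return List with `simulate` (a `sim_config` or NULL) and `call`
#'   (a `run_params`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("simulate", "call"))
  if (length(unknown) > 0) {
    abort(paste0("unknown config block(s): ", paste(unknown, collapse = ", ")))
  }
  sim_cfg <- NULL
  if (!is.null(raw$simulate)) {
    s <- raw$simulate
    if (!is.null(s$reference) && is.character(s$reference)) {
      s$reference <- read_reference_fasta(s$reference)
    }
    if (!is.null(s$target_sites)) {
      s$target_sites <- dplyr::bind_rows(lapply(s$target_sites, as_tibble))
    }
    allowed <- names(formals(sim_config))
    unknown <- setdiff(names(s), allowed)
    if (length(unknown) > 0) {
      abort(paste0("unknown simulate key(s): ", paste(unknown, collapse = ", ")))
    }
    sim_cfg <- do.call(sim_config, s)
  }
  call_params <- do.call(run_params, raw$call %||% list())
  list(simulate = sim_cfg, call = call_params)
}

#' Read a reference FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub(" .*", "", names(x)))
}

#' Read targeted sites from a BED-like file
#'
#' BED intervals (0-based half-open) with `ref` and `alt` in columns 5-6
#' (column 4 is a site name, kept). Only single-base sites are supported.
#'
#' @param path TSV path.
#' @return Tibble: `locus`, `position`, `name`, `ref`, `alt`.
#' @export
read_sites_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) abort("sites BED needs 6 columns: chrom start end name ref alt")
  names(df)[1:6] <- c("locus", "start", "end", "name", "ref", "alt")
  if (any(df$end - df$start != 1)) abort("only single-base sites are supported")
  tibble(locus = df$locus, position = as.integer(df$start),
         name = df$name, ref = df$ref, alt = df$alt)
}

#' Write variant calls as a minimal VCF
#'
#' VCF 4.2 with molecule counts and duplex support in INFO.
#'
#' @param calls Call tibble from [call_variants()] / [tidy.dbc_run()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=NSSCS,Number=1,Type=Integer,Description=\"Alt single-strand consensus molecules\">",
    "##INFO=<ID=NDUP,Number=1,Type=Integer,Description=\"Alt duplex molecules\">",
    "##INFO=<ID=VAFS,Number=1,Type=Float,Description=\"Single-strand VAF\">",
    "##INFO=<ID=VAFD,Number=1,Type=Float,Description=\"Duplex VAF\">",
    "##INFO=<ID=DS,Number=0,Type=Flag,Description=\"Duplex support\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf(
    "NSSCS=%d;NDUP=%d;VAFS=%s;VAFD=%s%s",
    calls$n_alt_sscs, dplyr::coalesce(calls$n_alt_duplex, 0L),
    ifelse(is.na(calls$vaf_sscs), ".", sprintf("%.6g", calls$vaf_sscs)),
    ifelse(is.na(calls$vaf_duplex), ".", sprintf("%.6g", calls$vaf_duplex)),
    ifelse(calls$duplex_support, ";DS", "")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  calls$locus, calls$position + 1L, calls$ref, calls$alt,
                  ifelse(calls$high_confidence, "PASS", "low_confidence"),
                  info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
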