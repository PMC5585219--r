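#' Generate a small pseudo-random reference
#'
#' Builds a synthetic reference of a few independent loci (emulating a
#' concatenation of targeted loci plus flanks) with a fixed seed, so the
#' whole pipeline can be exercised without external data. A copy of the
#' default reference ships in `inst/extdata/sim_reference.fa`.
#'
#' @param n_loci Number of loci.
#' @param locus_length Length of each locus in bp.
#' @param seed RNG seed for the reference itself.
#' @return Named character vector of locus sequences.
#' @export
sim_reference <- function(n_loci = 5, locus_length = 1000, seed = 42) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seqs <- vapply(seq_len(n_loci), function(i) {
    paste(sample(c("A", "C", "G", "T"), locus_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("locus%02d", seq_len(n_loci))
  seqs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default targeted sites for a simulated reference
#'
#' One site per locus, at the locus midpoint, with a transversion alternate
#' allele and a common true variant allele fraction.
#'
#' @param reference Named character vector of locus sequences.
#' @param vaf True variant allele fraction (recycled across sites).
#' @return Tibble: `locus`, `position` (0-based), `ref`, `alt`, `vaf`.
#' @export
default_target_sites <- function(reference, vaf = 0.1) {
  pos <- floor(nchar(reference) / 2)
  ref_base <- substr(reference, pos + 1, pos + 1)
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  tibble(
    locus = names(reference),
    position = unname(pos),
    ref = unname(ref_base),
    alt = unname(swap[ref_base]),
    vaf = vaf
  )
}

#' Default per-position annealing-mispairing profile
#'
#' Probability that each of the 12 canonical barcode positions carries an
#' annealing mispairing, decreasing towards the ligation site (position 12 is
#' adjacent to the ligation junction). The default is calibrated so that
#' roughly 80% of duplexes carry zero artifacts over the two ligation-
#' proximal 6-mers (about 17% carry one) and most duplexes carry three or
#' fewer artifacts over the full 24 barcode positions.
#'
#' @return Numeric vector of length 12.
#' @export
default_mispair_profile <- function() {
  c(0.30, 0.25, 0.20, 0.12, 0.08, 0.05,
    0.030, 0.025, 0.020, 0.015, 0.007, 0.003)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-read generator.
#' Defaults emulate the assay's statistical structure: ~170 bp cell-free DNA
#' fragments, paired-end 150 sequencing, zero-inflated negative-binomial PCR
#' family sizes with a peak between 6 and 12 reads, position-dependent
#' adapter annealing mispairings, low polymerase and sequencing substitution
#' error rates, and strand-asymmetric oxidative (C>A) damage on the minus
#' strand.
#'
#' @param reference Named character vector of locus sequences
#'   (default [sim_reference()]).
#' @param target_sites Tibble of targeted sites (`locus`, `position`, `ref`,
#'   `alt`, `vaf`); default [default_target_sites()] at VAF 0.1.
#' @param n_molecules Number of double-stranded molecules to simulate.
#' @param fragment_length_mean,fragment_length_sd Fragment size model (bp).
#' @param adapter An [adapter_spec()].
#' @param mispair_profile Per-canonical-position mispairing probabilities
#'   (length = barcode length), position `barcode_length` adjacent to the
#'   ligation site.
#' @param family_size_model List with `dropout` (probability a parental
#'   strand leaves no reads), `nb_size`, `nb_mu` (negative-binomial body;
#'   family size is `1 + NB(nb_size, nb_mu)` when not dropped out).
#' @param polymerase_error_rate Per-base substitution probability per read
#'   copy (PCR misincorporation, applied independently per copy).
#' @param damage_rate_c_to_a Per-C probability of oxidative C>A conversion on
#'   the damaged strand, applied once per molecule before amplification.
#' @param damaged_strand `"minus"` (default) or `"plus"`.
#' @param seq_error_rate Per-base sequencing substitution probability.
#' @param read_length Read length in bp (paired-end).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(reference = sim_reference(),
                       target_sites = default_target_sites(reference),
                       n_molecules = 500,
                       fragment_length_mean = 170,
                       fragment_length_sd = 10,
                       adapter = adapter_spec(),
                       mispair_profile = default_mispair_profile(),
                       family_size_model = list(dropout = 0.3, nb_size = 8, nb_mu = 7),
                       polymerase_error_rate = 1e-4,
                       damage_rate_c_to_a = 0,
                       damaged_strand = c("minus", "plus"),
                       seq_error_rate = 1e-3,
                       read_length = 150,
                       seed = 1L) {
  damaged_strand <- match.arg(damaged_strand)
  cfg <- list(
    reference = reference, target_sites = as_tibble(target_sites),
    n_molecules = n_molecules,
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    adapter = adapter, mispair_profile = mispair_profile,
    family_size_model = family_size_model,
    polymerase_error_rate = polymerase_error_rate,
    damage_rate_c_to_a = damage_rate_c_to_a,
    damaged_strand = damaged_strand,
    seq_error_rate = seq_error_rate,
    read_length = read_length, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$polymerase_error_rate, cfg$damage_rate_c_to_a,
             cfg$seq_error_rate, cfg$mispair_profile,
             cfg$family_size_model$dropout)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (any(cfg$target_sites$vaf < 0 | cfg$target_sites$vaf > 1)) {
    abort("true VAF must lie in [0, 1]")
  }
  adap <- cfg$adapter
  tagged_end <- adap$tag_length + adap$barcode_length
  if (cfg$fragment_length_mean <= 2 * tagged_end) {
    abort("fragment_length_mean must exceed twice the tag+barcode length")
  }
  if (cfg$read_length < tagged_end + 2) {
    abort("read_length shorter than tag + barcode + overhang + 1")
  }
  if (length(cfg$mispair_profile) != adap$barcode_length) {
    abort("mispair_profile length must equal the barcode length")
  }
  bad <- !cfg$target_sites$locus %in% names(cfg$reference) |
    cfg$target_sites$position >= nchar(cfg$reference[cfg$target_sites$locus]) |
    cfg$target_sites$position < 0
  if (any(bad)) abort("target position outside reference")
  ref_base <- substr(cfg$reference[cfg$target_sites$locus],
                     cfg$target_sites$position + 1,
                     cfg$target_sites$position + 1)
  if (any(ref_base != cfg$target_sites$ref)) {
    abort("target ref allele does not match the reference sequence")
  }
  invisible(cfg)
}

#' Simulate double-stranded cfDNA molecules
#'
#' Draws fragments spanning the targeted sites, each carrying the alternate
#' allele with probability equal to the site's true VAF (so the realized
#' alternate count is Binomial(n, VAF)).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` leaves the RNG state alone (used when
#'   called from [simulate_reads()], which seeds once).
#' @return Tibble: `molecule_id`, `locus`, `site_position`, `ref`, `alt`,
#'   `fragment_start`, `fragment_end` (0-based half-open), `carries_alt`.
#' @export
simulate_molecules <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_sim_config(config)
  n <- config$n_molecules
  sites <- config$target_sites
  site_idx <- rep_len(seq_len(nrow(sites)), n)
  locus <- sites$locus[site_idx]
  pos <- sites$position[site_idx]
  locus_len <- nchar(config$reference)[match(locus, names(config$reference))]

  len <- pmax(60L, round(stats::rnorm(n, config$fragment_length_mean,
                                      config$fragment_length_sd)))
  len <- pmin(len, locus_len)
  lo <- pmax(0L, pos - len + 1L)
  hi <- pmin(pos, locus_len - len)
  start <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  carries_alt <- stats::runif(n) < sites$vaf[site_idx]

  tibble(
    molecule_id = sprintf("M%05d", seq_len(n)),
    locus = locus,
    site_position = pos,
    ref = sites$ref[site_idx],
    alt = sites$alt[site_idx],
    fragment_start = as.integer(start),
    fragment_end = as.integer(start + len),
    carries_alt = carries_alt
  )
}

#' Attach barcoded adapters to simulated molecules
#'
#' Each fragment end receives a plus-oligo barcode drawn from the adapter
#' pattern; the annealed minus oligo is its reverse complement except at
#' positions flagged as mispaired, where the minus strand carries the same
#' (non-complementary) base as the plus strand, so the canonicalized minus
#' barcode shows the complementary base within the same degenerate set. One
#' strand-tag combination per molecule is drawn from the tag table.
#'
#' @inheritParams simulate_molecules
#' @param molecules Output of [simulate_molecules()].
#' @return `molecules` with added columns: `tag_plus`, `tag_minus`,
#'   `bc_plus_left`, `bc_canon_minus_left`, `bc_plus_right`,
#'   `bc_canon_minus_right`, and list-columns `mispair_left`,
#'   `mispair_right` (canonical positions 1..barcode length, position
#'   `barcode_length` adjacent to the ligation site).
#' @export
attach_adapters <- function(molecules, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adap <- config$adapter
  if (nrow(adap$tag_table) == 0) abort("empty tag_table")
  profile <- config$mispair_profile
  n <- nrow(molecules)
  L <- adap$barcode_length

  tag_idx <- sample.int(nrow(adap$tag_table), n, replace = TRUE)
  molecules$tag_plus <- adap$tag_table$plus_tag[tag_idx]
  molecules$tag_minus <- adap$tag_table$minus_tag[tag_idx]

  # Both oligos draw their degenerate positions from their own two-letter
  # sets; a non-complementary draw that survives annealing selection is a
  # mispairing. After canonical reverse-complementation the mispaired
  # position therefore shows the *other* allowed base of the plus set, so
  # mispaired barcodes still conform to the plus pattern.
  sets <- iupac_sets(adap$plus_pattern)
  flip <- function(base, j) {
    s <- sets[[j]]
    if (length(s) == 1) s else setdiff(s, base)[1]
  }
  one_end <- function() {
    bc <- sample_barcodes(n, adap$plus_pattern)
    mis_mat <- matrix(stats::runif(n * L) < rep(profile, each = n), nrow = n)
    mis <- apply(mis_mat, 1, which, simplify = FALSE)
    bcq <- vapply(seq_len(n), function(i) {
      if (length(mis[[i]]) == 0) return(bc[i])
      ch <- strsplit(bc[i], "")[[1]]
      for (j in mis[[i]]) ch[j] <- flip(ch[j], j)
      paste(ch, collapse = "")
    }, character(1))
    list(bc = bc, bcq = bcq, mis = mis)
  }
  left <- one_end()
  right <- one_end()
  molecules$bc_plus_left <- left$bc
  molecules$bc_canon_minus_left <- left$bcq
  molecules$mispair_left <- left$mis
  molecules$bc_plus_right <- right$bc
  molecules$bc_canon_minus_right <- right$bcq
  molecules$mispair_right <- right$mis
  molecules
}

# Apply independent per-base substitution errors at `rate`; returns the
# mutated sequence and a record of changes. Fast path: no errors.
mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, pos = integer(0),
                             from = character(0), to = character(0)))
  len <- nchar(seq)
  k <- stats::rbinom(1, len, rate)
  if (k == 0) return(list(seq = seq, pos = integer(0),
                          from = character(0), to = character(0)))
  pos <- sample.int(len, k)
  ch <- strsplit(seq, "")[[1]]
  from <- ch[pos]
  bases <- c("A", "C", "G", "T")
  to <- vapply(from, function(b) sample(setdiff(bases, b), 1), character(1),
               USE.NAMES = FALSE)
  ch[pos] <- to
  list(seq = paste(ch, collapse = ""), pos = pos, from = from, to = to)
}

#' Amplify tagged molecules and emit paired reads
#'
#' Each parental strand independently spawns a PCR family whose size is
#' drawn from the zero-inflated negative-binomial family model (size 0 models
#' strand dropout). Oxidative damage (C>A on the damaged strand) is applied
#' once per molecule before amplification; polymerase errors are applied per
#' copy; sequencing errors per read. Reads follow the construct layout
#' tag + barcode + T overhang + insert (+ A + barcode + tag read-through at
#' the 3' end), truncated to the configured read length, with constant Q30
#' qualities.
#'
#' @inheritParams simulate_molecules
#' @param tagged Output of [attach_adapters()].
#' @return List with `reads` (tibble: `read_id`, `molecule_id`, `strand`,
#'   `r1_seq`, `r2_seq`, `r1_qual`, `r2_qual`), `truth` (the `tagged` tibble
#'   plus per-strand family sizes and damage positions), and `errors`
#'   (tibble of injected substitutions: `read_id`, `mechanism`, `pos`,
#'   `from`, `to`; positions are construct coordinates for polymerase
#'   errors and read coordinates for sequencing errors).
#' @export
amplify_and_sequence <- function(tagged, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adap <- config$adapter
  rl <- config$read_length
  fam <- config$family_size_model
  n <- nrow(tagged)

  draw_family_size <- function(n) {
    size <- ifelse(stats::runif(n) < fam$dropout, 0L,
                   1L + stats::rnbinom(n, size = fam$nb_size, mu = fam$nb_mu))
    as.integer(size)
  }
  n_plus <- draw_family_size(n)
  n_minus <- draw_family_size(n)

  reads <- vector("list", 2 * n)
  errors <- vector("list", 2 * n)
  damage_pos <- vector("list", n)

  layout_5p <- function(tag, bc) {
    if (adap$tag_position == "before_barcode") paste0(tag, bc, adap$overhang_base)
    else paste0(bc, tag, adap$overhang_base)
  }
  layout_3p <- function(tag, bcq) {
    # raw 3' block on the strand: A + minus-oligo barcode + minus-oligo tag
    if (adap$tag_position == "before_barcode") {
      paste0("A", revcomp(bcq), revcomp(tag))
    } else {
      paste0("A", revcomp(tag), revcomp(bcq))
    }
  }

  for (i in seq_len(n)) {
    m <- tagged[i, ]
    ref_seq <- config$reference[[m$locus]]
    insert_top <- substr(ref_seq, m$fragment_start + 1, m$fragment_end)
    if (m$carries_alt) {
      off <- m$site_position - m$fragment_start + 1
      substr(insert_top, off, off) <- m$alt
    }
    insert_bottom <- revcomp(insert_top)

    # oxidative damage: once per molecule, pre-amplification, one strand
    dmg <- integer(0)
    if (config$damage_rate_c_to_a > 0) {
      target <- if (config$damaged_strand == "minus") insert_bottom else insert_top
      ch <- strsplit(target, "")[[1]]
      cpos <- which(ch == "C")
      hit <- cpos[stats::runif(length(cpos)) < config$damage_rate_c_to_a]
      if (length(hit) > 0) {
        ch[hit] <- "A"
        target <- paste(ch, collapse = "")
        if (config$damaged_strand == "minus") insert_bottom <- target
        else insert_top <- target
      }
      dmg <- hit
    }
    damage_pos[[i]] <- dmg

    construct_plus <- paste0(
      layout_5p(m$tag_plus, m$bc_plus_left), insert_top,
      layout_3p(m$tag_minus, m$bc_canon_minus_right)
    )
    construct_minus <- paste0(
      layout_5p(m$tag_minus, m$bc_plus_right), insert_bottom,
      layout_3p(m$tag_plus, m$bc_canon_minus_left)
    )

    make_reads <- function(construct, n_reads, strand) {
      if (n_reads == 0) return(list(reads = NULL, errors = NULL))
      rows <- vector("list", n_reads)
      errs <- vector("list", n_reads)
      for (r in seq_len(n_reads)) {
        rid <- sprintf("%s_%s_%02d", m$molecule_id, strand, r)
        pol <- mutate_bases(construct, config$polymerase_error_rate)
        r1 <- substr(pol$seq, 1, rl)
        r2 <- substr(revcomp(pol$seq), 1, rl)
        e1 <- mutate_bases(r1, config$seq_error_rate)
        e2 <- mutate_bases(r2, config$seq_error_rate)
        rows[[r]] <- tibble(
          read_id = rid, molecule_id = m$molecule_id, strand = strand,
          r1_seq = e1$seq, r2_seq = e2$seq,
          r1_qual = strrep("?", nchar(e1$seq)),
          r2_qual = strrep("?", nchar(e2$seq))
        )
        errs[[r]] <- dplyr::bind_rows(
          if (length(pol$pos)) tibble(read_id = rid, mechanism = "polymerase",
                                      pos = pol$pos, from = pol$from, to = pol$to),
          if (length(e1$pos)) tibble(read_id = rid, mechanism = "sequencing_r1",
                                     pos = e1$pos, from = e1$from, to = e1$to),
          if (length(e2$pos)) tibble(read_id = rid, mechanism = "sequencing_r2",
                                     pos = e2$pos, from = e2$from, to = e2$to)
        )
      }
      list(reads = dplyr::bind_rows(rows), errors = dplyr::bind_rows(errs))
    }

    rp <- make_reads(construct_plus, n_plus[i], "plus")
    rm_ <- make_reads(construct_minus, n_minus[i], "minus")
    reads[[2 * i - 1]] <- rp$reads
    reads[[2 * i]] <- rm_$reads
    errors[[2 * i - 1]] <- rp$errors
    errors[[2 * i]] <- rm_$errors
  }

  truth <- tagged
  truth$family_size_plus <- n_plus
  truth$family_size_minus <- n_minus
  truth$damage_positions <- damage_pos

  list(
    reads = dplyr::bind_rows(reads),
    truth = truth,
    errors = dplyr::bind_rows(errors)
  )
}

#' Run the whole simulator
#'
#' Seeds the RNG once from `config$seed` and chains
#' [simulate_molecules()], [attach_adapters()] and
#' [amplify_and_sequence()]. Identical config + seed yields identical
#' output.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_result`: `reads`, `truth`, `errors`,
#'   `config`.
#' @export
simulate_reads <- function(config) {
  set.seed(config$seed)
  molecules <- simulate_molecules(config)
  tagged <- attach_adapters(molecules, config)
  out <- amplify_and_sequence(tagged, config)
  out$config <- config
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", nrow(x$truth), "molecules,", nrow(x$reads),
      "read pairs,", nrow(x$errors), "injected errors\n")
  invisible(x)
}

#' Write simulated reads as paired FASTQ
#'
#' Illumina 1.8+-style headers carry the molecule id in the comment field.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param r1_path,r2_path Output paths; a `.gz` suffix gives gzip output.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  write_one <- function(path, seqs, quals) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", reads$read_id, " ", reads$molecule_id, "\n",
                      seqs, "\n+\n", quals), con)
  }
  write_one(r1_path, reads$r1_seq, reads$r1_qual)
  write_one(r2_path, reads$r2_seq, reads$r2_qual)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ into the read-pair tibble
#'
#' @param r1_path,r2_path Paths to the two mate files (phred33, optionally
#'   gzipped).
#' @return Tibble with `read_id`, `molecule_id` (comment field, `NA` when
#'   absent), `r1_seq`, `r2_seq`, `r1_qual`, `r2_qual`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  parse_one <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) %% 4 != 0) {
      abort(sprintf("corrupt FASTQ '%s': %d lines (record %d truncated)",
                    path, length(lines), length(lines) %/% 4 + 1))
    }
    hdr <- lines[seq(1, length(lines), by = 4)]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad) > 0) {
      abort(sprintf("corrupt FASTQ '%s' at record %d: header lacks '@'",
                    path, bad[1]))
    }
    parts <- stringr::str_split_fixed(sub("^@", "", hdr), " ", 2)
    tibble(
      read_id = parts[, 1],
      molecule_id = ifelse(parts[, 2] == "", NA_character_, parts[, 2]),
      seq = lines[seq(2, length(lines), by = 4)],
      qual = lines[seq(4, length(lines), by = 4)]
    )
  }
  r1 <- parse_one(r1_path)
  r2 <- parse_one(r2_path)
  if (nrow(r1) != nrow(r2) || any(r1$read_id != r2$read_id)) {
    abort("R1 and R2 files are not consistently paired")
  }
  tibble(
    read_id = r1$read_id, molecule_id = r1$molecule_id,
    r1_seq = r1$seq, r2_seq = r2$seq,
    r1_qual = r1$qual, r2_qual = r2$qual
  )
}
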