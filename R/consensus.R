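# --- reference handling -----------------------------------------------------

# Concatenate loci with '#' separators for fast exact seed search; keeps a
# map from concatenated coordinates back to (locus, local position).
make_ref_index <- function(reference) {
  if (length(reference) == 0) abort("empty reference")
  lens <- nchar(reference)
  sep_starts <- cumsum(c(1, lens + 1))[seq_along(reference)]
  list(
    concat = paste(reference, collapse = "#"),
    locus = names(reference),
    start = sep_starts,            # 1-based start of each locus in concat
    len = lens
  )
}

# Locate `seq` (plain A/C/G/T) on the forward concatenated reference with at
# most max_mm mismatches, proposing placements from exact k-mer seeds.
seed_place <- function(seq, idx, max_mm, k = 24) {
  L <- nchar(seq)
  if (L < k) return(NULL)
  offsets <- unique(c(1L, max(1L, (L - k) %/% 2L + 1L), L - k + 1L))
  cands <- integer(0)
  for (off in offsets) {
    seed <- substr(seq, off, off + k - 1L)
    hits <- gregexpr(seed, idx$concat, fixed = TRUE)[[1]]
    if (hits[1] != -1) cands <- c(cands, hits - (off - 1L))
  }
  cands <- unique(cands[cands >= 1 & cands + L - 1 <= nchar(idx$concat)])
  if (length(cands) == 0) return(NULL)
  best <- NULL
  cseq <- split1(seq)
  for (p in cands) {
    win <- substr(idx$concat, p, p + L - 1L)
    if (grepl("#", win, fixed = TRUE)) next
    mm <- sum(split1(win) != cseq)
    if (mm > max_mm) next
    if (is.null(best) || mm < best$mm) best <- list(pos = p, mm = mm)
  }
  best
}

concat_to_local <- function(pos, idx) {
  i <- findInterval(pos, idx$start)
  list(locus = idx$locus[i], local = pos - idx$start[i])   # 0-based local
}

# Glocal (read-global, reference-local) affine-gap alignment fallback for
# reads without an exact seed hit; returns the best placement or NULL.
pw_place <- function(seq, reference, max_edit) {
  best <- NULL
  for (loc in names(reference)) {
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(seq),
      subject = Biostrings::DNAString(reference[[loc]]),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2),
      gapOpening = 4, gapExtension = 1
    )
    edit <- Biostrings::nmismatch(al) +
      Biostrings::nindel(al)@insertion[, "WidthSum"] +
      Biostrings::nindel(al)@deletion[, "WidthSum"]
    if (edit <= max_edit && (is.null(best) || edit < best$mm)) {
      rng <- Biostrings::subject(al)
      best <- list(locus = loc, local = BiocGenerics::start(rng) - 1L,
                   width = BiocGenerics::width(rng), mm = edit)
    }
  }
  best
}

#' Align prepared reads to the small reference
#'
#' Places each insert on the reference by exact-seed search with mismatch
#' verification (substitution-only placement), falling back to glocal
#' affine-gap alignment for reads without a seed hit; both strands are
#' tried. Reads whose best placement exceeds 5% edit distance are rejected
#' as off-target. Unmerged pairs are placed mate-wise and represented as a
#' gapped pseudo-merged sequence whose gap positions carry `-`.
#'
#' @param tagged Output of [prep_reads()] (rows with `status == "rejected"`
#'   are passed through untouched).
#' @param reference Named character vector of locus sequences.
#' @param max_edit_frac Maximum edit distance as a fraction of insert length.
#' @return `tagged` with columns `locus`, `fragment_start`, `fragment_end`
#'   (0-based half-open), `map_strand` (`"+"`/`"-"`), `aln_mismatch` and
#'   `seq` (reference-forward insert sequence, `-` at uncovered positions);
#'   off-target rows get `status = "rejected"`, `reject_reason =
#'   "off_target"`.
#' @export
align_reads <- function(tagged, reference, max_edit_frac = 0.05) {
  idx <- make_ref_index(reference)
  n <- nrow(tagged)
  locus <- rep(NA_character_, n)
  fstart <- fend <- aln_mm <- rep(NA_integer_, n)
  strand <- seqf <- rep(NA_character_, n)
  reason <- tagged$reject_reason

  place_any <- function(s, max_mm) {
    fwd <- seed_place(s, idx, max_mm)
    rev_ <- seed_place(revcomp(s), idx, max_mm)
    if (!is.null(fwd) && (is.null(rev_) || fwd$mm <= rev_$mm)) {
      c(concat_to_local(fwd$pos, idx), list(mm = fwd$mm, strand = "+"))
    } else if (!is.null(rev_)) {
      c(concat_to_local(rev_$pos, idx), list(mm = rev_$mm, strand = "-"))
    } else {
      # fallback: full alignment, both strands
      b1 <- pw_place(s, reference, max_mm)
      b2 <- pw_place(revcomp(s), reference, max_mm)
      if (!is.null(b1) && (is.null(b2) || b1$mm <= b2$mm)) {
        list(locus = b1$locus, local = b1$local, mm = b1$mm, strand = "+")
      } else if (!is.null(b2)) {
        list(locus = b2$locus, local = b2$local, mm = b2$mm, strand = "-")
      } else NULL
    }
  }

  for (i in seq_len(n)) {
    if (!is.na(reason[i])) next
    s <- tagged$insert_seq[i]
    if (is.na(tagged$insert_right[i])) {
      max_mm <- floor(max_edit_frac * nchar(s))
      pl <- place_any(s, max_mm)
      if (is.null(pl)) { reason[i] <- "off_target"; next }
      locus[i] <- pl$locus
      fstart[i] <- pl$local
      fend[i] <- pl$local + nchar(s)
      strand[i] <- pl$strand
      aln_mm[i] <- pl$mm
      seqf[i] <- if (pl$strand == "+") s else revcomp(s)
    } else {
      # unmerged pair: place the two construct-frame parts independently
      sr <- tagged$insert_right[i]
      max_mm1 <- floor(max_edit_frac * nchar(s))
      max_mm2 <- floor(max_edit_frac * nchar(sr))
      p1 <- place_any(s, max_mm1)
      p2 <- place_any(sr, max_mm2)
      if (is.null(p1) || is.null(p2) || p1$locus != p2$locus ||
          p1$strand != p2$strand) {
        reason[i] <- "off_target"; next
      }
      if (p1$strand == "+") {
        left <- list(pos = p1$local, seq = s)
        right <- list(pos = p2$local, seq = sr)
      } else {
        left <- list(pos = p2$local, seq = revcomp(sr))
        right <- list(pos = p1$local, seq = revcomp(s))
      }
      gap <- right$pos - (left$pos + nchar(left$seq))
      if (gap < 0) { reason[i] <- "off_target"; next }
      locus[i] <- p1$locus
      fstart[i] <- left$pos
      fend[i] <- right$pos + nchar(right$seq)
      strand[i] <- p1$strand
      aln_mm[i] <- p1$mm + p2$mm
      seqf[i] <- paste0(left$seq, strrep("-", gap), right$seq)
    }
  }

  tagged$locus <- locus
  tagged$fragment_start <- fstart
  tagged$fragment_end <- fend
  tagged$map_strand <- strand
  tagged$aln_mismatch <- aln_mm
  tagged$seq <- seqf
  newly <- is.na(tagged$reject_reason) & !is.na(reason)
  tagged$reject_reason <- reason
  tagged$status[newly] <- "rejected"
  tagged
}

# --- family grouping --------------------------------------------------------

# Single-linkage clusters of equal-length strings under a Hamming threshold
# (plain union-find; buckets are small).
single_linkage_clusters <- function(strings, threshold) {
  n <- length(strings)
  if (n == 1) return(1L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mat <- matrix(unlist(strsplit(strings, "")), nrow = n, byrow = TRUE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sum(mat[i, ] != mat[j, ]) <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Group aligned reads into PCR families
#'
#' Reads are first bucketed by (locus, orientation, fragment start, fragment
#' end); within a bucket, combined UIDs are clustered by single linkage with
#' a Hamming threshold of `max(1, floor(mismatch_frac * tagged-read
#' length))`, mirroring a 1%-mismatch de-novo assembly over tag + insert.
#' Each cluster is one PCR family. Reads without orientation or coordinates
#' (rejected earlier) are ignored.
#'
#' @param aligned Output of [align_reads()].
#' @param adapter An [adapter_spec()] (for the tagged-read length).
#' @param mismatch_frac Mismatch tolerance of the family clustering.
#' @return `aligned` with a `family_id` column (NA for unassigned rows),
#'   deterministically ordered by coordinates then UID.
#' @export
group_families <- function(aligned, adapter = adapter_spec(),
                           mismatch_frac = 0.01) {
  use <- aligned$status %in% c("merged", "unmerged") & !is.na(aligned$locus)
  aligned$family_id <- NA_character_
  if (!any(use)) return(aligned)

  block2 <- 2L * (adapter$tag_length + adapter$barcode_length + 1L)
  sub <- aligned[use, ]
  key <- paste(sub$locus, sub$orientation, sub$fragment_start,
               sub$fragment_end, sep = "|")
  fam_global <- rep(NA_character_, nrow(sub))
  for (k in unique(key)) {
    sel <- which(key == k)
    ins_len <- sub$fragment_end[sel[1]] - sub$fragment_start[sel[1]]
    thr <- max(1L, floor(mismatch_frac * (ins_len + block2)))
    cl <- single_linkage_clusters(sub$uid[sel], thr)
    fam_global[sel] <- paste0(k, "|c", cl)
  }
  # stable, readable ids ordered by coordinates then representative UID
  ord <- order(sub$locus, sub$fragment_start, sub$fragment_end,
               sub$orientation, sub$uid)
  fam_levels <- unique(fam_global[ord])
  fam_id <- sprintf("F%05d", match(fam_global, fam_levels))
  aligned$family_id[use] <- fam_id
  aligned
}

# Per-position plurality over equal-length sequences; '-' (no coverage) is
# ignored, exact ties among concrete bases give 'N', all-gap columns stay
# '-'.
plurality_consensus <- function(seqs) {
  n <- length(seqs)
  if (n == 1) return(list(seq = seqs, n_ambiguous = sum(split1(seqs) == "N")))
  L <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  letters_ <- c("A", "C", "G", "T")
  counts <- vapply(letters_, function(b) colSums(mat == b),
                   numeric(L))
  counts <- matrix(counts, nrow = L)       # L x 4, robust for L == 1
  top <- apply(counts, 1, max)
  n_top <- rowSums(counts == top)
  cons <- letters_[max.col(counts, ties.method = "first")]
  cons[top == 0] <- "-"
  cons[top > 0 & n_top > 1] <- "N"
  list(seq = paste(cons, collapse = ""),
       n_ambiguous = sum(top > 0 & n_top > 1))
}

#' Summarise PCR families
#'
#' @param grouped Output of [group_families()].
#' @return Tibble with one row per family: `family_id`, `locus`,
#'   `orientation`, `fragment_start`, `fragment_end`, `size`, `rep_uid_5p`,
#'   `rep_uid_3p` (per-position plurality of member UIDs; ties take the
#'   alphabetically first base).
#' @export
summarize_families <- function(grouped) {
  sub <- grouped[!is.na(grouped$family_id), ]
  rep_uid <- function(uids) {
    if (length(uids) == 1) return(uids)
    mat <- matrix(unlist(strsplit(uids, "")), nrow = length(uids), byrow = TRUE)
    paste(apply(mat, 2, function(col) {
      tt <- sort(table(col), decreasing = TRUE)
      nm <- names(tt)[tt == max(tt)]
      sort(nm)[1]
    }), collapse = "")
  }
  sub |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      locus = .data$locus[1],
      orientation = .data$orientation[1],
      fragment_start = .data$fragment_start[1],
      fragment_end = .data$fragment_end[1],
      size = dplyr::n(),
      rep_uid_5p = rep_uid(.data$uid_5p),
      rep_uid_3p = rep_uid(.data$uid_3p),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$locus, .data$fragment_start, .data$fragment_end,
                   .data$orientation, .data$rep_uid_5p)
}

#' Build single-strand consensus sequences
#'
#' One consensus per PCR family with at least `min_reads` members: the most
#' common base at each position; exact ties become `N` (excluded from all
#' downstream counting); positions covered by no member (unmerged gaps) stay
#' `-`.
#'
#' @param grouped Output of [group_families()].
#' @param min_reads Minimum family size (independent reads) for a consensus.
#' @return Tibble of SSCS records: `sscs_id`, `family_id`, `locus`,
#'   `orientation`, `fragment_start`, `fragment_end`, `uid_5p`, `uid_3p`,
#'   `uid`, `seq`, `n_reads`, `n_ambiguous`, `trim5`, `trim3`.
#' @export
build_sscs <- function(grouped, min_reads = 3) {
  fams <- summarize_families(grouped)
  fams <- fams[fams$size >= min_reads, ]
  if (nrow(fams) == 0) {
    return(tibble(
      sscs_id = character(0), family_id = character(0), locus = character(0),
      orientation = character(0), fragment_start = integer(0),
      fragment_end = integer(0), uid_5p = character(0), uid_3p = character(0),
      uid = character(0), seq = character(0), n_reads = integer(0),
      n_ambiguous = integer(0), trim5 = integer(0), trim3 = integer(0)
    ))
  }
  reads_by_fam <- split(grouped[!is.na(grouped$family_id), ],
                        grouped$family_id[!is.na(grouped$family_id)])
  rows <- purrr::map2(fams$family_id, seq_len(nrow(fams)), function(fid, i) {
    members <- reads_by_fam[[fid]]
    cons <- plurality_consensus(members$seq)
    tibble(
      sscs_id = sprintf("S%05d", i),
      family_id = fid,
      locus = fams$locus[i],
      orientation = fams$orientation[i],
      fragment_start = fams$fragment_start[i],
      fragment_end = fams$fragment_end[i],
      uid_5p = fams$rep_uid_5p[i],
      uid_3p = fams$rep_uid_3p[i],
      uid = paste0(fams$rep_uid_5p[i], fams$rep_uid_3p[i]),
      seq = cons$seq,
      n_reads = fams$size[i],
      n_ambiguous = cons$n_ambiguous,
      trim5 = max(members$trim5 %||% 0L),
      trim3 = max(members$trim3 %||% 0L)
    )
  })
  dplyr::bind_rows(rows)
}

#' Family-size distribution statistics
#'
#' Histogram of PCR family sizes, the peak family size (the size > 1 whose
#' families contain the most reads; `NA` when every family is a singleton),
#' and the per-orientation fraction of families with unique mapping
#' coordinates.
#'
#' @param grouped Output of [group_families()].
#' @return List of class `family_size_stats`: `histogram` (tibble `size`,
#'   `n_families`, `n_reads`), `peak_family_size`,
#'   `unique_coord_fraction` (tibble per orientation).
#' @export
family_size_stats <- function(grouped) {
  fams <- summarize_families(grouped)
  hist <- fams |>
    dplyr::count(size, name = "n_families") |>
    dplyr::mutate(n_reads = .data$size * .data$n_families) |>
    dplyr::arrange(.data$size)
  big <- hist[hist$size > 1, ]
  peak <- if (nrow(big) == 0) NA_integer_ else big$size[which.max(big$n_reads)]
  uniq <- fams |>
    dplyr::group_by(.data$orientation) |>
    dplyr::summarise(
      n_families = dplyr::n(),
      frac_unique_coords = {
        key <- paste(.data$locus, .data$fragment_start, .data$fragment_end)
        mean(!(duplicated(key) | duplicated(key, fromLast = TRUE)))
      },
      .groups = "drop"
    )
  structure(
    list(histogram = hist, peak_family_size = peak,
         unique_coord_fraction = uniq),
    class = "family_size_stats"
  )
}

#' @export
print.family_size_stats <- function(x, ...) {
  cat("<family_size_stats> peak family size:", x$peak_family_size, "\n")
  print(x$histogram, n = 10)
  invisible(x)
}
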