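split1 <- function(x) strsplit(x, "")[[1]]

# phred33 quality characters in ascending order, for locale-free comparison
QUAL_CHARS <- strsplit(rawToChar(as.raw(33:126)), "")[[1]]

# Find the best ungapped overlap between s1 and s2rc (r2 already reverse
# complemented). Offsets d place s2rc's first base at 0-based position d of
# s1's frame (d may be negative). Candidates must reach min_overlap and stay
# under max_mismatch_frac; the best candidate maximises
# matches - 4 * mismatches (ties: longer overlap, then smaller |d|).
best_overlap <- function(c1, c2, min_overlap, max_mismatch_frac,
                         offsets = NULL) {
  L1 <- length(c1); L2 <- length(c2)
  if (is.null(offsets)) {
    offsets <- seq(-(L2 - min_overlap), L1 - min_overlap)
  }
  best <- NULL
  for (d in offsets) {
    a0 <- max(0L, d)
    b0 <- min(L1, d + L2)
    ov <- b0 - a0
    if (ov < min_overlap) next
    i1 <- (a0 + 1L):b0
    i2 <- (a0 - d + 1L):(b0 - d)
    mm <- sum(c1[i1] != c2[i2])
    if (mm / ov > max_mismatch_frac) next
    score <- (ov - mm) - 4 * mm
    cand <- list(d = d, overlap = ov, mismatches = mm, score = score)
    if (is.null(best) ||
        score > best$score ||
        (score == best$score && ov > best$overlap) ||
        (score == best$score && ov == best$overlap && abs(d) < abs(best$d))) {
      best <- cand
    }
  }
  best
}

# Seed-based candidate offsets: exact occurrences of s2rc's leading k-mer in
# s1 (and of s1's trailing k-mer in s2rc) propose offsets cheaply.
seed_offsets <- function(s1, s2rc, k = 20) {
  offs <- integer(0)
  if (nchar(s2rc) >= k) {
    seed <- substr(s2rc, 1, k)
    hits <- gregexpr(seed, s1, fixed = TRUE)[[1]]
    if (hits[1] != -1) offs <- c(offs, hits - 1L)
  }
  if (nchar(s1) >= k) {
    seed <- substr(s1, nchar(s1) - k + 1, nchar(s1))
    hits <- gregexpr(seed, s2rc, fixed = TRUE)[[1]]
    if (hits[1] != -1) {
      # s1 tail aligned at position h (1-based) of s2rc -> d = L1 - (h-1) - k
      offs <- c(offs, nchar(s1) - (hits - 1L) - k)
    }
  }
  unique(offs)
}

#' Merge read pairs with overlapping ends
#'
#' Finds the best ungapped overlap between read 1 and the reverse complement
#' of read 2. Disagreeing overlap positions take the higher-quality base
#' (ties go to read 1). Pairs with no acceptable overlap are kept as
#' unmerged (their mates are processed separately downstream).
#'
#' @param pairs Tibble with `read_id`, `r1_seq`, `r2_seq` and optional
#'   `r1_qual`, `r2_qual` (phred33), e.g. from [simulate_reads()] or
#'   [read_fastq_pairs()].
#' @param min_overlap Minimum acceptable overlap (nt).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return `pairs` with added columns `status` (`"merged"`/`"unmerged"`),
#'   `merged_seq`, `merged_qual`, `overlap_len`, `overlap_mismatches`.
#' @export
merge_pairs <- function(pairs, min_overlap = 30, max_mismatch_frac = 0.1) {
  n <- nrow(pairs)
  merged_seq <- rep(NA_character_, n)
  merged_qual <- rep(NA_character_, n)
  ov_len <- rep(NA_integer_, n)
  ov_mm <- rep(NA_integer_, n)
  has_qual <- all(c("r1_qual", "r2_qual") %in% names(pairs))

  for (i in seq_len(n)) {
    s1 <- pairs$r1_seq[i]
    if (nchar(s1) == 0 || nchar(pairs$r2_seq[i]) == 0) {
      abort("merge_pairs(): empty read")
    }
    s2rc <- revcomp(pairs$r2_seq[i])
    c1 <- split1(s1)
    c2 <- split1(s2rc)
    q1 <- if (has_qual) split1(pairs$r1_qual[i]) else rep("?", length(c1))
    q2 <- if (has_qual) rev(split1(pairs$r2_qual[i])) else rep("?", length(c2))

    best <- best_overlap(c1, c2, min_overlap, max_mismatch_frac,
                         offsets = seed_offsets(s1, s2rc))
    if (is.null(best)) {
      best <- best_overlap(c1, c2, min_overlap, max_mismatch_frac)
    }
    if (is.null(best)) next

    d <- best$d
    start <- min(0L, d)
    frame <- seq.int(start, max(length(c1), d + length(c2)) - 1L)  # 0-based
    v1 <- vq1 <- rep(NA_character_, length(frame))
    v2 <- vq2 <- rep(NA_character_, length(frame))
    at1 <- seq_along(c1) - start
    at2 <- d + seq_along(c2) - start
    v1[at1] <- c1; vq1[at1] <- q1
    v2[at2] <- c2; vq2[at2] <- q2
    r1rank <- match(vq1, QUAL_CHARS)
    r2rank <- match(vq2, QUAL_CHARS)
    take2 <- is.na(v1) |
      (!is.na(v2) & v1 != v2 & r2rank > r1rank)
    m_seq <- ifelse(take2, v2, v1)
    m_q <- ifelse(take2, vq2,
                  ifelse(!is.na(v2) & v1 == v2 & r2rank > r1rank, vq2, vq1))
    merged_seq[i] <- paste(m_seq, collapse = "")
    merged_qual[i] <- paste(m_q, collapse = "")
    ov_len[i] <- best$overlap
    ov_mm[i] <- best$mismatches
  }

  pairs$status <- ifelse(is.na(merged_seq), "unmerged", "merged")
  pairs$merged_seq <- merged_seq
  pairs$merged_qual <- merged_qual
  pairs$overlap_len <- ov_len
  pairs$overlap_mismatches <- ov_mm
  pairs
}

#' Extract strand tags and barcodes and validate them
#'
#' Slices the 5' and 3' tagged blocks off each merged read (the 3' block is
#' parsed after reverse complementation, so both stored barcodes are in
#' canonical plus-pattern orientation) and validates both barcodes against
#' the adapter's plus pattern. For unmerged pairs the 5' block comes from
#' read 1 and the 3' block from the start of read 2 (already canonical
#' there); pairs whose mates truncate inside a tagged block are rejected.
#'
#' @param merged Output of [merge_pairs()].
#' @param adapter An [adapter_spec()].
#' @return `merged` with added columns `tag_5p`, `tag_3p`, `uid_5p`,
#'   `uid_3p`, `uid` (concatenated), `insert_seq` (merged insert, or the
#'   read-1 part for unmerged pairs), `insert_right` (construct-orientation
#'   read-2 insert part for unmerged pairs, else `NA`), and `reject_reason`
#'   (`NA`, `"short"`, or `"barcode_pattern"`). `status` becomes
#'   `"rejected"` for failed reads.
#' @export
extract_tags <- function(merged, adapter) {
  tl <- adapter$tag_length
  bl <- adapter$barcode_length
  block <- tl + bl + 1L                 # tag + barcode + overhang
  before <- adapter$tag_position == "before_barcode"
  n <- nrow(merged)

  tag5 <- uid5 <- tag3 <- uid3 <- insert <- insert_r <-
    rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  slice5 <- function(s) {
    if (before) list(tag = substr(s, 1, tl), uid = substr(s, tl + 1, tl + bl))
    else list(tag = substr(s, bl + 1, bl + tl), uid = substr(s, 1, bl))
  }

  for (i in seq_len(n)) {
    if (identical(merged$status[i], "merged")) {
      s <- merged$merged_seq[i]
      L <- nchar(s)
      if (L < 2 * block + 1) { reason[i] <- "short"; next }
      f <- slice5(s)
      tail_block <- substr(s, L - block + 1, L)   # A + (raw 3' block)
      raw3 <- revcomp(substr(tail_block, 2, block))
      b <- slice5(raw3)
      tag5[i] <- f$tag; uid5[i] <- f$uid
      tag3[i] <- b$tag; uid3[i] <- b$uid
      insert[i] <- substr(s, block + 1, L - block)
    } else {
      r1 <- merged$r1_seq[i]; r2 <- merged$r2_seq[i]
      if (nchar(r1) < block + 1 || nchar(r2) < block + 1) {
        reason[i] <- "short"; next
      }
      f <- slice5(r1)
      # the start of r2 is the reverse complement of the construct's 3' end,
      # i.e. canonical tag + barcode followed by the overhang base
      b <- slice5(r2)
      tag5[i] <- f$tag; uid5[i] <- f$uid
      tag3[i] <- b$tag; uid3[i] <- b$uid
      insert[i] <- substr(r1, block + 1, nchar(r1))
      insert_r[i] <- revcomp(substr(r2, block + 1, nchar(r2)))
    }
  }

  ok <- is.na(reason)
  pat_ok <- rep(FALSE, n)
  if (any(ok)) {
    pat_ok[ok] <- matches_pattern(uid5[ok], adapter$plus_pattern) &
      matches_pattern(uid3[ok], adapter$plus_pattern)
  }
  reason[ok & !pat_ok] <- "barcode_pattern"

  merged$tag_5p <- tag5
  merged$tag_3p <- tag3
  merged$uid_5p <- uid5
  merged$uid_3p <- uid3
  merged$uid <- ifelse(is.na(reason), paste0(uid5, uid3), NA_character_)
  merged$insert_seq <- ifelse(is.na(reason), insert, NA_character_)
  merged$insert_right <- ifelse(is.na(reason), insert_r, NA_character_)
  merged$reject_reason <- reason
  merged$status[!is.na(reason)] <- "rejected"
  merged
}

#' Assign strand orientation from the tag pair
#'
#' A read whose observed (5', 3') tag pair appears in the adapter's tag
#' table derives from the plus strand; the swapped reading marks the minus
#' strand; anything else (including a pair matching both ways) is
#' `"unknown"` and excluded from duplex matching.
#'
#' @param tagged Output of [extract_tags()].
#' @param adapter An [adapter_spec()].
#' @return `tagged` with an `orientation` column
#'   (`"plus"`/`"minus"`/`"unknown"`, `NA` for rejected reads).
#' @export
assign_orientation <- function(tagged, adapter) {
  tab <- adapter$tag_table
  key <- paste(tab$plus_tag, tab$minus_tag)
  obs <- paste(tagged$tag_5p, tagged$tag_3p)
  swp <- paste(tagged$tag_3p, tagged$tag_5p)
  is_plus <- obs %in% key
  is_minus <- swp %in% key
  ori <- dplyr::case_when(
    is_plus & is_minus ~ "unknown",
    is_plus ~ "plus",
    is_minus ~ "minus",
    TRUE ~ "unknown"
  )
  ori[tagged$status == "rejected"] <- NA_character_
  tagged$orientation <- ori
  tagged
}

#' Soft-trim ligation-adjacent insert bases
#'
#' Marks the first and last `n` insert bases as masked for error accounting
#' and variant calling (end-repair artifacts concentrate next to the
#' ligation sites). Bases are masked, not removed: alignment coordinates are
#' unchanged.
#'
#' @param tagged Output of [extract_tags()] (or any downstream tibble).
#' @param n Number of bases to mask at each insert end.
#' @return `tagged` with `trim5` and `trim3` columns.
#' @export
soft_trim_ligation <- function(tagged, n = 2) {
  tagged$trim5 <- as.integer(n)
  tagged$trim3 <- as.integer(n)
  tagged
}

#' Prepare raw read pairs end to end
#'
#' Convenience chain: [merge_pairs()] then [extract_tags()],
#' [assign_orientation()] and [soft_trim_ligation()]. Every input pair ends
#' in exactly one of `merged`, `unmerged` or `rejected` (with a reason).
#'
#' @inheritParams merge_pairs
#' @inheritParams extract_tags
#' @param soft_trim Bases masked at each ligation site.
#' @return The annotated read tibble.
#' @export
prep_reads <- function(pairs, adapter = adapter_spec(), min_overlap = 30,
                       max_mismatch_frac = 0.1, soft_trim = 2) {
  pairs |>
    merge_pairs(min_overlap = min_overlap,
                max_mismatch_frac = max_mismatch_frac) |>
    extract_tags(adapter) |>
    assign_orientation(adapter) |>
    soft_trim_ligation(soft_trim)
}
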