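# --- duplex keys ------------------------------------------------------------

# Ligation-proximal barcode positions of one SSCS, concatenated. For the
# 12-nt design these are the terminal six positions of each canonical
# barcode (6 + 6 = 12 semi-degenerate sites); the 5-nt design uses the full
# barcodes (2 x 5 = 10 positions).
duplex_key_positions <- function(barcode_length) {
  if (barcode_length >= 12) (barcode_length - 5L):barcode_length
  else seq_len(barcode_length)
}

sscs_key <- function(uid_5p, uid_3p, barcode_length) {
  pos <- duplex_key_positions(barcode_length)
  paste0(substr(uid_5p, pos[1], barcode_length),
         substr(uid_3p, pos[1], barcode_length))
}

# A minus-strand SSCS reads the two adapters in swapped order, so its
# barcodes are compared against the plus SSCS cross-wise (plus 5' vs minus
# 3', plus 3' vs minus 5').
minus_key <- function(uid_5p, uid_3p, barcode_length) {
  sscs_key(uid_3p, uid_5p, barcode_length)
}

#' Match opposite-strand consensus sequences into duplexes
#'
#' Within each (locus, fragment start, fragment end) bucket, plus- and
#' minus-orientation SSCS are paired greedily by Hamming distance over the
#' ligation-proximal barcode key (smallest key distance first; key ties are
#' resolved by the full combined-UID distance; exact ties on both leave the
#' records unpaired). Pairs farther than `max_key_mismatches` are not
#' duplexes; accepted-key pairs whose full-UID distance exceeds
#' `spurious_threshold` are flagged as spurious coordinate collisions
#' (random UID pairs sit near half the UID length) and left unpaired.
#'
#' @param sscs SSCS tibble from [build_sscs()].
#' @param adapter An [adapter_spec()].
#' @param max_key_mismatches Maximum mismatches across the key positions.
#' @param spurious_threshold Maximum full-UID mismatches for a credible
#'   duplex.
#' @return List of class `duplex_match`: `duplexes` (tibble with
#'   `duplex_id`, `sscs_plus`, `sscs_minus`, coordinates, `key_mismatches`,
#'   `full_uid_mismatches`, list-column `mispair_positions` over the
#'   combined canonical barcode), `unpaired_plus`, `unpaired_minus` (SSCS
#'   tibbles), `spurious` (rejected candidate pairs), `clashes` (SSCS ids
#'   dropped on unresolvable ties).
#' @export
match_duplexes <- function(sscs, adapter = adapter_spec(),
                           max_key_mismatches = 2, spurious_threshold = 5) {
  bl <- adapter$barcode_length
  plus <- sscs[sscs$orientation == "plus", ]
  minus <- sscs[sscs$orientation == "minus", ]
  pairs <- list(); spurious <- list(); clash_ids <- character(0)
  used_plus <- character(0); used_minus <- character(0)

  buckets <- unique(rbind(
    plus[, c("locus", "fragment_start", "fragment_end")],
    minus[, c("locus", "fragment_start", "fragment_end")]
  ))
  for (b in seq_len(nrow(buckets))) {
    p <- plus[plus$locus == buckets$locus[b] &
                plus$fragment_start == buckets$fragment_start[b] &
                plus$fragment_end == buckets$fragment_end[b], ]
    m <- minus[minus$locus == buckets$locus[b] &
                 minus$fragment_start == buckets$fragment_start[b] &
                 minus$fragment_end == buckets$fragment_end[b], ]
    if (nrow(p) == 0 || nrow(m) == 0) next

    pk <- sscs_key(p$uid_5p, p$uid_3p, bl)
    mk <- minus_key(m$uid_5p, m$uid_3p, bl)
    cand <- tidyr::expand_grid(i = seq_len(nrow(p)), j = seq_len(nrow(m)))
    cand$key_mm <- hamming(pk[cand$i], mk[cand$j])
    cand$full_mm <- hamming(paste0(p$uid_5p, p$uid_3p)[cand$i],
                            paste0(m$uid_3p, m$uid_5p)[cand$j])
    cand <- cand[cand$key_mm <= max_key_mismatches, ]
    cand <- cand[order(cand$key_mm, cand$full_mm, p$sscs_id[cand$i],
                       m$sscs_id[cand$j]), ]

    avail_p <- rep(TRUE, nrow(p)); avail_m <- rep(TRUE, nrow(m))
    k <- 1
    while (k <= nrow(cand)) {
      # candidates tied on (key_mm, full_mm) are handled as one group
      grp <- which(cand$key_mm == cand$key_mm[k] &
                     cand$full_mm == cand$full_mm[k])
      grp <- grp[grp >= k]
      live <- grp[avail_p[cand$i[grp]] & avail_m[cand$j[grp]]]
      if (length(live) > 0) {
        dup_i <- cand$i[live][duplicated(cand$i[live]) |
                               duplicated(cand$i[live], fromLast = TRUE)]
        dup_j <- cand$j[live][duplicated(cand$j[live]) |
                               duplicated(cand$j[live], fromLast = TRUE)]
        for (g in live) {
          ii <- cand$i[g]; jj <- cand$j[g]
          if (!avail_p[ii] || !avail_m[jj]) next
          if (ii %in% dup_i || jj %in% dup_j) {
            # unresolvable tie: conservative no-match
            clash_ids <- c(clash_ids, p$sscs_id[ii], m$sscs_id[jj])
            avail_p[ii] <- FALSE; avail_m[jj] <- FALSE
            next
          }
          if (cand$full_mm[g] > spurious_threshold) {
            spurious[[length(spurious) + 1]] <- tibble(
              sscs_plus = p$sscs_id[ii], sscs_minus = m$sscs_id[jj],
              locus = p$locus[ii], fragment_start = p$fragment_start[ii],
              fragment_end = p$fragment_end[ii],
              key_mismatches = cand$key_mm[g],
              full_uid_mismatches = cand$full_mm[g]
            )
            next
          }
          mispos <- which(
            split1(paste0(p$uid_5p[ii], p$uid_3p[ii])) !=
              split1(paste0(m$uid_3p[jj], m$uid_5p[jj]))
          )
          pairs[[length(pairs) + 1]] <- tibble(
            sscs_plus = p$sscs_id[ii], sscs_minus = m$sscs_id[jj],
            locus = p$locus[ii], fragment_start = p$fragment_start[ii],
            fragment_end = p$fragment_end[ii],
            key_mismatches = cand$key_mm[g],
            full_uid_mismatches = cand$full_mm[g],
            mispair_positions = list(mispos)
          )
          avail_p[ii] <- FALSE; avail_m[jj] <- FALSE
          used_plus <- c(used_plus, p$sscs_id[ii])
          used_minus <- c(used_minus, m$sscs_id[jj])
        }
      }
      k <- max(grp) + 1
    }
  }

  duplexes <- dplyr::bind_rows(pairs)
  if (nrow(duplexes) > 0) {
    duplexes <- duplexes[order(duplexes$locus, duplexes$fragment_start,
                               duplexes$fragment_end, duplexes$sscs_plus), ]
    duplexes$duplex_id <- sprintf("D%05d", seq_len(nrow(duplexes)))
    duplexes <- dplyr::relocate(duplexes, "duplex_id")
  }
  structure(
    list(
      duplexes = duplexes,
      unpaired_plus = plus[!plus$sscs_id %in% used_plus, ],
      unpaired_minus = minus[!minus$sscs_id %in% used_minus, ],
      spurious = dplyr::bind_rows(spurious),
      clashes = unique(clash_ids)
    ),
    class = "duplex_match"
  )
}

#' @export
print.duplex_match <- function(x, ...) {
  cat("<duplex_match>", nrow(x$duplexes), "duplexes;",
      nrow(x$unpaired_plus), "unpaired plus,",
      nrow(x$unpaired_minus), "unpaired minus;",
      nrow(x$spurious), "spurious pair(s) rejected\n")
  invisible(x)
}

#' Build duplex consensus sequences
#'
#' Positions where the two strand consensuses agree keep the base; any
#' disagreement (including a one-strand ambiguity) becomes `N`, which is
#' excluded from error counting and variant support. Positions covered by
#' only one strand (unmerged gaps) take that strand's base.
#'
#' @param matched A `duplex_match` from [match_duplexes()].
#' @param sscs The SSCS tibble the match was built from.
#' @return The duplex tibble with added `seq`, `n_disagreements`, `trim5`,
#'   `trim3`, `n_reads_plus`, `n_reads_minus` columns.
#' @export
build_duplex_consensus <- function(matched, sscs) {
  dup <- matched$duplexes
  if (nrow(dup) == 0) {
    dup$seq <- character(0); dup$n_disagreements <- integer(0)
    return(dup)
  }
  sp <- sscs[match(dup$sscs_plus, sscs$sscs_id), ]
  sm <- sscs[match(dup$sscs_minus, sscs$sscs_id), ]
  cons <- character(nrow(dup)); ndis <- integer(nrow(dup))
  for (i in seq_len(nrow(dup))) {
    a <- split1(sp$seq[i]); b <- split1(sm$seq[i])
    out <- ifelse(a == b, a,
                  ifelse(a == "-", b, ifelse(b == "-", a, "N")))
    ndis[i] <- sum(a != b & a != "-" & b != "-")
    cons[i] <- paste(out, collapse = "")
  }
  dup$seq <- cons
  dup$n_disagreements <- ndis
  dup$trim5 <- pmax(sp$trim5, sm$trim5)
  dup$trim3 <- pmax(sp$trim3, sm$trim3)
  dup$n_reads_plus <- sp$n_reads
  dup$n_reads_minus <- sm$n_reads
  dup
}

#' Duplex recovery statistics
#'
#' Accounting used to estimate how many of the unique molecules are
#' represented by both parental strands: with `n_fwd` plus-strand and
#' `n_rev` minus-strand consensus sequences of which `d` assemble into
#' duplexes, the unique molecules are `(n_fwd - d) + (n_rev - d) + d` and
#' the recovery rate is `d` over that total (e.g. 1,000 + 1,000 with 600
#' duplexes gives 1,400 unique molecules and rate 600/1400 = 0.4286).
#'
#' @param n_fwd,n_rev Counts of single-strand consensus sequences per
#'   orientation.
#' @param d Number of assembled duplexes; must not exceed `min(n_fwd,
#'   n_rev)`.
#' @return One-row tibble: `n_fwd`, `n_rev`, `d`, `unique_molecules`,
#'   `recovery_rate`.
#' @export
duplex_recovery <- function(n_fwd, n_rev, d) {
  if (any(c(n_fwd, n_rev, d) < 0)) abort("counts must be non-negative")
  if (d > min(n_fwd, n_rev)) {
    abort("d cannot exceed min(n_fwd, n_rev)")
  }
  unique_molecules <- (n_fwd - d) + (n_rev - d) + d
  tibble(
    n_fwd = n_fwd, n_rev = n_rev, d = d,
    unique_molecules = unique_molecules,
    recovery_rate = if (unique_molecules == 0) NA_real_ else d / unique_molecules
  )
}

#' Annealing-mispairing profile of accepted duplexes
#'
#' A mispairing is any position where the canonicalized plus and minus
#' barcodes of an accepted duplex disagree. Frequencies are reported per
#' combined canonical barcode position (1..2L; positions L-5..L and
#' 2L-5..2L are the ligation-proximal key sites) together with histograms
#' of mispair counts per duplex over the full barcode and over the key
#' positions.
#'
#' @param duplexes Duplex tibble from [match_duplexes()] /
#'   [build_duplex_consensus()].
#' @param adapter An [adapter_spec()].
#' @return List of class `mispair_profile`: `per_position` (tibble
#'   `position`, `n_mispaired`, `frequency`, `terminal`), `histogram_full`,
#'   `histogram_terminal` (tibbles `n_mispairings`, `n_duplexes`,
#'   `fraction`), `n_duplexes`.
#' @export
mispairing_profile <- function(duplexes, adapter = adapter_spec()) {
  bl <- adapter$barcode_length
  n <- nrow(duplexes)
  key_pos <- c(duplex_key_positions(bl), bl + duplex_key_positions(bl))
  counts <- integer(2 * bl)
  per_dup_full <- integer(n)
  per_dup_term <- integer(n)
  for (i in seq_len(n)) {
    pos <- duplexes$mispair_positions[[i]]
    counts[pos] <- counts[pos] + 1L
    per_dup_full[i] <- length(pos)
    per_dup_term[i] <- sum(pos %in% key_pos)
  }
  hist_of <- function(x) {
    tb <- tibble(n_mispairings = x) |>
      dplyr::count(.data$n_mispairings, name = "n_duplexes")
    tb$fraction <- tb$n_duplexes / max(1L, n)
    tb
  }
  structure(
    list(
      per_position = tibble(
        position = seq_len(2 * bl),
        n_mispaired = counts,
        frequency = if (n > 0) counts / n else rep(NA_real_, 2 * bl),
        terminal = seq_len(2 * bl) %in% key_pos
      ),
      histogram_full = hist_of(per_dup_full),
      histogram_terminal = hist_of(per_dup_term),
      n_duplexes = n
    ),
    class = "mispair_profile"
  )
}

#' @export
print.mispair_profile <- function(x, ...) {
  cat("<mispair_profile> over", x$n_duplexes, "duplexes\n")
  print(x$histogram_full)
  invisible(x)
}
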