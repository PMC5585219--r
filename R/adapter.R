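#' @importFrom rlang .data `%||%` abort
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# IUPAC codes used in semi-degenerate barcode patterns. Only the two-letter
# degeneracies (W,S,M,R,Y,K), N, and the four concrete bases are meaningful
# for these adapters.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"),
  M = c("A", "C"), R = c("A", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  N = c("A", "C", "G", "T")
)

# Symbol-wise IUPAC complement (A<->T, C<->G, M<->K, R<->Y; W, S, N are
# self-complementary).
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  W = "W", S = "S", M = "K", K = "M", R = "Y", Y = "R", N = "N"
)

iupac_sets <- function(pattern) {
  syms <- strsplit(pattern, "")[[1]]
  bad <- which(!syms %in% names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid IUPAC symbol '%s' at position %d of pattern '%s'",
      syms[bad[1]], bad[1], pattern
    ))
  }
  IUPAC_SETS[syms]
}

#' Size of the sequence space of an IUPAC pattern
#'
#' The number of concrete A/C/G/T sequences consistent with a pattern is the
#' product of the per-position subset sizes; for a fully two-fold degenerate
#' pattern of length L (e.g. `WSMRWSYWKMWW`) this is `2^L`.
#'
#' @param pattern A single IUPAC pattern string over `A,C,G,T,W,S,M,R,Y,K,N`.
#' @return A numeric scalar (can exceed integer range for long patterns).
#' @examples
#' pattern_space_size("WSMRWSYWKMWW") # 4096
#' pattern_space_size("WSWSW")        # 32
#' @export
pattern_space_size <- function(pattern) {
  prod(lengths(iupac_sets(pattern)))
}

#' Enumerate every sequence consistent with an IUPAC pattern
#'
#' @inheritParams pattern_space_size
#' @param max_size Guard against accidental enumeration of huge spaces.
#' @return Character vector containing each consistent sequence exactly once.
#' @examples
#' length(enumerate_pattern("WSWSW")) # 32
#' enumerate_pattern("ACGT")
#' @export
enumerate_pattern <- function(pattern, max_size = 2^20) {
  sets <- iupac_sets(pattern)
  n <- prod(lengths(sets))
  if (n > max_size) {
    abort(sprintf(
      "pattern space of '%s' has %.0f sequences (> max_size = %.0f); use pattern_space_size() for counting",
      pattern, n, max_size
    ))
  }
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Test sequences against an IUPAC pattern
#'
#' A sequence matches when every base lies in the subset allowed at its
#' position. Ambiguity codes in the sequence itself never match (a consensus
#' `N` is not a concrete base). Length mismatch is an error, distinct from a
#' `FALSE` result.
#'
#' @param seq Character vector of sequences, each the same length as `pattern`.
#' @inheritParams pattern_space_size
#' @return Logical vector, one element per sequence.
#' @export
matches_pattern <- function(seq, pattern) {
  sets <- iupac_sets(pattern)
  L <- length(sets)
  if (any(nchar(seq) != L)) {
    abort(sprintf("sequence length must equal pattern length (%d)", L))
  }
  if (length(seq) == 0) return(logical(0))
  mat <- matrix(unlist(strsplit(seq, "")), ncol = L, byrow = TRUE)
  ok <- rep(TRUE, length(seq))
  for (j in seq_len(L)) {
    ok <- ok & mat[, j] %in% sets[[j]]
  }
  ok
}

#' Reverse complement of an IUPAC pattern
#'
#' Applies the symbol-wise IUPAC complement and reverses the order, so the
#' minus-oligo barcode pattern of a published design maps onto the plus
#' pattern (`revcomp_pattern("WWKMWRSWYKSW")` is `"WSMRWSYWKMWW"`).
#'
#' @inheritParams pattern_space_size
#' @return A single pattern string.
#' @export
revcomp_pattern <- function(pattern) {
  syms <- strsplit(pattern, "")[[1]]
  bad <- which(!syms %in% names(IUPAC_COMPLEMENT))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid IUPAC symbol '%s' at position %d", syms[bad[1]], bad[1]
    ))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[syms])), collapse = "")
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Character vectors, recycled to common length; paired elements
#'   must have equal nchar.
#' @return Integer vector of per-pair mismatch counts.
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    abort("hamming() requires equal-length strings")
  }
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# Fast reverse complement for plain A/C/G/T(/N/-) character vectors;
# avoids XStringSet construction overhead on millions of short strings.
revcomp <- function(x) {
  x <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Sample concrete barcodes from an IUPAC pattern
#'
#' Draws bases independently at each position, uniformly over the allowed
#' subset by default. Per-position weights can emulate the skewed base ratios
#' seen with machine-mixed oligo synthesis.
#'
#' @param n Number of barcodes.
#' @inheritParams pattern_space_size
#' @param weights Optional list (length = pattern length) of per-position
#'   probability vectors over the allowed bases; `NULL` means uniform.
#' @return Character vector of `n` barcodes conforming to `pattern`.
#' @export
sample_barcodes <- function(n, pattern, weights = NULL) {
  sets <- iupac_sets(pattern)
  L <- length(sets)
  cols <- vector("list", L)
  for (j in seq_len(L)) {
    w <- if (is.null(weights)) NULL else weights[[j]]
    cols[[j]] <- sample(sets[[j]], n, replace = TRUE, prob = w)
  }
  do.call(paste0, cols)
}

#' Adapter specification for a barcoded design
#'
#' Bundles the semi-degenerate barcode patterns of the two adapter oligos,
#' the strand-tag table and layout, for either the 12-nt design (variable
#' tri-nucleotide tag placed before the barcode) or the legacy 5-nt design
#' (fixed complementary `GAC`/`GTC` tag placed after the barcode).
#'
#' @param design `"v2_12nt"` (default) or `"v1_5nt"`.
#' @param tag_table Tibble with columns `plus_tag`, `minus_tag` giving the
#'   permitted strand-tag combinations; defaults to [default_tag_table()] for
#'   the 12-nt design and the fixed `GAC`/`GAC` (canonical) pair for v1.
#' @return An object of class `adapter_spec`.
#' @examples
#' adapter_spec()
#' @export
adapter_spec <- function(design = c("v2_12nt", "v1_5nt"), tag_table = NULL) {
  design <- match.arg(design)
  plus_pattern <- switch(design, v2_12nt = "WSMRWSYWKMWW", v1_5nt = "WSWSW")
  minus_pattern <- revcomp_pattern(plus_pattern)
  if (is.null(tag_table)) {
    tag_table <- switch(design,
      v2_12nt = default_tag_table(),
      # v1 tags are fixed and complementary (GAC on the plus oligo, GTC on
      # the minus oligo, i.e. GAC after canonical reverse complementation),
      # so they cannot discriminate strands on their own.
      v1_5nt = tibble(plus_tag = "GAC", minus_tag = "GAC")
    )
  }
  stopifnot(all(c("plus_tag", "minus_tag") %in% names(tag_table)))
  spec <- list(
    design_version = design,
    plus_pattern = plus_pattern,
    minus_pattern = minus_pattern,
    barcode_length = nchar(plus_pattern),
    tag_length = 3L,
    tag_table = as_tibble(tag_table),
    tag_position = switch(design, v2_12nt = "before_barcode", v1_5nt = "after_barcode"),
    overhang_base = "T"
  )
  class(spec) <- "adapter_spec"
  spec
}

#' @export
print.adapter_spec <- function(x, ...) {
  cat("<adapter_spec> design", x$design_version, "\n")
  cat("  plus pattern :", x$plus_pattern, "\n")
  cat("  minus pattern:", x$minus_pattern, "\n")
  cat("  tag position :", x$tag_position, "; ", nrow(x$tag_table),
      "permitted tag pair(s)\n")
  invisible(x)
}

#' Default strand-tag table for the 12-nt design
#'
#' Six plus-oligo tags crossed with four minus-oligo tags give 24
#' combinations, of which 19 are usable, unique and non-complementary.
#' Minus tags are stored in canonical orientation (as observed after
#' reverse-complementing the 3' end of a merged plus-strand read), so a
#' combination is dropped when (i) the canonical minus tag equals the plus
#' tag (the two oligos would be complementary across the tag, defeating the
#' deliberate tag mispairing that enforces faithful barcode annealing),
#' (ii) the swapped reading of the pair is itself a permitted pair (the
#' minus strand of one molecule would be indistinguishable from the plus
#' strand of another), or (iii) the two oligos carry the same raw tag
#' sequence. The published tag combinations are not public; this table is
#' the package's own reconstruction with the same counts and constraints.
#'
#' @return Tibble with columns `plus_tag`, `minus_tag` (19 rows; canonical
#'   orientation for both).
#' @export
default_tag_table <- function() {
  plus <- c("ACT", "AGG", "CAT", "GTA", "TCC", "TGA")
  minus_canonical <- c("ACT", "CAT", "GGA", "CTC")
  grid <- tidyr::expand_grid(plus_tag = plus, minus_tag = minus_canonical)
  # (i) complementary across the annealed tag region
  grid <- grid[grid$plus_tag != grid$minus_tag, , drop = FALSE]
  # (ii) swapped reading collides with another permitted pair
  ambiguous <- grid$plus_tag %in% minus_canonical & grid$minus_tag %in% plus
  grid <- grid[!ambiguous, , drop = FALSE]
  # (iii) identical raw oligo tags (plus tag equals the raw minus tag)
  grid <- grid[grid$plus_tag != revcomp(grid$minus_tag), , drop = FALSE]
  as_tibble(grid)
}

#' Diversity statistics over a set of UIDs
#'
#' Summarises a collection of molecular identifiers: uniqueness (computed on
#' the multiset, before deduplication) and the distribution of pairwise
#' Hamming distances. For large sets the mean distance is computed exactly
#' from per-position base counts, and the distance standard deviation from a
#' random subset of pairs.
#'
#' @param uids Character vector of equal-length UID strings (at least 2).
#' @param max_exact_n Up to this many UIDs the full pairwise distance set is
#'   used for the SD; beyond it, `n_pairs_sample` random pairs.
#' @param n_pairs_sample Number of random pairs for the sampled SD.
#' @return One-row tibble: `n_uids`, `n_unique`, `frac_unique`,
#'   `max_multiplicity`, `mean_pairwise_distance`, `sd_pairwise_distance`,
#'   `n_pairs` (pairs behind the SD estimate).
#' @export
uid_diversity_stats <- function(uids, max_exact_n = 4000,
                                n_pairs_sample = 200000) {
  n <- length(uids)
  if (n < 2) abort("uid_diversity_stats() needs at least 2 UIDs")
  L <- unique(nchar(uids))
  if (length(L) != 1) abort("UIDs must all have the same length")
  counts <- table(uids)
  mat <- matrix(unlist(strsplit(uids, "")), ncol = L, byrow = TRUE)

  # Exact mean pairwise distance: at each position the number of differing
  # unordered pairs is (n^2 - sum over bases of count^2) / 2.
  n_pairs_total <- n * (n - 1) / 2
  diff_pairs <- 0
  for (j in seq_len(L)) {
    tab <- tabulate(factor(mat[, j], levels = c("A", "C", "G", "T", "N")))
    diff_pairs <- diff_pairs + (n^2 - sum(tab^2)) / 2
  }
  mean_d <- diff_pairs / n_pairs_total

  if (n <= max_exact_n) {
    idx <- utils::combn(n, 2)
    d <- integer(ncol(idx))
    for (j in seq_len(L)) {
      d <- d + (mat[idx[1, ], j] != mat[idx[2, ], j])
    }
    n_pairs_used <- length(d)
  } else {
    i <- sample.int(n, n_pairs_sample, replace = TRUE)
    k <- sample.int(n, n_pairs_sample, replace = TRUE)
    keep <- i != k
    i <- i[keep]; k <- k[keep]
    d <- integer(length(i))
    for (j in seq_len(L)) {
      d <- d + (mat[i, j] != mat[k, j])
    }
    n_pairs_used <- length(d)
  }

  tibble(
    n_uids = n,
    n_unique = length(counts),
    frac_unique = sum(counts == 1) / n,
    max_multiplicity = max(counts),
    mean_pairwise_distance = mean_d,
    sd_pairwise_distance = stats::sd(d),
    n_pairs = n_pairs_used
  )
}
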