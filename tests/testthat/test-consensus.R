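test_that("error-free reads align back to their true fragment coordinates", {
  sim <- clean_sim()
  cfg <- clean_config()
  aligned <- align_reads(prep_reads(sim$reads), cfg$reference)
  expect_true(all(aligned$status != "rejected"))
  joined <- dplyr::left_join(
    dplyr::select(aligned, "read_id", "molecule_id", "fragment_start",
                  "fragment_end", "map_strand", "orientation"),
    dplyr::select(sim$truth, "molecule_id",
                  true_start = "fragment_start", true_end = "fragment_end"),
    by = "molecule_id"
  )
  expect_equal(joined$fragment_start, joined$true_start)
  expect_equal(joined$fragment_end, joined$true_end)
  # the reverse-strand mate of each molecule maps to the same interval with
  # the opposite mapping strand, while tag orientation is unchanged
  expect_equal(joined$map_strand == "-", joined$orientation == "minus")
})

test_that("random sequence is rejected as off-target", {
  set.seed(31)
  ref <- tiny_reference()
  rand <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  probe <- tibble::tibble(
    read_id = "r", status = "merged", reject_reason = NA_character_,
    insert_seq = rand, insert_right = NA_character_
  )
  out <- align_reads(probe, ref)
  expect_equal(out$status, "rejected")
  expect_equal(out$reject_reason, "off_target")
  expect_error(align_reads(probe, character(0)), "empty reference")
})

test_that("family grouping merges near-identical UIDs and splits distant ones", {
  uid <- strrep("A", 24)
  # identical UIDs, one bucket -> one family of five
  g <- group_families(make_aligned_bucket(rep(uid, 5)))
  expect_equal(dplyr::n_distinct(g$family_id), 1)
  expect_equal(summarize_families(g)$size, 5)

  # two UID groups at Hamming distance 11 -> two families
  far <- paste0(strrep("A", 13), strrep("C", 11))
  g2 <- group_families(make_aligned_bucket(c(rep(uid, 3), rep(far, 3))))
  expect_equal(dplyr::n_distinct(g2$family_id), 2)

  # distance 1 (barcode PCR/sequencing error) -> one family
  near <- paste0("C", strrep("A", 23))
  g3 <- group_families(make_aligned_bucket(c(rep(uid, 3), near)))
  expect_equal(dplyr::n_distinct(g3$family_id), 1)
})

test_that("grouping matches brute-force single linkage on random instances", {
  set.seed(77)
  for (trial in 1:30) {
    uids <- random_uid_instance(n_max = 20)
    bucket <- make_aligned_bucket(uids)
    g <- group_families(bucket)
    thr <- max(1, floor(0.01 * (168 + 32)))
    oracle <- bf_single_linkage(uids, thr)
    expect_true(same_partition(as.integer(factor(g$family_id)), oracle))
  }
})

test_that("grouping is idempotent and partitions all usable reads", {
  sim <- default_sim()
  aligned <- align_reads(prep_reads(sim$reads), tiny_reference())
  g1 <- group_families(aligned)
  g2 <- group_families(aligned)
  expect_identical(g1$family_id, g2$family_id)
  usable <- g1$status %in% c("merged", "unmerged")
  expect_true(all(!is.na(g1$family_id[usable])))
  expect_true(all(is.na(g1$family_id[!usable])))
})

test_that("consensus takes the plurality base and flags exact ties", {
  base_reads <- function(seqs) {
    n <- length(seqs)
    tibble::tibble(
      read_id = sprintf("r%d", seq_len(n)), status = "merged",
      uid_5p = strrep("A", 12), uid_3p = strrep("A", 12),
      uid = strrep("A", 24), orientation = "plus", locus = "locus01",
      fragment_start = 0L, fragment_end = nchar(seqs[1]),
      seq = seqs, reject_reason = NA_character_, trim5 = 2L, trim3 = 2L,
      family_id = "F00001"
    )
  }
  s <- build_sscs(base_reads(rep("ACGTACGT", 3)))
  expect_equal(s$seq, "ACGTACGT")
  expect_equal(s$n_ambiguous, 0)

  mut <- c("ACGTACGT", "ACGTACGT", "ACCTACGT")
  expect_equal(build_sscs(base_reads(mut))$seq, "ACGTACGT")

  tie <- c("ACGTACGT", "ACGTACGT", "ACCTACGT", "ACCTACGT")
  s_tie <- build_sscs(base_reads(tie))
  expect_equal(substr(s_tie$seq, 3, 3), "N")
  expect_equal(s_tie$n_ambiguous, 1)

  # below the minimum number of independent reads: no consensus
  expect_equal(nrow(build_sscs(base_reads(rep("ACGTACGT", 2)))), 0)
  expect_equal(nrow(build_sscs(base_reads(rep("ACGTACGT", 2)),
                               min_reads = 2)), 1)

  # uncovered (gap) columns are excluded, not ambiguous
  gap <- c("AC-TACGT", "AC-TACGT", "AC-TACGT")
  s_gap <- build_sscs(base_reads(gap))
  expect_equal(substr(s_gap$seq, 3, 3), "-")
  expect_equal(s_gap$n_ambiguous, 0)
})

test_that("family-size statistics find the read-weighted peak", {
  sizes <- c(rep(1, 10), rep(3, 5), rep(6, 4))
  uids <- sample_barcodes(length(sizes), strrep("W", 24))
  rows <- purrr::map2(seq_along(sizes), sizes, function(i, s) {
    b <- make_aligned_bucket(rep(uids[i], s))
    b$fragment_start <- b$fragment_start + 10L * i   # distinct coordinates
    b$fragment_end <- b$fragment_end + 10L * i
    b$read_id <- sprintf("f%02d_%s", i, b$read_id)
    b
  })
  g <- group_families(dplyr::bind_rows(rows))
  st <- family_size_stats(g)
  expect_equal(st$histogram$n_reads[st$histogram$size == 1], 10)
  expect_equal(st$histogram$n_reads[st$histogram$size == 3], 15)
  expect_equal(st$histogram$n_reads[st$histogram$size == 6], 24)
  expect_equal(st$peak_family_size, 6)
  expect_equal(st$unique_coord_fraction$frac_unique_coords, 1)

  singletons <- group_families(dplyr::bind_rows(purrr::map(1:5, function(i) {
    b <- make_aligned_bucket(uids[i])
    b$fragment_start <- b$fragment_start + 10L * i
    b$fragment_end <- b$fragment_end + 10L * i
    b$read_id <- paste0("s", i)
    b
  })))
  expect_true(is.na(family_size_stats(singletons)$peak_family_size))
})

test_that("zero-error consensus reproduces the true fragments", {
  run <- clean_run()
  sim <- clean_sim()
  cfg <- clean_config()

  # one family per simulated strand with at least one read
  truth <- sim$truth
  n_strands <- sum(truth$family_size_plus > 0) +
    sum(truth$family_size_minus > 0)
  fams <- summarize_families(run$reads)
  expect_equal(nrow(fams), n_strands)

  # SSCS sequences equal the true (possibly variant-carrying) fragment
  reads_by_fam <- run$reads[!is.na(run$reads$family_id), ]
  fam_mol <- tapply(reads_by_fam$molecule_id, reads_by_fam$family_id,
                    function(x) unique(x))
  expect_true(all(lengths(fam_mol) == 1))
  sscs <- run$sscs
  mol <- truth[match(unlist(fam_mol[sscs$family_id]), truth$molecule_id), ]
  true_frag <- substr(cfg$reference[mol$locus], mol$fragment_start + 1,
                      mol$fragment_end)
  off <- mol$site_position - mol$fragment_start + 1
  substr(true_frag, off, off) <- ifelse(mol$carries_alt, mol$alt,
                                        substr(true_frag, off, off))
  expect_equal(sscs$seq, unname(true_frag))
})
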