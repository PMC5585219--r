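# a duplex partner of plus SSCS (u5, u3) reads the two adapters in swapped
# order: (u3, u5) when annealing was perfectly faithful
partner_of <- function(p, id = "Sm") {
  make_sscs(p$uid_3p, p$uid_5p, "minus", id)
}

mutate_at_pos <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "T"), b)[1],
                    character(1))
  paste(ch, collapse = "")
}

test_that("duplex matching respects the terminal-key mismatch threshold", {
  set.seed(55)
  u5 <- sample_barcodes(1, "WSMRWSYWKMWW")
  u3 <- sample_barcodes(1, "WSMRWSYWKMWW")
  p <- make_sscs(u5, u3, "plus", "Sp")

  perfect <- match_duplexes(dplyr::bind_rows(p, partner_of(p)))
  expect_equal(nrow(perfect$duplexes), 1)
  expect_equal(perfect$duplexes$key_mismatches, 0)
  expect_equal(perfect$duplexes$full_uid_mismatches, 0)

  # mismatches inside the terminal six of each barcode hit the key
  two <- partner_of(p)
  two$uid_3p <- mutate_at_pos(two$uid_3p, c(8, 11))
  two$uid <- paste0(two$uid_5p, two$uid_3p)
  m2 <- match_duplexes(dplyr::bind_rows(p, two))
  expect_equal(nrow(m2$duplexes), 1)
  expect_equal(m2$duplexes$key_mismatches, 2)

  three <- partner_of(p)
  three$uid_3p <- mutate_at_pos(three$uid_3p, c(8, 11, 12))
  m3 <- match_duplexes(dplyr::bind_rows(p, three))
  expect_equal(nrow(m3$duplexes), 0)
  expect_equal(nrow(m3$unpaired_plus), 1)
  expect_equal(nrow(m3$unpaired_minus), 1)
})

test_that("coordinate collisions between unrelated molecules are spurious", {
  set.seed(56)
  # random UIDs that happen to agree at the key positions but nowhere else
  p <- make_sscs(sample_barcodes(1, "WSMRWSYWKMWW"),
                 sample_barcodes(1, "WSMRWSYWKMWW"), "plus", "Sp")
  q <- partner_of(p, "Sm")
  # scramble the non-key positions (1..6 of each barcode) completely
  flip_head <- function(s) mutate_at_pos(s, 1:6)
  q$uid_5p <- flip_head(q$uid_5p); q$uid_3p <- flip_head(q$uid_3p)
  q$uid <- paste0(q$uid_5p, q$uid_3p)
  m <- match_duplexes(dplyr::bind_rows(p, q), spurious_threshold = 5)
  expect_equal(nrow(m$duplexes), 0)
  expect_equal(nrow(m$spurious), 1)
  expect_equal(m$spurious$full_uid_mismatches, 12)

  # fully random opposite-strand pairs at shared coordinates sit near half
  # the combined UID length apart
  dists <- replicate(300, {
    a <- sample_barcodes(2, "WSMRWSYWKMWW")
    b <- sample_barcodes(2, "WSMRWSYWKMWW")
    hamming(paste0(a[1], a[2]), paste0(b[1], b[2]))
  })
  expect_gt(mean(dists), 11)
  expect_lt(mean(dists), 13)
})

test_that("key clashes resolve by full-UID distance, exact ties abstain", {
  set.seed(57)
  u5 <- sample_barcodes(1, "WSMRWSYWKMWW")
  u3 <- sample_barcodes(1, "WSMRWSYWKMWW")
  p <- make_sscs(u5, u3, "plus", "Sp")

  # candidate at key distance 1 beats candidate at key distance 2
  m1 <- partner_of(p, "Sm1"); m2 <- partner_of(p, "Sm2")
  m1$uid_3p <- mutate_at_pos(m1$uid_3p, 12)
  m2$uid_3p <- mutate_at_pos(m2$uid_3p, c(11, 12))
  res <- match_duplexes(dplyr::bind_rows(p, m1, m2))
  expect_equal(nrow(res$duplexes), 1)
  expect_equal(res$duplexes$sscs_minus, "Sm1")

  # key tie: smaller full-UID distance wins
  m3 <- partner_of(p, "Sm3"); m4 <- partner_of(p, "Sm4")
  m3$uid_3p <- mutate_at_pos(m3$uid_3p, 12)
  m3$uid_5p <- mutate_at_pos(m3$uid_5p, 1:2)        # full distance 3
  m4$uid_3p <- mutate_at_pos(mutate_at_pos(m4$uid_3p, 12), 1:5)
  m4$uid_5p <- mutate_at_pos(m4$uid_5p, 1:6)        # full distance 12
  res2 <- match_duplexes(dplyr::bind_rows(p, m3, m4),
                         spurious_threshold = 24)
  expect_equal(res2$duplexes$sscs_minus, "Sm3")

  # identical candidates on both criteria: conservative no-match
  m5 <- partner_of(p, "Sm5"); m6 <- partner_of(p, "Sm6")
  res3 <- match_duplexes(dplyr::bind_rows(p, m5, m6))
  expect_equal(nrow(res3$duplexes), 0)
  expect_true("Sp" %in% res3$clashes)
})

test_that("matching is exclusive and order-insensitive", {
  set.seed(58)
  n <- 12
  p_list <- lapply(seq_len(n), function(i) {
    make_sscs(sample_barcodes(1, "WSMRWSYWKMWW"),
              sample_barcodes(1, "WSMRWSYWKMWW"), "plus",
              sprintf("Sp%02d", i))
  })
  m_list <- lapply(seq_len(n), function(i) partner_of(p_list[[i]],
                                                      sprintf("Sm%02d", i)))
  all1 <- dplyr::bind_rows(c(p_list, m_list))
  all2 <- dplyr::bind_rows(c(rev(m_list), rev(p_list)))
  r1 <- match_duplexes(all1)
  r2 <- match_duplexes(all2)
  expect_equal(nrow(r1$duplexes), n)
  ids <- c(r1$duplexes$sscs_plus, r1$duplexes$sscs_minus)
  expect_equal(anyDuplicated(ids), 0)
  key1 <- paste(r1$duplexes$sscs_plus, r1$duplexes$sscs_minus)
  key2 <- paste(r2$duplexes$sscs_plus, r2$duplexes$sscs_minus)
  expect_setequal(key1, key2)
})

test_that("duplex consensus keeps agreements and masks disagreements", {
  set.seed(59)
  u5 <- sample_barcodes(1, "WSMRWSYWKMWW")
  u3 <- sample_barcodes(1, "WSMRWSYWKMWW")
  seq_ref <- paste(sample(c("A", "C", "G", "T"), 168, replace = TRUE),
                   collapse = "")
  p <- make_sscs(u5, u3, "plus", "Sp", seq = seq_ref)
  m <- partner_of(p); m$seq <- seq_ref

  same <- build_duplex_consensus(match_duplexes(dplyr::bind_rows(p, m)),
                                 dplyr::bind_rows(p, m))
  expect_equal(same$seq, seq_ref)
  expect_equal(same$n_disagreements, 0)

  # a strand-specific damage call becomes an ambiguity, not a variant
  m_dmg <- m
  substr(m_dmg$seq, 50, 50) <- if (substr(seq_ref, 50, 50) == "A") "C" else "A"
  dmg <- build_duplex_consensus(
    match_duplexes(dplyr::bind_rows(p, m_dmg)), dplyr::bind_rows(p, m_dmg))
  expect_equal(substr(dmg$seq, 50, 50), "N")
  expect_equal(dmg$n_disagreements, 1)

  # both strands carrying the alternate support it
  p_alt <- p; m_alt <- m
  alt <- if (substr(seq_ref, 60, 60) == "G") "T" else "G"
  substr(p_alt$seq, 60, 60) <- alt
  substr(m_alt$seq, 60, 60) <- alt
  both <- build_duplex_consensus(
    match_duplexes(dplyr::bind_rows(p_alt, m_alt)),
    dplyr::bind_rows(p_alt, m_alt))
  expect_equal(substr(both$seq, 60, 60), alt)
})

test_that("duplex recovery follows the unique-molecule accounting", {
  r <- duplex_recovery(1000, 1000, 600)
  expect_equal(r$unique_molecules, 1400)
  expect_equal(r$recovery_rate, 600 / 1400)

  expect_equal(duplex_recovery(5, 7, 0)$unique_molecules, 12)
  expect_equal(duplex_recovery(5, 7, 0)$recovery_rate, 0)
  expect_equal(duplex_recovery(3, 3, 3)$unique_molecules, 3)
  expect_equal(duplex_recovery(3, 3, 3)$recovery_rate, 1)
  expect_error(duplex_recovery(3, 5, 4), "exceed")

  # monotone non-decreasing in d for fixed strand counts
  rates <- vapply(0:50, function(d) duplex_recovery(50, 60, d)$recovery_rate,
                  numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("mispairing profiles count positions and per-duplex artifacts", {
  dup <- tibble::tibble(
    duplex_id = c("D1", "D2"),
    mispair_positions = list(c(1L, 7L), integer(0))
  )
  prof <- mispairing_profile(dup)
  expect_equal(prof$per_position$n_mispaired[c(1, 7)], c(1, 1))
  expect_equal(sum(prof$per_position$n_mispaired), 2)
  expect_equal(
    prof$histogram_full$n_duplexes[prof$histogram_full$n_mispairings == 2], 1)
  expect_equal(sum(prof$per_position$terminal), 12)
  expect_true(all(which(prof$per_position$terminal) %in% c(7:12, 19:24)))
})

test_that("zero-dropout error-free libraries recover every duplex", {
  ref <- tiny_reference()
  base <- function(profile, seed) {
    sim_config(
      reference = ref, target_sites = default_target_sites(ref, vaf = 0.2),
      n_molecules = 40,
      family_size_model = list(dropout = 0, nb_size = 8, nb_mu = 7),
      mispair_profile = profile,
      polymerase_error_rate = 0, seq_error_rate = 0, damage_rate_c_to_a = 0,
      seed = seed
    )
  }
  # faithful annealing: complete recovery with clean keys
  cfg <- base(rep(0, 12), 23)
  run <- run_call(simulate_reads(cfg)$reads, ref, cfg$target_sites,
                  params = run_params(min_reads = 1))
  expect_equal(run$recovery$recovery_rate, 1)
  expect_equal(nrow(run$duplexes), 40)
  expect_true(all(run$duplexes$key_mismatches == 0))

  # with annealing artifacts, each duplex's key mismatches equal the
  # simulated ligation-proximal mispairs of its molecule
  cfg2 <- base(default_mispair_profile(), 24)
  sim2 <- simulate_reads(cfg2)
  run2 <- run_call(sim2$reads, ref, cfg2$target_sites,
                   params = run_params(min_reads = 1, max_key_mismatches = 12,
                                       spurious_threshold = 24))
  expect_equal(nrow(run2$duplexes), 40)
  truth <- sim2$truth
  fam_mol <- tapply(run2$reads$molecule_id, run2$reads$family_id, unique)
  plus_mol <- unlist(fam_mol[run2$sscs$family_id[
    match(run2$duplexes$sscs_plus, run2$sscs$sscs_id)]])
  tr <- truth[match(plus_mol, truth$molecule_id), ]
  expected_key_mm <- vapply(seq_len(nrow(tr)), function(i) {
    sum(tr$mispair_left[[i]] >= 7) + sum(tr$mispair_right[[i]] >= 7)
  }, numeric(1))
  expect_equal(run2$duplexes$key_mismatches, expected_key_mm)

  # and the full mispair positions are recovered exactly
  expected_pos <- lapply(seq_len(nrow(tr)), function(i) {
    sort(c(tr$mispair_left[[i]], 12L + tr$mispair_right[[i]]))
  })
  expect_equal(lapply(run2$duplexes$mispair_positions, sort), expected_pos)
})
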