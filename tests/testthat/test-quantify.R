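test_that("pileups count every spanning record in exactly one bucket", {
  rec <- tibble::tibble(
    locus = "locus01",
    fragment_start = c(0L, 0L, 0L, 0L, 20L),
    fragment_end = c(30L, 30L, 30L, 30L, 50L),
    seq = c("ACGTACGTACGTACGTACGTACGTACGTAC",
            "ACGTACGTACNTACGTACGTACGTACGTAC",   # N at position 10
            "ACGTACGTACTTACGTACGTACGTACGTAC",   # alt T at position 10
            "ACGTACGTACCTACGTACGTACGTACGTAC",   # third allele C
            strrep("A", 30)),                   # does not span position 10
    trim5 = 0L, trim3 = 0L
  )
  sites <- tibble::tibble(locus = "locus01", position = 10L,
                          ref = "G", alt = "T")
  pile <- pileup_sites(rec, sites)
  expect_equal(pile$n_ref, 1)
  expect_equal(pile$n_alt, 1)
  expect_equal(pile$n_other, 1)
  expect_equal(pile$n_ambiguous, 1)
  # conservation: the four buckets sum to the spanning records
  expect_equal(pile$n_ref + pile$n_alt + pile$n_other + pile$n_ambiguous, 4)
  expect_equal(pile$vaf, 1 / 3)

  # uncovered site: all zero, VAF undefined
  empty <- pileup_sites(rec, tibble::tibble(locus = "locus01",
                                            position = 400L,
                                            ref = "A", alt = "T"))
  expect_equal(empty$n_ref + empty$n_alt + empty$n_other + empty$n_ambiguous,
               0)
  expect_true(is.na(empty$vaf))

  ref <- c(locus01 = strrep("A", 100))
  expect_error(
    pileup_sites(rec, tibble::tibble(locus = "locus01", position = 400L,
                                     ref = "A", alt = "T"),
                 reference = ref),
    "outside")
})

test_that("soft-trimmed positions never contribute to counts", {
  rec <- tibble::tibble(
    locus = "locus01", fragment_start = 0L, fragment_end = 10L,
    seq = "TAAAAAAAAT",                    # mismatches at both ends
    trim5 = 2L, trim3 = 2L
  )
  ref <- c(locus01 = strrep("A", 10))
  prof <- background_error_profile(rec, ref)
  expect_equal(prof$n_errors, 0)
  expect_equal(prof$total_bases, 6)

  prof0 <- background_error_profile(dplyr::mutate(rec, trim5 = 0L, trim3 = 0L),
                                    ref)
  expect_equal(prof0$n_errors, 2)
  expect_equal(prof0$by_class$n_errors[prof0$by_class$class == "A>T"], 2)

  # a site flagged as a known variant is excluded from both terms
  site <- tibble::tibble(locus = "locus01", position = 0L)
  prof_ex <- background_error_profile(
    dplyr::mutate(rec, trim5 = 0L, trim3 = 0L), ref, exclude_sites = site)
  expect_equal(prof_ex$n_errors, 1)
  expect_equal(prof_ex$total_bases, 9)
})

test_that("a masked ligation-adjacent error vanishes from the profile", {
  # inject a substitution at the first insert base of an otherwise clean
  # library and check the soft trim hides it from error accounting
  sim <- clean_sim()
  cfg <- clean_config()
  reads <- sim$reads[1:30, ]
  block <- 16                              # tag + barcode + overhang
  target <- substr(reads$r1_seq[1], block + 1, block + 1)
  bad <- if (target == "A") "C" else "A"
  substr(reads$r1_seq[1], block + 1, block + 1) <- bad

  prepped <- align_reads(prep_reads(reads), cfg$reference)
  usable <- prepped[prepped$status == "merged", ]
  prof <- background_error_profile(usable, cfg$reference, cfg$target_sites,
                                   level = "raw")
  expect_equal(prof$n_errors, 0)

  usable$trim5 <- 0L; usable$trim3 <- 0L
  prof0 <- background_error_profile(usable, cfg$reference, cfg$target_sites,
                                    level = "raw")
  expect_equal(prof0$n_errors, 1)
})

test_that("variant calls require duplex support for high confidence", {
  sites <- tibble::tibble(locus = "locus01", position = c(10L, 20L, 30L),
                          ref = "A", alt = "T")
  s_pile <- tibble::tibble(
    locus = "locus01", position = c(10L, 20L, 30L), ref = "A", alt = "T",
    level = "sscs", n_ref = c(95L, 97L, 50L), n_alt = c(5L, 3L, 0L),
    n_other = 0L, n_ambiguous = 0L, vaf = c(0.05, 0.03, 0)
  )
  d_pile <- tibble::tibble(
    locus = "locus01", position = c(10L, 20L, 30L), ref = "A", alt = "T",
    level = "duplex", n_ref = c(40L, 42L, 20L), n_alt = c(2L, 0L, 0L),
    n_other = 0L, n_ambiguous = 0L, vaf = c(0.0476, 0, 0)
  )
  calls <- call_variants(s_pile, d_pile)
  expect_equal(calls$detected, c(TRUE, TRUE, FALSE))
  expect_equal(calls$duplex_support, c(TRUE, FALSE, FALSE))
  expect_equal(calls$high_confidence, c(TRUE, FALSE, FALSE))
})

test_that("zero-error pipelines have zero background at every level", {
  run <- clean_run()
  expect_equal(run$error_profiles$raw$overall_rate, 0)
  expect_equal(run$error_profiles$sscs$overall_rate, 0)
  expect_equal(run$error_profiles$duplex$overall_rate, 0)
})

test_that("oxidative damage is strand-asymmetric and duplex-corrected", {
  run <- damage_run()
  by_class <- run$error_profiles$sscs$by_class
  c_to_a <- by_class$n_errors[by_class$class == "C>A"]
  g_to_t <- by_class$n_errors[by_class$class == "G>T"]
  # minus-strand C>A damage shows up as G>T in reference-forward classes
  expect_gt(g_to_t, 0)
  expect_equal(c_to_a, 0)
  expect_equal(sum(by_class$n_errors) - g_to_t, 0)
  expect_equal(run$error_profiles$duplex$overall_rate, 0)
})

test_that("error suppression is monotone across consensus levels", {
  gl <- dplyr::bind_rows(lapply(ensemble_runs(), `[[`, "glance"))
  expect_gt(mean(gl$error_rate_raw), mean(gl$error_rate_sscs))
  expect_gte(mean(gl$error_rate_sscs), mean(gl$error_rate_duplex))
})

test_that("estimated VAF stays inside the exact binomial interval", {
  runs <- ensemble_runs()
  v <- 0.2
  ok <- vapply(runs, function(r) {
    n_mol <- r$config$n_molecules / nrow(r$config$target_sites)
    lo <- stats::qbinom(0.005, n_mol, v) / n_mol
    hi <- stats::qbinom(0.995, n_mol, v) / n_mol
    all(r$calls$vaf_sscs >= lo & r$calls$vaf_sscs <= hi)
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("expected copies derive from mass at 3.3 pg per haploid genome", {
  expect_equal(copies_from_mass(2.3), 697)
  expect_equal(copies_from_mass(3.3), 1000)
  expect_equal(copies_from_mass(0), 0)
})

test_that("unique-molecule accounting reports efficiency and spread", {
  counts <- tibble::tibble(site = c("a", "b", "c"),
                           unique_molecules = c(400L, 500L, 0L))
  acc <- unique_molecule_table(counts, input_mass_ng = 2.3)
  expect_equal(acc$expected_copies, 697)
  expect_equal(acc$per_site$efficiency[3], 0)
  expect_equal(acc$mean_molecules, 300)
  expect_equal(acc$sd_molecules, sd(c(400, 500, 0)))
})
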