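# Shared fixtures: small simulated libraries, built once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

tiny_reference <- function(n_loci = 2, locus_length = 600, seed = 99) {
  sim_reference(n_loci = n_loci, locus_length = locus_length, seed = seed)
}

# error-free library (no substitution errors, no annealing artifacts):
# every downstream value is exactly derivable from truth
clean_config <- function(n_molecules = 120, seed = 5, ...) {
  ref <- tiny_reference()
  sim_config(
    reference = ref,
    target_sites = default_target_sites(ref, vaf = 0.2),
    n_molecules = n_molecules,
    mispair_profile = rep(0, 12),
    polymerase_error_rate = 0, seq_error_rate = 0, damage_rate_c_to_a = 0,
    seed = seed, ...
  )
}

clean_sim <- function() cached("clean_sim", simulate_reads(clean_config()))

clean_run <- function() cached("clean_run", {
  cfg <- clean_config()
  run_call(clean_sim()$reads, cfg$reference, cfg$target_sites)
})

# oxidative damage only: strand-asymmetric C>A on the minus strand
damage_config <- function() {
  ref <- tiny_reference()
  sim_config(
    reference = ref,
    target_sites = default_target_sites(ref, vaf = 0),
    n_molecules = 80,
    polymerase_error_rate = 0, seq_error_rate = 0,
    damage_rate_c_to_a = 0.01,
    seed = 17
  )
}

damage_run <- function() cached("damage_run", {
  cfg <- damage_config()
  run_call(simulate_reads(cfg)$reads, cfg$reference, cfg$target_sites)
})

# library with realistic error rates, used for full-pipeline checks
default_sim <- function() cached("default_sim", {
  ref <- tiny_reference()
  simulate_reads(sim_config(
    reference = ref, target_sites = default_target_sites(ref, vaf = 0.2),
    n_molecules = 150, seed = 11
  ))
})

default_run <- function() cached("default_run", {
  ref <- tiny_reference()
  run_call(default_sim()$reads, ref, default_target_sites(ref, vaf = 0.2))
})

# ensemble of independent seeds with positive error rates, for the
# error-suppression and VAF-recovery properties
ensemble_runs <- function() cached("ensemble_runs", {
  ref <- tiny_reference()
  sites <- default_target_sites(ref, vaf = 0.2)
  lapply(101:110, function(s) {
    cfg <- sim_config(
      reference = ref, target_sites = sites, n_molecules = 60,
      polymerase_error_rate = 3e-4, seq_error_rate = 2e-3,
      damage_rate_c_to_a = 0, seed = s
    )
    run <- run_call(simulate_reads(cfg)$reads, ref, sites)
    list(glance = glance(run), calls = run$calls, config = cfg)
  })
})

# independent single-linkage oracle: threshold graph, transitive closure
# over the full pairwise distance matrix
bf_single_linkage <- function(strings, threshold) {
  n <- length(strings)
  chars <- strsplit(strings, "")
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(chars[[i]] != chars[[j]])
    }
  }
  A <- D <= threshold
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (identical(A2, A)) break
    A <- A2
  }
  match(apply(A, 1, paste, collapse = ""),
        unique(apply(A, 1, paste, collapse = "")))
}

same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# synthetic one-bucket input for group_families()
make_aligned_bucket <- function(uids, insert_len = 168) {
  n <- length(uids)
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)),
    status = "merged",
    uid_5p = substr(uids, 1, nchar(uids) %/% 2),
    uid_3p = substr(uids, nchar(uids) %/% 2 + 1, nchar(uids)),
    uid = uids,
    orientation = "plus",
    locus = "locus01",
    fragment_start = 100L,
    fragment_end = 100L + insert_len,
    seq = strrep("A", insert_len),
    reject_reason = NA_character_,
    trim5 = 2L, trim3 = 2L
  )
}

# random clustering instance: a few founder UIDs, each with mutated copies
random_uid_instance <- function(n_max = 50, uid_len = 24) {
  n <- sample(3:n_max, 1)
  founders <- sample_barcodes(max(1, n %/% 5), strrep("N", uid_len))
  vapply(seq_len(n), function(i) {
    base <- sample(founders, 1)
    k <- sample(0:3, 1)
    ch <- strsplit(base, "")[[1]]
    if (k > 0) {
      pos <- sample.int(uid_len, k)
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
}

# constructed SSCS rows for duplex-matching tests
make_sscs <- function(uid_5p, uid_3p, orientation, sscs_id,
                      locus = "locus01", start = 50L, end = 218L,
                      seq = NULL) {
  tibble::tibble(
    sscs_id = sscs_id, family_id = paste0("F_", sscs_id), locus = locus,
    orientation = orientation, fragment_start = start, fragment_end = end,
    uid_5p = uid_5p, uid_3p = uid_3p, uid = paste0(uid_5p, uid_3p),
    seq = seq %||% strrep("A", end - start),
    n_reads = 3L, n_ambiguous = 0L, trim5 = 2L, trim3 = 2L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE when a molecule's target site escapes the soft-trim mask at both
# fragment ends (mirrors the pileup masking rule)
site_unmasked <- function(truth, trim = 2L) {
  off <- truth$site_position - truth$fragment_start
  len <- truth$fragment_end - truth$fragment_start
  off >= trim & off < len - trim
}
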