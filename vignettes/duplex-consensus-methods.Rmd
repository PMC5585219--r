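---
title: "Duplex consensus calling with semi-degenerate barcoded adapters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling with semi-degenerate barcoded adapters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexbc)
```

## The problem and the model

Circulating tumor DNA is present in plasma at variant allele fractions
(VAF) that routinely sit below the raw substitution error rate of
short-read sequencing. Three nested consensus levels recover signal from
this noise:

1. **Raw reads.** Merged read pairs aligned to the targeted reference;
   errors from PCR and sequencing occur at ~10⁻³–10⁻⁴ per base.
2. **Single-strand consensus (SSCS).** All reads descending from one
   parental strand of one original molecule form a PCR family (same
   mapping coordinates, same UID up to a 1% mismatch tolerance). The
   per-column plurality base over ≥3 independent reads cancels errors
   that arise independently per read; a position where the top count is
   tied becomes `N` and is excluded from every downstream count.
3. **Duplex consensus.** The two opposite-strand SSCS of one molecule are
   matched and compared; any disagreement becomes `N`. Artifacts that are
   systematic on one strand but absent on the other — most prominently
   oxidative 8-oxoguanine damage, which appears as an asymmetric excess
   of C>A over its reciprocal G>T — survive step 2 but are cancelled
   here. Only variants supported by both strands are high confidence.

The adapters that make this possible carry, on the plus oligo, a
12-nt semi-degenerate barcode `WSMRWSYWKMWW` (each position a two-letter
IUPAC set, 2¹² = 4,096 sequences; the minus oligo carries the reverse
complement pattern `WWKMWRSWYKSW`) and a tri-nucleotide strand tag that is
deliberately non-complementary between the two oligos. A molecule's
combined 24-nt UID (two barcodes) separates molecules that share mapping
coordinates; random UIDs differ at half their positions on average
(6.01 of 12, 12 of 24), so genuinely distinct molecules are essentially
never confused with PCR duplicates.

### Duplex matching on the ligation-proximal key

Annealing of the two adapter oligos is imperfect: since both oligos draw
each degenerate position independently from complementary two-letter
sets, a position can end up non-complementary ("annealing mispairing"),
and after canonical orientation such a position shows the *other* allowed
base of the plus set — it still conforms to the pattern, but the two
strands of the duplex disagree there. Empirically these artifacts
concentrate in the barcode positions far from the ligation site, so
duplex partners are identified on the six ligation-proximal positions of
each barcode (a 6 + 6 = 12 nt key), tolerating at most 2 mismatches
(`max_key_mismatches`). We read the published rule as a combined-12
threshold rather than 2-per-6-block; the two readings coincide for ≤2
total mismatches except in the rare 2+1 split, and the threshold is
configurable. Key ties between candidates are resolved by the full 24-nt
UID distance; an exact tie on both criteria conservatively leaves all
parties unpaired. A candidate pair whose full-UID distance exceeds
`spurious_threshold` (default 5, chosen because nearly all true duplexes
carry five or fewer artifacts while random pairs sit near 12) is flagged
as a coordinate collision between unrelated molecules and rejected.

For the legacy 5-nt design (`WSWSW`, fixed complementary `GAC`/`GTC` tag
after the barcode) the full 2 × 5 barcode is the key, with the same ≤2
mismatch rule; its fixed tags cannot discriminate strands, which is one
reason the 12-nt design superseded it.

### Recovery accounting

With `n_fwd` plus-strand and `n_rev` minus-strand consensus sequences of
which `d` assemble into duplexes, the library contains an estimated
`(n_fwd − d) + (n_rev − d) + d` unique molecules and the duplex recovery
rate is `d` over that total:

```{r}
duplex_recovery(1000, 1000, 600)
```

## What the simulator emulates

`sim_config()` encodes the study conditions as defaults:

| parameter | default | rationale |
|---|---|---|
| `fragment_length_mean` | 170 bp (sd 10) | the characteristic mononucleosomal size of cfDNA |
| `read_length` | 150 | paired-end 150 sequencing |
| `family_size_model` | zero-inflated NB: dropout 0.3, `1 + NB(size 8, mu 7)` | reproduces both a peak PCR family size in the 6–12 band and realistic (~50%) duplex recovery; dropout models a parental strand never making it into the data |
| `mispair_profile` | 0.30 … 0.003, decreasing | monotone decline toward the ligation site; calibrated so ~80% of duplexes show zero artifacts over the 12 key positions and ~17% one, with most duplexes ≤3 artifacts over all 24 positions — the published shape, since exact per-position rates are not tabulated |
| `polymerase_error_rate` | 1 × 10⁻⁴ /base/copy | PCR misincorporation, applied independently per read copy (a late-cycle model; early-cycle jackpot errors shared by a whole family are deliberately out of scope because consensus cannot remove them) |
| `seq_error_rate` | 1 × 10⁻³ /base | Q30 sequencing; qualities are constant Q30 because consensus is count-based, not quality-weighted |
| `damage_rate_c_to_a` | 0 (off; tests use 10⁻³–10⁻²) | oxidative C>A conversion applied once per molecule, pre-PCR, on the minus strand by default — matching damage acquired during library processing of one strand |
| `vaf` (per site) | 0.1 | each molecule carries the alternate allele with this probability, so the realized count is Binomial(n, VAF) |

The reference is a pseudo-random 5 × 1 kb FASTA (shipped in
`inst/extdata/`, regenerable via `sim_reference()`), standing in for a
concatenation of targeted loci with flanks. One targeted site per locus
sits at the locus midpoint.

Every read traces to a truth record (molecule, fragment, barcodes,
mispaired positions, family sizes, each injected error with its
mechanism), so tests can assert exact equalities rather than
plausibility.

**What the simulator does not model:** indels (substitutions only),
cycle-dependent quality profiles, capture-bait efficiency differences,
adapter dimers and contamination, early-cycle PCR jackpots, and the
nonrandom fragment-end distribution of real cfDNA (our fragment ends are
uniform around the site, so mapping-coordinate collisions are rarer than
in a deep real library). Passing tests therefore demonstrate the
correctness of the algorithms under the model, not the absolute error
rates achievable on patient data: the published per-patient background
(10⁻⁵ → 10⁻⁶-scale) depends on depth and library complexity we do not
reproduce at desk scale. The package instead asserts the *structural*
claims — suppression is monotone raw ≥ SSCS ≥ duplex, damage is
strand-asymmetric at SSCS level and absent at duplex level, and an
error-free library round-trips exactly.

## Numerical and design choices

- **Tag table.** The published set of strand-tag combinations is not
  public; the shipped default reconstructs the stated counts — 6 plus × 4
  minus oligos yielding 19 usable pairs — by excluding complementary,
  swap-ambiguous and identical-oligo combinations
  (see `default_tag_table()`). Orientation is assigned from the (5′, 3′)
  tag pair: a table hit reads plus, a swapped hit reads minus, anything
  else is `unknown` (kept for single-strand analyses, never duplexed).
  This treats a molecule as carrying one tag combination, a deliberate
  simplification of adapter chemistry in which the two fragment ends are
  ligated independently.
- **Barcode composition.** Degenerate positions draw uniformly from their
  two-letter sets; per-position weight overrides exist
  (`sample_barcodes()`) because synthesis machines skew ratios, but no
  published values are available to calibrate them.
- **Merging.** Best ungapped overlap of read 1 against the reverse
  complement of read 2, minimum overlap 30 nt, mismatch fraction ≤ 0.1
  (permissive on purpose — family clustering re-filters at 1%);
  disagreements take the higher-quality base, ties read 1. Exact k-mer
  seeds propose offsets before an exhaustive scan. Unmerged pairs are
  kept and represented after alignment as a gapped pseudo-merged sequence
  whose gap positions (`-`) are excluded from every count; pairs whose
  mates truncate inside a tagged block are rejected.
- **Alignment.** Exact-seed placement with mismatch verification against
  the small concatenated reference (the simulator produces substitutions
  only), falling back to glocal affine-gap `pairwiseAlignment` when no
  seed hits; best placement over both strands; >5% edit distance is
  off-target. Coordinates are 0-based half-open internally, 1-based in
  user-facing report formats (VCF).
- **Family grouping.** Exact-coordinate bucketing (locus, orientation,
  start, end) — not fuzzy ±1, because the glocal aligner produces no
  soft-clips — then single-linkage clustering of combined UIDs at
  `max(1, floor(0.01 × tagged-read length))` mismatches, mirroring a
  1%-mismatch de-novo assembly over tag + insert. An independent
  brute-force transitive-closure oracle verifies the clustering on random
  instances.
- **Consensus ties.** Plurality with exact ties → `N` (also when >2 bases
  tie); `N` means "no concrete call" everywhere downstream. We use `N`
  rather than two-base IUPAC codes because downstream rules only need
  excluded-position semantics.
- **Soft trim.** The first and last 2 insert bases are masked (end-repair
  artifacts cluster at ligation sites); masked positions are excluded
  from error-rate numerators and denominators and contribute only
  ambiguous counts at a targeted site.
- **VAF denominator.** `n_alt / (n_alt + n_ref + n_other)` — third
  alleles count in the denominator, ambiguous calls do not, matching
  "mutant molecules over molecules with a concrete base call".
- **Accounting statistics.** Replicate summaries use the sample (n − 1)
  standard deviation.
- **Degenerate inputs.** Empty read sets produce a zero-count run;
  singleton UID sets are an error for diversity statistics; a site
  outside every reference locus is an error while a merely uncovered site
  reports `NA` VAF.

## Problem sizes

The shipped tests simulate libraries of 40–150 molecules over 2 loci
(~600 bp each) with families averaging ~8 reads — a few thousand read
pairs per run — and verify stochastic properties over a 10-seed ensemble;
Monte-Carlo barcode statistics use 10,000–12,000 draws. These sizes make
every distributional check well-powered while the whole suite stays in
the minutes range on one core.

## Limitations

Indel variants and structural rearrangements are not called (a
breakpoint-spanning contig in the reference reduces a fusion to an
ordinary targeted site, but no such recipe is automated here). No
position-specific error model or significance test is attached to the
calls: `high_confidence` is the duplex-support rule, not a p-value.
Genome-scale alignment is out of scope — the aligner expects the small
targeted reference this assay uses.
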