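---
title: "arrayscan: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arrayscan: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayscan)
```

# Scope and scientific setting

`arrayscan` packages the desk-scale quantitative analyses used when a
tandemly arrayed gene family (here motivated by high glycine–tyrosine
keratin-associated proteins, HGT-KRTAPs, and the epidermal differentiation
complex) shows signs of concerted evolution: paralogs within one genome that
are nearly or exactly identical, arranged tail-to-head, with elevated GC,
while orthologous comparisons between species still carry the expected
divergence. Two evolutionary scenarios produce this picture — very recent
independent duplication in each lineage, or an ancient array homogenized by
persistent nonallelic gene conversion — and the package's statistics
(neighbor identity, within- vs between-species Ks, clock dating) are exactly
the quantities used to weigh them. A forward-time simulator generates both
regimes with known ground truth, so every stage of the pipeline is testable
without external data.

# Expression classification

Genes are classified over a genes × tissues TPM matrix (replicates averaged
per tissue with the arithmetic mean, the Human Protein Atlas convention).
The rules are evaluated in a fixed order per gene:

1. **not detected** — TPM < `detect_threshold` (default 1) in every tissue;
2. **tissue enriched** — the highest tissue is at least `fold_threshold`
   (default 5) times the second highest. "At least" is read as `>=`, so a
   gene exactly at 5× is enriched; a second-highest of exactly 0 with a
   positive maximum is treated as infinite fold (reported as `Inf`);
3. **group enriched** — the candidate group is *exactly* the set of tissues
   with per-gene Z-score ≥ `z_threshold` (default 1), with Z computed on raw
   TPM across tissues. The group qualifies when its size is between 2 and
   `group_max` (default 7) and its mean TPM is ≥ `fold_threshold` times the
   mean of all remaining tissues;
4. **other** otherwise.

Design notes. No subset search is performed for groups: the Z rule alone
defines the candidate, which is deterministic and faithful to the rule text;
an exhaustive-enumeration oracle in the test suite confirms the two
formulations agree. Z-scores use raw TPM by default because the source
protocol states no log transform; `log_z = TRUE` exposes the log2(TPM+1)
variant. A gene whose expression is exactly constant across tissues has an
undefined Z (sd = 0) and falls through to *other*. Classification is
scale-invariant for genes above the detection floor, and raising the fold
threshold can only demote genes — both asserted as properties.

The differential screen contrasts two replicate groups with Welch's t-test
on log2(TPM + 1) and Benjamini–Hochberg adjustment across all tested genes.
The published analysis used DEGseq; the screen that matters scientifically
is the *conjunction* — |fold| > 2 ∧ adjusted P < 0.05 ∧ membership in the
anchor-tissue expression set — so the test statistic is a documented,
pluggable choice rather than a reimplementation of one tool. Fold change is
computed on replicate means of TPM + 1 (the pseudocount avoids division by
zero); genes with zero variance on both sides get p = 1 (no within-group
evidence), with the fold still reported.

# Residue composition

Amino-acid proportions are computed over the 20 standard residues; `X`
(unknown, e.g. from `N` codons) is excluded from numerator and denominator
because it is not a residue call. GC content is computed over the
unambiguous A/C/G/T of the CDS — the published figure does not state whether
UTRs/introns were included, so CDS-only is chosen and carried in the output
schema; GC at third codon positions (GC3) is reported alongside but not used
in any screen. The tyrosine candidate screen is the conjunction
tyr ≥ 5% ∧ anchored expression class. Group summaries use a classic one-way
ANOVA (F from between/within mean squares); only the omnibus test is
offered, matching how such comparisons are reported (significance stars, no
post-hoc tests).

# Alignment and p-distance

Protein pairs are aligned globally with a Gotoh affine-gap dynamic program
under BLOSUM62 (defaults: gap open 11, extend 1; a gap of length L costs
open + extend·L). Among equal-scoring tracebacks the preference is
match/mismatch, then gap in the first sequence, then gap in the second —
output is deterministic. The p-distance is the fraction of mismatched
columns among columns where *neither* sequence has a gap (gap columns carry
no substitution information); identity = 1 − p-distance, the "similarity"
statistic plotted across neighboring array members. The aligner's scores are
checked against an independent suffix-recursion DP oracle in the tests.

# NG86 Ks and clock dating

The synonymous substitution estimator follows Nei & Gojobori (1986) with a
Jukes–Cantor multiple-hit correction:

* CDS pairs are codon-aligned by aligning the proteins and threading the
  gaps back onto the nucleotides; columns with a gap in either sequence are
  dropped pairwise, as are codon pairs containing `N` or a stop.
* At each codon position the synonymous site fraction is the share of the 3
  possible changes that preserve the amino acid; changes to stop codons
  count as nonsynonymous, so S + N = 3 per compared codon exactly. S is
  averaged over the two sequences.
* Codons differing at 2–3 positions are scored by averaging the synonymous /
  nonsynonymous step counts over all minimal substitution pathways with
  equal weights, excluding pathways that pass through a stop codon; if every
  pathway is blocked the codon pair is dropped and counted in a diagnostics
  field.
* pS = Sd/S; Ks = −(3/4)·ln(1 − (4/3)·pS), undefined (saturated) when
  pS ≥ 3/4 — reported as `NA` with a flag, and excluded (with a count) from
  clade summaries.
* Divergence time is T = Ks/(2μ) with μ = 2×10⁻⁹ substitutions per site per
  year by default, so the canonical between-species mean Ks of 0.03 dates to
  7.5 My.

The published analysis used codeml's pairwise ML mode; NG86 was chosen here
because it is self-contained and exactly testable by hand (the test suite
freezes a worked 8-codon example), and in the regime that matters for
homogenized arrays (Ks ≤ ~0.05) counting and ML estimates agree closely. The
estimator sits behind a small interface and can be swapped.

# Tandem-array statistics

An array report orders genes by locus start on one contig (0-based,
half-open coordinates internally; GFF3 is converted at the boundary, BED
passes through; strandless records are rejected because orientation is an
analyzed quantity), aligns adjacent protein pairs, and reports per-pair and
mean neighbor identity, tail-to-head orientation (all strands equal), and
identical-CDS clades (exact string equality, the strict reading of
"identical paralogs"; a relaxed ≥ 0.99 protein-identity mode is available).
Overlapping loci only warn — assemblies do contain overlapping annotations —
and the start-order is retained. Cross-array comparisons pool the
neighbor-identity samples into a one-way ANOVA.

# CNE decay

Coverage of a conserved noncoding element is the union of its retained hit
intervals (identity ≥ `min_identity`, default 0.6 — the published "mapping
quality" basis is not defined, so identity filtering is the documented
choice) divided by its length. Status uses strict cuts on both sides:
decayed below 50%, intact above 90%. Because the two published cuts leave a
gap, coverage in [50%, 90%] is reported as *intermediate* rather than being
silently absorbed into either class — a coverage of exactly 0.5 is therefore
not decayed, and exactly 0.9 is not intact. The cross-species contrast flags
elements decayed in the focal species and intact in *all* others, and
reports decayed fractions per region label. A desk-scale Smith–Waterman
search (both strands, recursive splitting of the query around each hit so a
deletion-split element reports both segments) can generate hits when only
sequences are available.

# The simulators: what they emulate, and what they do not

**Tandem arrays.** An ancestral CDS is drawn uniformly over sense codons.
Under the *ancestral* duplication mode the array exists at the split and
each copy evolves independently in each species for `t_split` years; under
*post_split* a single gene evolves per species and is copied at the present
(the recent-independent-duplication scenario, which yields identical copies
within species by construction). Mutations are Jukes–Cantor: the per-branch
count is Poisson(μ·t·L·n), positions and target bases uniform, and
stop-creating changes are rejected and redrawn (keeping the realized rate
interpretable; synonymous-site divergence is unaffected because a synonymous
change can never create a stop). Gene conversion events arrive at
`conversion_rate` per gene per year; each copies a geometric-length tract
(mean `tract_len`) from a uniformly chosen same-species donor and is skipped
if the chimeric copy would contain a stop. All events are time-stamped in an
event log. Under conversion_rate 0 the expected between-species divergence
is 2·μ·t, and the test suite verifies the NG86 estimate centers on 0.03 at
μ = 2×10⁻⁹, t = 7.5 My over 100 seeds. Selection is deliberately *not*
modeled: the biological account attributes homogenization to conversion and
selection jointly, and only the conversion component is simulated — a green
regime-contrast test therefore establishes that conversion alone raises
neighbor identity in this generator, not that conversion explains any real
array. For the regime contrast, 10⁻⁶ events·gene⁻¹·yr⁻¹ (~7.5 events per
gene over the branch) is used as the "high conversion" regime; the rate was
fixed from a scan of the generator before any acceptance assertion was
written, since no empirical conversion rate is available to match.

**Expression matrices.** Baselines are log-normal (median 10 TPM, sdlog 1);
planted enriched genes multiply their focus tissues by the planted fold
(default 10); not-detected genes draw baselines below 1 TPM; unplanted genes
get a mild per-tissue log-normal profile (sdlog 0.5) so the background is
not artificially flat; replicate noise is multiplicative log-normal with
σ = 0.2 by default — a realistic within-tissue spread for bulk RNA-seq TPM.
The generator plants clean block structure: it does not emulate correlated
tissues, compositional (library-size) coupling, count noise at low TPM, or
batch effects, so label-recovery tests validate the classifier's rule logic,
not its robustness on real atlases.

**CNE decay.** A contiguous block of the element is deleted
(`decay_fraction`), the remainder substituted at `point_rate`, and the
result embedded in random flanks. The returned "expected coverage band"
[(1−f)(1−2p), 1−f] is construction-level truth; a local aligner can overrun
the deletion junction by a few chance-matching bases, so tests assert the
recovered status and coverage rather than strict band containment.

# Numerical and interface conventions

* Coordinates are 0-based half-open everywhere inside the package;
  conversions happen only in `read_loci()`/`read_hits()`/`write_loci()`
  (GFF3 and outfmt-6 are 1-based inclusive; BED and PAF pass through).
* Readers reject rather than repair malformed input, naming the offending
  record; FASTA round-trips are identity and are property-tested.
* Terminal stop codons are trimmed before translation; internal stops are
  hard errors (the analyses concern intact genes). `N` codons translate to
  `X` and are excluded from Ks counting.
* All simulator functions take an integer seed and are byte-reproducible;
  they save and restore the caller's RNG state.
* The pipeline (`run_full()`) validates its configuration before any stage
  runs, stages outputs in a hidden directory and publishes them only on
  success, names the failing stage in errors, and emits a manifest with a
  canonicalized config hash; reruns are byte-identical. Configuration is
  JSON (round-trip tested).

# Known limitations

* NG86 underestimates Ks relative to ML codon models as divergence grows;
  beyond pS ≈ 0.3 the Jukes–Cantor correction is increasingly strained, and
  at pS ≥ 3/4 the estimate is refused outright.
* The group-enrichment rule inherits the ambiguity of its source protocol
  (tissues vs organ systems); tissue grouping is therefore an input, fixed
  by the replicate map, not hard-coded.
* The Smith–Waterman hit generator is for desk-scale verification, not a
  genome aligner; real CNE coverage should come from a dedicated aligner's
  hit table via `read_hits()`.
* Identical-CDS clades use exact string equality; a single sequencing error
  splits a clade (the relaxed identity mode exists for that case).
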