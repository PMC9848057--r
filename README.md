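# arrayscan

Quantitative tools for studying **tandem gene-family homogenization** and
**tissue-specific expression** in mammalian genomes — the analysis style used
to characterize expanded keratin-associated protein (KRTAP) arrays and the
epidermal differentiation complex (EDC) in scaled mammals. The package is for
comparative genomicists who have a set of coding sequences, gene loci, a
tissue expression matrix, and conserved-noncoding-element (CNE) alignments,
and who want reproducible, testable versions of the standard desk analyses:

* **Expression atlas classification** — Human-Protein-Atlas-style categories
  per gene over a TPM matrix: *not detected* (TPM < 1 everywhere), *tissue
  enriched* (top tissue ≥ 5× the second), *group enriched* (the set of
  tissues with per-gene Z ≥ 1, group mean ≥ 5× the rest), else *other*; plus
  a differential screen (Welch's t on log2(TPM+1), Benjamini–Hochberg FDR,
  fold > 2, anchored to an expression class).
* **Residue composition** — glycine/tyrosine/GC fractions per gene, the
  tyrosine-rich candidate screen (tyr ≥ 5% ∧ skin-anchored expression), and
  per-group means with one-way ANOVA.
* **Tandem-array homogenization** — global protein alignment
  (Needleman–Wunsch/Gotoh, BLOSUM62, affine gaps), neighbor identity
  `1 − p-distance` along the array, tail-to-head orientation, identical-CDS
  clades, and cross-array ANOVA.
* **Ks and molecular-clock dating** — a Nei–Gojobori (1986) estimator:
  per-codon synonymous site fractions, pathway-averaged difference counts,
  Jukes–Cantor correction `Ks = −(3/4)·ln(1 − (4/3)·pS)`, and dating
  `T = Ks / (2μ)` with μ = 2×10⁻⁹ substitutions·site⁻¹·yr⁻¹
  (so Ks = 0.03 ⇒ T = 7.5 My).
* **CNE decay scoring** — merged alignment coverage per element with strict
  cuts (decayed < 50%, intact > 90%), desk-scale Smith–Waterman hit
  generation, and a cross-species decay contrast.
* **Synthetic data with planted truth** — forward-time simulation of tandem
  arrays under duplication, Jukes–Cantor point mutation, a species split, and
  nonallelic gene conversion (unidirectional tract copies, geometric tract
  lengths); planted-structure expression matrices; constructed CNE decay.
  Every analysis stage is therefore verifiable without any external download.

## Worked example

Simulate a six-copy tandem array evolving for 7.5 My after a species split
under persistent gene conversion, then ask the two questions the method is
built for — *how homogenized is the array within a genome?* and *how long
ago did the species split?*

```r
library(arrayscan)

sim <- simulate_array(n_genes = 6, codons = 100, mu = 2e-9, t_split = 7.5e6,
                      conversion_rate = 1e-6, seed = 7)

neighbor_identity_profile(sim$records$sp1, sim$loci$sp1)
#> array_report: 6 genes on ctg_sp1
#>   mean neighbor identity: 0.96
#>   tail-to-head: TRUE ; clades: 2+1+1+1+1

rec <- rbind(sim$records$sp1, sim$records$sp2)
s <- clade_ks_summary(rec, sim$records$sp1$gene_id, sim$records$sp2$gene_id)
sprintf("within sp1 mean Ks %.4f | between mean Ks %.4f -> T %.2f My",
        s$within_a$mean_ks, s$between$mean_ks, s$between$mean_t / 1e6)
#> "within sp1 mean Ks 0.0211 | between mean Ks 0.0365 -> T 9.13 My"
```

Conversion homogenizes copies *within* each genome (mean neighbor identity
0.96, one clade of identical paralogs, within-species Ks below the
between-species value) while the between-species mean Ks still tracks the
split: 0.0365 dates to 9.1 My against a true 7.5 My — single-array sampling
noise; averaged over 100 simulated arrays the estimate centers on
2·μ·t = 0.03 (that calibration is asserted in the test suite).

The same classifier that anchors the screens:

```r
simx <- simulate_expression(n_genes = 200, tissues = 12, fold = 10,
                            noise_sigma = 0.2, seed = 7)
table(classify_genes(simx$matrix)$category)
#>  group_enriched    not_detected           other tissue_enriched
#>              20              20             120              40
```

All 60 planted enriched/not-detected labels are recovered here (the planted
design was 40 tissue-enriched, 20 group-enriched, 20 not-detected).

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "arrayscan", package = "arrayscan"))')
Rscript $CLI classify --matrix expr.tsv --replicates map.tsv --out classes.tsv
Rscript $CLI ks --cds cds.fa --pairs pairs.tsv --mu 2e-9 --out ks.tsv
Rscript $CLI run --config config.json     # full pipeline + manifest
```

## Further reading

The methods vignette (`vignettes/arrayscan-methods.Rmd`) documents the
models, rule evaluation order, numerical conventions (coordinate systems,
tie-breaking, saturation handling), what the simulators do and do not
emulate, and known limitations.
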