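# codonscope

Codon-usage statistics for coding transcriptomes.

Assembled transcriptomes — for example from GC-rich protists such as core
dinoflagellates, where post-transcriptional regulation makes codon bias a
candidate control mechanism — can be profiled for codon usage once in-frame
coding regions are in hand. `codonscope` implements that whole workflow:

* **BLAST-guided coding-region extraction** — take transcripts longer than
  500 nt, keep the top BLAST/tBLASTn hit per query with e-value below
  1e-10, cut out the aligned span, reverse-complement negative-frame hits,
  trim the 3' end to a codon multiple, and count in-frame stop codons as a
  contamination estimator.
* **Per-gene and per-species codon statistics** — codon counts; relative
  synonymous codon usage `RSCU(c) = n · x_c / X` (family size *n*, codon
  count *x_c*, family total *X*; values sum to *n* per amino acid); GC
  content overall and by codon position; synonymous third-position GC
  (GC3s, excluding ATG, TGG and stops); Wright's effective number of
  codons `Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆` with
  `F̂ = (n Σp² − 1)/(n − 1)` per family; the codon bias index
  `CBI = (N_opt − N_ran)/(N_tot − N_ran)`; and the frequency of optimal
  codons `Fop = N_opt/N_tot`.
* **Correspondence analysis** of the 59-variable-codon count matrix (SVD of
  standardized residuals; per-axis inertia sums to chi-squared/N), with an
  optimal-codon set inferred from the axis-1 extremes.
* **Composition statistics** — dinucleotide observed/expected ratios
  (expected from mononucleotide frequencies; 1.00 = no pairing preference)
  and a within-sequence codon-bias flag: a codon is flagged in a sequence
  when its frequency exceeds the species mean plus one standard deviation
  for that codon.
* **An expected-Nc null curve** — simulated genes whose codon choice
  depends only on a uniformly drawn third-position GC bias *s*, alongside
  the closed form `Nc(s) = 2 + s + 29/(s² + (1−s)²)`.
* **A seeded synthetic transcriptome generator** with controllable GC3
  bias, within-family codon preferences, stop-bearing contaminants and
  matching BLAST-tabular fixtures, so the full pipeline is testable
  without any downloads.

## Worked example

Simulate a GC-biased species, write its FASTA and BLAST fixtures, and run
the full pipeline:

```r
library(codonscope)

spec   <- generator_spec("demo_species", n_genes = 300,
                         theta_gc3 = 0.75, seed = 42)
bundle <- generate_species(spec)
paths  <- write_species_bundle(bundle, "demo")

cfg <- run_config(paths[["fasta"]], paths[["hits"]],
                  "demo_species", "demo/out")
fit <- run_species(cfg)
print(fit)
```

```
[demo_species] read_fasta: 300 records
[demo_species] filter_by_length(>500): 300 -> 298 records
[demo_species] select_top_hits(<1e-10): 300 hits -> 300 queries
[demo_species] extract_coding_regions: 298 coding regions
Codon usage fit for 'demo_species'
  genes: 298   codons: 93797   internal stops: 5
  Nc (gene mean): 47.025   GC3s (pooled): 0.751   GC: 0.573
  optimal codons: 17 (ca_axis1_quantile0.05_alpha0.01); CBI 0.328, Fop 0.549
  |cor(CA axis 1, GC3s)| = 0.994
```

Reading the output: two transcripts fell below the 500-nt filter; the
extracted set carries 93,797 codons of which 5 in-frame stops indicate a
small contaminant fraction. The realized GC3s (0.751) matches the
simulated bias, and the depressed effective number of codons (47 of a
possible 61) with a near-perfect axis-1/GC3s correlation is the signature
of composition-driven codon bias: gene position in the ordination is
explained by third-position GC, not by gene-specific codon preferences.
`fit$summary` holds the species summary row; the stage TSVs
(`gene_indices.tsv`, `rscu_long.tsv`, `ca_coordinates.tsv`,
`dinucleotide_ratios.tsv`, `bias_flags_per_codon.tsv`, ...) are written
under `demo/out/`. The least-used codons in this fit are AT-ending, as
expected under GC3 bias:

```r
sort(coef(fit)[genetic_code()$variable_codons])[1:4]
#   ACT   CGA   GGT   GTT
# 0.276 0.290 0.303 0.330
```

`run_panel()` repeats this across a list of species and adds the
panel-level tables (GC by codon position versus overall GC, observed Nc
against the simulated null curve with per-species offsets, pooled RSCU
keyed by codon GC weight).

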