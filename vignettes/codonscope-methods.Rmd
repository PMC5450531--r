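---
title: "Methods behind codonscope"
author: "codonscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind codonscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscope)
```

# Scope and model

`codonscope` profiles codon usage in sets of protein-coding regions cut
out of assembled transcriptomes. The intended data are
transcriptome-scale collections (hundreds to tens of thousands of
genes) where coding regions are identified by protein-level BLAST hits
rather than by ab initio ORF calling — a deliberate choice that
sidesteps frameshifts, gene fragments and mis-assembled ends, at the
cost of analysing only the aligned portion of each gene. The guiding
application is GC-rich protist transcriptomes (core dinoflagellates and
similar lineages), where the question of interest is whether codon bias
is gene-specific — a candidate translational control mechanism — or
simply a reflection of global nucleotide composition.

All statistics assume the standard ("universal") nuclear genetic code.
The three six-fold degenerate amino acids (Leu, Ser, Arg) are treated
as whole families of size six, not split 2+4; this is what makes RSCU
values over the leucine family sum to exactly six.

# Coding-region extraction

`filter_by_length()` keeps transcripts strictly longer than 500 nt and
`select_top_hits()` keeps hits with e-value strictly below 1e-10 —
both thresholds are exclusive and configurable. One hit per query is
retained: lowest e-value, ties broken by highest bit score, then input
order. Only the single top HSP is used; overlapping HSPs for one query
are never merged, since merging rules would have to invent frame
reconciliation that the alignment does not provide.

`extract_coding_region()` takes the nucleotides between the hit's query
coordinates (1-based inclusive, as in BLAST tabular output; the same
convention is used internally, so no coordinate conversion exists
anywhere in the package), reverse-complements when the hit frame is
negative, and trims the 3' end — never the 5' end, because the hit
start anchors the reading frame — to a multiple of three. The result is
in frame +1 by construction. In-frame `TAA`/`TAG`/`TGA` triplets are
counted per gene; under the standard code genuine coding sequence
contains none, so `tabulate_stops()`'s stop-bearing fraction estimates
the contaminant (or mis-framed) fraction of the input.

Ambiguity characters (`N`) are kept in sequences; any codon containing
a non-ACGT character is excluded from every downstream count and
tallied separately. The same rule is applied once, in
`count_codons()`, so no statistic can disagree about it.

# Per-gene indices

For each gene with at least `min_codons` codons (default 30; shorter
genes give wild Nc estimates and are reported as missing, never as
zeros):

* **GC, GC1, GC2, GC3** — fraction of counted codons with G or C at
  each position; the overall GC is their mean, exactly.
* **GC3s** — third-position G/C fraction over the 59 sense codons that
  admit synonymous substitution (ATG, TGG and stops excluded).
* **Nc** — Wright's estimator. Per family with usage $n \ge 2$ and
  within-family frequencies $p_i$,
  $\hat F = (n \sum p_i^2 - 1)/(n - 1)$, an unbiased estimator of codon
  homozygosity. Class means $\bar F_k$ are taken over informative
  families ($n \ge 2$, $\hat F > 0$) and
  $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
  If the single 3-fold family (Ile) is uninformative,
  $\bar F_3 := (\bar F_2 + \bar F_4)/2$; if the 2-, 4- or 6-fold class
  has no informative family, Nc is undefined for that gene. The
  estimate is capped at 61: on finite genes $\hat F$ scatters below
  $1/k$ under uniform usage, so the raw estimator exceeds the
  theoretical maximum about half the time.
* **CBI and Fop** — computed against an optimal-codon set, which the
  package never guesses: it is either supplied explicitly or derived
  from the data (below), and the derivation is recorded in a
  `method_tag`. Published tables produced with codonW's default
  (an *E. coli*-derived optimal set) are therefore not directly
  comparable unless that set is supplied.

Species summaries report unweighted gene means for Nc, CBI and Fop and
pooled (usage-weighted) GC3s and GC; because published tables do not
always state which convention they use, the pooled Nc and the gene-mean
GC3s are carried alongside.

# Correspondence analysis and optimal codons

`codon_ca()` runs classical correspondence analysis on the gene × 59
count matrix (raw counts, not RSCU — per-gene RSCU is unstable for rare
amino acids, and count-based CA is the convention of the field's
tooling): with $P = X/N$, row masses $r$ and column masses $c$, the
standardized residuals $D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$ are
decomposed by SVD; squared singular values are the per-axis inertias
and sum to $\chi^2/N$. Axis signs are arbitrary in CA, so axis 1 is
oriented to correlate non-negatively with per-gene third-position GC
computed from the matrix itself, making plots comparable across runs.
Genes below the per-gene codon minimum are excluded.

`determine_optimal_codons()` takes the genes in the top and bottom 5%
(configurable) of axis 1, calls the extreme with the lower pooled Nc
the high-bias group, and for each multi-codon amino acid tests the
2 × k group-by-codon contingency table (chi-squared, significance level
0.01). When significant, the codon with the highest RSCU in the
high-bias group — provided it is higher there than in the low-bias
group — is declared optimal. Fewer than 10 genes per extreme group is
an error. One caveat is intrinsic to this design: selecting extremes on
an axis fitted to the same counts is mildly self-selecting, so even a
perfectly homogeneous gene set yields a few spurious "optimal" codons;
the inferred set is a descriptive summary of the gradient, not a
significance-controlled discovery set.

# The expected-Nc null curve

`enc_null_curve()` simulates genes whose codon choice carries no
information beyond composition: a synonymous GC bias $s$ is drawn
uniformly on (0, 1) per gene (1000 genes by default), amino acids are
uniform over the 18 multi-codon families, the third-position G/C class
is chosen with probability $s$, and codons within a class are uniform.
Nc is computed per simulated gene; binned means (width 0.02, with
standard errors) form the null curve that observed species are compared
against by `enc_offset()`. Wright's closed form
$N_c(s) = 2 + s + 29/(s^2+(1-s)^2)$ is carried alongside as the
analytic reference.

Two numerical properties of this null are worth knowing. First, it is
not exactly symmetric about $s = 0.5$: the isoleucine family offers one
G/C-ending codon against two A/T-ending ones, so
$N_c(s) \ne N_c(1-s)$ by up to about 1.3 codons at $s = 0.2/0.8$ — the
closed form, which assumes even splits, hides this. Second, gene length
matters: at the 300-codon default (the scale of BLAST-extracted genes)
the capped estimator averages roughly 0.7 below the closed form near
$s = 0.5$, while at 3000 codons it converges to it. The package
therefore uses 300-codon simulated genes when the curve serves as a
comparison standard for equally-sized real genes, and long genes when
checking the estimator against the analytic value.

# Composition statistics

`dinucleotide_profile()` counts overlapping adjacent pairs within each
coding region — never across sequence boundaries — pools them per
species, and compares with the product of the pooled mononucleotide
frequencies taken from the same sequences (keeping observed and
expected on one footing). A ratio of 1.00 means no pairing preference.
Counting is strand-specific; coding-strand biases (such as avoidance of
UA, the dinucleotide inside two of the three stop codons) would be
diluted by reverse-complement folding.

`species_codon_stats()` computes, per codon, the mean and standard
deviation of the within-sequence frequency across all sequences, zeros
included. The population (divisor $n$) standard deviation is the
default — the species' sequence set is treated as the population of
interest, not a sample — with the sample version available.
`flag_biased_codons()` then flags codon/sequence pairs whose frequency
strictly exceeds mean + 1 sd. Only over-use is flagged: amino acids
absent from a protein produce structural zeros that would make
under-use calls meaningless. Under this rule an unbiased transcriptome
still flags roughly 13–16% of observations — the upper tail of the
frequency distribution — approximately uniformly across codons; the
informative signal is deviation from that uniform baseline, not the
baseline itself.

# The synthetic generator

`generate_species()` emulates the inputs of a real study — transcript
FASTA plus BLAST tabular hits — with known truth. Its defaults are
chosen once, on the scale of real coding transcriptomes, and are the
conditions under which the package's tests run:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 500 | desk-scale stand-in for the 2000–12,000 genes of real panels |
| gene length | lognormal, median 300 codons, sdlog 0.35, min 30 | BLAST-extracted coding regions average ~300 codons |
| `theta_gc3` | 0.5 | probability a variable third position is G/C; panels span 0.55–0.89 |
| `theta_gc3_sd` | 0.05 | per-gene GC3 spread (Beta-distributed); real species show per-gene GC3s scatter on this scale |
| `preference_concentration` | 5 | Dirichlet concentration of within-class codon weights; mild, realistic preference (Nc a few codons below the composition-only null) |
| `contamination_fraction` | 0.006 | stop-bearing contaminant rate typical of BLAST-filtered transcriptomes |
| `utr_length` | 50–150 nt each side | keeps most transcripts above the 500-nt filter, as real BLAST-hit transcripts are |
| `ua_penalty` | 1 (off) | optional multiplicative suppression of UA-ending codons, to reproduce UA avoidance by construction |
| `minus_strand_fraction` | 0.1 | antisense-assembled transcripts are common in de novo assemblies |

Hits cover the true ORF completely with probability 0.85 and are
otherwise trimmed in whole codons by up to 3% per end, so coverage
never falls below 94% and frame is always preserved — the behaviour of
genuine protein-level alignments. E-values are drawn below 1e-12.
Contaminant genes receive 1–3 in-frame stops at random internal
codons. All randomness flows from the spec's single seed; the same
spec reproduces byte-identical files.

Because the third-position class is chosen with probability
`theta_gc3` in every family, the realized GC3s is analytically equal to
`theta_gc3` in expectation, which is what makes parameter-recovery
tests sharp. The generator does **not** emulate expression levels,
splice isoforms, sequencing error, realistic UTR composition, or amino
acid composition differences between genes; passing tests therefore
demonstrate correctness of the statistics and the extraction logic
under a clean composition-driven model, not robustness to assembly
artifacts beyond the modelled contamination.

# Test and verification design

Every statistic is checked against an independent brute-force
recomputation (explicit loops over codons), RSCU additionally against
`seqinr::uco`, and the correspondence analysis against both a
hand-summed chi-squared and `MASS::corresp`. Property-style tests
cover the RSCU normalisation, the Nc bounds and anchors (61 under
uniform usage — exact because of the cap — and 20 under
one-codon-per-amino-acid usage), the GC identity
$gc = (gc_1+gc_2+gc_3)/3$, extraction frame/coordinate invariants, and
generator parameter recovery on a 15-species GC gradient
(theta 0.55–0.89, 500 genes per species — the problem size chosen for
the checks; mean Nc is required to *rank-correlate* strongly and
negatively with GC3s rather than decrease strictly, since per-species
random preference draws add species-level noise, exactly as real
species panels show). `scripts/acceptance.R` re-derives the headline
quantities from scratch under a caller-supplied seed.

# Known limitations

* CBI/Fop depend entirely on the optimal-codon set; the CA-derived set
  is descriptive (see above) and its `method_tag` should accompany any
  reported value.
* The dinucleotide expectation uses pooled mononucleotide frequencies;
  per-sequence composition heterogeneity inflates apparent deviations
  slightly.
* Only the top HSP per query is used; chimeric transcripts with two
  genuine coding regions contribute one.
* The Nc missing-class rules make per-gene Nc undefined for genes with
  very skewed amino-acid usage; such genes are excluded from means, so
  species with many short or biased genes summarise over a subset.
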