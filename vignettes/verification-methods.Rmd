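---
title: "Verifying a POLLED genome edit: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying a POLLED genome edit: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polledcheck)
```

`polledcheck` verifies a homology-directed-repair (HDR) edit at the bovine
*POLLED* locus: that the intended allele is present and intact, that the
insertion sequence sits nowhere else in the genome, whether donor-plasmid
backbone integrated alongside it, that transmission to offspring is
Mendelian at the genome-wide scale, and how the animals relate to one
another. This vignette explains the underlying models, the tunable
parameters, what the synthetic data emulate (and do not), and the design
choices made where the procedure was genuinely open.

## Allele models of the locus

Three alleles are modelled explicitly. The wild-type horned allele p
carries a 212-bp repeat R immediately followed by a 10-bp segment
(`CTGGTATTCT`). The Celtic *POLLED* allele P~C~ replaces the 10-mer with a
second copy of R, a net gain of 202 bp. The unintended P~C~\* allele
carries, in addition, the full donor-plasmid backbone (~3.9 kb) and a
second copy of the 1.6-kb HDR template adjacent to the edit.

Coordinates are 0-based half-open throughout the package; FASTA, VCF and
BED input/output convert at the boundary. The order and orientation of the
integrated blocks in P~C~\* are not observable from a screen alone, so
`plasmid_integration_spec()` exposes them as parameters with a documented
default (backbone forward, then the template copy, immediately 3′ of the
second repeat copy).

`diff_replacement()` recovers the single replacement event between an
edited allele and its source by longest common prefix/suffix. Because the
repeat's boundary bases can coincide with the replaced segment's
(micro-homology), the recovered event can be shifted by a few bases from
the nominal edit coordinates; junction structure is therefore always
*derived from the sequences at hand*, never hard-coded. In particular, the
short deletion that reads spanning the repeat's 3′ junction show against
the unedited reference is an emergent property of the sequences: 10 bp for
a homology-free synthetic repeat, and potentially longer for real
sequences whose repeat end shares bases with its context.

## Junction signatures and read classification

An error-free read spanning a novel junction of an edited allele shows a
characteristic alignment pattern against the unedited reference:

* reads inside the repeat or over its 5′ junction align perfectly
  (class A);
* reads over the junction between the second repeat copy and the
  downstream flank align full-length with one short deletion (class B);
* reads over the repeat–repeat junction cannot be explained by a single
  gapped alignment and require a split (primary + supplementary)
  placement, while aligning cleanly to the *amended* reference — the
  reference with the insertion introduced (class C).

`derive_junction_signatures()` computes these patterns for any edited
allele by aligning probe reads over each junction, and `classify_reads()`
assigns each baited read a class. The decision logic is: clean full-length
alignment to the reference → A; full-length alignment whose only indel is
a deletion matching a derived signature → B; otherwise, clean full-length
alignment to the amended locus → C; anything else is UNEXPLAINED and
reported with its alignments. A read that is clean on the amended locus
but not on the reference necessarily spans a novel junction (its context
does not exist in the reference), so class C needs no separate span gate.
"Clean" tolerates a configurable mismatch fraction (default 5%) to absorb
sequencing errors without admitting structural differences; reads with
heavier damage at a junction fall out as UNEXPLAINED, which is the
behaviour a reviewer wants surfaced rather than silently absorbed.

Pairwise alignment uses Biostrings' affine-gap implementation with
match +1, mismatch −4, gap open −6, gap extend −1 (configurable via
`align_scoring()`); the split search realigns soft-clipped tails of at
least 20 bp as one supplementary piece, which suffices to resolve a single
novel junction at locus scale.

## Baiting and ectopic-insertion detection

Read selection mirrors the k-mer baiting idea: a read is selected iff it
shares at least one canonical 25-mer with the insertion sequence
(`build_bait_index()`, `bait_reads()`). For error-free stretches this is
exactly the "shares ≥ 25 bp" criterion, deterministic and
orientation-independent; error tolerance is obtained by lowering `k`
rather than by approximate matching.

`detect_ectopic_insertions()` places each baited read genome-wide by exact
k-mer seeding at the read ends and middle (both strands), verifies
candidate placements by local alignment, keeps the best placement per
read, and clusters placements outside the expected window. Clusters with
at least `min_support` reads (default 3) are reported; an empty result
means the insertion sequence is present only at the expected position.
Reads wholly inside the insertion place at the expected locus (the repeat
content exists there), so detection rests on junction-spanning reads whose
flanks anchor them to the ectopic site — which is also why a planted copy
is reported at its flanks within about one read length.

## Plasmid screening and long-read allele assignment

Backbone presence is called from breadth of coverage: baited short reads
are aligned locally to the backbone and `present = breadth ≥ 0.25` by
default — far above the near-zero breadth of spurious hits and far below
the near-1.0 breadth of a real carrier, so the call is insensitive to the
exact threshold. The HDR-template-homologous region must be excised first
(`backbone_without_insert()`), otherwise genome-homologous sequence
inflates breadth.

Long reads are baited with k = 15 and ≥3 hits (15-mers survive a 10%
error rate often enough to anchor a 10-kb read; 25-mers would not), then
assigned to the P~C~ vs P~C~\* models. Whether "support" should require
junction spanning or whole-allele alignment is not observable from the
published description; this package *defines* support by the diagnostic
junctions: a read supports an allele iff it fully spans a junction window
(±500 bp) and its local alignment score there exceeds the other model's
score *for the same read segment* by at least `min_margin` (default 20
score units). Aligning whole 10-kb reads against 16-kb allele models is
quadratic and adds no discriminating information beyond the junctions, so
the junction-window formulation is both the contract and the
implementation. Seed diagonals are clustered before anchoring because a
read spanning the entire insertion has two distinct diagonals against the
shorter model; evaluating each cluster separately prevents a mixed
anchor from extracting the wrong read segment. On a compound heterozygote
the two support counts are binomial-balanced given junction-spanning
coverage; the package asserts calibration (each count within the central
99% binomial range), not any particular realized pair of counts, because
published counts of that kind are single stochastic outcomes.

## Variant QC and trio statistics

The hard-filter engine applies the conventional short-variant thresholds
(QD < 2.0, FS > 60.0, SOR > 4.0, ReadPosRankSum < −8.0, DP > 3,105 for
both types; MQ < 40.0 and MQRankSum < −12.5 for SNPs;
InbreedingCoeff < −0.8 for indels). A missing annotation leaves its rule
unevaluated — the common hard-filtering convention. The DP bound is
interpreted as cohort-summed depth and is configurable, since a per-sample
reading of a 3,105× bound would never fire at ~20× coverage. Site filters
run in a fixed order (multiallelic → genotype rate < 95% → MAF < 5%) with
per-rule exclusion counts, and thresholds are exclusive: a site at exactly
5% MAF is retained.

Mendelian consistency of a trio genotype (s, d, o) in dosage coding is
`o ∈ [ (s==2)+(d==2), (s≥1)+(d≥1) ]`; exactly 12 of the 27 combinations
are errors. Sites with any missing genotype in the trio are skipped — they
are neither errors nor tested — a conservative convention the package
documents rather than inherits silently. The per-variant percentage is
100·errors/denominator; "percentage per individual" is that value divided
by the 3 trio members, the only reading consistent with all twelve
published row pairs. The group comparison is a fixed-effects one-way ANOVA
on the 12 per-trio per-variant percentages (6/3/3), giving df = 2 and 9;
per-family averaging is rejected because it cannot produce those degrees
of freedom. Tukey HSD is the post-hoc convention (flagged as such — the
published analysis does not name one). Zero counts are replaced by 0.5
only in the log2 plotting path, never in statistics.

The windowed scan tiles each contig from 0 in 10-kb bins, excludes bins
with ≤10 errors summed over all offspring, and flags bins whose per-group
rate exceeds 1 error/kb in *all* groups as consistently high.

`expected_error_rate()` is the analytic oracle for parameter recovery: it
sums the exact probability of an observed-inconsistent trio over the 27
true-genotype combinations (HWE parents, Mendelian offspring), each
genotype perturbed by the symmetric single-step error model — adjacent
dosage states at rate ε, direct 0↔2 at ε² — integrated over the allele
frequency distribution by quadrature. The same error model drives the
generator, so recovery tests compare like with like; real genotyping
errors are heterozygote-biased in ways this symmetric model only loosely
matches, which is a documented simulation contract, not a claim about
real data.

## Relatedness

VIF pruning slides a 50-SNP window in 5-SNP steps and recursively removes
the SNP with the highest variance inflation factor
(VIF = 1/(1−R²), R² from regressing the SNP on the other retained SNPs in
the window) until all VIFs are ≤ 2; a site removed anywhere stays removed.
Degenerate windows are handled explicitly: zero-variance sites are left
out of the regression, singular windows use a pseudo-inverse, and exact
collinearity is treated as infinite VIF. One consequence deserves
emphasis: when the window size reaches the sample count the within-window
regression is saturated (R² = 1 for every SNP regardless of true LD), so
pruning at the published settings necessarily removes on the order of half
the sites per window for small cohorts. That is a property of the VIF
definition, not of this implementation; the package's
independence-retention test therefore runs in the regime where the
statistic is well-posed (window ≪ samples).

The 1−IBS distance for a pair is `1 − Σ(2−|g_i−g_j|)/(2M)` over co-called
sites (heterozygote pairs count as IBS 2, the standard state definition).
Dendrograms default to average-linkage (UPGMA) clustering with neighbor
joining behind a flag: the published figure names only the plotting
package, not the tree algorithm, so the package picks a deterministic,
documented default rather than guessing, and orders samples
lexicographically before clustering so tied merges resolve identically
across platforms. Newick export carries 6-decimal branch lengths.

## The synthetic-data generator

The generator's defaults are the study conditions: 2×150-bp paired reads
at 20× with insert 400 ± 60 bp; long reads at 14× with log-normal lengths
around 10 kb and 10% error (60/20/20 substitution/insertion/deletion);
twelve trios in three groups (6/3/3) across four families with shared
sires; allele frequencies uniform on [0.05, 0.95]; genotyping error
ε = 0.005 with 0.2% missingness (matching a 99.8% genotyping rate).
Hotspot bins multiply ε by 50 where planted. Parents default to a single
panmictic population (flat HWE, as the generator contract states); an
optional Balding–Nichols `family_fst` parameter adds family/breed-level
differentiation, and the family-clustering property test sets it to 0.15 —
cattle-breed-scale divergence — because unrelated dams drawn from one
population cannot form family-connected subtrees, whereas the real cohort
comprised distinct breeds. The 212-bp repeat and the plasmid backbone are
random sequences by default (their real sequences are not published);
hooks accept real sequences where a user has them.

Everything is reproducible from `(seed, config)` alone, and ground truth
(read origins, pre-error genotypes, planted hotspots and ectopic copies)
is returned alongside every output so detectors are scored exactly.

What the synthetic data do *not* emulate: reference bias, indel errors in
short reads, chimeric long reads, PCR duplicates, quality-score structure,
linkage disequilibrium beyond family structure, and real repeat content
around the locus. Passing tests therefore demonstrate that the procedures
are correct under their stated models, not that real cattle genomes hold
no surprises.

## Problem sizes and numerical choices

The test suite exercises the pipeline at desk scale, chosen as the
package's own test design: insertion stability on a 1-Mb genome at 20×
(clean and with a planted ectopic copy); backbone screening across 20
plasmid-free 60-kb simulations plus one carrier; long-read assignment on a
60-kb compound heterozygote at 14× and 10% error; parameter recovery at
ε ∈ {0.002, 0.005} over 10⁵ sites. Genome-scale quantities from the real
cohort (raw and trusted variant counts, the 4,438 error-prone bins, the
171 consistently-high regions, the second and third published F
statistics, and the published 8-vs-12 long-read counts) depend on the full
cattle genome and that cohort's data and are deliberately out of numeric
scope; the corresponding procedures are covered by the property suite
instead.

Other numerical choices: alignment "cleanliness" tolerates 5% mismatches
and no indels or clips; deletion signatures match within ±2 bp; ectopic
clusters are single-linkage within two read lengths; the in-silico PCR
default is exact primer matching (mismatches opt-in, and never in the
3′-terminal 3 bases when anchored) because a presence/absence screen wants
determinism; multiple PCR products are all reported, since band-pattern
genotyping needs the full set.
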