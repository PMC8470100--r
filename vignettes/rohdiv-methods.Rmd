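---
title: "Methods: ROH, islands, inbreeding, structure and Ne in rohdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH, islands, inbreeding, structure and Ne in rohdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdiv)
```

`rohdiv` characterises genomic diversity in small, closed populations —
heritage livestock and poultry breeds genotyped on dense SNP arrays — with
runs of homozygosity (ROH) at its core. This vignette is the package's own
account of the statistical machinery: what each method assumes, which
parameters matter, how the bundled simulator is built, and where the design
was genuinely open.

## Genotype panels and quality control

All analyses operate on a `genotype_panel`: a samples × SNPs matrix of
B-allele counts (0 = homozygous A, 1 = heterozygous, 2 = homozygous B,
−1 = missing), a marker map sorted by `(chrom, pos_bp)`, and one population
label per sample. Coordinates are 1-based inclusive base pairs throughout;
only BED export converts to the 0-based half-open convention. PLINK text
PED/MAP is the interchange format; when no allele reference is supplied, the
A allele of each marker is the first allele encountered in file order. Every
downstream statistic is invariant to that orientation (tested by flipping
markers), so the arbitrary choice is harmless.

`qc_filter()` retains autosomal SNPs (`chrom` ≤ 30 by default, matching
avian assemblies where the first 30 chromosomes are autosomes on the array)
with per-SNP call rate **strictly greater** than the threshold (default
0.99). A call rate tied at exactly the threshold is removed: the filter is a
literal "> 99%". The filter is one joint pass over the combined panel; when
per-population marker counts are reported downstream they may differ
slightly from the joint count because monomorphic-within-breed markers
remain in the panel (a per-breed secondary filter is deliberately not
applied, since there is no principled rule for one).

## Consecutive-run ROH detection

`detect_roh()` implements the consecutive-run (scanning) method rather than
PLINK's sliding-window heuristic. Per chromosome, a run grows over
consecutive homozygous SNPs and terminates at:

* a heterozygous call, once the allowance `max_het` (default **0**) is used;
* a missing call, once `max_missing` (default **0**) is used;
* a gap between consecutive SNPs larger than `max_gap_bp` (default
  **1,000 kb**) — a gap splits the run but does not disqualify its flanks.

A terminated run is reported iff it has at least `min_snps` homozygous
members (default **150**) *and* spans at least `min_length_bp` (default
**1 Mb**). The length of a segment is `end_bp − start_bp + 1` with
boundaries at the first and last member SNP — not midpoints to flanking
SNPs — so reported intervals are exactly the SNP positions that constitute
the run, and the same length is used for the minimum-length test (a run of
≥150 SNPs spanning <1 Mb is rejected). The defaults suppress short
LD-induced homozygous stretches and target genuine autozygosity; on arrays
of different density the `min_snps`/`min_length_bp` pair should be rescaled
to the panel's SNP spacing.

With the default zero allowances the scan output coincides with the set of
*maximal* all-homozygous, gap-bounded intervals, and the test suite verifies
exact equality against an exhaustive interval-enumeration oracle on random
panels. With positive allowances "maximal valid interval" is no longer
unique (overlapping candidates can absorb different heterozygotes); the
implementation then follows a greedy left-to-right contract — absorbed calls
are interior only, runs start and end on homozygous SNPs — which is
documented behaviour rather than oracle-tested equivalence.

Summaries (`summarize_roh()`) report, per population: total segment count,
per-animal count range/mean/SD, length range/mean, mean summed coverage in
bp and as a percent of the genome, and counts in the canonical length
classes 1–2, 2–4, 4–8, 8–16 Mb (left-closed, right-open, with a `16+`
overflow class; a segment of exactly 2 Mb belongs to 2–4).

## ROH islands and incidence

The per-SNP incidence track counts, for each marker, the samples with at
least one ROH covering its position — the Manhattan-plot quantity used for
homozygosity mapping.

An ROH *island* is, by default, an **exact-boundary** cluster: segments are
grouped by identical `(chrom, start_bp, end_bp)` and a group is an island
when at least `sharing_threshold(n, fraction)` distinct samples carry it,
with `fraction` defaulting to 0.75. The threshold is the smallest integer ≥
`fraction × n` (ceiling — e.g. 136 of 181 at 75%, 15 of 25 at 60%), with a
small numeric guard so that products like `0.6 × 25` do not ceiling up
through floating-point excess. Exact-boundary sharing is a strong criterion
that only consecutive-run detection makes meaningful (all carriers stop at
the same SNPs); an incidence-based caller — maximal runs of SNPs whose
incidence fraction reaches the threshold — is available via
`find_islands(method = "incidence")` for analyses in the mapping style.
Exact sharing implies incidence sharing at every interior SNP; the converse
does not hold, and both directions are asserted in the tests.

Cross-population sharing (`cross_breed_sharing()`) merges islands from
different populations transitively on ≥1 bp overlap and reports union
boundaries — the merge rule is a design choice (union rather than
intersection) made because a shared selection signature is better summarised
by its full extent.

Gene annotation (`annotate_islands()`) is a pure interval intersection with
1-based inclusive arithmetic and a ≥1 bp overlap rule, equivalent to
`bedtools intersect` on the exported BED (verified against `bedtools` in the
test suite). A gene abutting an island at `end_bp + 1` is *not* reported.

## Inbreeding coefficients

`f_roh()` computes, per sample,
\[
F_{ROH} = \frac{\sum_{\text{segments}} \text{length}_{bp}}{L_{auto}},
\]
with \(L_{auto}\) defaulting to 902,020,024 bp — the autosomal length
covered by a ~650K turkey SNP panel; set it to your own panel's covered
length for other species/arrays.

`f_hom()` is the method-of-moments excess-homozygosity estimator
\[
F_{HOM} = \frac{O - E}{L - E},
\]
where \(O\) is the observed homozygous count over the sample's typed SNPs,
\(L\) the typed count, and
\(E = \sum_{snps} \left[1 - 2\hat p\hat q\,\frac{n_{al}}{n_{al}-1}\right]\)
the Hardy–Weinberg expectation from within-population frequencies with the
small-sample correction (\(n_{al}\) = non-missing allele observations at the
SNP). SNPs with fewer than two allele observations are excluded from both
\(O\) and \(E\); frequencies use non-missing calls only, no pseudo-counts.
\(F_{HOM}\) is legitimately negative for samples less homozygous than
expectation and is never clamped; population means can be negative. In a
drift-free Hardy–Weinberg population its mean is ~0 (tested by simulation).

The per-population diversity table reports the *mean per-individual*
observed homozygous SNP count and its expectation \(\sum(1-2\hat p\hat q\,
n_{al}/(n_{al}-1))\). These definitions make the table internally
consistent: observed homozygous count ≈ `n_snps × (1 − obs_het)` and the
expected count pairs with the \(E\) used by \(F_{HOM}\). (An alternative
reading — "number of SNPs with zero heterozygous calls" — was considered and
rejected because it is not arithmetically consistent with the mean
heterozygosities such tables print.)

`froh_vs_fhom()` fits the ordinary least-squares regression of \(F_{HOM}\)
on \(F_{ROH}\) per population and reports the Pearson correlation; on
simulated inbred lines the two coefficients correlate strongly (tested).

## Population structure

*F*~ST~ uses the Weir & Cockerham (1984) two-population method-of-moments
estimator as a **ratio of sums** over SNPs,
\(\hat F_{ST} = \sum_l a_l / \sum_l (a_l + b_l + c_l)\), skipping SNPs
monomorphic across the pooled pair. The ratio-of-sums form (rather than
averaging per-SNP ratios) is the standard multi-locus choice because per-SNP
ratios are noisy and biased at low MAF. Hudson's estimator is available via
`estimator = "hudson"`. The estimator is symmetric in the two populations
and invariant to allele-label swaps (both tested). Under the Balding–Nichols
model — breed frequencies Beta-distributed around an ancestral frequency
with parameter θ — the multi-locus estimate recovers θ (tested at θ = 0.05,
0.2, 0.5).

Identity-by-state distance between two samples is `1 − mean(s)/2` over SNPs
non-missing in both, with `s = 2 − |g_i − g_j|` shared alleles; it is a
pseudo-metric (zero diagonal, symmetric) but not necessarily triangular.
Neighbour-joining on that matrix uses the Saitou–Nei agglomeration (via
`ape::nj`), with negative branch lengths — possible on non-additive input —
clamped to zero and flagged. On additive matrices NJ is exact: topology and
branch lengths are recovered to numerical precision (tested on random 5–8
taxon trees).

PCA mean-centres genotypes per SNP, imputes missing calls to the SNP mean
(the standard choice for genotype PCA: it is variance-neutral per SNP), and
takes the SVD; Patterson scaling \(1/\sqrt{\hat p(1-\hat p)}\) is optional.
Eigenvalues are those of the sample covariance; percent variance is
eigenvalue over the sum of all non-trivial eigenvalues.

## Effective population size from LD

`pairwise_r2()` computes squared Pearson correlations of genotype codes for
intra-chromosomal pairs within a distance cap, over samples non-missing at
both SNPs; monomorphic SNPs are skipped. `estimate_ne()` bins pairs by
distance, maps distance to recombination fraction (linear
`c = rate × bp` by default with rate 1e−8 M/bp ≈ 1 cM/Mb; Haldane and
Sved–Feldman mappings available), adjusts each bin's mean r² for finite
sample size (−1/(2n) for unphased genotypes, −1/n phased), and inverts
Sved's expectation \(E[r^2] = 1/(\alpha + 4N_ec)\):
\[
\hat N_e(\text{bin}) = \frac{1}{4\bar c}\left(\frac{1}{\bar r^2_{adj}} -
\alpha\right), \qquad t = \frac{1}{2\bar c} \text{ generations ago.}
\]
α = 2 (mutation accounted) is the default for empirical panels; α = 1 is
appropriate for mutation-free simulations and is what the package's own
validation uses. The default 30 log-spaced bins over 50 kb–5 Mb span roughly
10–1000 generations at 1 cM/Mb. Bins whose adjusted r² is non-positive or
not invertible are dropped with a warning. Two caveats are inherent to the
method: estimates at times deeper than the population's history reflect
founder linkage equilibrium, not demography; and the recombination-rate map
linearly rescales both axes (doubling the rate halves every `t` and rescales
Ne — tested as a covariance property).

## The forward-time simulator

`simulate_breeds()` provides ground truth, emulating multi-breed SNP panels
in three layers:

1. **Breed divergence** — ancestral frequencies uniform on [0.05, 0.5];
   per-breed frequencies Balding–Nichols Beta draws with parameter
   `theta_fst`, so expected pairwise F~ST~ equals θ.
2. **Breeding** — discrete generations of random mating among monogamous
   pairs, selfing forbidden, no sexes; a bottleneck schedule sets the
   population size from a given generation onward. Gametes recombine with
   Poisson(`recomb_rate × chrom_length`) crossovers at half-integer
   positions (so a crossover never coincides with an integer SNP position
   and allele phase and ancestry use the same partition).
3. **Truth tracking** — every haplotype carries its founder-haplotype
   ancestry as a breakpoint list. A sample is autozygous wherever its two
   haplotypes copy the same founder haplotype; inside such a segment every
   SNP genotype is homozygous *by construction* (asserted on every
   simulation). Segments spanning fewer than two SNPs are omitted from the
   segment table — no marker-based method could see them — but still count
   toward the realized autozygous fraction. Pedigree inbreeding is computed
   exactly by the tabular kinship method; at population size 2 the mating
   system is a full-sib line and the pedigree F follows the classical
   recursion \(F_t = (1 + 2F_{t-1} + F_{t-2})/4\) (first bred generation
   F = 0; ten rounds give F = 0.859375, which the simulator reproduces
   exactly).

What the simulator does **not** emulate: mutation, selection, sex
chromosomes, a realistic species genetic map, genotyping error beyond the
optional uniform `add_genotyping_noise()` layers, and array ascertainment
bias. Consequently, passing recovery tests demonstrates the estimators'
internal correctness under drift, bottlenecks and recombination — not
robustness to array design or call-quality artefacts of real data.

## Validation problem sizes

The packaged validation suites run at deliberately modest sizes chosen to
exercise every code path while keeping the default test run fast: ROH oracle
equivalence on 100 random panels of ≤800 SNPs × ≤12 samples with relaxed
thresholds; 50 full-sib lines (N = 2, 10 generations, 3 × 100 Mb
chromosomes, 1,500 SNPs each, ROH thresholds rescaled to the ~66 kb marker
spacing: `min_snps = 10`, `min_length_bp = 1 Mb`) for the
F~ROH~-vs-pedigree-F comparison; 20 replicates × 5,000 SNPs × 2 × 25
samples per θ for F~ST~ recovery; 8 drift replicates (N = 50, 30
generations, 1,200 SNPs on 100 Mb) for Ne recovery with bins spanning
2.5–25 Mb (t ≈ 2–20 generations, safely inside the simulated history); 50
random additive trees for NJ.

## Known limitations

* Exact-boundary islands are sensitive to any genotyping error at boundary
  SNPs; the incidence-based caller is more forgiving and recommended when
  error rates are non-trivial.
* F~ST~ and F~HOM~ assume within-population sampling of unrelated-ish
  individuals; strong family structure inflates both.
* The Ne trajectory's absolute scale depends on the assumed recombination
  map; with the default uniform 1 cM/Mb the *shape* is more trustworthy
  than the values.
* The pipeline treats every population label as a breed; mislabeled samples
  propagate to every per-population statistic.
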