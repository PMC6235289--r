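---
title: "Models and methods behind micdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind micdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`micdiv` analyzes per-locus allele tables from deep amplicon sequencing of a
microbial population: at each ~400-bp locus, a set of denoised allele
sequences with read counts, usually anchored to one or two reference
genomes. This vignette documents the models implemented, the parameters
that matter, the synthetic-data generator used to validate every stage, and
the numerical and design choices made where more than one reasonable
construction exists.

## Data model and coordinates

Allele sequences are stored projected onto the reference coordinate frame
of their locus: all sequences at a locus have length L, deletions relative
to the reference appear as `-`, and insertions are dropped. This matches
reference-anchored analyses in which the coding frame of a genome is
enforced: columns exist only where the reference carries a base.
Coordinates are 0-based half-open internally (coding intervals) and
1-based in all reports — the unambiguous-slicing convention. The "most
abundant allele" is defined with ties broken by the lexicographically
smallest sequence, so every downstream statistic is deterministic.

Codon-aware alignment (`codon_align`) pairs reference and allele codons
over the designated coding interval; a codon in which the allele carries an
indel is gapped out completely (an `NA` sentinel in both lists — never a
`-` character inside a codon string), and the remaining codons stay in the
reference frame. This deliberately suppresses amino-acid distances of
indel-rich alleles; it is the price of robustness against frame loss when
coding indels are dominated by sequencing error.

The homology screen (`screen_nonhomologous`) removes alleles below a
gap-free column identity of 0.5 to both reference homologs. It replaces a
BLAST-based screen with an alignment-free criterion on already-anchored
sequences: same intent, no external binary. It will not reproduce the
composition of a database-wide screen (e.g. insertion-sequence detection),
only the "clearly not this locus" class.

## Coalescent simulator

The simulator is the package's null-model engine and the source of all
synthetic data.

**Rate conventions.** Time is scaled so each pair of lineages coalesces at
rate 1 (expected pairwise TMRCA 1). Mutations occur at rate θ/2 per site
per unit time at mutational equilibrium, so the expected pairwise diversity
per site is θ — matching the empirical usage π ≈ θ. Recombination
breakpoints fall on integer boundaries interior to a lineage's ancestral
span at rate ρ/2 per boundary per lineage, so the expected number of
breakpoints separating a random pair is ρ per boundary and the total scaled
rate is ρ(L−1) ≈ ρL. These conventions differ from the 4N scaling of
classical simulators and are stated here because every parameter below
depends on them.

**Genealogies.** With ρ = 0 a plain Kingman sampler is used; with ρ > 0 the
Hudson ancestral recombination graph over the discrete L-site interval,
with per-site ancestral material tracked per lineage and sites retired as
they reach their marginal MRCA. The two samplers are cross-checked against
each other at ρ = 0 (two-sample KS on pairwise differences) — a dual-route
guard against errors in the much more intricate ARG bookkeeping. Above
2000 leaves the ARG subsamples with a warning: cost grows steeply while the
reported statistics are insensitive at these depths.

**Mutation overlay.** Kimura two-parameter with transition/transversion
ratio κ: a mutation event is a transition with probability κ/(κ+1) (at
gc_bias = 1), so observed transition:transversion counts converge to κ:1.
This is the parameterization under which "ti/tv = 10" means what it says at
the count level. GC bias multiplies all rates into {G,C} by β, giving a
reversible chain with stationary GC fraction β/(1+β) (β = 2.5 gives ≈ 71%
GC, the regime relevant for thermophile synonymous sites). The
state-dependent process is simulated exactly by uniformization against the
fastest per-base rate, and mutations are applied oldest-first so each event
sees the current base of its whole descendant leaf set. Note one
finite-sites consequence: at θ = 0.02 and κ = 10, transition saturation
makes the exact expected pairwise distance ≈ 3.5% below the infinite-sites
value θL; the tests account for this with the closed-form K2P expectation
rather than pretending the bias away.

**Asexual frequency null.** The gamma construction: K = 5000 gamma(θL/K, 1)
variables, normalized and sorted, approximate the Poisson–Dirichlet allele
frequency spectrum of the neutral infinite-alleles model. Its
heterozygosity moment 1 − (θL/K + 1)/(θL + 1) is a closed-form test anchor,
and the construction is cross-validated against explicit Kingman simulation
on the top-allele frequency distribution.

## Synthetic-data generator

The generator's defaults are the study conditions the analyses target:
θ = 0.02/site, L = 400 bp, κ = 10, ρ ∈ {0, 0.035, 0.1}/site, read depths
300–4000, GC bias β = 2.5 where composition matters, target d_n/d_s = 0.12,
and a 454-style error overlay with 0.63 substitution errors per read
(10:1 transition-weighted), a coding indel-error profile a·exp(b·pos)
solved so the per-site rate is 1% at position 400 with a read-average of
0.5%, and a constant intergenic indel rate.

**d_n/d_s thinning.** Candidate mutations in coding sequence are classified
against the current codon of their descendant leaf set; non-synonymous
candidates are accepted with probability q. q is solved from the target
ratio using the counting-method site definitions on the ancestral codon
composition — so the generator's dial and the estimator's scale agree by
construction, and a 10% calibration check on ≥10^5 codon comparisons holds
without per-run tuning. Thinning reduces realized coding diversity below
θ; the generator reports its bookkeeping (candidates by class, q) so both
raw and realized rates are visible.

**What it does not emulate.** PCR chimeras, flowgram-level 454 noise,
selection beyond the non-synonymous thinning, gene conversion, demography.
Passing tests therefore demonstrate correctness of the statistics under
neutral/recombinant drift with i.i.d. errors — not that real amplicon data
meet those assumptions.

## Site classification and frequency spectra

Site classes follow the reference-anchored construction: columns where the
reference carries a base; second codon positions as the always-non-synonymous
class; third positions as synonymous, provided the most common amino acid at
the codon (read-weighted) is not M, W, or Stop, with counts restricted to
alleles encoding that amino acid; first positions of L/R/S codons as a
supplementary synonymous class; everything outside coding intervals as
intergenic. Polymorphic sites are reduced to *transition dimorphs* —
exactly two variants forming A/G or C/T — polarized by f_A/T, which is
always well-defined (each transition pairs one A/T with one G/C nucleotide)
and strand-symmetric.

Spectra use ℓ = log[f/(1−f)] with *natural* logarithm and unit bins at
integer edges: under that choice the neutral density is flat and equal to
θ/2 at ℓ = 0, which the implementation verifies against its own
beta-binomial expectation. Depth conditioning divides each bin's count by
(bin width in f) × (number of sites with R above the reciprocal of the
bin's smaller minor-frequency edge); the eligibility rule is idempotent —
removing sites too shallow for a bin does not change that bin. The
minor-frequency binning uses powers of 2 from 1/2 down past 10^−3.

One intrinsic feature worth knowing: restricting third-site counts to
alleles encoding the most common amino acid removes rare variants that ride
on amino-acid-changing alleles (e.g. an ATA codon whose third-site A→G
transition creates Met), mildly depleting the rare tail of the synonymous
SFS relative to a naive all-alleles count. Comparisons against the
beta-binomial expectation therefore calibrate θ from the measured
synonymous transition heterozygosity — the same calibration used for real
data — rather than from the simulation input.

## d_n/d_s estimators

The counting method uses Nei–Gojobori site counts (synonymous site
fractions per codon, averaged over the two sequences), pathway-averaged
substitution counts for multi-difference codons, and the Jukes–Cantor
multiple-hit correction; proportions at or beyond 3/4 are reported as
missing, never clipped, and ratios with d_s = 0 are missing, never
infinite. The internal method divides observed synonymous and
non-synonymous codon-difference counts by their expectation under pure
i.i.d. errors, computed by exact enumeration of single-base errors weighted
by the λ matrix with the two-error codon term included at second order.
The single-coalescence-time model treats each unit (four-fold-degenerate
codon, or amino-acid site) as mutated independently with one shared
probability; the MLE is the pooled fraction Σc/Σm — invariant under merging
loci — and expected histograms are exact binomial mixtures (the binomial,
not Poisson, likelihood is primary; the MLE is identical).

## Linkage statistics

Haplotype labels follow the deleterious-pair interpretation: A and B are
the major variants, so ab is the doubly-minor haplotype; "fully linked"
means only AB and ab observed, "ab-absent" exactly the other three.
Fixed-site pairs take r² = 0 by convention. The joint-frequency-matched
downsampling bins (f_a, f_b) in logarithmic decade-thirds (unordered pair
of bins); the binning is a parameter because no canonical choice exists,
and each draw reproduces the target histogram exactly while inheriting only
the synonymous pairs' conditional haplotype structure. Pairs are formed
within loci only, consistent with 400-bp amplicons.

## False-negative mixture

Within each (n reads, d coding substitutions) cell, counts s_i (i of the d
substitutions synonymous) are modeled as x·Binom(i; d, p_S) errors plus
r·Binom(i; d, q) genuine alleles, with q = p_S/(p_S + dnds·(1−p_S)) implied
by the internal-method definition of the assumed biological d_n/d_s. The
d = 1 system is solved exactly; d ≥ 2 cells by a closed-form two-variable
non-negative least squares (deterministic, seedless). Components are
clipped to [0, s_i] with re-attribution so x + r = s holds element-wise.
The degenerate case dnds = 1 (q = p_S) makes the two shapes identical; the
solver refuses it explicitly rather than returning an arbitrary split.
Clipping at zero produces a small positive bias in strata whose per-cell
expected counts are comparable to their sampling noise; recovery tests
therefore run at realistic stratum magnitudes (tens of thousands of
singleton putative errors), where the bias is negligible.

## Numerical choices and problem sizes

Frequencies renormalize to 1 within 1e−9 after any screen. Distance
spectra include self-pairs (weight f_i²) by default so identical draws
contribute mass at zero — the frequency-weighted-random-alleles reading —
with a flag for sensitivity analysis. Percentile bands use linear
interpolation (type-7 quantiles). The test suite and acceptance script use
deliberately modest problem sizes — e.g. 400–500 simulated loci at depth
100 for distance spectra, 60 loci at depth 1000 for the SFS comparison,
10^4 error reads for the pure-error d_n/d_s check, 100 seeds for
false-negative recovery — chosen so Monte-Carlo error is several times
smaller than each tolerance being asserted.

## Known limitations

* The ARG is quadratic-ish in leaves in plain R; above 2000 leaves it
  subsamples (with a warning) rather than pretending to scale.
* The identity-based homology screen is a stand-in for database-wide
  screening and inherits none of its taxonomy.
* The internal d_n/d_s's error normalization treats λ as known; in real
  pipelines λ is estimated by the denoiser and its uncertainty is not
  propagated.
* Reference-projected storage cannot represent insertions relative to the
  reference; indel diversity beyond the reference frame is out of reach by
  design.
* No selection, demography, or gene conversion in the simulator beyond
  non-synonymous thinning; nulls are therefore drift/recombination nulls.
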