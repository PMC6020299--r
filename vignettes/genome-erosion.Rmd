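---
title: "Diagnosing transposon-driven genome erosion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing transposon-driven genome erosion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`luxerode` packages the comparative-genomics analyses used to diagnose a
bacterial genome caught mid-reduction: a host-restricted symbiont whose
genome is shrinking through gene deletion and pseudogenization while a
handful of insertion-sequence (IS) families proliferate and decay. This
vignette explains each model, its assumptions and tunable parameters, the
numerical choices, what the synthetic generator does and does not
emulate, and the known limitations.

## The pseudogene rule

Every CDS is translated (to the first stop codon; a count of
internal-stop translations is reported) and compared against a reference
proteome with the package's affine-gap dynamic-programming aligner.
A locus is called a **possible pseudogene** when, relative to its
best-scoring hit,

- `length_ratio = query aa length / subject aa length < 0.60`, **or**
- `similarity_frac = positives / aligned columns < 0.30`,

with strict inequalities: a locus at exactly 60% length is functional.
Both ratios use full protein lengths, not aligned spans — the rule
targets truncated loci, and a truncated locus keeps near-perfect
similarity over the part that survives while its full-length ratio
collapses. Similarity counts aligned residue pairs with a positive
BLOSUM62 score (the "positives" convention); `X` scores zero. Loci whose
best score falls below `min_score = 50` are **orphans**, not
pseudogenes: the rule needs a reference to compare against. Defaults are
BLOSUM62, gap open 11, gap extend 1, local mode — all configurable.

For large proteomes `best_hit()` shortlists candidates by shared
4-mers (a seeded-search heuristic in the BLAST tradition) before exact
dynamic programming; with no index the scan is exhaustive and provably
returns the score optimum.

## Intra-sample diversity

From a per-site pileup (contig, pos, ref, depth, A, C, G, T) the
package computes `alt_freq = (depth − ref_count) / depth` — all
non-reference reads — and the majority alternate base (ties broken
A < C < G < T). Sites with a nonzero alternate frequency are partitioned
by two thresholds: below `f_err = 0.0005` (0.05% of the per-site depth)
is *error-like*, above `f_poly = 0.01` (1%) is *polymorphic*, between is
*intermediate*. The polymorphism rate is `1000 · n_polymorphic / genome
length`; a callable-length denominator is available by passing that
length instead.

**A deliberate, documented tension:** the error-like threshold is
defined per site against the per-site depth. At any depth below 2,000×,
a single alternate read already exceeds 0.05%, so no site with a nonzero
alternate count can be error-like, and `frac_error_like` is essentially
zero whenever coverage is moderate. The implementation keeps the literal
per-site definition because it is the stated form of the thresholds this
package implements; users who want the error floor quantified at modest
coverage should read the spectrum (`alt_frequency_spectrum()`), whose
log-spaced bins show the error mass concentrated at the lowest observable
frequencies regardless of where the fixed threshold falls. The
package's own acceptance checks report this honestly: on synthetic data
at 1,000× with a 10⁻³ error rate, the planted-polymorphism rate is
recovered exactly while `frac_error_like` stays near zero.

## Clock models and the likelihood-ratio test

Likelihoods come from Felsenstein pruning over compressed site patterns
(identical columns computed once and weighted) with per-node rescaling,
under reversible substitution models: Jukes-Cantor, GTR, an equal-rate
amino-acid model, or a custom symmetric exchangeability matrix (a
PAML-dialect reader is provided); optional discrete-gamma rate
heterogeneity uses K equal-weight categories with mean-of-bin rates.
The rate matrix is scaled to one expected substitution per unit time and
exponentiated through the symmetric eigendecomposition of
`diag(π)^{1/2} Q diag(π)^{−1/2}`, which stays well conditioned at the
branch-duration floor of 10⁻⁹.

The **null model** is a strict global clock: node times on an
ultrametric tree (root fixed at 1 — the scale is absorbed by the
background rate `b`) with branch length = duration × b. The
**alternative** adds exactly one parameter: a multiplier `r` (bounded
below at 10⁻³) on every branch of a designated monophyletic foreground
clade, including its stem branch by default — the stem carries most of
the separation signal (`include_stem = FALSE` is available). Models are
compared by `LR = 2(lnL_A − lnL_0)` (floored at 0) against the χ² upper
tail with df equal to the one extra parameter. Substitution-model
parameters are supplied by the caller and held fixed across both fits,
which is what keeps df at 1.

Optimisation is quasi-Newton (L-BFGS-B) on transformed parameters —
logit of each node-time proportion `t_child/t_parent`, log b, log r —
from a deterministic initialisation (subtree-size-based times, a
distance-based rate guess), with optional jittered restarts. The
local-clock fit is initialised at the global-clock optimum with r = 1,
so monotone descent guarantees the nesting inequality `lnL_A ≥ lnL_0`;
a violation raises an error rather than returning a negative LR.
Convergence is the optimiser's own gradient/step criterion; the
`converged` flag is honest and `glance()` exposes it.

Two identifiability cases are handled explicitly. A foreground covering
all taxa leaves only `r·b` identifiable — the fit proceeds with a
warning. Less obviously, a foreground clade **whose stem parent is the
root** is nearly unidentifiable on its own: the global clock can absorb
the clade's acceleration by stretching the clade's node times toward the
root. The demonstration and acceptance analyses therefore accelerate a
nested clade; users testing a root-child clade should expect reduced
power and interpret r̂ cautiously.

## TE census and burst detection

Family assignment aligns each CDS against a transposase reference set
(one representative per family) and assigns the best-scoring family when
identity ≥ 0.3 over aligned columns, reference coverage ≥ 0.3, and the
alignment score ≥ 100. The score floor exists because long, meandering
local alignments of unrelated proteins occasionally satisfy the identity
and coverage fractions by chance while scoring an order of magnitude
below genuine family members. Decayed copies are rarely in frame and
often carry premature stops, so when given a genome the classifier
scores the three forward-frame conceptual translations (stops kept as
`X`) and keeps the best; the winning translation is returned in the
records for downstream phylogenetics. The shared-k-mer prefilter uses
k = 4 here and falls back to an exhaustive scan over the (small)
reference set when no k-mer is shared — family members diverged to ~45%
identity can lose every exact 5-mer by chance.

A copy is **complete** iff its aligned fraction of the reference is
≥ 0.9 *and* terminal inverted repeats are present — the conjunction of
the two decay signatures (truncation, lost IRs). IRs are sought within a
100-bp window at each element end: the longest pair (u, reverse
complement of v) with ≤ 2 mismatches and length ≥ 10, found by exact
search (verified against quadratic brute force in the tests).

**Insertion-free regions** are maximal intervals ≥ 20 kb between
consecutive TE features (and contig ends), annotated with the functional
genes they contain; in a genome riddled with insertions they mark gene
clusters under selection.

**Burst detection** builds a neighbor-joining tree (own implementation;
negative branches clamped to zero with the deficit moved to the sister,
exact on additive matrices) over one family's copies plus outgroup
transposases, from Poisson-corrected protein distances
`d = −ln(1 − p)` (p = mismatch fraction over aligned columns, saturated
distances capped at 10). Rooted on an outgroup tip, the report gives the
copies' monophyly, the stem length under their MRCA, the mean crown
depth, and `burst_ratio = stem / crown`. Verdicts: *single_expansion*
iff the copies are monophyletic with ratio ≥ 3; *multiple_expansions*
iff they split into ≥ 2 maximal clades (each ≥ 2 copies) with ratio ≥ 3;
otherwise *no_expansion*. The ratio threshold of 3 is a calibrated
default chosen so uniform-rate (non-burst) evolution rarely mimics a
stem three times the crown depth; it is exposed as `ratio_single`.
Trees should be built from near-full-length copies: two fragments from
opposite ends of an element share no alignable columns, and their
pairwise "distance" is meaningless — the demonstration uses copies ≥ 80%
of the reference length. NJ was chosen over ML deliberately: the burst
statistic needs branch-length geometry, not model-based support values,
and NJ keeps the module self-contained and exactly testable against
additive matrices.

## Reduction metrics

Orthologs are reciprocal best hits by protein alignment score;
nucleotide identity is computed by back-mapping each aligned residue
pair to its codons (three nucleotide comparisons per aligned column).
ANI is the length-weighted mean of per-pair identities (unweighted mean
behind a flag). Percent reduction is `100 (1 − target/reference)`,
signed. Category counts let one gene contribute to several categories;
pathway completeness requires every enzyme label to match at least one
*functional* gene — an enzyme surviving only as a pseudogene does not
count. A small synthetic amino-acid-pathway fixture ships in
`inst/extdata/` as an editable template.

## The synthetic generator: what it does and does not emulate

`simulate_ancestor()` builds clean ORF genes (start codon, stop codon,
no internal stops) with i.i.d. base composition at a target GC,
Poisson-length genes and spacers, per-gene category tags and an optional
single-category cluster. `degrade_genome()` applies per-gene fates
(deleted / pseudogenized / retained — an exact partition recorded in the
truth), truncates pseudogenes at a recorded point (uniform surviving
fraction, default 0.2–0.45 so calls are clear-cut), inserts TE bursts
with a 4-nt target-site duplication, and decays each copy by point
substitutions and optional one-ended truncation. A configurable fraction
of pseudogenizations is caused by a TE inserting at the truncation
point. Genes carrying a protected category are kept intact and their
cluster receives no insertions — the within-genome footprint of
purifying selection. Each burst can diverge its founder element once
(`founder_sub_rate`, stop-free within the ORF) before copying: this is
what produces the long stem separating a genome's copies from database
representatives, and without it a burst is geometrically indistinguishable
from the reference radiating in place. `simulate_alignment()` evolves
i.i.d. sites under a reversible model with a foreground multiplier;
`simulate_pileup()` draws Poisson depths, binomial error counts
(rate/3 per non-reference base) and binomial alternate reads at planted
polymorphic sites. Everything is deterministic under its seed, with
seeds recorded in the truth.

Not emulated: read-level errors and mapping artefacts (the pileup is
generated, not aligned), recombination, codon-aware selection (decay
substitutions ignore reading frame — the pseudogene rule works on
protein alignment ratios, not frame logic), multi-contig assemblies
(one contig per ancestor), composite transposons, and realistic
intergenic architecture. Passing the recovery tests therefore shows the
*algorithms* are correct under their stated models, not that real
annotation noise (RAST miscalls, chimeric assemblies, UniRef version
drift) is handled; published pseudogene counts and between-species ANI
depend on those externals and are out of desk scope.

## Problem sizes and reproducibility

The bundled demonstration (`demo_synthetic()`) uses a 1,000-gene
ancestor (~1 Mb), 30% pseudogenization with truncations below 50%, a
200-copy IS5-like burst (founder divergence 0.3, copy decay 0.02,
truncation probability 0.3), a 10-taxon coalescent tree with 6-kb
alignments and r = 3.5, and a 100-kb pileup at 1,000× with 160 planted
polymorphic sites at frequency 0.05 — sizes at which every recovery
bound is decisively testable on a single CPU in about a minute. The
replicated clock analyses (20 recovery replicates; 200 null replicates
for type-I calibration at α = 0.05) are run by the acceptance script
and the acceptance tests. `run_pipeline()` accepts a YAML or list
config (unknown keys rejected before any compute; YAML rather than a
TOML dialect, keeping the dependency footprint to packages already in
the import set), writes per-stage JSON plus a consolidated report, and
embeds a hash of the analysis-relevant config so reruns are
bit-identical.

## Known limitations

- The pseudogene rule is database-relative: counts shift with the
  reference proteome, and frameshift-only pseudogenes (full-length but
  broken frame) are found only via their internal-stop truncation.
- The per-site error-like threshold is uninformative below ~2,000×
  coverage (see above); the spectrum is the robust view.
- The clock engine fixes topology and substitution parameters; it tests
  one foreground clade at a time and does not search trees or dates.
- Burst verdicts depend on outgroup sampling: with no outgroup lineage
  between two expansions, their clades can coalesce and be read as one.
- NJ distances ignore alignment uncertainty; heavily saturated families
  (capped distances) should be interpreted with care.
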