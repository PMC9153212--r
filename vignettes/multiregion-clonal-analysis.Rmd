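---
title: "Multi-region clonal evolution analysis with multiclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-region clonal evolution analysis with multiclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiclone)
```

# The problem

Autopsy studies of diffuse midline glioma (and of infiltrative tumors
generally) profile several tumor regions and several histologically normal
tissues from one patient with deep targeted sequencing (~2500X) and SNP
arrays. The analytical task is to turn per-variant read counts and
allele-specific copy-number segments into a patient-level picture of clonal
evolution: which mutations arose together, how the resulting clones relate
on a phylogeny, what fraction of each region each clone occupies, and
whether "normal" tissues carry trails of invading tumor subclones.
`multiclone` implements that chain end to end, together with a synthetic
cohort generator so that every stage can be validated without access to
patient-level data.

# The model

## Cellular composition

A sample is a mixture of diploid normal cells (fraction $1-t$) and tumor
cells (purity $t$). A copy-number variant (CNV) with integer state $M$ is
carried by a fraction $f$ of the tumor cells, so the composite copy number
an assay measures is

$$c = (1-t)\,2 + t\,[(1-f)\,2 + f M].$$

A somatic mutation carried at mutant-allele multiplicity $n$ by a fraction
$g$ of the CNV-bearing cells has expected variant allele fraction (VAF)

$$v = \frac{t f g n}{c}, \qquad g = \frac{v c}{t f n},$$

and its cancer cell fraction is $\mathrm{CCF} = g f$. Both $f$ and $g$ must
lie in $[0, 1]$; a candidate copy model that pushes either outside that
range (beyond a noise allowance) is wrong and an alternative model must be
considered. Because somatic mutation rates are tiny, one mutation belongs
to a single lineage, so a correct model must be feasible in **every**
region where the mutation is detected.

The functions `composite_copy()`, `cnv_ccf()`, `expected_vaf()`,
`mutation_g()`, `mutation_ccf()` and `enumerate_copy_models()` implement
this algebra; the test suite verifies the round trips to 1e-12.

### An identifiability caveat: $g \cdot n$

The VAF depends on $g$ and $n$ only through their product. A mutation
duplicated before a gain ($n = 2$, fraction $g$) is indistinguishable from
an unduplicated one in twice the cells ($n = 1$, fraction $2g$) whenever
$2g \le 1$. Model enumeration therefore resolves multiplicity reliably in
the clonal-duplication regime ($g > 0.5$, e.g. a founder mutation on a
gained chromosome arm), and reports the ranked alternatives otherwise.
Ranking ties prefer the later-timing model (`after_cnv`), the parsimonious
default.

## Tumor purity

The founder mutation (in this disease, the histone H3 K27M substitution)
is present in every cancer cell, so its clonality fixes the purity:
$t = 2v/(n - v(M-2))$, which is $t = 2v$ at a diploid founder locus
(`estimate_purity()`). A single site measured at 2500X carries binomial
noise of about $\pm 0.02$ on $t$; the *founder clone*, however, is defined
by all truncal variants, and `refine_purity()` rescales the single-site
estimate so the founder cluster's mean CCF is exactly 1. This is the
two-sided generalization of the superclone check: an apparent truncal CCF
above 1 diagnoses underestimated purity, and `check_superclone()` rescales
$t$ upward by the maximal truncal CCF (CCF scales as $1/t$, so the maximum
becomes exactly 1); a rescale that would need $t > 1$ is an error. The
pipeline applies the superclone check at the clone level (the founder
cluster's mean profile) because single variants exceed 1 by noise alone.

## CNV cellular prevalence from allelic imbalance

An unbalanced copy change shifts the B-allele fraction (BAF) of germline
heterozygous SNPs away from 0.5. For allele-specific state $(a, b)$,
$a \ge b$, total $M = a+b$, carried by a fraction $\mathrm{CP}$ of **all**
cells, the folded deviation is

$$\mathrm{AI} = \frac{\mathrm{CP}\,(a-b)}{2\,(2 + \mathrm{CP}(M-2))},
\qquad \mathrm{CP} = \frac{4\,\mathrm{AI}}{(a-b) - 2\,\mathrm{AI}\,(M-2)}.$$

`infer_segment_cp()` inverts AI for every candidate state and scores each
candidate by the residual of the *other* observable — the composite copy
number — in copy units. Two design points deserve emphasis:

* **Confounded gain states.** $(1+k, 1)$ at prevalence $x$ produces exactly
  the same $(\mathrm{AI}, c)$ as $(2, 1)$ at $kx$. Scoring in copy units
  makes the confounded states tie *exactly* (scoring by CP residuals does
  not: the residual shrinks with amplitude and noise then systematically
  favors the highest-copy state). Ties fall to parsimony — fewest total
  copies — and all alternatives are reported. High-amplitude states are
  still selected whenever the low-copy explanation would require CP > 1.
* **Bi-allelic duplication** ($a = b$) is AI-invisible; its CP comes from
  $c$ alone, and CN-LOH ($M = 2$) leaves $c$ uninformative, so its CP
  comes from AI alone. The two observables are complementary.

Arrays are unphased, so the per-SNP B allele sits on either haplotype;
`multiclone` works with folded deviations $|BAF - 0.5|$ throughout. The
mean folded deviation is upward-biased near zero under Gaussian BAF noise
(a folded-normal mean), and `calibrate_segments()` removes that bias by
numerically inverting the folded-normal mean when the noise sd is known.
One $(a, b)$ state is enforced per segment per patient, chosen by the
summed score over samples that carry the event; conflicts are visible in
the per-sample alternatives.

`fit_cnv_timing()` resolves early-versus-late acquisition: a truncal event
predicts $\mathrm{CP} \approx t$ in every region, while a branch event
tracks that branch's CCF profile; placements must agree with the observed
CP within 0.1 everywhere (array-derived CP noise dominates) and the
feasible placement with the smallest summed squared residual wins.

## Mutation clustering

Mutations sharing a lineage share a per-region CCF profile.
`cluster_mutations()` fits a finite mixture in which a variant's
likelihood is the product over samples of
$\mathrm{Binomial}(\mathrm{alt};\, \mathrm{depth},\, e + (1-2e)\,q\,\phi_k)$
with $q = t n / c$ the variant's VAF-per-unit-CCF under its copy model,
$\phi_k$ the cluster's per-sample CCF, and $e$ the residual per-read error
rate (default 1e-3 inside the likelihood, which also keeps the success
probability off zero). EM details:

* initialization per $k$: k-means on the CCF rows (20 restarts), a Ward
  hierarchical cut (deterministic and robust when profiles are well
  separated), the best $(k-1)$-fit with its worst-explained cluster split
  in two (keeps the likelihood near-monotone in $k$), plus random variant
  rows up to `n_restarts` (default 8);
* the M-step uses the moment update
  $\phi = \sum r(\mathrm{alt} - \mathrm{depth}\,e) / ((1-2e)\sum r\,\mathrm{depth}\,q)$,
  clamped into $[0,1]$; convergence at relative log-likelihood change
  below 1e-8 or 500 iterations;
* $K$ is chosen by BIC over `1:min(15, n_variants)` (the cohort range is
  4–15 clones per patient), stopping after two consecutive increases;
* labels are canonicalized by descending mean CCF, so output is
  seed-stable; empty components are dropped; zero-depth cells contribute
  no likelihood and such variants are assigned from their covered samples.

Clusters of any size are retained — a subclone separated from its parent
by a single variant can carry the decisive evidence.

## Tree construction

`build_tree()` enumerates rooted arborescences over the clusters (root:
the truncal cluster, CCF ≈ 1 everywhere) subject to, in every retained
sample (purity ≥ 5%):

* **ancestor dominance / crossing rule** — a descendant's CCF can never
  exceed an ancestor's: two clusters whose CCF ordering reverses between
  samples must sit on branching lineages;
* **sum's rule (pigeonhole)** — children's CCFs cannot sum beyond their
  parent's.

Both rules hold up to a slack. With no uncertainty information the slack
is the fixed tolerance `tol` (default 0.05, matching binomial noise at the
study depth); when cluster standard errors are supplied the slack adapts
per pair (3 SE, floored at 0.0075, capped at `tol`/2 per cluster, errors
adding in quadrature for the sum rule) — a fixed tolerance discards the
precision of 2500X data and admits parents the data exclude.

Among constraint-satisfying trees, each node attaches to its **nearest
dominating parent**: the tree minimizing the purity-weighted squared CCF
distance between children and parents wins, with ties broken by total
sum-rule violation and then lexicographically. (Preferring shallow trees
instead collapses true parent→child chains into stars; minimizing
violation first lets noise-level violations override the distance. Both
variants were measured to roughly halve exact ancestry recovery.) Samples
with higher purity weigh more, since they measure CCF more accurately.
Every parent a node takes in any other constraint-satisfying tree is
recorded in `$ambiguous` — uncertainty is reported, never silently
resolved. The search is exhaustive for the cluster counts this data
produces (≤ 15 with pruning); the test suite proves equality with
brute-force enumeration over all parent functions on 1,000 random
instances.

## Decomposition, classification, lineage statistics

`decompose_regions()` turns CCFs into clone fractions: the clone at a node
holds $\mathrm{CCF}(\mathrm{node}) - \sum \mathrm{CCF}(\mathrm{children})$,
and a **founder clone** absorbs $1 - \sum$ (non-root fractions) when
positive — cancer cells carrying only truncal variants, or a rare
descendant whose private mutations escaped detection. Low-purity samples
(< 5%) are decomposed from clusters measured in high-purity samples and
flagged `inferred_only`; regions where more than one lineage holds at
least 5% are flagged `multi_lineage`.

`classify_variants()` labels variants truncal / shared / private by their
presence pattern (detection: ≥ 3 mutant reads and VAF ≥ 0.002) over
samples above the purity cutoff.

`lineage_stats()` measures each immediate child branch of the founder:
molecular age = mutations from the trunk to the most distant descendant;
average CCF = the lineage's summed descendant clone fractions averaged
over qualifying regions. `lineage_age_ccf_cor()` tests the age–occupancy
relation across lineages by Pearson correlation.

## Tumor-in-normal contamination

`test_presence()` is a two-stage test. Stage 1 gates on the founder site:
a one-sided exact test of the mutant read count against a per-site error
model built from a panel of normals (`build_error_model()`; pooled rate
with a Jeffreys pseudocount, floored at 1e-6, leave-one-out against the
tested sample). The tail probability integrates the Beta posterior of the
panel rate (a beta-binomial tail), so panel sampling noise cannot inflate
the test size — with a plug-in rate the measured type-I error exceeded the
nominal level. Only if the founder is significant is the tumor fraction
estimated (`estimate_tumor_fraction()`, the same clonality inversion as
purity: 2% tumor gives founder VAF 1%) and are the mutation clusters
tested: member-site tails combined by Fisher's method,
Benjamini–Hochberg across the clusters of the sample, presence called at
q ≤ 0.05, and the present clusters' CCFs computed within the contaminating
population (tumor fraction in the role of purity). No cluster is ever
called in a sample whose founder gate failed.

# The synthetic cohort generator

`sim_config()` + `simulate_truth()` + the observation functions emulate a
DMG-like multi-region autopsy cohort. Defaults, each chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_regions` | 5 | cohort median 4, range 3–7 (drawn 4–7 in the studies) |
| `n_clusters` | 8 | cohort clones per patient 4–15 |
| `mutations_per_cluster` | 8–20 | deep-sequenced cluster sizes |
| `purity_shape` | Beta(8, 2) | median ≈ 0.82, cohort median 0.8 |
| `deep_depth` | 2500 | targeted deep-sequencing tier |
| `base_error_rate` | 1e-5 | error-suppressed sequencing; a 1e-3 background would defeat the 0.002-VAF detection rule itself |
| `admixture_concentration` | 5 | minor admixtures in the reported 5–50% range |
| `p_multi_lineage` | 0.5 | ~half of regions host multiple lineages; with > 2 lineages, 3- and 4-branch admixtures occur |
| `min_ccf_separation` | 0.15 | study-like cluster separation |
| `snps_per_segment`, `baf_noise_sd`, `c_noise_sd` | 50, 0.03, 0.03 | array-scale noise (not calibrated to any particular platform) |
| `contamination_fractions` | 0, 0.02 | the 2%/12% tumor-in-normal scale |

Region compositions are Dirichlet draws over a sparse support: the trunk
plus one or more lineage subtrees (each further child included with
probability 0.6, keeping supports downward-closed — a clone only occupies
a region its parent reached). Purities are Beta draws; normals mix a
configured clone subset at fraction $\phi$; read counts are Binomial over
Poisson depths (floor 1) with symmetric error mixing
$p = v(1-e) + (1-v)e$; segment observations emit per-sample folded BAF
deviations and noisy composite copies.

**Identifiability conditioning.** Tree and compositions are jointly
redrawn (≤ 25 topologies × 60 composition draws) until every cluster is
observable (peak CCF ≥ 0.05 in some region), profiles are separated by at
least `min_ccf_separation`, and the noise-free occupancy patterns admit
exactly **one** sum/crossing-rule tree with a 0.05 margin. Unconstrained
random compositions leave the generating tree unidentifiable in most
draws — no method could recover it, and ambiguity would not be a property
of the method under test. Real multi-region designs are likewise chosen
to resolve lineages. The conditioning is part of the study definition and
applies to every simulated cohort.

**Age–CCF coupling** (`age_ccf_coupling`, default 0): when positive, a
lineage's weight in region occupancy (both its selection probability and
its Dirichlet concentration) scales as
$(\mathrm{age}/\overline{\mathrm{age}})^{\mathrm{coupling}}$. The
age–CCF study uses exponent 1.6, anchored to the reported pattern of a
lineage at twice the molecular age holding about thrice the average CCF
($\log 3 / \log 2 \approx 1.6$).

## What the generator does and does not emulate

It reproduces the statistical structure the inference assumes: clonal
founder, tree-consistent CCFs, sparse admixed region occupancy,
allele-specific CNVs with their BAF/copy signatures, deep-coverage
binomial noise, and lineage-specific contamination of normals. It does
**not** simulate read-level artifacts, mutational signatures, spatially
continuous invasion, clock-calibrated branch lengths, or array-platform
specifics; passing tests therefore demonstrate correctness of the
inference under the stated generative model, not robustness to every
failure mode of real assays.

# Validation studies and their sizes

The acceptance suite (and `scripts/acceptance.R`) runs: 200 full-pipeline
recovery replicates (purity, exact variant-level ancestry, per-region
composition L1, classification); 500 early-vs-late CNV timing replicates
at CP noise sd 0.03; 1,000 mixed normals (tumor fractions 0, 0.005, 0.02,
0.12) plus 1,500 dedicated pure normals for a low-noise type-I estimate,
at a deliberately pessimistic residual error of 1e-3; 40 ten-lineage
age–CCF cohorts; and 1,000 random tree instances compared against
brute-force enumeration. These sizes keep the whole suite within a few
minutes per study on one core while leaving Monte-Carlo noise well below
the margins being asserted.

**A known shortfall, reported rather than hidden:** the age–CCF study
shows a positive correlation in every cohort (median r ≈ 0.83), but only
~85% of 10-lineage cohorts reach p < 0.05. A 10-point Pearson test needs
r ≥ 0.632; the published cohort-level effect (R = 0.68 over ~2 dozen
lineages) would give roughly 40% power at n = 10, and pushing the coupling
harder saturates occupancy shares and *lowers* the correlation. The
binding noise is the binary region-occupancy process, which matches the
reported occupancy variability. The corresponding acceptance assertion is
left failing by design, with the analysis recorded here.

# Known limitations

* Sex chromosomes are out of scope; the copy-number algebra is stated for
  autosomes.
* Multiplicity is unidentifiable below $g n \le 1$ (see above); ranked
  alternatives are always reported.
* Scaled gain states are confounded in (AI, c); parsimony picks the
  fewest-copies explanation and alternatives are reported.
* The clustering is a finite mixture with BIC, deterministic and testable;
  it shares the input/output contract of Dirichlet-process samplers used
  elsewhere but does not claim equivalence.
* Haplotype phase is never used; maternal/paternal reflection analyses
  are out of scope.
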