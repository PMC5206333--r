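---
title: "Population-genetic analysis of tetraploid microsatellite data with polypopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of tetraploid microsatellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`polypopgen` implements a complete population-genetic workflow for
tetraploid microsatellite (SSR) genotypes of the kind produced for rare
island plants: a few hundred individuals from a handful of populations
spread over islands, scored at under a dozen SSR loci, with four gene
copies per locus and — in real fragment data — frequent allele-dosage
ambiguity. The pipeline covers per-population diversity statistics, Bruvo
inter-individual distances with principal coordinate analysis, Bayesian
admixture clustering of a dominant (band presence/absence) recoding,
hierarchical AMOVA with Phi statistics and Slatkin gene-flow estimates,
Monmonier barrier detection on a Delaunay network of sampling sites, the
standard/stratified/partial Mantel protocol that discriminates
hierarchical-island from stepping-stone structure, and beta-regression
models of genetic distance against geographic distance and barrier
covariates compared by AIC and pseudo-R².

A synthetic-data generator with known truth makes every stage testable
without access to any particular field dataset.

# The data model and dosage ambiguity

A tetraploid SSR genotype is a multiset of up to four allele sizes (bp).
`polypopgen` stores each cell as an integer vector: length 4 means the
dosage is fully known (copies counted with multiplicity), lengths 1–3 mean
only the distinct allele set is known, and length 0 is missing. This
matters because fragment analysis shows *which* alleles an individual
carries but, for partial heterozygotes, not *how many copies* of each.
Nothing in the package silently invents dosage; instead every downstream
statistic declares its resolution policy:

* **Allele frequencies** (`alleleFrequencies()`): under the default
  `equal-split` policy an ambiguous cell with k distinct alleles gives
  each of them weight 4/k, so every scored cell contributes exactly four
  gene copies; `known-only` restricts to dosage-known cells for
  sensitivity analysis.
* **Within-individual identity** (the Q_ind behind the inbreeding
  coefficients) is averaged *exactly* over all dosage completions of the
  distinct set (there are at most three), which is consistent with the
  completion averaging used for Bruvo distances. The expected per-allele
  multiplicity under uniform completions is 4/k, so the two conventions
  agree on frequencies.
* **Bruvo distances** expand each ambiguous genotype to all completions to
  four copies and average the optimal-assignment distance over completion
  pairs (the "genome addition" convention familiar from polyploid SSR
  software). A corollary worth knowing: two *identical ambiguous*
  genotypes have a positive expected distance, because different
  completions of the same distinct set differ; only dosage-known clones
  are at distance zero.

# Diversity statistics

Per population the package reports the multilocus mean allele count (NA),
rarefied allelic richness (AR), Nei's unbiased gene diversity
He = (n/(n−1))(1 − Σp²) with n the gene copies used, the individual
inbreeding coefficient Fi, and the private-allele percentage Pa; totals
add the pooled allele count, total diversity HT, multilocus FIS, and the
summed Pa.

**Rarefaction.** AR is the expected allele count in a subsample of g gene
copies, Σ_a (1 − C(N−N_a, g)/C(N, g)), evaluated through `lchoose` so the
fractional counts produced by equal-split weighting are handled by the
gamma-function continuation. The default g is the smallest gene-copy count
over population–locus combinations — with complete data, four times the
smallest population size (24 for the default study shape, whose smallest
population has six plants). This standardises richness to the smallest
sample, the usual convention.

**HT.** Total diversity per locus uses the unweighted mean of population
allele frequencies with the small-sample correction
HT = 1 − Σx̄² + HS/(ñ·s) (HS the mean unbiased within-population
diversity, ñ the harmonic-mean gene-copy count, s the number of
populations). A known estimator artifact: when populations are nearly
identical, HT can undershoot the *unbiased* HS by a term of order HS/ñ;
the tests account for exactly that margin.

**Fi and FIS.** Fi compares the mean identity-in-state of the six
within-individual gene-copy pairs with the identity over
between-individual pairs from the same population:
Fi = (Q_ind − Q_pop)/(1 − Q_pop), combined across loci as a ratio of
summed numerators to summed denominators; FIS is the same ratio pooled
over individuals. Negative values mean heterozygote excess. Significance
comes from permuting gene copies among individuals within populations
(999 permutations by default, two-sided); ambiguous cells are resolved to
one sampled completion for the permutation pool. Monomorphic
population–locus combinations contribute nothing (their denominator is
zero).

**Pa.** An allele is private when observed in exactly one population. The
default denominator is the total distinct allele count over all
populations, which makes the per-population percentages sum to the
printed total — the property that selects this definition over the
per-population-denominator alternative (available via
`denominator = "own"`).

# Distances

**Bruvo.** Per allele pair the distance is 1 − 2^(−|x|) with x the
repeat-count difference; repeat counts are anchored at the locus' minimum
observed size (only differences matter). The genotype distance minimises
the mean over all 4! = 24 bijective copy assignments — exhaustive and
exact, no Hungarian approximation is needed at ploidy four. Multilocus
distances average over loci scored in both individuals.

**Nei (dominant).** Population distances treat each band as a biallelic
locus with presence frequency p: D = −ln(J12/√(J1·J2)) with the J terms
averaged over bands. The 1972 standard form is the default (matching what
binary exports are usually fed to); the 1978 unbiased variant — which
removes a small-sample homozygosity bias that can correlate with unequal
population sizes — is a flag. Disjoint profiles give an infinite
distance, capped at a configurable ceiling (default 10) and flagged so
regressions can exclude them.

**Geographic.** Haversine great-circle distances in metres on a sphere of
radius 6 371 000 m.

# Ordination

`pcoa()` double-centres −½D² (Gower), eigendecomposes, and scales
eigenvectors by the square roots of the positive eigenvalues. Negative
eigenvalues are reported as a mass, not corrected, because Bruvo matrices
are near-Euclidean in practice and a silent correction would change the
inertia percentages; a Lingoes correction is available behind a flag. Axis
signs are fixed by making the largest-magnitude loading positive so plots
are reproducible.

# Admixture clustering

The dominant matrix is modelled as haploid biallelic loci — the natural
reading of feeding a 0/1 export to a STRUCTURE-style model; the
recessive-allele dominant-marker model is deliberately out of scope. The
Gibbs sampler (in C++) alternates:

1. per-(individual, band) cluster-of-origin indicators;
2. cluster band frequencies p_kl under the correlated-frequencies F-model,
   p_kl ~ Beta(p̄_l(1−F_k)/F_k, (1−p̄_l)(1−F_k)/F_k), which is conjugate
   given the indicators;
3. Metropolis updates for the ancestral frequencies p̄_l and the drift
   parameters F_k (uniform priors, reflecting random-walk proposals);
4. Dirichlet(α) admixture proportions, with a Metropolis step on the
   single shared α (uniform(0, 10) prior, the common default).

Each run starts from the best of several short independent pilot chains
(by current log-likelihood): the conjugate updates converge within a few
hundred sweeps, so chains headed for a poorly merged local mode — the
dominant failure of short runs at K near the true cluster number — are
cheap to detect and discard before the main run. The reported Q matrix
is the posterior mean over post-burn-in iterations.
The model likelihood per run is estimated as mean − variance/2 of the
thinned post-burn-in log-likelihood trace — the deviance-based estimator
STRUCTURE prints. The variance term penalises over-parameterised K, whose
traces mix poorly; using the plain trace mean instead makes the
log-likelihood keep climbing with K and destabilises the Evanno
statistic.

Desk-scale defaults are 20 000 repetitions, 5 000 burn-in, 3 replicates
per K over K = 1–7, thinning every 10 — a full scan runs in minutes on
one CPU; classic full-scale settings (500 000/50 000, 10 replicates,
K 1–10) are a configuration away. Replicate runs are aligned by the
greedy scheme: run 1 is the reference and each later run gets the column
permutation minimising squared distance to the running mean (exhaustive
over K! for K ≤ 8). ΔK follows the Evanno second-difference rule
|L(K+1) − 2L(K) + L(K−1)|/sd(L(K)) over interior K.

# AMOVA, FST and gene flow

The three-level AMOVA partitions squared Euclidean distances between
binary band vectors among clusters, among populations within clusters,
and within populations, with unbalanced-design coefficients in the
expected mean squares. Missing bands are pairwise-deleted with rescaling
by the number of compared bands, which keeps every individual usable.
Negative variance components are truncated at zero for the percentage
display but reported signed in the raw output. P-values use the standard
three permutation schemes (individuals among all populations; individuals
among populations within clusters; whole populations among clusters).
Pairwise and global FST are the Phi_ST of two-level AMOVAs, truncated at
zero. Slatkin's gene-flow estimate defaults to the diploid form
Nm = (1/FST − 1)/4; published Nm tables for this kind of data cannot
always be reproduced from rounded FST entries by either standard form, so
the choice is documented rather than asserted, and the haploid form is a
flag.

# Barriers

Sampling sites are triangulated (Bowyer–Watson) on an equirectangular
projection centred on their centroid — over a few hundred kilometres the
projection distortion cannot change the triangulation topology. Exactly
collinear sites get a deterministic micro-jitter. Each Monmonier barrier
starts at the uncrossed Delaunay edge with the largest genetic distance
and grows across the Voronoi diagram in both directions, always crossing
the adjacent uncrossed edge with the largest distance, until it reaches
the outer boundary or closes a loop; crossed edges leave candidacy, so
barrier edge sets are disjoint and later barriers rank lower. Ties break
by lexicographic population-pair order, making the procedure fully
deterministic and scale-invariant. Sea versus land is not modelled; the
network is purely geometric.

# Isolation by distance

`mantelTest()` implements three permutation schemes over off-diagonal
pairs: standard (permute entity labels), stratified (label swaps within
strata — the conventional reading of "permuted with clusters"; a
whole-stratum mode exists because the phrase is ambiguous), and partial
(correlate residuals after regressing both matrices on a covariate
matrix, permuting residual labels). P-values are one-tailed with the
(1 + hits)/(1 + permutations) correction; 4 999 permutations is the
default for the protocol, matching the resolution of the smallest
p-values such analyses report. For n ≤ 8 labels the standard scheme can
enumerate all n! permutations exactly. `himSsmProtocol()` packages the
four tests that discriminate a hierarchical island model (HIM) from a
stepping-stone model (SSM) and attaches the decision tags: significance
of the raw genetic~geographic test alone discriminates nothing; a
non-significant stratified test supports HIM; a significant
genetic~geographic test partialling clusters, with high r, supports SSM;
a significant genetic~clusters test partialling geography supports HIM.

**Beta regression.** Genetic distances are mapped into (0, 1) by min–max
rescaling followed by the Smithson–Verkuilen compression
(y(n−1) + 0.5)/n — Nei distances are unbounded above and no canonical
mapping exists, so the transformation is recorded in every fit and shared
across a model ladder (AIC ordering is invariant to it). The likelihood
is Beta with logit mean link and constant precision, maximised by
quasi-Newton from OLS-on-logit starting values with a method-of-moments
precision, then polished by Newton steps until the gradient is
numerically zero. Pseudo-R² is the squared Pearson correlation between
the link-transformed response and the linear predictor.

**Model ladders.** The distance-only model is compared against models
adding barrier covariates one order at a time, under two barrier
definitions: cluster-boundary indicators (the pair straddles a given
genetic cluster's boundary), added cluster by cluster; or
Monmonier-order indicators (the pair is newly separated when barriers
1..k are applied, via connected components of the cut Delaunay graph).
By default each ladder step carries a single cumulative indicator
("separated at order ≤ k"); separate per-order indicators are the
alternative. Geographic distance enters in kilometres so coefficients
stay O(1).

# The synthetic generator

`simulateHierarchical()` draws ancestral allele frequencies uniformly on
the simplex over each locus' motif lattice, then applies two rounds of
multi-allele Balding–Nichols drift (Dirichlet with concentration
p(1−F)/F): `fCT` among island clusters, `fSC` among populations within
clusters. `simulateSteppingStone()` instead diverges populations through
a latent Gaussian field whose correlation decays with effective distance
(geographic kilometres plus a penalty across each planted barrier),
giving a monotone expected genetic-vs-geographic relation.

The default configuration reproduces the study shape the package targets:
9 populations in 5 island clusters (129 individuals, sizes 6–21), 8 loci
with 10–31 alleles on their published motif lattices, an Azores-like
coordinate layout, and a planted sea barrier in the stepping-stone model.
The drift split fCT = 0.13, fSC = 0.02 was calibrated so the
dominant-matrix global Phi_ST sits near 0.45 while keeping the five
clusters individually resolvable by the admixture scan; a flatter split
with the same global Phi_ST leaves cluster pairs that merge at desk-scale
MCMC. Per-cluster drift scales inversely with cluster sample size
(F_c = fCT · n̄/n_c): small island populations drift more, which is both
the biologically expected pattern and what keeps every cluster's
detectability (sample size × divergence) comparable — with uniform drift
the smallest cluster contributes so little likelihood that model-choice
statistics fold it into a neighbour. The size-weighted mean drift equals
fCT, so the global differentiation target is unaffected. Mean
within-population He lands in the 0.7–0.8 range and HT near 0.85,
matching the diversity profile such datasets show.

**Heterozygote excess.** Tetraploid outcrossers often show negative FIS.
A rejection device (redraw genotypes containing duplicate alleles) turns
out to be self-defeating: it biases sample allele frequencies toward rare
alleles, which drags the between-individual identity down together with
the within-individual one, cancelling the FIS signal. The generator
therefore draws genotypes under Hardy–Weinberg and then *swaps duplicate
gene copies between individuals* until the mean within-individual
identity reaches Q_pop + fisTarget·(1 − Q_pop). Swaps permute the
realised gene pool, so population allele frequencies are preserved
exactly and the target (default −0.19) is hit by construction, up to the
one-swap granularity. This is a phenomenological device, not a mating
model.

**What the generator does not emulate.** No mutation during the
simulation (the stepwise-mutation process only shapes the allele lattice,
not the sampling), no coalescent genealogy, no null alleles or scoring
error, no linkage. Passing tests therefore demonstrate that the
*estimators and algorithms* behave correctly under controlled truth; they
do not validate the generator as a model of any real species' history.

# Numerical choices and degenerate inputs

* Assignment minimisation in Bruvo distances enumerates all 24
  permutations — exact at trivial cost.
* Nei distances cap at 10 by default; capped pairs are flagged.
* PCoA reports (never corrects) negative eigenvalues by default.
* Monomorphic population–locus combinations are skipped in inbreeding
  ratios; populations of one individual are skipped in pairwise FST with
  a warning; a cluster containing a single population leaves Phi_SC
  partially confounded and is flagged, not refused.
* Collinear site configurations fall back to a deterministic jitter of
  10⁻³ of the configuration span.
* Beta-regression fits error out after three scaled restarts rather than
  returning an unconverged object; every returned fit has a
  numerically-zero gradient.
* All stochastic stages (permutation tests, MCMC, simulation) consume
  seeds derived from a single master seed, so pipeline runs are
  bit-reproducible.

# Problem sizes used by the test suite

The suite exercises the full study shape (129 individuals) for the
parameter-recovery, admixture and protocol checks, with desk-scale MCMC
(20 000 repetitions, 3 replicates, K = 1–7) and permutation counts of
99–999; oracle-equivalence checks run on fixtures of at most 30
individuals where exhaustive enumeration is exact. These sizes were
chosen so the whole suite completes in minutes on a single CPU while
leaving every statistical property measurable.

# Known limitations

* The admixture model treats bands as independent haploid loci; bands
  from the same SSR locus are in fact negatively correlated. This is the
  standard simplification for binary exports and matters little for
  clustering, but the absolute log-likelihoods are not comparable to
  co-dominant analyses.
* FIS and Fi are defined against the individual's own population;
  software that references the total sample will report different (often
  more negative) values on structured data.
* With only three replicates the Evanno denominator sd(L(K)) is noisy;
  the variance-penalised likelihood estimator stabilises it, but scans of
  borderline datasets can still move the peak by one K.
* The Monmonier implementation follows the classic maximum-difference
  rule without bootstrap support for barriers (the corresponding study
  design did not use it either).

# Pipeline orchestration

`runPipeline()` chains every stage (filter → diversity → distances →
PCoA → admixture scan → AMOVA/FST → barriers → Mantel protocol → model
ladders), writes per-stage CSV tables plus a JSON summary with the seeds
used, skips the spatial stages with a notice when coordinates are absent,
and derives all stage seeds from one master seed. Stages are recomputed
on every run; at desk scale the whole pipeline takes minutes, so a
content-addressed stage cache would add state without payoff.
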