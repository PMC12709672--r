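---
title: "Methods: community ecology of acidophile microbiomes with amdniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community ecology of acidophile microbiomes with amdniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdniche)
```

## Scope

`amdniche` implements a community-ecology workflow for 16S rRNA amplicon
surveys of extreme environments such as acid mine drainage (AMD): systems
with pH often below 3 and metal loads in the g/L range, dominated by
specialized acidophiles. The pipeline takes an ASV-by-sample count table,
ASV sequences, a rooted phylogeny, a taxonomy with genus assignments, and
per-sample physicochemistry, and produces five families of results:

1. **Occupancy/abundance classification** — persistent abundant taxa and
   conditionally rare taxa (CRT).
2. **Within-OTU microdiversity** — effective number of ASVs per 98.7%
   identity OTU, with persistence and variability.
3. **Niche proportionality** — rho between closely related ASVs on
   centred log-ratio (CLR) data, modelled against nucleotide divergence.
4. **Assembly-process partitioning** — five ecological processes from
   phylogenetic-bin null models (beta-NTI and modified Raup–Crick).
5. **Process–environment association** — Monte-Carlo cross-validated
   bivariate models with permutation p-values.

A synthetic-community generator with planted ground truth makes every
stage testable without any external dataset.

## Classification rules and their parameters

An ASV is **abundant** when its relative abundance reaches 1% in at least
one sample (inclusive), otherwise **permanently rare**. Occupancy (the
fraction of samples with at least one read) classifies ASVs as **broad**
(>= 75%), **narrow** (<= 10%) or **intermediate**. **Persistent abundant**
taxa are those abundant *and* broad. **CRT** are ASVs whose per-sample
relative-abundance vector is strongly bimodal — Sarle's sample-corrected
bimodality coefficient

$$b = \frac{g_1^2 + 1}{g_2 + \frac{3(n-1)^2}{(n-2)(n-3)}} \ge 0.9$$

(with $g_1$, $g_2$ the bias-corrected sample skewness and excess
kurtosis) — and that reach 1% in at least one sample: taxa that are rare
almost everywhere but occasionally bloom. For a normal sample $b \to 1/3$;
a balanced two-point mixture approaches 1. The coefficient is undefined
below $n = 4$ or at zero variance; such ASVs are never flagged. Note that
at small sample numbers ($n \approx 25$) a vector with a single bloom has
$b \approx 0.9$ by construction, so CRT calls near that scale are
intrinsically borderline; the classification is intended for surveys with
tens of samples. All thresholds are arguments with the field-standard
defaults above, and classification can be restricted to a metadata-defined
subset (e.g. `filter = "pH < 4"`), since persistence is usually assessed
within the acidic habitat itself. Occupancy is computed over all filtered
samples by default; stratified runs are a matter of passing a different
filter.

## Microdiversity

ASVs are clustered into OTUs by greedy centroid clustering at 98.7%
global-alignment identity (abundance-sorted candidates, ties broken by
id; identity = matches / alignment columns with terminal gaps excluded;
scoring +1/-2 with gap open/extend 10/1). For equal-length sequences with
few mismatches the ungapped alignment is provably optimal under this
scoring, so a Hamming fast path handles the common amplicon case and the
full aligner the rest. OTUs whose summed read count exceeds 5000 are
retained and rarefied — one uniform draw without replacement of exactly
5000 reads from the flattened member-by-sample matrix — and three
statistics come from that single subsample: effective microdiversity
`exp(Shannon)` of member totals, persistence (fraction of samples with a
read) and variability (CV of per-sample totals). One seeded draw is the
default; the rarefaction seed derives deterministically from the master
seed and the OTU id. A single subsample serving all three statistics is
the only reading under which they are mutually consistent. High
(>= 2 effective ASVs) and low classes are compared by two-sided Wilcoxon
tests, BH-adjusted across the tested responses.

## Niche proportionality

Within each genus holding at least 10 closely related ASVs — the largest
connected component of the graph linking pairs at <= 5 nt divergence
(an alternative strict-diameter rule is available via `rule =
"diameter"`) — counts pass five filters in order: drop all-zero ASVs;
drop all-zero samples; keep ASVs present in >= 5% of remaining samples
(>= 3 samples); drop ASVs with CV < 0.1; add a pseudocount of 1. Rho is
then

$$\rho_{ij} = 1 - \frac{\mathrm{var}(z_i - z_j)}{\mathrm{var}(z_i) + \mathrm{var}(z_j)}$$

on CLR-transformed values $z$, computed within the genus submatrix (the
pipeline follows the per-genus preprocessing order; a community-wide CLR
is a trivial variation the user can apply by hand). A significance cutoff
is calibrated by permutation: each ASV's counts are shuffled independently
across samples (destroying association, preserving marginals), and the
smallest cutoff on a 0.05-step grid whose estimated false discovery rate
falls below 5% is retained. Rho is finally regressed on pairwise
nucleotide divergence (substitutions + internal gap columns) by OLS, with
BH adjustment across genera; an analogous model uses Euclidean distance
between abundance-weighted environmental niche centroids.

## Assembly processes

Tree tips are grouped into phylogenetic bins by single-linkage clustering
of cophenetic distance cut at `ds` (default 0.2), with bins below
`min_size` (default 12) merged into their phylogenetically nearest bin.
For every sample pair within every bin, the abundance-weighted beta mean
nearest taxon distance (bMNTD; bMPD available via `metric`) is
standardized against a null built by shuffling tip identities within the
bin (z = beta-NTI). By default the nearest-taxon search **excludes the
focal taxon itself** in the other sample: with ASV-level data, shared
near-identical variants otherwise contribute exact zeros and blind the
index precisely where microdiverse communities carry signal; excluding
conspecifics asks where each taxon's nearest *relative* sits, and neutral
communities still calibrate correctly (deterministic fractions stay below
15% in the package's null simulations). Set
`exclude_conspecifics = FALSE` for the strict classical definition.

Pairs not decided by selection (|z| <= 1.96) consult the modified
Raup–Crick metric: observed within-bin Bray–Curtis against nulls that
preserve each sample's within-bin richness and total reads, draw taxa
with probability proportional to occupancy and fill abundances
proportional to mean relative abundance, rescaled to [-1, 1]. The decision
rule is: z > 1.96 heterogeneous selection (HeS); z < -1.96 homogeneous
selection (HoS); otherwise RC > 0.95 dispersal limitation (DL),
RC < -0.95 homogenizing dispersal (HD), else drift (DR). Thresholds
follow the cited framework's conventions and are exposed as arguments.
Bin results aggregate to sample- and community-level importances by
abundance weights renormalized per pair over retained bins; the five
fractions sum to 1 at every scope. Null replicate counts default to
199 (z) and 999 (RC); RC is computed lazily only for undecided pairs.

**Bin scale matters.** The tip-shuffle null can only see selection whose
phylogenetic grain is finer than the bin: if an entire bin is uniformly
favoured, observed and null placements coincide and the pair falls to
drift. Conversely the Raup–Crick null is sharpest in large bins (where
richness makes "more turnover than chance" well resolved) and widest in
small ones. The package's own regime-recovery simulations therefore match
the bin scale to the process probed — community-scale shuffles for
homogeneous selection, large bins for dispersal limitation, the fine
default for drift — and real analyses should treat `ds`/`min_size` as a
sensitivity axis, not a constant of nature. This scale-dependence is a
property of binned null models generally, not of this implementation.

## Process–environment association

Per-sample process importances are CLR-transformed (zeros replaced by
1e-6 then renormalized); environmental variables are log(x+1)-transformed
(pH included, for uniformity; exclude it by passing a reduced matrix).
Every process-variable pair is scored by Monte-Carlo cross-validated
R²: repeated 90/10 train/test splits of an intercept+slope model, squared
errors pooled over repetitions (pooled rather than per-repetition
averaging: at six-sample test splits the pooled form is far more stable).
Significance comes from permuting the response: observed and permuted
statistics reuse the same splits at a reduced repetition budget (default
100 per evaluation), which makes them exchangeable under the null — the
package's calibration tests confirm uniform null p-values. The default
permutation budget is 999; `p = (1 + #{perm >= obs})/(n_perm + 1)`.
Associations are significant at BH-adjusted p < 0.05 *and* R²CV > 0.01.
Variance inflation factors (1/(1-R²) of each variable on the others)
diagnose the strong geochemical collinearity expected in AMD, where
metals track pH; associations are interpreted as suites of correlated
drivers, which is why collinear variables are retained.

## The synthetic community generator

`sim_config()`/`simulate_community()` generate the full input bundle with
known structure. Defaults are chosen once to emulate a multi-season AMD
survey at reduced scale and are the package's study conditions:

* **Layout** — 60 samples (10 sites x water/sediment x 3 events),
  50,000 reads/sample, 40 lineages of 1–16 member ASVs, 412-nt
  sequences, members within 2 substitutions of their parent (so planted
  lineages re-cluster at 98.7% identity).
* **Environment** — site pH spread over 2–7; Fe, Mn, Zn, Cu, Cd, sulfate
  and EC log-linear in pH with lognormal noise (Fe ~ 1400 mg/L at pH 2.5,
  declining to ~10 mg/L at pH 7), ORP declining with pH, DO lower in the
  first event. The log-linear coupling deliberately produces VIFs well
  above 5, so association analyses face realistic multicollinearity.
* **Occupancy classes** — 5% broad / 20% intermediate / 70% narrow
  (emulating the rare-majority structure of AMD surveys), planted by
  masking narrow taxa to the site nearest their pH optimum and
  intermediate taxa to the 3–6 nearest sites. Narrow and intermediate
  baselines are kept low enough that masked taxa never cross the 1%
  bloom threshold: planted occupancy classes and CRT flags must not
  overlap, because a narrow taxon peaking above 1% *is* operationally a
  CRT.
* **CRT** — 15 taxa at 0.01–0.08% baseline with a x100 bloom in 1–3
  random samples.
* **Niches** — lineage pH optima from a Brownian trait on the backbone
  tree, rank-uniformized over the optimum range so the favoured fraction
  does not swing with the tree draw; Gaussian response with breadth tied
  to occupancy class.
* **Phylogeny/sequences** — pure-birth backbone rescaled to a 16S-like
  height of 0.6 substitutions/site, parents forced > 5% divergent,
  members grafted at Jukes–Cantor distances matching their substitution
  counts (the tests verify member branch lengths against JC within 20%;
  for very recent backbone splits the enforced 5% sequence floor
  dominates the tree distance, a deliberate inconsistency at that edge).
* **Regimes** — `mixed` (default; the occupancy/CRT machinery),
  `selection` (strong filtering with niche conservatism at the lineage
  scale, a recruitment lottery and a competitive-exclusion floor so
  presence sets turn over partially — the configuration in which
  homogeneous selection is detectable), `dispersal_limitation` (disjoint
  ASV pools across site blocks, assigned phylogenetically at random so
  restricted dispersal does not masquerade as selection), and `drift`
  (one shared pool under heavy lognormal demographic noise).
* **Fine-scale niche divergence** — with
  `niche_divergence_coupling = c`, every mutated member drifts along its
  own orthogonal in-sample niche axis by `c * sqrt(substitutions)`, so
  the squared niche distance between two members is exactly
  `c^2 * divergence`. This plants the rho-vs-divergence signal
  deterministically; symmetric random-walk variants were rejected
  because their chi-square scatter at fixed divergence needs unrealistic
  genus sizes before the regression sees the trend.

What the generator does **not** emulate: sequencing error and chimeras
(inputs are assumed denoised), read-level data, temporal autocorrelation
beyond the event effect, taxon–taxon interactions, and the taxonomic
composition of real AMD communities. Passing recovery tests therefore
demonstrates that the *statistical machinery* recovers planted structure
of realistic magnitude — not that any biological claim about a specific
system is reproduced.

## Numerical and design choices

* All stochastic operations take an explicit integer seed; nested stages
  derive substreams from the master seed and a stable label hash, so a
  full pipeline is reproducible bit for bit and parallel-safe.
* Sample and feature order is preserved from the inputs; nothing sorts
  silently. Zero-total samples are an error, never silently normalized.
* Unequal sequencing depth is handled through per-sample relative
  abundance, not global rarefaction, matching the upstream convention of
  denoised amplicon workflows; rarefaction appears only inside the
  microdiversity module where the effective-number statistic requires a
  common denominator.
* Greedy abundance-sorted centroid clustering emulates the standard
  heuristic; replicating any specific external clustering binary
  bit-for-bit is a non-goal.
* Degenerate inputs resolve to `NA`/`NULL` with a message (zero-variance
  bimodality, undefined CV at zero mean, constant CLR responses in the
  association stage, empty bins), never to silent numbers.
* Problem sizes in the package's tests are scaled-down versions of the
  full survey conditions, chosen so the whole suite runs in minutes on
  one CPU:
  survey-scale classification at 60 x 500 and 50,000 reads, regime
  recovery at 40 samples x 600 ASVs with 99/199 null replicates over
  five seeds per regime, and calibration checks over 40–80 null runs.
  The statistical thresholds those checks assert are not scaled.

## Known limitations

* Homogeneous selection is invisible to the within-bin null when niche
  conservatism is coarser than the bin (see "Bin scale matters").
* The fitted Raup–Crick null estimates occupancy and mean abundance from
  the data; at small sample numbers that estimation noise biases RC
  slightly positive, which is why the calibration tests use disjoint
  sample pairs and generous sample counts.
* Sarle's bimodality coefficient is a small-sample-corrected moment
  statistic; with fewer than ~30 samples single-bloom taxa sit at the
  0.9 boundary.
* The rho-divergence model treats ASV pairs as exchangeable
  observations; shared-member correlation inflates nominal significance
  slightly, which the BH correction across genera does not repair. The
  package reports the OLS p-values as the field's convention dictates.
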