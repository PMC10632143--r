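---
title: "Models and methods behind microclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microclone)
```

# The problem

Adult epidermis is a patchwork of somatic clones descended from basal stem
cells. Laser-capture microdissection (LCM) of tiny epidermal fragments
("microbiopsies", typically the progeny of a few tens of basal cells)
followed by whole-exome sequencing yields, per patient, a matrix of
candidate somatic mutations by microbiopsies with alt-read and depth
counts. Because each microbiopsy is oligoclonal, mutation counts per
microbiopsy do not equal mutation counts per cell lineage: the same clone
can span several microbiopsies and one microbiopsy can host several
clones. `microclone` implements the chain of statistical steps that turn
such count matrices into clone-level biology: contaminant filtering,
clone deconvolution, phylogeny, mutational-signature attribution (with a
psoralen/PUVA TpA signature), transcription/replication strand analyses,
mixed-effects burden models, and per-gene mutated-cell fractions — plus a
synthetic cohort generator so every stage is testable without patient
data.

# Filtering candidate calls

**Genotyping.** A site is considered genotypable when at least one
microbiopsy covers it at depth ≥ 4 with ≥ 3 alt reads; anything else is
`low_support`. These thresholds are deliberately permissive: downstream
clustering pools evidence across microbiopsies.

**Germline filter.** A rare heterozygous germline variant that escaped
panel-of-normals filtering sits near VAF 0.5 in *every* sample of a
patient (0.95 on male sex chromosomes, allowing hemizygosity plus
residual error). Reads are pooled across the patient's microbiopsies and
tested two-sided against `Binomial(pooled_depth, p0)` with an exact test
(likelihood-method two-sided p, computed by direct enumeration);
Benjamini–Hochberg correction is applied across mutations, and calls
with q > 1e-3 — i.e. those *consistent* with the germline hypothesis —
are flagged `germline`. The test is two-sided because contamination can
push germline VAFs both below and above p0.

**Overdispersion (ρ) filter.** Recurrent sequencing artifacts sprinkle
low-level signal over all samples and are well described by a single
binomial; true clonal mutations are present at high VAF in some samples
and absent from others, which demands a heavily overdispersed
beta-binomial. For each mutation the beta-binomial likelihood of its
alt/depth vector, with the mean fixed at the pooled VAF, is maximized
over a 100-point log-spaced grid of ρ in [1e-6, 10^-0.05]; calls with
ρ̂ < 0.1 are flagged artifacts. Fixing the mean at the pooled VAF keeps
the grid search one-dimensional and mirrors how a shared artifact would
actually behave; cells with zero depth contribute no likelihood term.

**DBS merging.** Adjacent substitutions are merged into a double-base
substitution when a two-sided Fisher exact test on their pooled alt/ref
counts shows no significant difference (p ≥ 0.05, configurable); runs
longer than two merge greedily left to right.

**Sensitivity.** Near-replicate pairs (the same histological feature
dissected twice and sequenced independently) estimate per-dissection
calling sensitivity as the fraction of one member's calls found in the
other, symmetrized and summarized by the median across pairs.

# Dirichlet-process VAF clustering

Mutations carried by the same clone share a VAF profile across the
patient's microbiopsies. We cluster autosomal SBSs with a Chinese
restaurant process mixture: each cluster has an unknown VAF per
microbiopsy with a conjugate Beta(1, 1) prior, emissions are
`Binomial(depth, vaf)`, and the partition follows a Dirichlet process
whose concentration is resampled every sweep under a Gamma(1, 1)
hyperprior (auxiliary-variable update). The collapsed Gibbs sampler
integrates cluster VAFs out analytically, so each sweep only touches
integer count sums; an integer lgamma lookup table makes the inner loop
cheap.

Numerical and design choices that matter:

* **Initialization is all-singletons.** Starting from one big cluster
  looks natural but cannot mix: with many zero-VAF microbiopsies the
  diffuse Beta(1, 1) predictive charges a new singleton roughly
  `-log(depth+1)` per covered dimension, so an established cluster is
  never escaped through a one-mutation state. Starting from singletons,
  clusters coalesce bottom-up within a few sweeps and genuinely distinct
  clones stay apart.
* **Point estimate.** After burn-in and thinning, the recorded partition
  minimizing Binder loss against the posterior co-clustering matrix is
  reported — a deterministic label-alignment rule. Under a fixed seed the
  whole fit is reproducible.
* **Centroids** are posterior means `(alt_sum + 1) / (depth_sum + 2)`
  per cluster and microbiopsy; cellular fractions are `CF = 2 x VAF`
  under the diploid copy-neutral assumption (copy-number analysis is out
  of scope).
* Clusters smaller than `min_cluster_size` (default 2) are dissolved
  into the best-fitting remaining cluster.
* Zero-depth cells are missing data, not evidence of absence.

Defaults are 3000 sweeps, 1000 burn-in, thinning 5; the test-suite and
examples run shorter chains (a few hundred sweeps) because the
coalescent initialization converges quickly at those problem sizes.

# Clone phylogeny by the pigeonhole principle

If clusters A and B together exceed 100% cellular fraction in some
microbiopsy, cells must carry both sets of mutations, so the
consistently smaller cluster is nested inside the larger — *strong*
evidence. Dominance without the combined fraction ever exceeding 1 is
only *weak* evidence; crossing CFs mean independent clones. Dominance is
assessed with a tolerance of ε = 0.05 CF (exact dominance is brittle at
depth ~50); strong evidence in both directions is flagged a conflict and
the pair left unresolved. Each cluster attaches to its tightest
superset (smallest mean CF), preferring strong over weak parents;
branch length is the cluster's mutation count, and a clone's burden is
its root-to-tip sum. Pruning keeps nested clusters only on strong
evidence and un-nested clusters only when their median member VAF
exceeds 0.3, discarding branches where a low-VAF "cluster" may actually
be a mixture of clones.

# Signature attribution

Spectra use the canonical 96 pyrimidine-centred trinucleotide classes.
The bundled catalog holds four synthetic process spectra shaped like the
processes active in psoriatic skin — UV dipyrimidine C>T (SBS7b-like), a
merged clock-like entry (SBS1-like CpG C>T plus a flat SBS5-like
component; the two are not separable at clone-level counts), an APOBEC
TpC entry, and the psoralen signature, which places all mass on T>A,
T>C and T>G at TpA sites (mutated T with 3' A), T>A emphasized. The
catalog is constructed in code, not copied from an external database.

Exposures are maximum-likelihood multinomial mixture weights fitted by
EM (convergence at relative log-likelihood change < 1e-8 or 10,000
iterations), scaled to attributed mutation counts; exposures plus the
optional sparsity-thresholded unassigned mass always equal the observed
total. De-novo signature discovery is deliberately out of scope: the
reusable computation is supervised attribution against a fixed catalog.

**Damage potential.** For a gene set, every possible SBS is enumerated
with its trinucleotide context and consequence (synonymous, missense,
nonsense, or splice — the 2 bp at each intron end); weighting sites by a
signature's class probabilities and normalizing by the same quantity
under a baseline (uniform rate or another signature) gives the relative
likelihood that the signature produces each consequence class. A
signature is interpreted as relative per-site rates by class, the
reading under which a flat signature coincides exactly with a uniform
mutation rate.

# Strand and replication analyses

For TpA mutations inside transcripts, the mutated T lies on the
untranscribed strand when its strand equals the gene's coding strand.
`strand_asymmetry` reports the untranscribed:transcribed ratio with an
exact binomial test. `tss_profile` bins mutations into twenty 1-kb
windows around the TSS per strand and expression quintile, normalizes to
the −10 kb bin, and tests transcription-coupled damage (TCD, on the
untranscribed strand) and repair (TCR, transcribed strand) by
likelihood-ratio tests between per-bin linear models with and without a
downstream-of-TSS indicator. Rates per expression decile are per-bp and
relative to the lowest decile. Replication effects report the
leading:lagging ratio of the mutated-T strand and per-timing-bin
relative rates; pentanucleotide enrichment normalizes observed 5-mer
counts by background 5-mer weights, where the ApTpApT double palindrome
is the expected top context under psoralen. Mutations in genes
overlapping on both strands are excluded from strand calls (strand
undefined). The per-bin TSS models are unweighted (bin coverage is
uniform in the generator; with real annotations a covered-bp offset
would be the natural refinement).

# Burden models

Clone burdens are modelled with linear mixed models carrying nested
random intercepts for patient and biopsy-within-patient — clones from
one biopsy share sun exposure, biopsies from one patient share
everything else. Fits compared by likelihood-ratio tests are ML; final
estimates are REML. Because psoralen mutations do not accumulate with
age, the "total burden" response is the clone burden minus its
psoralen-attributed exposure. The PUVA dose model regresses
psoralen-attributed burden on the ordinal PUVA band (dummy coding
against the no-PUVA band). Reported p-values for single coefficients are
Wald-normal; LRTs are preferred for model comparison. Detection-
sensitivity correction divides an observed burden by
`P(depth >= 4, alt >= 3)` under `depth ~ Poisson(mean_depth)`,
`alt ~ Binomial(depth, VAF)` — the model-consistent counterpart of the
genotyping rule, isolated in one function so a different correction can
be swapped in. Records missing disease duration are excluded from
duration models only.

The clonality summary regresses per-patient median microbiopsy VAF on
age, with an LRT for a psoralen-carrier indicator. The basal stem-cell
count of a microbiopsy is its projected area divided by the footprint of
a 9-µm cell, `area / (π 4.5²)`.

# Selection summary

The fraction of a patient's cells mutated in a gene is
`Σ 2·VAF·volume / Σ volume` over the patient's microbiopsies, computed
separately for lesional and nonlesional tissue and capped at 1 (with a
flag). When a clone carries several mutations in one gene only the
highest-VAF mutation counts (ties broken by genomic position); without
clone labels the rule applies per microbiopsy. Lesional and nonlesional
fractions are compared per gene with a paired Wilcoxon signed-rank test,
BH-corrected across genes.

# The synthetic cohort generator

`simulation_config()` defaults *are* the study conditions the package
targets:

| parameter | default | meaning |
|---|---|---|
| `age_effect` | 14.6 | non-psoralen exonic mutations/exome/year of age |
| `clock_age_effect` | 0.65 | SBS1/5 mutations/exome/year of age |
| `duration_effect_sbs15` | 0.16 | SBS1/5 mutations/exome/year of disease |
| `puva_extra_burden` | 616 | extra psoralen mutations/clone, >200-cycle band |
| `detection_sensitivity` | 0.89 | per-dissection call probability |
| `strand_asymmetry_tpa` | 1.72 | untranscribed:transcribed TpA ratio |
| `leading_lagging_ratio` | 1.09 | replication-strand ratio |
| `mean_depth` | 56 | mean sequencing depth |
| `age_range` | 18–88 | patient ages (uniform) |

Each biopsy receives 1 + Poisson root clones whose presence across
microbiopsies decays exponentially with distance (scale 500 µm, matching
the millimetre scale over which clones share microbiopsies); root CFs
are Beta(2.5, 1.5), rescaled when they would exceed 0.95 together, and
each root clone may carry one nested subclone at a U(0.4, 0.9) fraction
of its parent — calibrated so the median VAF of called mutations sits
near 0.26, the oligoclonal regime typical of adult epidermis.
Burden components per clade follow the mixed-model generative process
(patient and biopsy random intercepts, clone-level noise); the psoralen
component uses compositional Gamma noise (patient then clone level, CVs
0.3 and 0.2) so band means — and hence the 616-mutation band contrast —
hold exactly in expectation while burdens stay non-negative and
right-skewed. Reads are `depth ~ Poisson(mean_depth)`,
`alt ~ Binomial(depth, CF/2)`. Germline spikes are drawn at p = 0.5
(0.95 on male X) in every sample; artifact spikes share one low success
probability across samples (true ρ ≈ 0). Genic TpA mutations implement
the strand ratio inside transcripts (with a net transcription effect
`tc_net` = 0.89 < 1: repair outweighs damage, so genic rates drop with
expression), an expression-dependent gene weight, a timing-dependent
weight, and an independently drawn replication strand — origins fire
within genes, so coupling replication orientation to genes would only
add finite-annotation noise to a quantity the generator promises
exactly.

What the generator does *not* emulate: real genome sequence and context
frequencies (positions are random; contexts are drawn from the process
spectra), copy-number variation, clone competition dynamics, UV dose
heterogeneity across body sites beyond a site covariate, shared clones
across biopsies of one patient, and calling-pipeline artifacts beyond
the two spike families. Passing recovery tests therefore demonstrates
the estimators' correctness under the stated statistical model, not
robustness to everything real data can do.

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen to
keep Monte-Carlo error well inside each check's tolerance: mixed-model
recovery uses 100–300 patients with 5 clones each, averaged over three
replicate cohorts; strand/replication recovery uses 100,000 mutations
over 1,000 toy genes; clustering/phylogeny recovery uses three patients
at depth 100 with chains of ~800 sweeps; null calibrations use 500
replicates. Every stochastic step is seeded: cohorts are pure functions
of their configuration, the Gibbs point estimate is reproducible, and
the acceptance script derives all sub-seeds from its `--seed` argument.

# Known limitations

* Clusters are fit per patient; the hierarchical sharing layer across
  patients of the original nonparametric formulation is out of scope.
* Indels and DBSs are not clustered; they can be assigned post hoc to
  the nearest SBS cluster by VAF.
* Wald p-values in `lmm_fit` are normal-approximate; use `lrt_nested`
  for inference that matters.
* The damage-potential enumeration assumes single-isoform, in-frame gene
  models and a fixed 2-bp splice-site definition.
* `pigeonhole_nesting` is quadratic in clusters and intended for the
  tens of clusters a patient yields.
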