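---
title: "Simulating genomic and forward selection in a conifer breeding program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic and forward selection in a conifer breeding program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`conifergs` simulates a closed conifer breeding program forward in time and
asks a practical question: how much faster does genetic gain reach the forest
when selection is genomic (GS) rather than phenotypic forward selection (FS),
once the shorter breeding cycle and the available deployment pathways
(seedlings vs somatic-embryogenesis clones, clonal archives, top-grafting)
are accounted for?

This vignette explains the model, the choices behind its defaults, and what
the tests do and do not demonstrate.

## The simulated world

**Genome.** One chromosome of 150 cM carries a neutral SNP panel and 350
bi-allelic QTL. The single chromosome stands in for a 12-chromosome conifer
genome: a 600-SNP panel corresponds to roughly 7K genome-wide markers, 4,900
to 60K. Meiosis follows the Haldane model — crossover counts are Poisson with
one expected crossover per Morgan, break points uniform, no interference.
The map function is our choice; nothing in the study design pins it down,
and at these marker densities interference would be a second-order effect.

**Demography.** Three phases build the population that enters the breeding
program:

1. *Historical*: 500 generations of random union of gametes, 300 female and
   300 male parents, constant size 1,000, recurrent mutation at 1e-5 per
   locus per gamete. Founders start in linkage equilibrium with allele
   frequencies uniform on (0.10, 0.90); LD accrues by mutation-drift
   balance.
2. *Extended*: 10 generations at size 500 (100 + 100 parents), mutation
   still active. The bottleneck pushes short-range LD towards the level of a
   closed breeding population.
3. *Recent*: 10 discrete generations of the breeding program proper — 32
   female and 32 male parents selected on BLUP EBVs, mated in a ring in
   which each parent is crossed with its two neighbours (64 crosses), 15
   offspring per cross (960 clones), 4 phenotyped ramets per clone, no
   mutation.

Conifers are monoecious; sexes here are random 50:50 labels that constrain
parent selection, mirroring the sexed-parent structure of the original
design. The ring alternates females and males in EBV-rank order — the
design fixes "each parent crossed twice" but not the arrangement, and
rank-adjacent pairing is the natural reading of a circular mating plan among
selected parents.

**Marker panel timing.** The SNP panel is *finalized at the start of the
recent phase*: surplus candidate loci are carried through the burn-in and
the panel is drawn among loci with minor allele frequency above 0.10 in the
population entering the breeding program (`finalize_panel()`). QTL are drawn
among segregating candidates at the same point. This mirrors how panels are
ascertained in practice and leaves only a few percent of panel markers to
drift out of range during the breeding phase — consistent with the program's
panel bookkeeping, in which 576 of 600 simulated SNPs still contribute to genomic
prediction. Fixing the panel at founding instead would lose more than a
third of the markers to 510 generations of drift.

**Trait.** QTL substitution-effect magnitudes are gamma(shape 0.50,
scale 26) with random signs, rescaled by one constant so that the variance
of true breeding values (TBVs) in the population entering the breeding
program is exactly the additive variance, 300 (squared trait units; the
reference traits are diameter growth in mm and wood density in kg/m³). TBVs
are centred there, so "gain above a base mean of zero" is well defined.
Non-additive variance is a clone-level deviation, 15% of the additive
variance (45); there is no explicit dominance or epistasis at individual
QTL. The residual variance solves
h² = σ²a / (σ²a + σ²d + σ²e), giving σ²e = 255 at h² = 0.5 and 1,155 at
h² = 0.2. The design fixes h² and the two genetic variances but leaves σ²e
implicit;
treating h² as narrow-sense over the full phenotypic variance is our
recorded choice. Phenotypes are exactly TBV + clone deviation + ramet
residual.

## Genetic evaluation

EBVs come from Henderson's mixed-model equations for
y = μ + Z_a a + Z_d d + e with var(a) = A σ²a, var(d) = I σ²d over clones
and var(e) = I σ²e, with variance components fixed at the simulation truth
(no REML — the values are known by construction). The non-additive
relationship matrix is the identity over clones: ramets of a clone share one
deviation and distinct clones are uncorrelated, exactly matching how the
deviations are simulated. A is the full tabular-method numerator
relationship matrix.

Two implementation details matter:

* For balanced ramet data the clone effect can be absorbed exactly: clone
  means are sufficient, with residual variance σ²d + σ²e/m per mean. The
  record-level and clone-mean solvers agree to numerical precision
  (`solve_mme()` vs the internal fast path; tested).
* Each recent generation is evaluated on a *rolling two-generation*
  pedigree: grandparents enter as founders, the 64 parents carry their own
  records from the previous generation, and the 960 offspring carry
  theirs. A single evaluation of the full cumulative pedigree (~10,000
  individuals by generation 10) is what a production analysis would run;
  the rolling window keeps the dense mixed-model equations near 1,000
  unknowns per generation while retaining the information that matters
  most — own records, sib structure, and parent records. One consequence
  is that EBVs are deviations from each evaluation's own base rather than
  from a single program-wide base.
* Two evaluations run on that pedigree. The *full* evaluation uses all
  four ramets per clone and supplies the response and accuracy weights for
  genomic training. The *selection* evaluation uses a single record per
  clone and drives parent selection and the forward-selection comparator.
  The reason for the split is empirical: the breeding program this design
  emulates reports selection-stage EBV accuracies of 0.52 (h² = 0.2) and
  0.75 (h² = 0.5) — exactly the single-record BLUP regime (√h² plus
  pedigree information), not the ~0.69/0.87 a four-ramet clone mean would
  give — and its per-generation gains are only consistent with selection
  at that accuracy. Selecting on clone means instead over-selects: the
  program strip-mines its own genetic variance within a few generations
  and every realized quantity in the final generation collapses.

Per-clone accuracies r_i = sqrt(1 − PEV_i / (A_ii σ²a)) come from the
inverse coefficient matrix. Realized accuracy — the correlation between
(G)EBVs and true breeding values across the 960 prediction clones — is
reported separately, and is the quantity the accuracy tables report. The two differ under selection: PEV-based accuracies
refer to unselected-base variance, while ten generations of truncation
selection deplete the realized genetic variance (Bulmer effect plus fixation
of large-effect QTL), which lowers realized correlations.

## Genomic prediction

SNP effects are estimated by BayesC: each SNP has zero effect with prior
probability π = 0.95, otherwise a normal effect with a common variance
carrying a scaled inverse chi-square prior (ν = 4.2). The Gibbs sampler
cycles per-SNP inclusion indicators and effects, the common effect variance,
the residual variance and the mean; posterior means over the post-burn-in
iterations give the effect estimates. Defaults are 40,000 iterations with
4,000 discarded — the design fixes the total chain length but not the
burn-in; 10% is conventional. The prior scale of the effect variance is
derived at chain start from the expected per-SNP variance
σ²a / ((1 − π) Σ 2 p q); it is configurable.

The response is the vector of training-clone EBVs, weighted per clone by
the Garrick de-regression weight
w_i = ((1 − h²)/h²) / (c + (1 − r_i²)/r_i²), with the weight scaling the
residual variance of that record. c, the fraction of genetic variance not
captured by the markers, is not pinned down by the design;
0.5 is a conventional default and is configurable. Training clones are drawn
at random from generations 4–8; the prediction population is the 960 clones
of generation 10; markers monomorphic or below 1% MAF in the training set
are dropped. GEBVs are X â over the kept SNPs, centred on training means,
and their realized accuracy is cor(GEBV, TBV) in the prediction population.

## Gain accounting and deployment

Nine of the 960 prediction clones (1%) are selected on EBV (the FS
comparator) or GEBV (GS); the gain per generation is the mean *true*
breeding value of the selected clones minus the candidate mean — the
selection criterion never grades itself. Gains per year divide by the
generation interval: 17 years (FS), 14 (FS with a clonal archive, FSCA), 9
(GS), 7 (GS with top-grafting, GSTG). FSCA and GSTG reuse FS's and GS's
per-generation gains: the archive and top-grafting shorten the cycle
without changing the selection. In the per-year benefit table the
percentages are computed from the 2-decimal rounded rates, because that is
the convention under which every published cell (including the
−47% GSTG cell at h² = 0.2, TP = 800) reproduces exactly.

Deployment is an exact scheduling computation. Breeding cycle i selects at
year B_i = T_cs + G(i − 1); its material reaches the forest in the T_sd-th
year after selection *counted inclusively*, D_i = B_i + (T_sd − 1), with
T_sd = 8 (FS seedlings), 5 (other seedling options) or 1 (clonal options,
i.e. availability in the selection year). Eight 25-year rotations start
back-to-back at years 0, 25, …, 175; each rotation deploys the newest
available cycle, whose material carries merit i·g. This inclusive-year
convention is the unique simple one that reproduces every published total
(37 g for FS seedlings, 72 g for GS seedlings; 8.11%, 21.62%, 24.32% for
the FS/FSCA contrasts) and is locked by regression tests plus an
independent year-by-year calendar oracle. Two recorded quirks: the merit of
cycle-i material is i·g, following the worked rotation example rather than
the ambiguous "g(b_i − 1)" formula; and the GS clone option's availability
uses the GS scheme's 9-year selection points, although the published
timeline table prints 7 years crossing-to-selection for that row — the
published deployment percentages are only consistent with 9.

## Problem sizes, presets and what the tests show

The `"full"` preset mirrors the study conditions (500-generation burn-in,
panels up to 4,900 markers, training populations of 800–3,000, 40,000 MCMC
iterations). The `"desk"` preset — used by the test suite — keeps the
demography untouched but shrinks panels to ≤ 600 markers, chains to 2,000
iterations, and training populations to 133/167/333/500 — the full-scale
800/1,000/2,000/3,000 grid scaled by one sixth so the largest desk cell
stays at 500 clones while the grid keeps the same relative spacing. Ten
replicates are the default at both scales. Within a replicate,
factorial cells use *nested* training-set and marker subsets (a smaller
cell is a prefix of a larger one), so trend contrasts across cells are
paired comparisons instead of being diluted by independent subsampling
noise. The demography is
deliberately not reduced: the burn-in is what establishes the
linkage-disequilibrium regime (a 100-generation burn-in leaves adjacent-pair
LD near 0.07 instead of ~0.15–0.2, starving the genomic-prediction signal),
and the compiled meiosis core makes the full 510 generations a matter of
seconds. The acceptance script runs the full
demography with the 600-SNP panel and 20,000-iteration chains over twelve
replicates: at that panel size the whole genome fits easily in memory, the
chain's Monte Carlo error on posterior-mean effects is far below
replicate-to-replicate spread, and twelve replicates put the standard error
of the mean realized accuracy near 0.035.

The synthetic world deliberately omits several features of real conifer
data: genotyping and phenotyping errors, missing data, environmental trends
and genotype-by-environment interaction, multi-chromosome genomes, overlap
between generations, and any imputation between marker densities. Passing
tests therefore demonstrate the internal consistency of the machinery and
the reproduction of the design's arithmetic and trends under its stated
conditions — not performance on field data.

Two empirical observations from running the pipeline at full scale are
worth recording as known behaviour. Short-range LD among panel markers at
the start of the breeding phase averages about 0.15–0.2 for the 600-SNP
panel, in the neighbourhood of the 0.17 average reported for the
radiata-pine-like populations this simulation emulates (the exact pair set
behind such figures — adjacent pairs or a window — is rarely stated; we
report adjacent-pair means and do not treat reported values as targets).
And ten generations of truncation selection deplete the prediction
population's genetic variance substantially — the gamma effect distribution
concentrates variance in a handful of QTL, which selection fixes within a
few generations — so realized accuracies and per-generation gains in the
final generation sit well below what the unselected base would support, and
are sensitive to exactly how the evaluation base and selection history are
modelled; the dual evaluation documented above is this package's fixed
choice. A corollary worth stating plainly: because selection accuracy rises
with heritability, the high-heritability program erodes its generation-10
variance faster than the low-heritability one, and the realized genomic
accuracy in that final generation can order *against* heritability at small
training sizes. The test suite documents this: the training-size and
marker-density trends and the genomic-vs-pedigree comparison hold, while
the heritability ordering of final-generation genomic accuracy does not
reproduce at desk scale.

## Numerical choices and degenerate inputs

* Ties in truncation selection break by clone id, making selections
  deterministic under replicated criteria.
* Monomorphic loci yield undefined LD; they are excluded from averages and
  counted, never silently zeroed. Empty distance bins are missing, not zero.
* A clone with zero EBV accuracy would need infinite residual variance in
  the weighted sampler; such records are dropped with a warning.
* The Gibbs sampler refuses non-finite responses, reports divergence with
  the iteration index, and is bitwise reproducible given a seed because all
  randomness flows through R's RNG.
* Singular mixed-model systems (e.g. confounded mean and genetic effects,
  duplicated genotypes in A) raise errors naming the confounded terms
  rather than returning silently regularized solutions.
* All stage seeds derive from one master seed; no stage consumes another's
  stream.
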