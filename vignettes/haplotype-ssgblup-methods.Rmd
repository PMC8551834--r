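---
title: "Haplotype-based single-step genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based single-step genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hapstep` studies whether haplotype information improves single-step
genomic prediction (ssGBLUP) in livestock populations of different
genetic diversity. This vignette documents the models it implements, the
assumptions behind the simulator, the tunable parameters and their
defaults, the numerical choices, and the limits of what the package's own
tests can show.

# The prediction models

All evaluations use the animal model

$$\mathbf{y} = \mathbf{X b} + \mathbf{Z u} + \mathbf{e},\qquad
  \mathbf{u} \sim N(\mathbf{0}, \mathbf{H}\sigma^2_g),\quad
  \mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e),$$

with the generation class as the only fixed effect (first level absorbed
into the intercept). $\mathbf{H}$ combines pedigree and genomic
relationships so genotyped and non-genotyped animals are evaluated
jointly; its inverse enters the mixed-model equations directly:

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
  \begin{bmatrix} \mathbf{0} & \mathbf{0} \\
  \mathbf{0} & \tau(\alpha\mathbf{G} + \beta\mathbf{A}_{22})^{-1} -
  \omega\mathbf{A}_{22}^{-1}\end{bmatrix}.$$

$\mathbf{G}$ is VanRaden's first method,
$\mathbf{G} = \mathbf{MM}'/(2\sum_i p_i(1-p_i))$, with dosages centred by
twice the allele frequency of the *current genotyped set* (the usual
evaluation-software default) and missing dosages mean-imputed to $2p_i$
before centring. Defaults $\alpha = 0.95$, $\beta = 0.05$,
$\tau = \omega = 1$. Blending is not cosmetic: with data-derived
frequencies $\mathbf{M}$ has zero column means, so raw $\mathbf{G}$ is
singular (the ones vector lies in its null space) and only
$\alpha\mathbf{G} + \beta\mathbf{A}_{22}$ is invertible.

Four marker configurations define the model variants: individual SNPs
(HD or medium panel); independent (non-blocked) SNPs plus pseudo-SNPs in
one $\mathbf{G}$; pseudo-SNPs only; and independent SNPs and pseudo-SNPs
in two relationship matrices,
$\mathbf{y} = \mathbf{Xb} + \mathbf{Z}\mathbf{u}_1 +
\mathbf{Z}\mathbf{u}_2 + \mathbf{e}$ with
$\mathbf{u}_k \sim N(\mathbf{0}, \mathbf{H}_k \sigma^2_{g_k})$ assumed
uncorrelated (no covariance term is offered) and overall GEBV
$\mathbf{u}_1 + \mathbf{u}_2$.

Before any genomic model runs, the off-diagonals of
$\alpha\mathbf{G}+\beta\mathbf{A}_{22}$ are correlated with those of
$\mathbf{A}_{22}$; a correlation below `minGACor` (default 0.30, exposed
as a parameter because no standard numeric cutoff exists) marks the scenario
`skipped_poor_G` rather than producing GEBVs from incoherent genomic
information. REML non-convergence likewise yields
`failed_convergence`; failures propagate as status codes, never
silently.

# Solving and variance components

The mixed-model equations are solved by Jacobi-preconditioned conjugate
gradient (relative-residual tolerance $10^{-12}$, cap 5000 iterations; a
direct sparse factorisation backs the oracle tests). GEBVs of validation
animals — genotyped, never phenotyped — propagate through the
$\mathbf{H}$ structure.

`estimateVarComps()` offers three routes to the same REML maximum:

* **profile** (default): the restricted likelihood profiled over
  $\sigma^2_e$ is an exact function of the variance ratios
  $\lambda_k = \sigma^2_e/\sigma^2_{g_k}$ computable from one sparse
  Cholesky factorisation of the MME per evaluation,
  $-2\ell_R(\lambda) = (n-p)(1 + \log\hat\sigma^2_e) -
  \sum_k q_k\log\lambda_k + \log|\mathbf{C}(\lambda)| + \text{const}$.
  One-dimensional problems use golden-section search, two-component
  models Nelder–Mead in $\log\lambda$. This scales to the pipeline's
  population sizes (tens of thousands of equations) because it never
  forms dense traces.
* **ai**: average-information updates with exact trace terms from a
  dense factorisation, falling back to an EM step whenever the AI update
  leaves the parameter space; bounded to mid-sized problems (~8000
  equations). Tests verify it lands on the profile optimum.
* **em**: plain EM, monotone but slow; used as a reference.

Convergence is a relative parameter change below `tol` (default
$10^{-8}$). Non-convergence and boundary estimates are reported, not
raised, so the scenario runner can record them. The degenerate
two-component model with duplicated marker sets has a flat likelihood
ridge; AI-REML is expected to flag it rather than "converge".

# The simulator

The generator defines the study conditions; its defaults are the
conditions under which every reported number in this package is computed.

**Historical phase.** Random union of gametes with a census schedule
(linear interpolation between breakpoints) expressing a bottleneck and
recovery; recurrent mutation (rate $10^{-4}$ per locus per gamete:
allele flip for bi-allelic markers, uniform redraw within the allele set
for QTLs) acts in this phase only, the standard behaviour of breeding-
program simulators. Markers start at frequency 0.5; QTLs (2–6 alleles,
uniformly drawn) start at equal allele frequencies. Recombination is a
Poisson process along the genetic map (Haldane, no interference), with
1 cM = 1 Mb for physical coordinates — the accepted approximation in
sheep.

**Panels and trait.** Marker panels are sampled per chromosome from
candidates still segregating (MAF ≥ 0.05) after the historical phase;
the medium panel nests inside the HD panel. Per-allele QTL effects are
gamma(shape 0.4) with random sign, centred and rescaled so the realised
QTL variance in the founder generation equals `qtlH2 * varPheno`; the
remaining genetic variance, `(h2 − qtlH2) * varPheno`, is an
infinitesimal polygenic term (founders $N(0, \sigma^2_{poly})$;
offspring get the parent average plus a Mendelian deviation with
variance $\tfrac12\sigma^2_{poly}(1-\bar F_{parents})$, inbreeding from
Meuwissen–Luo). Phenotype = mean + TBV + $N(0, (1-h^2)\,\sigma^2_P)$,
with $\sigma^2_P = 100$ and $h^2 = 0.30$ (QTL half) or $0.10$ (QTL
one-tenth).

**Recent phases.** Each generation every breeding female has one litter
of 1/2/3 lambs with odds 0.30/0.50/0.20 by a randomly assigned male;
dams per sire 25, replacement rates 40% (sires) and 20% (dams), female
herd growth 0.10 or 0.15 per generation to a cap. Candidates are ranked
by phenotype, by pedigree-BLUP EBV solved on all records to date with
the true variance components (a deliberate simplification; see the
limitations section), or randomly; ties break by a
seeded shuffle. Composites are founded by sampling the parent breeds
after their phenotypic-selection phase in the stated admixture
proportions (62.5/37.5 and 37.5/37.5/25.0), mate at random for five
generations, then enter EBV selection like the pure breeds.

**Genotyping.** True dosages from the stored phase are perturbed: 5%
missing calls and 1% of the rest replaced by a random different code.
Quality control keeps loci with MAF ≥ 0.01 whose heterozygote frequency
departs from $2p(1-p)$ by less than 0.15. Haplotype blocking and
pseudo-SNP encoding use the simulator's true phase (genotype phasing is
deliberately out of scope), jointly for the genotyped training and
validation sets.

# Haploblocks and pseudo-SNPs

Within a sliding window of `windowSnps` (default 100) consecutive SNPs,
an interval of ≥ 2 SNPs is a *candidate block* when (i) every member has
$r^2 \ge$ threshold with at least one other member and (ii) the mean
pairwise $r^2$ of the interval reaches the threshold. A non-overlapping
set of candidates maximising the total number of SNPs covered is chosen
by weighted-interval-scheduling dynamic programming, with deterministic
tie-breaks (earlier start, then longer). This is a documented
approximation with the same inputs (pairwise $r^2$, threshold) and the
same output contract (non-overlapping multi-SNP blocks) as the
clique-based LD-block literature; the stage is a plain function, so an
alternative blocking implementation can be swapped in. Tests pin the
selection to exhaustive enumeration on small maps.

Each block's distinct haplotype strings (enumerated over the genotyped
sets; alleles absent there get no pseudo-locus) become pseudo-loci whose
dosage is the carried copy number, so block dosages sum to 2 per
individual. Gametes with missing alleles inside a block contribute twice
the allele frequency instead (mean imputation, flagged). Pseudo-SNPs
pass the same QC as SNPs, each treated as bi-allelic (this allele vs
all others).

# Diversity estimators

$r^2$ is the squared correlation of allele indicators across gametes
(equal to $D^2/(p_A q_A p_B q_B)$ from the haplotype table; a dosage-
correlation fallback serves unphased input). `Ne_LD` inverts Sved's
$E(r^2) = (4N_ec+2)^{-1}$ at a target distance (default $c = 0.1$ M,
i.e. 10 Mb ≈ five generations ago, taken as current Ne) using marker
pairs within ±5% of the target distance — the distance binning is not
specified in the source literature, so it is a parameter. Both pooled
and per-chromosome averaging are exposed, pooled being the default.
`Ne_Inb` uses the realised rate of inbreeding between the last two
generation means. No small-sample correction of $r^2$ is applied
(deliberately out of scope), so LD-based Ne carries a mild downward bias
of order $1/(2n)$ relative to the census in small samples.

# Reduced scale: sizes and what they imply

The shipped default (`presetReduced()`) is sized for a desk, not a
cluster, and every count is configuration: 5 × 100 cM chromosomes;
4,000 HD / 1,000 medium markers; 300 QTLs; 125 historical generations
(census 600 → 350 bottleneck → 800 recovery); founder sizes 150
(Breed_A/B), 300 (Breed_C), 550 (Breed_D/E); female herd capped at 250
dams (≈ 480 offspring per generation at the cap); training/validation
split 1,500 phenotyped (EBV generations 1–8), 400 genotyped among them
(generations 4–7), 150 genotyped validation animals (generations 9–10),
generation 8 a genotype gap; whole pedigree retained. These sizes keep a
full five-replicate scenario comparison plus REML within minutes while
preserving the design's structure: a small-founder breed with strong LD
(blocks form even at $r^2 \ge 0.6$), larger-founder breeds and
composites with weaker LD. The full-scale design (26 ovine autosomes
totalling 2,656 cM, 576,595/46,827 markers, 3,057 QTLs, 80,000-strong
historical population, 60,000/8,000/2,000 split) ships as
`presetPaper()`; running it is a cluster-scale exercise, and the
absolute accuracies it would deliver are *not* reproducible at desk
scale, where training sets are ~40× smaller. What is reproducible — and what the
acceptance tests assert — is the qualitative structure: pseudo-SNP-only
models are less accurate and more biased than SNP models in every
replicate, combined models are statistically indistinguishable from SNP
models, the medium panel tracks the HD panel within 0.02, and pedigree
REML on the selected small-founder breed returns a realised heritability
close to — and, as expected under selection, slightly below — the
simulated 0.30. The acceptance script averages that
REML estimate over ten replicates to keep its Monte-Carlo error small.

The tiny fixtures used in unit tests relax `minGACor` to 0.10: with only
~100 markers the genomic relationships are noisy, and the smoke tests
exercise the pipeline, not the gate.

# What the generator does not emulate

Only additive gene action is simulated — no dominance, epistasis or
genotype-by-environment interaction (a common explanation in the
literature for why haplotypes do not beat SNPs in purely additive
simulations). Phasing is perfect; real pipelines phase statistically and
phasing error would erode pseudo-SNP quality. There are no genotyping
batch effects, no pedigree errors, no selective genotyping, and sex
chromosomes are absent. Passing tests therefore demonstrate internal
correctness and the stated qualitative contrasts under these idealised
conditions, not performance on real data.

# Numerical notes and degenerate inputs

* Dosage storage is one byte per allele; meiosis and Meuwissen–Luo
  inbreeding are compiled kernels driven by R's RNG, so a single seed
  makes whole replicates bit-reproducible.
* The profiled REML objective was validated against the direct
  $\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| +
  \mathbf{y}'\mathbf{Py}$ form on small fixtures; AI and EM land on the
  same optimum.
* Component heritabilities are bounded to $(5\times10^{-4}, 0.9995)$
  during optimisation; estimates at the bound are flagged `boundary`
  (e.g. pure-noise phenotypes).
* Monomorphic loci: excluded from LD (undefined $r^2$), removed by QC
  (MAF rule), harmless in $\mathbf{G}$ (zero-variance columns add
  nothing, but an all-monomorphic panel is an error since the VanRaden
  scale is zero).
* Degenerate blocks: a monomorphic block yields one pseudo-locus with
  all dosages 2, which QC then removes.
* Tie-breaks everywhere are deterministic (seeded shuffle in selection,
  earlier-start/longer-interval in blocking), so fixed seeds give
  identical scenario tables across machines.

# Known limitations

Pedigree-BLUP EBV selection uses the true variance components rather
than re-estimating each generation (re-estimation would slow the simulator several-fold for little
behavioural difference). The weighted-interval blocking is an
approximation to clique-based LD partitioning; block boundaries can
differ from that family of algorithms even though the counts behave the
same way with threshold and diversity. Dense `aMatrix()` is intentionally
capped (~12,000 animals); larger pedigrees use the sparse inverse and
`aSubmatrix()`. The two-component model often sits on a flat likelihood
ridge when the two marker sets carry overlapping signal — exactly the
convergence fragility reported for such parameterisations — and is
reported as non-converged rather than papered over.
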