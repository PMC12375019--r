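---
title: "Viability-selection and structural-variant scans in hybrid zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viability-selection and structural-variant scans in hybrid zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hzscan)
```

## The problem

Hybrid zones are natural experiments in selection against (or occasionally
for) admixture. When hybrids suffer an ecological mismatch — for example,
intermediate and inferior seasonal-migration routes — their reduced
survival leaves a footprint in cross-sectional samples: genotypes that
lower viability become rarer in older age classes. `hzscan` implements
this viability-scan logic for cohorts genotyped at ancestry informative
markers (AIMs), together with the follow-up analyses such a scan feeds:
gene-overlap enrichment, and a structural-variant evidence suite
(inversions suppress recombination in heterokaryotypes and leave joint
signatures in local PCA, LD, heterozygosity and Hi-C contact maps).

## Data model

Genotypes are ancestry states at AIMs: 0 = homozygous coastal ancestry,
1 = interspecific heterozygote, 2 = homozygous inland ancestry, with
missing calls allowed. Two per-individual summaries drive everything:

- genome-wide ancestry `q` = (mean state)/2, so a parental coastal bird
  scores 0, an F1 hybrid 0.5, a parental inland bird 1;
- interspecific heterozygosity `h` = proportion of loci with state 1.

Hard calls come from ancestry posteriors with a strict `> 0.9` rule
(anything at or below the threshold is missing), and AIMs are selected
from parental panel counts with a strict `> 0.5` allele-frequency
difference. Both thresholds are deliberately strict inequalities and are
exposed as parameters.

## The scans

**Per-locus scan** (`het_scan`). For each locus, the binary heterozygosity
indicator is regressed on `ancestry * age + sex` with a binomial-logit
GLM; age is coded 0/1/2 (HY, SY, ASY). The age term captures uniform
viability selection on heterozygosity; the ancestry-by-age interaction
captures selection whose direction depends on genomic background. Wald
tests on individual coefficients give per-term p-values; Benjamini-
Hochberg q-values are computed in two strata (all autosomes pooled, Z
chromosome alone) because the Z has its own effective test density;
outliers are `q < 0.05`, strict.

Age is coded numerically rather than as an ordered factor: the prediction
curves of interest are monotone across three classes, and a single linear
coefficient gives the single per-term p-value the scan reports. The
ordered-polynomial alternative is available via `age_coding = "factor"`
(the reported age p-value is then the linear contrast).

**Pairwise mismatch scan** (`pair_scan`). For a pair of loci, an
individual's ancestry mismatch is its perpendicular Euclidean distance
from the line joining the parental mean-genotype anchors at those loci;
with anchors (0,0) and (2,2) this reduces to `|s_i - s_j|/sqrt(2)`. The
same design is fitted with a Poisson log-link GLM. The response is a
continuous non-negative distance, so the "Poisson" fit is really a set of
quasi-likelihood estimating equations with dispersion fixed at 1; the
coefficients and Wald statistics are identical to a Poisson fit and the
caveat (real dispersion is below 1, so p-values are conservative) is
documented here once rather than warned about per pair. The full pair
universe is quadratic in loci and is gated behind `allow_all = TRUE`;
the normal interface takes an explicit or randomly subsampled pair list
with a recorded seed.

**Degenerate cases.** Loci with fewer than 20 complete cases or a
monomorphic response are skipped with flags. Apparent complete separation
(|coefficient| > 30 on the logit scale) marks the fit non-converged and
its p-values missing — the plain GLM is kept, penalized regression is
deliberately out of scope. Pairs with coincident anchors or constant
distances are skipped and counted.

## Enrichment

Linkage blocks are intervals spanning all same-chromosome loci with
`r2 > 0.5` (strict) against a focal locus; genes overlap a block if their
1-based closed intervals share at least one base (BED input is converted
from 0-based half-open on read). With `a` of `b` block genes tied to
viability and `c` candidates, the expected overlap is `(a/b)*c` and the
test is a 1-df goodness-of-fit chi-square over the candidates split into
overlap / non-overlap — algebraically the squared one-sample proportion
z-statistic. An exact binomial tail is reported alongside as a
cross-check. The recombination contrast is a two-sided Wilcoxon rank-sum
test with midrank ties, computed by exact enumeration when both groups
have at most 10 observations and by a tie-corrected normal approximation
otherwise.

## Structural-variant suite

Local PCA runs in non-overlapping 100 kb windows: genotypes are
mean-imputed per locus (PCA only — scans never impute), centered, and the
top-2 eigenpairs of the individuals-by-individuals covariance summarize
each window. The distance between windows is the Frobenius distance
between their rank-2 covariance reconstructions, computed through the
eigenvalue/eigenvector identity rather than by forming the matrices.
Classical (Torgerson) MDS embeds the window distances; k-means on two MDS
axes with the mean silhouette choosing k (ties to the smaller k)
summarizes the landscape. Outlier windows satisfy `|z| > 1` on MDS1 —
absolute value because an MDS axis has arbitrary sign; a signed option
exists — and regions are maximal runs of at least 10 consecutive windows
(gaps break runs). Region genotyping is PCA plus k-means (k = 3) on PC1
with clusters ordered by their PC1 means; an inversion predicts the
central cluster to be heterokaryotypic, with the highest
region-restricted heterozygosity, and LD elevated across all samples but
absent within the major homokaryotype cluster.

## Hi-C comparison

Contact matrices are compared as: coverage masking (log1p row sums
z-scored once, single pass, bins outside [-1.5, 5] masked), ICE-style
iterative balancing to equal row visibility (tolerance 1e-5, 200
iterations), scaling the higher-coverage matrix down to the common total,
block-summing bins (10 kb to 1 Mb by default), and an entrywise log2
ratio with zeros and masked bins propagated as missing. The balancing
algorithm is the package's choice: the tool chain the field uses names
only the thresholds, and iterative correction is the simplest method with
the required fixed point. The pipeline order (mask, balance, normalize,
merge, ratio) is recorded in every run manifest.

## The synthetic cohort generator

`simulate_cohort` generates the statistical structure the scans assume,
plus ground truth for recovery testing. Haplotypes are two-state Markov
ancestry tracts along each chromosome (switch probability per gap =
`tract_switch_rate` x gap in Mb), a deliberate simplification: it creates
the block-wise ancestry LD the scans exploit without coalescent
machinery. Individuals come from a mixture of ancestry classes — parental
coastal/inland, F1, backcrosses, and a dominant later-generation class
whose individual ancestry proportions follow a Beta distribution — with
defaults (2/5/1/2/5/85 percent; Beta concentration 1.5) chosen to emulate
the center of an old, deeply admixed zone with a broad ancestry spectrum
and a mean inland ancestry of 0.77; the later-generation Beta mean is
solved so the cohort hits the configured target mean.

Age classes arise mechanistically from viability: each bird survives two
annual transitions with logit-linear survival, and the cohort is the
cross-section of survivors (HY/SY/ASY = 0/1/2 transitions survived). The
planted effects are:

- `beta_het` (and optionally `beta_int`, multiplying het by q) at target
  loci — per-locus selection on interspecific heterozygosity;
- `beta_dq` at target pairs — selection on the pair's mismatch distance
  whose sign flips around the mean ancestry (`(q - 0.77) * d`), mirroring
  the empirical pattern that mismatch declines in coastal-leaning birds
  and rises in inland-leaning ones, and loading squarely on the
  ancestry-by-age interaction the scan tests.

Two design decisions matter for interpreting recovery tests. First, the
planted effects are orthogonalized to genome-wide ancestry before use
(their q-conditional mean, a cubic fit, is absorbed into the survival
baseline): selection is locus- or pair-specific *conditional* on q, and q
itself confers no survival differential. Without this, any strong
one-directional selection shifts the survivor ancestry distribution, and
because per-locus heterozygosity depends on q non-linearly while the scan
controls q linearly, every locus in the genome inherits a spurious age
signal; the orthogonalized generator isolates the per-locus mechanism the
scan is meant to detect. Second, default effect sizes (`beta_het = -2`,
`beta_dq = -6`, baseline survival logits 0.5/0.5) are calibrated once for
detectability at the study's cohort size (about 900 birds): the source
system does not report effect sizes, and these choices put the planted
Wald statistics comfortably above the noise floor of a few hundred
competitors without driving genotype classes extinct in the oldest class
(which collapses Wald tests — the Hauck-Donner effect).

The inversion is modelled as an ancestry-defining arrangement: each
haplotype draws one ancestry for the whole interval, so heterokaryotypes
are heterozygous at every interval locus and recombination is effectively
suppressed. Homokaryotypes are then exactly monomorphic across the
region, so analyses that need within-arrangement polymorphism (the LD
homozygote contrast) use a small per-haplotype ancestry-call error rate
(`ancestry_error = 0.05` in the packaged tests) to emulate call noise.

What the generator does *not* emulate: genotyping error by default,
kinship and family structure, sex-linked (hemizygous) Z genotypes in
females, spatially varying sampling sites, realistic demography or
mutation, and real LD decay within ancestry blocks. Passing recovery
tests therefore demonstrate that the estimators detect the mechanisms
they target under the stated statistical structure, not that the
thresholds are optimal for any particular empirical system.

## Calibration caveat worth knowing

Under a strict null (no selection) with the broad default ancestry
mixture, the scan's raw p-values are *conservative* at some cohort draws:
the linear-logit control of q is misspecified against the curved
relationship E[het | q], and because all loci share one design matrix,
the miscalibration is correlated across loci. The packaged calibration
test therefore uses a later-generation-only cohort with a moderate
ancestry spread (Beta concentration 8), for which the linear control is
locally adequate and the age and interaction p-values are uniform. The
practical reading for real data: a genome-wide excess of small p-values
should be interpreted against this shared-design behavior, and the
deficit direction (conservative) does not produce false positives.

## Problem sizes used by the packaged tests

Recovery and calibration tests run at reduced genome scale chosen as the
package's standard validation sizes: 5 chromosomes x 40 loci for the scan
tests (cohorts of 400-900), a 2-chromosome genome with 1,000 loci on a
10 Mb chromosome for the inversion suite (300 birds, 2.5 Mb planted
inversion, 25 windows), and 300-bin contact matrices merged 10-fold for
the Hi-C pipeline. Each test fixes its seed and states its configuration
inline.
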