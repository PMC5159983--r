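---
title: "Methods: PMD/HMD segmentation and differential methylation in placental WGBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMD/HMD segmentation and differential methylation in placental WGBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placemeth)
```

# The problem

The human placenta carries a methylome unlike adult somatic tissue: large
partially methylated domains (PMDs, typically > 100 kb, intermediate
methylation) alternate with highly methylated domains (HMDs). Because the
signal of interest is the *regional* methylation level, low-coverage WGBS
(×1–2 per sample) suffices once counts are pooled over windows and domains —
individual CpG calls at that depth are nearly binary and uninformative on
their own. `placemeth` implements the complete analysis built on that idea:
pooled consensus mapping, supervised HMM segmentation of domain boundaries,
per-sample domain summaries, an X-chromosome-based estimate of maternal
blood contamination, and group-difference testing with FDR control.

# Containers and conventions

All coordinates are 0-based half-open, matching BED. CpG-report input files
use 1-based positions (the prevalent convention for that format) and the
reader converts. A CpG's counts live on the plus-strand C; minus-strand
calls are folded onto `pos − 1` by `combine_strands()`, and a minus-strand
call whose partner was never seen on the plus strand is remapped rather than
dropped, so no data are silently lost at track edges. Records with zero
total calls are dropped at parse time — they cannot contribute to any
count-pooled statistic. CpGs covered on only one strand are retained; the
strand-combining summary flags how many minus-strand calls were unpaired.

# Window statistics

Windows are fixed-width tiles (default 20 kb; the final partial tile of each
chromosome is kept and flagged). Window methylation is **count-pooled**,
`sum(meth) / sum(total)`, not a mean of per-CpG fractions: at ×1–2 coverage
per-CpG fractions are near-binary, and pooling weights every read call
equally. Windows with fewer than `min_support = 10` total calls are treated
as missing rather than noisy; the threshold is exposed as an argument since
no single value suits every depth. "Percent of windows below 60%" uses a
strict inequality — a window at exactly 0.60 is not below. The 1%-bin
distribution summary normalizes each sample's histogram to unit mass and
reports min/mean/max and the population standard deviation of the per-bin
masses across samples; no smoothing is applied to it. Profile smoothing for
figures is a degree-1 local polynomial with a tricube kernel over a
bandwidth in bp; a Gaussian kernel density (`window_density()`, Silverman
bandwidth) is provided for display only and never feeds a statistic.

# Domain segmentation

Segmentation is a two-state hidden Markov model over the ordered window
fractions of a pooled consensus track (individual ×1.5 samples are too
shallow to segment alone; pooling ~17 samples gives an effectively
high-coverage map).

*Emissions.* Gaussian per state on the window methylation fraction. The
emission family is a design choice: training data are annotated windows, so
Gaussian moments give closed-form supervised estimation, and on [0,1]
fractions averaged over hundreds of calls the normal approximation is
adequate. An emission-sd floor of 0.01 guards constant (hand-annotated,
possibly idealized) training segments.

*Transitions.* Self-transition `1 − 1/L̄` per state, where `L̄` is the mean
annotated run length in windows — the maximum-likelihood geometric
run-length fit. The initial distribution is the stationary distribution of
the transition matrix.

*Decoding.* Viterbi (hard boundaries are the deliverable), in log space.
Missing windows contribute no emission term — the path is bridged by
transitions alone rather than by imputation, so a missing stretch inherits
whichever state the flanking evidence supports. Exact ties resolve toward
PMD deterministically. The observation unit (window width) is a parameter;
20 kb is the default used throughout.

*Post-processing.* The default policy is `keep`: the decoded boundaries are
reported as-is. An opt-in `merge` policy absorbs domains shorter than a
floor (default 100 kb, motivated by the typical PMD length scale) into the
longer flanking neighbour, shortest first, ties to the preceding neighbour.

Per-sample domain methylation is count-pooled per domain, with global and
per-chromosome PMD/HMD means pooled over all CpGs in domains of that state —
so the global mean computed through the table equals the same quantity
computed directly from the raw track restricted to that state's base pairs.

# Contamination QC

Male placentas have one active X, leaving X CpG-island promoters lowly
methylated; female cells carry an inactive X whose CGIs are roughly half
methylated. Maternal blood in a male placental sample therefore raises CGI
methylation in X HMDs linearly with the female-cell fraction `f`:

`x_cgi_meth = (1 − f) · male_baseline + f · female_baseline`

inverted and clipped to [0,1] by `estimate_female_fraction()`. The baselines
have no canonical published values; the defaults 0.10 and 0.50 encode "low
on the single active X, half-methylated in female cells" and are mandatory,
visible parameters — with baselines matched to a known admixture model the
estimator recovers planted fractions to within ±0.02 at ×1.5 coverage over
~50 islands (verified in the test suite). CGI selection requires full
containment inside an HMD; islands straddling a boundary are excluded.
The contamination–PMD correlation is computed over male samples only, since
the estimator's logic presumes a single active X; female samples are
reported descriptively (their elevated CGI methylation reflects their own
genome, not contamination).

# Differential statistics

Per-feature group comparisons use the Welch unequal-variance t-test (the
conservative reading of a generic "two-tailed t test"; a pooled-variance
flag exists). BH-FDR at 5% is applied **within each feature class as its own
family** — domains, chromosomes, promoters, CGIs, gene bodies, 20 kb
windows, chromatin-state elements are each tested and corrected separately,
mirroring how each class is analysed on its own. Features with fewer than
two non-missing values in a group, or zero variance in both groups, are
skipped and counted instead of contributing artificial p-values; fully
degenerate scalar tests follow explicit conventions (p = 1 for equal
zero-variance means, p = 0 flagged otherwise).

Chromatin-state profiles average per CpG within an element (so deep CpGs do
not dominate), then across samples per group; state-level distributions are
summarized by box statistics with whiskers at the furthest element within
1.5 × IQR.

Univariate regressions rescale responses to declared units — 5 percentage
points for PMD methylation, 2 for HMD, 5 for the percent-below-60% metric —
approximating a 2-SD change per unit, so coefficients are directly
comparable. "Adjusted for" models (e.g. PMD adjusted for HMD) add the second
covariate, which may be another response column. Categorical predictors use
declared reference levels (sex reference M, race/ethnicity reference white
non-Hispanic). Model selection uses Gaussian-likelihood AIC (intercept and
error variance counted; AICc is available behind a flag but not default),
ties to the fewer-parameter then first-declared candidate, and the selected
model's coefficients get HC1 sandwich-robust 95% confidence intervals — HC1
is the declared flavour among the sandwich family.

# The synthetic cohort generator

The generator defines the study conditions for every test; it is part of the
package, not a fixture.

*Architecture.* Alternating PMD/HMD segments with geometric lengths (PMD
mean 300 kb, HMD 150 kb — geometric matches the HMM's implicit run-length
law, keeping train/decode self-consistent; a heavy-tailed lognormal option
exists for robustness checks). Boundaries align to the 20 kb window grid.
State means 0.55 (PMD) and 0.85 (HMD) put the two modes of the window
distribution where placental data show them. CpGs are spaced geometrically
(mean 100 bp); each CpG carries a fixed logit-scale locus effect
(sd 0.1) shared across samples so windows are not unrealistically uniform.
The X chromosome hosts dense CpG islands (1 kb, CpGs every ~20 bp) placed
fully inside HMDs, methylated at 0.10 in male placenta and 0.50 in female
cells.

*Samples.* Depth is Poisson per CpG (default mean ×1.5, jittered ±15%
between samples); methylated counts are binomial with success probability
`logistic(locus logit + sample-state offset)`. Offsets act on the logit
scale so mixtures and shifts stay inside [0,1] without clipping. Each sample
draws a shared genome-wide component (sd 0.074) plus PMD- and HMD-specific
components (sd 0.069 and 0.042). These three values were derived once,
analytically, from the study-scale anchors: across ~47 samples the expected
normal range is ≈ 4.4 sd, so inter-sample ranges of ~11 percentage points
over PMDs and ~5 over HMDs translate (through the logistic slope `p(1−p)`
at each state mean) to total logit sds of ~0.10 and ~0.085, and the shared
component is sized so the implied PMD–HMD correlation is ≈ 0.64. The
within-group sd at domain scale used in differential tests is 2.5
percentage points — a declared free parameter used consistently, since no
within-group variance is published at that scale.

*Planted truth.* One designated autosomal HMD receives a logit shift for the
ASD group equivalent to a 5-percentage-point difference at the HMD mean;
contamination re-draws methylated counts at the same depths under
`(1−f)·p_placenta + f·p_blood` with blood at 0.85 over autosomes and 0.50
over X CGIs. "Visual annotation" for HMM training is simulated as a random
~30% subset of the true domains. Everything planted — domains, offsets, DMR
location and size, contamination fractions, the training subset — is
recorded in the truth ledger and serialized by `write_cohort()`.

*What the generator does not emulate:* read-level artefacts (bisulfite
conversion failure, mapping bias, sequence context), real CpG density
heterogeneity outside CGIs, cell-type mixture beyond a single blood
admixture axis, and hg19-specific annotation. Passing tests therefore
demonstrate correctness of the pipeline's statistics and decoding under the
declared generative model, not robustness to every artefact of real
libraries.

# Problem sizes and numerical choices

The shipped checks use desk-scale genomes chosen so the full suite runs in
minutes: segmentation recovery on a 10 Mb two-autosome genome at pooled ×25
(emulating 17 pooled ×1.5 samples); contamination recovery over ~60 X CGIs
at ×1.5, 20 replicates per planted fraction; FDR control over 200 null
cohorts of 500 features at 24 vs 23 samples; DMR detection over 100
replicates of the same shape; Viterbi validated exactly against exhaustive
enumeration on instances of up to 12 windows (2^12 paths). Exact-path ties
in the Viterbi are broken toward PMD; BH q-values come from the monotone
step-up adjustment; the Welch df uses the Welch–Satterthwaite formula;
regression oracles are matched to 1e-8. Degenerate inputs (all-missing
chromosomes, empty tracks, zero-variance features, rank-deficient designs)
raise informative errors or are skipped with counts, never silently
imputed.

# Known limitations

Single-sample segmentation at ×1 coverage is out of scope (the model is
trained and decoded on pooled data); unsupervised (Baum–Welch) training and
more than two states are not implemented; the contamination baselines are
parameters, not estimates, so absolute contamination levels are only as
good as the supplied anchors; and the feature scan treats features as
independent within a family, as BH does.
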