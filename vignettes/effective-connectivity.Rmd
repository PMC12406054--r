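---
title: "Modelling scene-encoding effective connectivity and its link to gaze and memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling scene-encoding effective connectivity and its link to gaze and memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedcm)
```

## The scientific problem

During natural scene encoding, people move their eyes; restricting that
exploration (maintained fixation on a cross) changes both later memory and
the neural dynamics of the visual-mnemonic hierarchy. `gazedcm` models how
unrestricted ("free") versus restricted ("fixed") viewing modulates the
directed coupling between three regions — the occipital pole (OCP, early
visual cortex), the parahippocampal place area (PPA, scene-selective
cortex) and the hippocampus (HPC) — and how that modulation relates to two
retrieval measures: confidence-graded recognition memory strength and gaze
reinstatement (the image-specific similarity between encoding and
retrieval scanpaths).

The package implements the full chain: a generative (forward) model of
region-of-interest BOLD, subject-level Bayesian inversion, hierarchical
group inference over a structured model space, behavioural scoring, and a
canonical-correlation association stage. A synthetic-data generator plants
known effects at every stage, so each analysis can be validated by
parameter recovery rather than by inspection.

## The generative model

Neuronal dynamics follow the bilinear state equation

$$\dot z = \Big(A + \textstyle\sum_j u_j B_j\Big) z + C u,$$

where $z$ is one neuronal state per region, $u$ the experimental inputs,
$A$ the endogenous (average) coupling, $B_j$ the modulation of coupling by
input $j$, and $C$ the direct driving influence. Two input channels are
used: channel 1 is a boxcar over *all* encoding trials and drives OCP;
channel 2 is a boxcar over *free-viewing* trials only and carries the
modulatory effects. The driving channel is mean-centred after
discretization, so $A$ reads as the average effective connectivity across
conditions and $B$ as the free-viewing deviation from that average; the
modulatory channel is left uncentred so that $B$ applies exactly on free
trials.

Two unit conventions matter:

* **Self-connections** are parameterized on a unitless log scale:
  the diagonal of the effective Jacobian is $-0.5\,e^{a_{rr} + u_j
  b_{rr}}$ Hz. Positive values mean stronger self-inhibition; negative
  modulation is disinhibitory ("self-excitatory"). Modulation therefore
  acts *inside* the exponent on the diagonal, and additively (in Hz) on
  between-region entries.
* **Driving inputs** are reported on the conventional scale of this model
  family, in which the integrator applies $C/16$. Printed values of order
  one (the package default plants 0.638 into OCP) then produce neuronal
  excursions of a few hundredths of a Hz, which keeps the haemodynamic
  cascade in its physiological regime. Without this convention a
  mean-centred driving input of that magnitude drives blood inflow
  non-positive and the observation model has no solution.

Each region's neuronal state enters a balloon–windkessel cascade
(vasodilatory signal, inflow, venous volume, deoxyhemoglobin) with
canonical constants (resting oxygen extraction 0.4, resting venous volume
4 %, echo time 40 ms) and three free per-region log-scalings: transit
time, signal decay, and the intra/extravascular ratio. At rest the
predicted BOLD is exactly zero. Integration uses a fixed-step 4th-order
Runge–Kutta scheme on a microtime grid of `dt = TR/16` (0.125 s at the
default TR of 2 s); a fixed step keeps the free-energy surface smooth for
the optimizer, and halving `dt` changes sampled BOLD by less than 1e-3 %
signal (checked in the tests). Runs are concatenated with neuronal and
haemodynamic states reset at run boundaries.

## Subject-level inversion

`dcm_fit()` inverts the model by variational Laplace: a Gaussian posterior
is propagated by Gauss–Newton ascent on the free energy
$F = \text{accuracy} - \text{complexity}$, with step-halving so accepted
steps never decrease $F$; per-region log noise precisions are updated by
expectation–maximization under a Gaussian hyperprior; per-run intercept
and linear-drift confounds are projected out of data and predictions.
Sensitivities are computed by central finite differences (step `1e-4`,
configurable via `control$fd_step`). Convergence is declared after four
consecutive iterations with $|\Delta F| < 0.01$ nats (cap 128 iterations).

Priors are zero-mean shrinkage priors: variance 1/16 on every enabled
connectivity entry, 1/256 on haemodynamic log-scalings, and variance 0
(fixed at zero) on entries disabled by the switch specification. The noise
log-precision hyperprior is deliberately weak (mean 0, variance 16): the
observation scale of ROI data is not known a priori, and a tight
hyperprior at the wrong scale silently overrides the data — in our
simulations it mis-estimated the noise sd five-fold and collapsed all
estimates toward the prior. With the weak hyperprior the EM step recovers
the true noise sd to within a few percent.

Observation noise is modelled as independent across scans. Serial
correlation in ROI averages is a real phenomenon; modelling it is out of
scope here and its main effect (mild overconfidence of subject-level
posteriors) is absorbed by the between-subject variance at the group
level.

## Group level: PEB, model reduction, families

`peb_fit()` implements parametric empirical Bayes: subject posteriors are
data for the hierarchical model $\theta_i \sim N(X\beta, \Sigma_b)$, with
a closed-form Gaussian posterior for $\beta$ conditional on the
between-subject precision, which is optimized under a standard-normal
hyperprior on its log scaling. All evidence bookkeeping uses Bayesian
model reduction (`bmr_reduce()`): the evidence and posterior of any model
whose prior shrinks the full model's prior are obtained in closed form,
without refitting.

Because several modulatory parameters are only weakly identified in a
single subject at realistic noise (their likelihood information is an
order of magnitude below the A-matrix entries, and strongly collinear with
upstream modulation), `peb_iterate()` re-inverts each subject with the
group prediction as an empirical prior — full covariance, so the group
posterior's correlation structure constrains the subject fits — and
re-estimates the group model, for a small fixed number of rounds. This is
the standard empirical-prior iteration for hierarchies of nonlinear
models; it re-expands each subject's local Gaussian approximation around
the group solution. Its known cost is some re-use of the data across
levels, so group-level posterior probabilities after iteration should be
read as model-conditional summaries rather than strictly calibrated
frequencies.

The modulatory hypothesis space is all $2^7 = 128$ on/off patterns of the
seven modulatory switches (three self-connections; OCP→PPA, PPA→OCP,
PPA→HPC, HPC→PPA). `assign_families()` groups them by directionality into
the null model plus bottom-up, top-down, bidirectional, self, and the
three `+SELF` combinations (sizes 1, 3, 3, 9, 7, 21, 21, 63). Family
comparison gives every family equal prior mass, uniform within family —
without that correction the 63-member family would win on prior mass
alone; the null model is treated as its own singleton family, so eight
prior masses of 1/8. Parameters are then Bayesian-model-averaged within
the winning family; a parameter's posterior probability (Pp) is the summed
posterior mass of member models in which it is switched on, and
parameters with Pp ≥ 95 % are flagged in reports. The endogenous and
driving blocks are pruned instead by a greedy automatic search
(`automatic_prune()`): repeatedly remove the single parameter whose
removal most increases the evidence, stop when none does, and average over
the visited models weighted by evidence.

## Behavioural measures

Recognition responses for previously viewed images are scored 2 (correct,
high confidence), 1 (correct, low), 0 (miss, low), −1 (miss, high); lures
are never scored. Gaze reinstatement for one image is the Fisher-z
Pearson correlation between that image's duration-weighted fixation
density maps at encoding and retrieval, minus a control: the mean
similarity to `k = 50` other encoding maps from the same participant and
condition. Density maps sum an isotropic Gaussian per fixation, weighted
by duration, on a 1-px grid; the kernel default of 63 px corresponds to
about one degree of visual angle at the package's reference geometry
(500-px images spanning ~8°) and is configurable, since density-map
smoothing conventions vary. Correlations are clipped at |r| = 0.999 so
identical maps transform to a finite z. Maps are not renormalized to unit
mass — Pearson correlation is scale-invariant, so this cannot change any
reported similarity.

One calibration fact the tests document: the *raw* similarity of two
unrelated scanpaths is slightly positive (≈ +0.06 at the reference
geometry) because both maps concentrate mass away from the image borders.
The control score has the same baseline, so the *corrected* reinstatement
score is centred on zero for unrelated pairings — which is exactly why
the control subtraction exists.

Per subject, both measures are reduced to the free-minus-fixed difference
of condition means and then mean-centred across subjects
(`behavior_differences()`).

## Connectivity–behaviour association

`cva()` relates the modulatory parameters that survived the 95 % Pp
threshold (X) to the two behavioural differences (Y) by canonical variate
analysis. X columns are z-standardized so weights are comparable across
parameters on different scales; loadings — the correlations between each
original variable and the canonical variates, which are what we interpret
— are unaffected by this choice. Shared variance of function $i$ is
$100 r_i^2$. Two significance summaries are reported per function:
Bartlett's chi-square on Wilks' Λ (asymptotic) and a seeded permutation
test (≥ 1999 row permutations of Y), and the permutation p is the one to
trust at cohort sizes of a few dozen. The type-I error of the permutation
test is verified at 5 % ± 2 % over 400 null replicates in the acceptance
suite. Scene-vs-scrambled differences per connection use paired t tests
with Benjamini–Hochberg FDR across the seven connections, plus the
omnibus image-type × connection repeated-measures interaction with
Greenhouse–Geisser correction (via `car`).

## What the synthetic data emulate — and what they do not

`ground_truth()` fixes the study conditions: group-mean connectivity
seeded from the full-model scene-encoding estimates (e.g. bottom-up
OCP→PPA 0.747 Hz; free-viewing modulation of HPC→PPA −2.44; driving input
0.638), between-subject sd 0.15 on connectivity and 0.05 on haemodynamic
log-scalings, observation noise sd 0.1 % signal (≈ SNR 1 against the
simulated per-region signal sd of 0.04–0.2 %), a planted correlation of
0.6 between self-modulation and the memory advantage, retrieval jitter of
20 px, and free/fixed fixation rates of 10 and 2 per trial (the ordering,
not the counts, is the empirically constrained feature). The task
schedule reproduces the encoding design: runs of 72 images (36 free, 36
fixed, pseudo-randomized), 4-s presentations separated by a fixation
cross of 1.72–4.16 s, in a 500-s active window with 10-s lead-in and
12.4-s tail, TR = 2 s; scene and scrambled conditions differ only in run
count (6 vs 2) and labels.

The generator does not emulate: serially correlated physiological noise,
haemodynamic nonlinearities beyond the balloon model, saccade kinematics
or saliency structure in fixation placement, image content, or
subject-level differences in task compliance. Passing recovery tests
therefore demonstrates internal consistency of the estimation chain under
the stated statistical structure — not robustness to every property of
real data.

Validation problem sizes are chosen to keep the whole suite fast on one
CPU: recovery cohorts use 12 subjects × 200 scans (54 trials), the
reduction-vs-refit check uses a 2-node network at 100 scans, gaze
calibration uses 200 images at 150-px maps, and the CVA size check uses
400 null replicates at N = 36.

## Known limitations

* At 200 scans and SNR ≈ 1, the PPA self-modulation parameter is only
  weakly identified: its data sensitivity is ~10× below the endogenous
  entries and 0.92-collinear with the OCP→PPA modulation, so its
  group-level sign is recovered but with Pp well below 95 %. Doubling the
  scan count (still a quarter of the full scene design) resolves it; this
  is a data-volume limit of the reduced validation scale, not of the
  estimator, and the acceptance suite reports it as measured.
* Free energies are comparable across models fitted to the same data with
  the same confound structure; they are not absolute evidence values.
* The iterated empirical-prior scheme re-uses data across hierarchy
  levels (see above).
* `bmr_reduce()` is exact for Gaussian posteriors; for strongly supported
  parameters of the nonlinear model its evidence change can differ
  substantially from an explicit refit. The pipeline only ever prunes
  switchable coupling/modulatory entries, where agreement is within
  fractions of a nat (verified against refits).

## A worked miniature

```{r, eval = FALSE}
library(gazedcm)
res <- run_pipeline(run_config(n_subjects = 6L, seed = 1L))
print(res)
summary(res$fits$scene[[1]])
print(res$group$scene$bma)
print(res$cva)
```

The same stages scale to the full study conditions through
`make_task_design()` (6 scene + 2 scrambled runs), `dcm_fit()` per
subject and condition, `peb_iterate()` + `modulatory_bma()` per
condition, `reinstatement_table()` + `behavior_differences()`, and
`cva()`.
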