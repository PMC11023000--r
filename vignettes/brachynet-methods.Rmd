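---
title: "Modelling HDR brachytherapy plan approval with an adversarial network pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HDR brachytherapy plan approval with an adversarial network pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachynet)
```

## The problem

In high-dose-rate brachytherapy (HDRBT) of cervical cancer, a physician
reviews each fraction's plan primarily through four dosimetric measures: the
D90% of the high-risk CTV and the D2cc of bladder, rectum and sigmoid, all
expressed as equivalent dose in 2-Gy fractions (EQD2, linear-quadratic model
with alpha/beta = 10 Gy for the CTV and 3 Gy for organs at risk). Approval
is judged on the *total course*: EQD2 from external-beam radiotherapy, the
fractions already delivered, the fraction under review, and the expected
remaining fractions. `brachynet` models the probability that a plan would be
approved, which is the quantity an automatic treatment-planning loop needs
as its objective.

Two small convolutional networks are trained jointly:

* the **dose prediction network (DPN)** maps the patient anatomy and the
  prescription dose to the approved-quality per-fraction dose quadruple
  (generator role), and
* the **plan-approval probability network (PPN)** maps the anatomy and a
  total-course dose quadruple to an approval probability in (0, 1)
  (discriminator role).

## Representations

**Dose.** A per-fraction quadruple $D^i$ at fraction $i$ of $N$ is
extrapolated to the course total
$$D^{T_i} = \tfrac{N}{i} D^i + \tfrac{N}{i} D^{i-} + D^{\mathrm{EBRT}},$$
where $D^{i-}$ is the sum of the per-fraction EQD2 of fractions $1..i-1$,
so that $\tfrac{N}{i}(D^i + D^{i-})$ is $N$ times the mean delivered
fraction dose. `total_course_dose()` implements this; it is linear in each
argument and, for a course of identical fractions, independent of $i$.

**Anatomy.** A 4 x 20 matrix of distance histograms: for the CTV, the
distance of each CTV voxel to the nearest source dwell position; for each
OAR, the unsigned distance of each organ voxel to the CTV boundary (exact
Euclidean distance transform, boundary defined by 6-connectivity face
adjacency). Distances are binned into 20 equal bins over 0-100 mm; values
beyond 100 mm are clamped into the last bin so that row sums are conserved.
Rows are normalized to fractions by default so the networks see organ
*shape* rather than volume; raw counts remain available for the consistency
audit. Out-of-range clamping, the unsigned treatment of OAR voxels that
overlap the CTV, and the voxel-center coordinate convention
(world = origin + index x voxel size) are deliberate conventions chosen for
testability; none is forced by the underlying idea.

## Architecture

Both networks share a trunk of four 3x3 'same' convolutions (channels
16-32-32-16), each followed by a LeakyReLU (slope 0.2) and a dropout layer
(rate 0.5), then a flatten and two dense layers (hidden width 64, LeakyReLU
between them). The PPN ends in a sigmoid; the DPN ends in a LeakyReLU over
four outputs. The second input (total dose for the PPN, prescription for the
DPN) is tiled to a 4 x 20 matrix and stacked with the anatomy as a second
channel, preserving the per-structure row correspondence. Channel widths and
the dense width are configuration-exposed; the defaults keep the model small
(about 100k parameters) because the data regime is hundreds of plans, not
millions of images.

Inputs are scaled to comparable magnitudes before entering the network:
anatomy rows are fractions (at most 1), total-course doses are divided by
100 Gy, prescriptions by 10 Gy, and the DPN's outputs are expressed in units
of 10 Gy. The scaling constants are recorded in every checkpoint descriptor.

**Dropout mode.** The dropout layers after the 2D convolutions are
channel-wise (one Bernoulli draw per feature map per sample), the standard
form of dropout after convolutional layers; an element-wise mode is kept as
a configuration option. On the synthetic task the element-wise form at rate
0.5 injects so much gradient noise at batch size 4 that the dose regression
cannot reach its validation floor within the 100-epoch budget.

## Training scheme

1. **DPN pre-training** minimizes
   $E\,\lVert \mathrm{DPN}(R, A) - D \rVert^2$ over approved plans.
2. **PPN pre-training** minimizes $E\,\lvert \mathrm{PPN}(F(D), A) - Y
   \rvert^2$ over approved plans ($Y = 1$) plus synthetic unapproved plans
   ($Y = 0$) obtained by perturbing each approved plan's per-fraction EQD2
   in the unfavorable direction: each OAR scaled up by $1 + m$, the CTV
   scaled down by $1 - m$, with $m$ uniform on 5-25% independently per
   structure (four negatives per approved plan by default). Overdosed OARs
   and an underdosed target are the canonical rejection reasons; whether a
   physician would also reject an overdosed CTV at this stage is left to the
   evaluation-time perturbations, which scale in both directions.
3. **Adversarial joint training** alternates, once per mini-batch, a PPN
   update and a DPN update. The loss is least-squares-GAN style: the PPN is
   pushed toward $\mathrm{PPN}(F(D), A) \approx 1$ on approved plans and
   $\mathrm{PPN}(F(\mathrm{DPN}(R, A)), A) \approx 0$ on generated plans,
   while the DPN (with the PPN frozen) minimizes
   $\lvert 1 - \mathrm{PPN}(F(\mathrm{DPN}(R, A)), A) \rvert^2$. The course
   extrapolation $F$ is linear, so the DPN gradient chains through it with
   the factor $N/i$. A min-max formulation can be written with either sign
   orientation; this package follows the orientation in which the PPN is the
   discriminator (real plans toward 1, generated toward 0), which is the
   standard adversarial setup and the only one consistent with using the PPN
   as an approval probability.

Optimization is Adam with L2 regularization (coefficient $10^{-5}$,
configuration-exposed), initial learning rate $5\times10^{-4}$, batch size
4, and a reduce-on-plateau schedule (factor 0.1, patience 5 epochs on the
validation loss; during joint training each network keeps its own schedule
driven by its own pre-training-style validation loss). The schedule engages
after a 75-epoch warm-up: at this data scale the validation loss of the PPN
is non-monotone over the first tens of epochs (the first epoch lands near
the class-prior loss, then the curve wanders upward before the
cross-structure discrimination signal is found), and an all-time-minimum
patience rule active from epoch one misreads that warm-up as a plateau and
anneals the learning rate to zero before anything is learned. Each
pre-training stage and the joint stage run 100 epochs. Alternation in the
joint stage is one PPN update then one DPN update per mini-batch.

Checkpoint selection differs by stage. Pre-training returns the parameters
of the best validation-loss epoch. The joint stage tracks both networks from
their incoming (pre-trained) state onward and returns the DPN with the
lowest validation dose error and the PPN with the highest mean validation
AUC over the four plus/minus perturbation levels -- the same criterion used
to advance the best-performing model between stages. This matters because
the adversarial dynamics are genuinely rough at this scale: early in the
joint stage the DPN exploits the pre-trained PPN's monotone extrapolation
(raising CTV dose, lowering OAR doses without bound), and as the PPN learns
to reject those excursions it passes through its most discriminative states;
selection by validation AUC retains exactly that state, while the dose-error
criterion protects the DPN from being returned mid-excursion.

**Adam moment decays.** The printed protocol fixes the learning rate,
batch size, dropout, kernel, slope and plateau rule; the remaining optimizer
constants are tuned for validation performance, as such protocols prescribe.
With the common default $\beta_2 = 0.999$, the combination of batch-4
gradient noise, 0.5 dropout and the plateau rule freezes the learning rate
well before the dose regression reaches its validation floor. The package
default is $\beta_1 = 0.9$, $\beta_2 = 0.98$: the faster-adapting second
moment brings the DPN to its floor inside the 100-epoch budget, after which
the plateau schedule behaves as intended. Both constants are fields of
`train_config()`.

## The synthetic cohort

Clinical HDRBT plan data are not publicly distributable, so the package
ships a generator that reproduces the statistical structure the framework
relies on, with a *hidden, recoverable* ground truth:

* **Anatomy.** In `"masks"` mode, a randomized ellipsoidal CTV (volume
  roughly 20-130 cm^3) around a straight tandem dwell line with two ovoid
  dwell clusters; bladder (anterior), rectum (posterior) and sigmoid
  (superior) ellipsoids carved so their minimum distance to the CTV boundary
  equals a sampled gap of 2-25 mm. These go through the full
  distance-transform featurization. In `"fast"` mode, histograms are drawn
  directly from a parametric Beta-shaped family with the same qualitative
  shape (CTV mass near the applicator, OAR mass starting at the gap);
  per-fraction anatomies jitter the patient-level parameters. Fast mode
  exists so that training-scale studies run in minutes; both modes share the
  policy below.
* **Physician policy.** For each OAR, the mean approved per-fraction dose is
  `prescription * min(cap, c0 + c1 * proximity)`, where proximity is the
  fraction of that organ's histogram mass within 20 mm of the CTV boundary
  — organs closer to the target unavoidably receive more dose. The CTV mean
  is `prescription * (1 + eps)`, `eps ~ N(0, 0.03)`. Every structure's dose
  then receives multiplicative lognormal noise with relative spread
  `sigma_rel` (default 0.10), emulating the ~10% case-to-case dosimetric
  variation observed among clinically similar anatomies. The coefficients
  are retained so tests can verify they are recoverable by regression.
* **Courses.** 1-5 fractions per patient (weighted toward 4-5, matching
  multi-fraction tandem-and-ovoid practice), prescriptions drawn from the
  discrete clinical set {5.5, 6, 7, 7.5, 8} Gy per fraction, and a fixed
  EBRT quadruple (45 Gy CTV / 40 Gy OARs EQD2 by default). A discrete
  prescription set is required for the consistency audit, which conditions
  on exactly equal prescriptions.

What the generator does **not** emulate: physical dose deposition (TG-43),
deformable anatomy between fractions, applicator-geometry variety, or
inter-physician variation. Passing tests on this cohort demonstrate that the
pipeline recovers a smooth anatomy-to-dose policy under realistic noise; it
does not certify clinical accuracy.

## Evaluation battery

* `perturbation_protocol()` scores approved plans against copies whose
  per-fraction HDRBT dose is scaled by plus or minus 5/10/15/20% (sign drawn
  independently per structure; the EBRT and delivered components are
  unchanged) and reports accuracy/sensitivity/specificity at threshold 0.5
  (configuration-exposed) and the trapezoidal AUC. The ROC construction
  groups tied scores into single threshold steps, making the AUC exactly the
  pairwise concordance estimator.
* `oar_sweep()` and `three_oar_grid()` examine how the approval probability
  responds to scaling one (or all three) OAR dose(s), with the CTV fixed or
  scaled by 110%.
* `consistency_audit()` finds same-prescription plan pairs whose anatomy
  matrices differ by less than 10% in relative Frobenius norm and summarizes
  their dosimetric differences — the data-quality bound on what any
  data-driven model of this problem can achieve.
* `dpn_relative_error()` reports per-structure relative errors of the DPN
  against approved doses.

## Numerical and implementation notes

* The conv trunk, its backward pass and the exact 3-D Euclidean distance
  transform (lower-envelope algorithm) are compiled code; everything else is
  plain R. Backpropagation is verified against central finite differences,
  and the distance transform against an exhaustive all-pairs oracle.
* Dropout masks are drawn from a compiled xorshift stream seeded from R's
  RNG, so whole training runs are bit-reproducible under `set.seed()` /
  `train_config(seed = )`.
* Validation losses are computed in eval mode (dropout off) on the full
  validation set; large batches are evaluated in chunks of 256 to bound
  memory.
* Degenerate inputs fail loudly: empty structures, all-zero anatomy pairs in
  the similarity, one-class label sets, corrupted checkpoints and
  out-of-schema configurations are errors, not warnings.
* Problem sizes used by the package's own studies: training-scale runs use
  200 fast-mode patients (about 760 plans; grouped 5-fold split, one fold
  held out as test patients, one as validation), the consistency audit uses
  150 patients at `sigma_rel = 0.10`. These sizes put the recovery targets
  well above estimation noise while keeping a full three-stage run in the
  minutes range on one CPU.

## A worked example

```{r example, eval = FALSE}
co <- build_cohort(n_patients = 200, seed = 11, sigma_rel = 0.05)
folds <- grouped_kfold(unique(co$plans$patient_id), k = 5, seed = 11)
test <- cohort_patients(co, folds[[1]])
val <- cohort_patients(co, folds[[2]])
train <- cohort_patients(co, unlist(folds[3:5]))

fit <- brachynet(train, val, train_config(seed = 11))
summary(fit)

dpn_relative_error(fit, test)$mean          # per-structure relative error
perturbation_protocol(fit, test)$metrics    # AUC vs perturbation level
oar_sweep(fit, test, "bladder")             # approval vs OAR scaling
```

## Known limitations

* The approval probability is calibrated only against synthetic negatives;
  absolute probabilities are not clinically calibrated.
* The PPN's behavior for doses far *below* the training manifold is an
  extrapolation: pre-training negatives perturb OARs upward only, so the
  low-dose side of the sweep curves is constrained only by the adversarial
  stage and by smoothness.
* Fast-mode anatomies share one parametric family; conclusions about
  histogram-level generalization should be checked in `"masks"` mode.
* The t-SNE latent-space visualization of the PPN features is not part of
  the tested core; the penultimate dense activations can be extracted from
  checkpoints by users who want it.
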