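---
title: "Dual-student adversarial domain adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-student adversarial domain adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsseg)
```

## The problem

A segmentation model trained on labeled images from one *source* domain
(one scanner protocol, one lesion-severity population) typically degrades
on a shifted *target* domain for which no labels exist. Unsupervised domain
adaptation (UDA) trains with labeled source data plus unlabeled target data
so that the deployed model works on the target. `dsseg` implements a
dual-student adversarial UDA framework for semantic segmentation, at a
scale where every mechanism runs and is testable on a single CPU.

## The model

Two student segmentation networks $G_1, G_2$ (identical U-Net
architectures) are initialized *differently* — one Xavier-uniform, one
Kaiming-normal, with distinct seeds — and updated independently: no weight
averaging, no EMA coupling. The motivation is the known failure of
mean-teacher methods, where the teacher's weights converge to the
student's and biased target predictions become self-reinforcing. Here the
only channel between the students is a *loss*, and it is gated by an
explicit reliability test.

Each training batch contains labeled source items $I_s$ and unlabeled
target items $I_t$. Per student $i$, one step assembles four terms:

1. **Supervised loss** on source:
   $L_{seg} = 0.5\,L_{dice} + L_{ce}$, with class-averaged soft dice and
   class-normalized cross-entropy (`dice_loss()`, `cross_entropy_loss()`).
   The compound form is the standard remedy for extreme class imbalance in
   lesion segmentation.
2. **Transform consistency** on target: a stochastic perturbation is
   sampled (`sample_transform()`), split into an exact spatial part
   (90-degree rotations, axis flips) and an intensity part (contrast gain,
   Gaussian noise). The student predicts on the perturbed image; its
   prediction on the clean image is replayed through the *spatial part
   only* and treated as a constant; $L_{con}$ is the mean squared error
   between the two probability maps.
3. **Cross-coordination** on target: for each student, predictions on the
   clean and (inverse-replayed) perturbed inputs are compared by
   `compute_reliability()`: a voxel is *reliable* when the predicted labels
   agree and at least one of the two max-probabilities exceeds the
   confidence threshold $\xi$; the *stability distance* $\varepsilon$ is
   the Euclidean norm of the difference of the two full probability maps
   (one scalar per sample). Sample-level reliability is the voxel map
   reduced by quorum (default: more than half the voxels). The exchange
   rule (`cross_coordination_loss()`): if both students are reliable, only
   the strictly less stable one (larger $\varepsilon$) pays an MSE toward
   the other's prediction; otherwise a student pays it only if the *other*
   student is reliable. The target of the MSE never receives gradient —
   knowledge flows, weights never couple.
4. **Adversarial alignment**: each student owns a discriminator — five
   stride-2 4$\times$4 convolutions, leaky-ReLU 0.2, dropout 0.5 — trained
   to label the student's softmax output maps as source (1) or target (0).
   The student receives the generator-side BCE pushing its target outputs
   toward "source"; its weight $\lambda_{adv}$ starts at 0.1 and steps to
   1.0 late in training (default at 80% of iterations), because the
   adversarial signal is only trustworthy once segmentation is decent.

The per-student total is
$L = L_{seg} + \xi_w L_{con} + L_{cross} + \lambda_{adv} L_{adv}$.
Students use SGD (momentum 0.9, weight decay $10^{-4}$) under a poly
schedule $lr = base \cdot (1 - t/T)^{0.9}$; discriminators use Adam
($\beta_1 = 0.45$, $\beta_2 = 0.999$) on detached predictions.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `xi_threshold` | 0.8 | confidence gate in the reliability rule; unitless probability. No reference value exists; 0.8 is a conventional confidence cut. |
| `xi_weight` | 1.0 | weight of $L_{con}$. Kept **constant** for the dual-student modes (ramping is explicitly argued against for them); a separate knob from `xi_threshold` — the two roles share a symbol in the source formulation but nothing ties their values. |
| `quorum` | 0.5 | fraction of reliable voxels that makes a *sample* reliable. The reliability rule is voxel-wise but the exchange rule needs one bit per sample; quorum reduction is this package's bridge. Values > 1 force the bit to 0 (used by the reduction tests). |
| `lambda_adv_initial/final` | 0.1 / 1.0 | adversarial weight before/after `lambda_switch_iter` (default $0.8\,T$). "Switch late" honors the idea that the weight must be small while segmentation is still poor. |
| `ema_alpha` | 0.99 | EMA coefficient, **mean-teacher baseline arm only**; deliberately absent from the dual-student modes. |
| `base_lr` | 0.01 (0.02 desk) | SGD base rate under the poly schedule. |
| `disc_input` | `"probs"` | discriminators see softmax maps by default; `"logits"` is exposed because the source description is ambiguous between the two. |

## Baseline arms

`train(config, ds)` runs one of seven arms sharing optimizers, schedules
and data streams: `super_all` (supervised on source+target labels; upper
bound, synthetic data only, requires explicitly unhiding target labels),
`super_source` (lower bound), `da_mt` (single student + EMA teacher +
consistency), `da_entropy_mini` (single student + mean softmax entropy on
target), `da_adv` (single student + discriminator only), `da_ds` (dual
student without discriminators), and `proposed` (full framework).

One deliberate deviation: the `da_mt` arm applies the canonical
mean-teacher sigmoid ramp-up ($e^{-5(1-t)^2}$ over the first quarter of
training) to its consistency weight. With a constant full-strength weight,
the cold EMA teacher drags the student into predicting pure background on
the shifted target (we measured foreground DSC collapsing to ~0.1%),
which is a broken baseline rather than the mean-teacher method. The
dual-student modes keep the constant weight: their consistency target is
the student's own clean prediction, which does not suffer the cold-start
pathology — and their robustness to it is part of the point.

## The synthetic phantom world

`phantom_spec()` generates two-channel 2D (or 3D) images containing 1–2
rotated-ellipse lesions with three nested classes (whole ⊃ core ⊃
enhancing analogue), per-class per-channel intensities with Gaussian
texture, and guaranteed class imbalance (foreground fraction < 0.25 by
rejection). Two preset shifts:

* `cross_grade`: target lesions 0.6× smaller with a mild intensity shift —
  an analogue of adapting across lesion severity populations.
* `cross_modality`: strong per-channel affine remap (channel 1 partially
  inverted: $a=-0.7, b=0.85$; channel 2 $a=1.35, b=-0.15$) plus swapped
  core/enhancing contrast — an analogue of adapting across imaging
  sequences. Lesion geometry is untouched, so label distributions are
  identical across domains.

What the phantoms emulate: multi-channel input, nested-class structure,
severe imbalance, a controllable and *real* domain gap (verified: a
source-only model loses DSC on target for both presets). What they do not:
anatomy, MRI physics, bias fields, partial-volume effects, 3D context at
realistic resolution. A green adaptation test therefore establishes that
the optimization machinery mitigates the stated kind of shift at desk
scale — not that the method attains any particular accuracy on real brain
MRI.

Desk-scale geometry is fixed once: 32×32, C=2, M=4, batch 2, 600
iterations, U-Net depth 2 / base width 8 / dropout 0.1, discriminator base
width 8, base LR 0.02. The network and LR are the package's own choices
(the reference recipe fixes only optimizer family, momentum, weight decay,
poly power, betas, batch size); they were sized to make a full
three-arm × three-seed comparison run in minutes on one CPU and were not
revisited afterwards.

## Numerical choices

* Soft-dice smoothing $10^{-5}$ in numerator and denominator: a class
  absent from both prediction and target scores perfectly instead of 0/0.
* Probabilities clipped to $[10^{-7}, 1-10^{-7}]$ before any logarithm.
* Spatial transforms are restricted to exact lattice symmetries so that
  replaying a prediction is bit-exact; free-angle rotation would force
  interpolation into the consistency target and is deliberately excluded.
* $\varepsilon$ ties ($\varepsilon_i = \varepsilon_j$, both reliable):
  neither student pays — strict inequality.
* Argmax ties in reliability labels: first class wins (deterministic).
* Dice of two empty masks is 1; Hausdorff of two empty masks is 0 (equal
  boundary sets); one empty mask yields a sentinel (image diagonal) plus a
  warning. Both the classical max and the averaged Hausdorff variants are
  implemented (`variant = "max"` is the reporting default; which variant a
  given reference table used is generally not determinable, so the variant
  is recorded in every report).
* Batch norm uses batch statistics in training and running statistics
  (momentum 0.1) at evaluation; the EMA teacher also averages the running
  statistics.
* NaN in any loss component aborts the step naming the component.

## Design choices where the design was open

* **Transforms per student**: independent draws by default (each student's
  consistency term is self-contained); `share_transforms = TRUE` gives
  both students the same draw.
* **Discriminator "real" examples**: source *predictions*, not source
  ground-truth maps — both domains pass through the same network family.
* **Batch composition**: `batch_size` source items *and* `batch_size`
  target items per step.
* **Which student is reported**: validation (mean foreground DSC on the
  held-out target validation split, every `eval_every` iterations) selects
  the best snapshot across iterations and students; the mean-teacher arm
  reports its teacher, per that method's convention.
* **Initialization assignment**: student 1 Xavier, student 2 Kaiming;
  configurable.

## Limitations

* Networks are 2D only. The losses, transforms, metrics, and phantom
  generator are rank-agnostic, but the hand-written U-Net/discriminator
  kernels (this build has no autodiff backend) implement rank 2;
  `segnet_config(spatial_rank = 3)` errors clearly.
* The adversarial game at desk scale is noisy: best-on-validation
  checkpointing matters, and single-seed comparisons are not meaningful —
  the in-package experiments always compare over seed sets.
* The mean-teacher arm remains seed-sensitive under the strong
  cross-modality shift even with its ramp-up: on some seeds it collapses
  on target. This mirrors the instability argument that motivates the
  dual-student design, and it is reported as measured.
* Reference-scale runs (15000 iterations, 128³ volumes, four channels) are
  config-expressible but far outside CPU budget; nothing in this package
  validates accuracy at that scale.
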