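---
title: "Task and behavioural PLS for source-space oscillatory power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task and behavioural PLS for source-space oscillatory power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

`oscpls` implements the statistical pipeline for a two-group (younger and
older adults), multi-phase visuospatial relational-memory experiment
recorded with MEG.  Each of the 204 trials presents three study objects
sequentially (0–9 s), a 2 s maintenance delay (9–11 s) and a 4 s test
display (11–15 s) in which the participant judges whether the relative
spatial positions among the objects changed.  Beamformed virtual-channel
time courses at 90 cerebral AAL regions are reduced to band-limited
oscillatory power — theta (2–7 Hz, with a 4–7 Hz variant that excludes the
delta range), alpha (9–14 Hz), beta (15–30 Hz) — inside task windows chosen
to capture sustained power changes rather than the initial evoked response:

| window | interval | reference |
|---|---|---|
| pre-stimulus | −0.75 to 0 s | first study onset |
| first study | 0.25 to 2.5 s (0.25 to 1.25 s for the response-locked baseline) | first study onset |
| delay | 0.75 to 1.5 s | delay onset |
| test | 0.25 to 2.5 s | test onset |
| response | −1.0 to 0 s | button press |

A second window variant (`analysis_windows(variant = "results")`) uses a
−0.25–0 s pre-stimulus and a 0.25–1.5 s delay window; both parameterisations
circulate for this design and the package exposes the choice rather than
hiding it.  Response-locked analyses keep only correct trials answered more
than 1 s after test onset (strict inequality), so the pre-response window
cannot reach back into the delay period.

## Spectral stage

`compute_tfr()` is a short-time Fourier decomposition with Hann-tapered
overlapping segments.  Following the convention of fixing the number of
windows per trial rather than the hop, the hop is derived as
`floor((n_samples - window_points) / (n_windows - 1))` (defaults 512 points,
200 windows).  Power is a one-sided spectral density,
$2\,|\mathrm{FFT}(w x)|^2 / (f_s \sum w^2)$ with DC and Nyquist not doubled,
averaged over segments and trials.  `band_window_power()` averages over all
frequency and time bins whose centres fall in the closed band/window
intervals; the closed-interval bin-centre rule makes behaviour at the shared
band edges (7/9/14/15 Hz) reproducible.  Band power enters the statistics as
natural-log mean power by default (a linear flag exists); mean-centering and
the Gaussian noise model downstream are the reason.  No wavelet or
multitaper options are provided, and no per-frequency baseline z-scoring:
the analysis design compares windows by subtraction.

## Mean-centered task PLS

With groups $g$, conditions (windows) $c$ and column $j$ ranging over the
90 × 3 channel–band pairs, the task data matrix $X$ stacks participants
within conditions within groups (rows) against columns $j$.  The cell-mean
matrix $M$ (one row per $g \times c$ cell) is centered — by the grand column
mean by default, so latent variables (LVs) may express group and condition
effects jointly; a `within_condition` option removes each condition's mean
across groups, restricting LVs to group differences — and decomposed:

$$M_c = U S V^\top,$$

where each LV $i$ comprises a design salience $u_i$ (a contrast over cells),
a brain salience $v_i$ (weights over channel × band) and a singular value
$\sigma_i$.  Brain scores are the projections $X_c v_i$ of identically
centered participant rows; their cell means reproduce $U S$ exactly, which
the test suite checks numerically.  Crossblock covariance percentages are
$100\,\sigma_i^2 / \sum_j \sigma_j^2$.  Each LV's sign is fixed by making
the largest-magnitude brain-salience element positive, so results are
deterministic across platforms.

**Permutation test.** Participants' data are randomly reassigned to
conditions — and, in the default `subjects` scheme, subjects are also
reassigned to groups — with each subject's rows moving as a block.  The
blocking matters: band power shares a subject-level intercept across a
subject's conditions, and a permutation that relabels rows freely (ignoring
which rows belong to the same subject) does not draw from the null
distribution of the observed statistic under that within-subject
correlation.  We verified this empirically: with subject intercepts in the
generator, the free-row scheme produces systematically non-uniform null
p-values (KS p ≈ 1e−4 over 200 replicate null datasets), while the
subject-respecting scheme is calibrated.  A `conditions_only` scheme
(condition labels within subject, groups fixed) covers the
condition-effects-only null, and the free `rows` scheme is retained for
comparison; the scheme used is recorded in every result.  For each of
`n_perm` reorderings the decomposition is recomputed and
$p_i = \#\{\sigma_i^{perm} \ge \sigma_i^{obs}\}/n_{perm}$ — the literal
counting rule, with an optional add-one smoothing that is off by default.

**Bootstrap.** Subjects are resampled with replacement within group, each
subject's condition rows moving together and condition assignment staying
fixed.  Every bootstrap decomposition is aligned to the original saliences
before summarising.  The alignment is the orthogonal-Procrustes solution
restricted to *signed permutations*: bootstrap LVs are matched to original
LVs greedily by absolute correlation and sign-flipped to agree.  A free
rotation over the full retained LV set was evaluated and rejected: when the
set includes weak or degenerate LVs, the unrestricted (or singular-value-
weighted) rotation pulls every draw toward the projection of the original
saliences onto the bootstrap subspace, shrinking the apparent bootstrap
dispersion and collapsing the coverage of the percentile intervals for the
dominant salience elements — the opposite of what alignment is for.  Signed
permutations handle exactly the sign and order indeterminacy of the SVD and
leave the dispersion intact.

Per element the bootstrap yields the SE, the bootstrap ratio
(salience / SE), and a type-1 (inverse-ECDF) percentile CI, so with two
draws the interval is their min/max by construction.  An element is marked
reliable when its 95% CI excludes zero; a $|BSR| \ge 1.96$ reading of
"95 percent confidence bounds" is available through the reported ratios.
Draws in which a group contains fewer than two distinct subjects are
redrawn (capped), and identical-subject degeneracies are flagged rather
than divided by.

## Behavioural PLS

For each group, accuracy (%), mean correct RT (ms) and hippocampal volume
(mm³) are Pearson-correlated with every channel × band contrast column (one
contrast row per subject, e.g. test minus first study).  The group-wise
correlation blocks are stacked (group-major, measures within group — groups
are not pooled and measures are not standardised across groups) and the
stack is decomposed by SVD.  Permutation reassigns behaviour rows relative
to brain rows within group; the bootstrap resamples subjects within group,
recomputes the correlation stack, and aligns draws as above.  Per group and
LV the correlation between brain scores and each measure is reported with
its bootstrap CI.  These score–behaviour correlations are optimistically
biased at small n (the scores are built from the same correlations), which
is why the permutation test on $\sigma_1$, not the correlations, carries
the significance claim.

## Behavioural statistics

Accuracy is `100 × #correct / #trials` over all 204 trials (non-responses
count as incorrect in this forced-choice design — the original accuracy
denominator is not documented, and the choice is flagged here); RT is
averaged over correct trials only.  Group comparisons use the
pooled-variance two-sample t (df = n₁ + n₂ − 2 = 30, matching the printed
degrees of freedom; Welch by flag).  From the published group summaries
(RT 1543 ± 205 vs 2042 ± 553 ms, n = 16 each) the pooled t is 3.38; the
companion F statistic printed for the same contrast (11.77) is
inconsistent with t² = 11.45, so the package reports t and t² and does not
chase the F.  The fatigue check splits each subject's correct-trial RTs at
trial 102; the 2.5 SD outlier rule flags values strictly beyond 2.5
within-group SDs with the candidate included — a rule that cannot flag
anything for groups smaller than nine, since max |z| is (n−1)/√n.
Subjects flagged as RT outliers are excluded from the response-locked
behavioural PLS only, mirroring the original exclusion.

## The synthetic-data generator

The generator is the package's ground-truth instrument: every downstream
stage is validated against effects it plants.  Defaults are the study
conditions — 2 × 16 subjects, 90 channels, 3 bands, 204 trials, behaviour
scales from the published group summaries (accuracy 82.5 ± 9.2 / 81.3 ±
10.7%, RT 1543 ± 205 / 2042 ± 553 ms log-normal, volumes 7595 ± 940 /
7322 ± 813 mm³).

Log power is `band baseline + planted effects + subject intercept +
N(0, noise_sd)` with `noise_sd = 1` and `subject_sd = 0.5`; planted
magnitudes are expressed in within-cell SD units
(`s = sqrt(noise_sd² + subject_sd²)`), which keeps them scale-free — the
study gives no amplitude scale for source power, so SD units are the only
meaningful currency.  Gaussian noise on log power matches the
event-related desynchronisation convention of analysing relative power
changes; a linear-power mode exists by flag.

Brain–behaviour coupling uses one standard-normal latent $z$ per subject:
it loads with weight `strength × s` on the coupled channel–band cells of
the task condition, and on the subject's log-RT location with the loading
that makes the correlation between the mean coupled-column contrast and
log RT equal the configured `r` exactly, after accounting for the noise
dilution of the contrast (`2 noise_sd²/K` for K coupled columns).  A
requested `r` that no RT loading can reach is rejected at configuration
time.  Trial RTs are log-normal around the subject location (trial spread
0.25 log units) with a 5% fast-guess mixture uniform on 300–1000 ms — so
the RT > 1 s response-locked filter is non-trivial — and a linear practice
drift whose first-half minus last-half difference is 134 ms, the size of
the published split-half effect.  Accuracy is Bernoulli per trial around a
subject-level rate; per-subject summaries are computed by the behaviour
module from trials, never emitted directly, so the summarisation path is
exercised.

Raw time courses, for exercising the spectral stage end-to-end, are 1/f
background plus band-limited sinusoidal carriers whose amplitude is
piecewise constant over the task phases; a carrier of amplitude $A$
contributes $A^2/2$ to band power, giving an analytic oracle.  The
generator does not model sensor physics, head geometry, beamformer leakage
or spatial correlation between channels; passing tests therefore certify
the statistics, not MEG forward modelling.

## Numerical and design choices

- **Seeds.** One top-level seed deterministically derives per-stage
  substreams; identical (config, seed) pairs are bit-identical end to end,
  and run provenance records a config hash.
- **Degenerate inputs.** A constant task matrix yields all-zero singular
  values and a degeneracy flag, not an error; zero bootstrap SEs flag the
  ratio as undefined; zero-variance behavioural columns are errors at fit
  time and redraws inside the bootstrap.
- **Tie-breaks.** Exceedance counting uses `>=` with a 1e−12 guard;
  quantiles are type 1; the sign convention breaks salience sign ties at
  the first maximal element.
- **Problem sizes in the test suite.** Oracle agreement is checked on
  4-cell × 6-column instances against an independent eigensolver (1e−10),
  permutation exactness against exhaustive enumeration of a 3-subject ×
  2-condition instance, null calibration over 200 replicate datasets at
  200 permutations (KS), bootstrap coverage over 300 Gaussian replicates
  at 200 draws, and full-scale recovery at 16/group × 90 channels × 3
  bands with 1000 permutations and bootstraps.

## Known limitations

- **Percentile-interval coverage at low SNR.** The bootstrap percentile CI
  is only asymptotically calibrated for elements of a normalized singular
  vector: noise in the other elements inflates the norm and shrinks the
  dominant element, a bias the percentile rule does not correct.  Pooled
  coverage is ≈ 0.94 in a well-conditioned regime (96 subjects, clearly
  separated LV1) but drops to ≈ 0.86–0.90 for 24 subjects at unit effect
  norm, concentrated in the largest element.  The calibration check
  therefore runs in the regime where the method claims validity, and
  reliability calls on weakly determined LVs should be read with this bias
  in mind.
- **Power of the behavioural permutation test at n = 16/group.** With a
  planted power–RT coupling of r = −0.6 spread over the broadband effect
  columns, the σ₁ permutation test detects the behavioural LV in less than
  half of replicate datasets at the study's sample size; at non-detecting
  seeds the leading LV is a chance accuracy/volume pattern.  Parameter
  recovery of the coupling itself is accurate (±0.05 at 200 subjects per
  group).  This is a property of the design size, not of the
  implementation, and it argues for caution when interpreting borderline
  behavioural LVs from 16-subject groups.
- **Task-PLS centering variant.** The original analysis does not name its
  centering among the variants in common use; grand-mean centering of the
  group × condition cell means is the default here, with condition-wise
  centering as an option, and the variant used is recorded in every
  result.
- **Brain scores** are computed from rows centered by the same offsets as
  the cell means (grand mean by default); whether the original used raw or
  centered rows is not documented — centering only shifts scores by a
  constant and leaves correlations and cell-mean contrasts intact.
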