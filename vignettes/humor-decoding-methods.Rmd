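---
title: "Lag-resolved decoding of reported experiences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lag-resolved decoding of reported experiences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humordec)
```

## The analysis problem

A subject watches naturalistic movie stimuli inside an fMRI scanner and
continuously reports a subjective experience (here: how funny the current
moment feels) with a slider device sampled at 100 Hz.  The scientific
question is *when*, relative to the moment the report begins, multi-voxel
activity patterns in a given brain region become informative about the
event: does decodable information exist only after the report, or already
seconds before it?

`humordec` answers this with a lag-resolved multi-voxel pattern analysis
(MVPA):

1. **Labelling.**  The pooled slider samples of all runs are binarized into
   "manipulation present / absent" by exact one-dimensional 2-means
   clustering.  Presence is sorted into 2 s bins (one bin per fMRI volume,
   TR = 2 s); a bin with at least one presence sample is manipulated.  The
   first bin of each maximal manipulated stretch is an *event onset* and
   receives the label h0; bins up to 8 s after an onset receive h2 ... h8,
   bins up to 6 s before the next onset receive h-2 ... h-6, and bins more
   than 6 s before and more than 8 s after every onset are *neutral*.
   When rules conflict, an onset bin is always h0 and positive lags take
   priority over negative lags.
2. **Preprocessing.**  Each voxel's time series is divided by its own mean
   over the first 30 s of the initial rest period (15 volumes), removing
   baseline differences between runs.  The sample for the bin at lag *t*
   is the single volume acquired *t* seconds from the report; no
   hemodynamic shift is applied at labelling time, so a decoder at lag *t*
   reads what the scanner measured *t* seconds from the report.
3. **Decoding.**  For each (region, lag) pair a binary classifier
   discriminates h*t*-labelled from neutral-labelled samples.  Because
   neutral samples outnumber event samples by more than an order of
   magnitude, each decoder is a *balanced-subsampling ensemble*: 500
   training sets are drawn by keeping every event sample and an equally
   sized random subsample of the neutral pool; one linear support vector
   machine (hinge loss, L2 penalty, C = 1) is trained per set; and the
   final decoder is the arithmetic mean of the 500 weight vectors and
   biases.  Performance is the area under the ROC curve (AUC) of the
   decision values on a held-out run, in leave-one-run-out cross-validation;
   folds whose test run lacks either class are skipped and recorded.
4. **Group statistics.**  Subject-level mean AUCs are tested against the
   chance level 0.5 with a one-sided one-sample t-test per (region, lag)
   cell; between-experiment comparisons use Welch's two-sided test and
   same-subject relabelling comparisons use paired two-sided tests.  Each
   comparison family (all cells of one table) is corrected with the
   Benjamini-Hochberg false-discovery-rate procedure at q = 0.05.
5. **Volume-by-volume prediction.**  Decoders from cells passing the FDR
   gate are applied to every volume of their held-out runs; thresholding
   the decision value at 0 gives a binary outcome raster, and the fraction
   of onsets with a positive outcome at each peri-onset lag gives the
   detection-probability curve.

## The synthetic experiment

No public recordings accompany this analysis, so the package ships a
first-class generator that emulates both experimental designs with known
ground truth:

* **Movie-viewing design**: runs of 32 s rest, ~270 s movie, 30 s rest at
  TR = 2 s; sparse reported events (about 3 per run, hard minimum gap
  20 s, drawn from a dead-time-corrected Poisson process so neutral bins
  dominate the label counts roughly 30:1); slider holds of 0.5-3 s.
* **Control design**: 32 s rest then six cycles of 16 s manipulation and
  16 s rest, eight runs; the slider follows a 0.5 Hz cycle during
  manipulation blocks, motor-region voxels respond to manipulation, and no
  anticipatory signal exists anywhere.

Voxel time series are `baseline * (1 + signal + noise)` with baseline 100.
In ROIs flagged informative, a neural boxcar starting `signal_lead` seconds
before each event and ending at the event is convolved with a double-gamma
HRF and scaled by `signal_amplitude` and by per-voxel weights (drawn once
per subject, non-zero for `informative_voxel_fraction` of voxels, so the
spatial pattern is stable across runs).  ROIs whose name contains "motor"
respond to the report itself (the slider hold).  Noise is AR(1)
(coefficient 0.3, marginal sd `noise_sd`) plus white noise of half that sd,
matching the short-memory autocorrelation of resting BOLD without heavier
machinery.  Facial-marker coordinate traces (4 markers x 2 axes, 60 Hz)
carry motion bursts jittered around event times plus occasional spurious
bursts; the laughter trace overlaps, but is not identical to, the
subject's own events.

Defaults and what they mean:

| parameter | default | meaning |
|---|---|---|
| `tr` | 2 s | volume spacing; equals the label bin width, so bins map 1:1 to volumes |
| `event_rate` | 3 /run | expected reported events per run |
| `min_event_gap` | 20 s | hard event separation, keeps neutral bins abundant |
| `hold_duration_range` | 0.5-3 s | slider hold; no public statistics exist for this, so the range is a configurable judgement call |
| `signal_lead` | 2 s | anticipatory neural onset before the event |
| `signal_amplitude` | 0.03 | HRF-response scale as a fraction of baseline (peak % BOLD change of order a few percent) |
| `noise_sd` | 0.02 | marginal AR(1) noise sd as a fraction of baseline |
| `hrf_params` | peak 6 s, undershoot 16 s, ratio 6 | canonical double-gamma, parameterized by lobe modes |
| `slider_delay` | 0 s | report reaction delay (subjects report promptly; configurable) |

The master `seed` drives fixed per-subject and per-run streams, so any
subject or run can be regenerated in isolation and the whole study is
bit-reproducible.

### What the generator does not emulate

Head motion, slice-timing effects, physiological noise regressors, spatial
autocorrelation, and registration artifacts are all outside the model, and
real anticipatory activity is unlikely to be a clean boxcar with a fixed
lead.  Passing tests on this generator therefore demonstrate that the
*analysis machinery* is correct and calibrated - labels align to the right
bins, cross-validation does not leak, null data decode at chance, the FDR
gate holds its level, planted information is recovered at the planted lag
and nowhere else - not that any particular real dataset will yield the
same effect sizes.

## Design decisions

**Hold bins keep their positive-lag labels.**  After an onset, a sustained
slider hold could either be excluded from labelling or labelled like any
other post-onset bin.  The published label-count tables for this paradigm
report identical h0 and h2 sample counts, which is only possible when
post-onset bins are labelled regardless of the manipulation state, so that
is the default; the literal "no labels for hold continuations" reading is
available via `suppress_hold_bins = TRUE`.

**Label precedence.**  An onset bin is always h0, even when it falls
within 8 s of an earlier onset; positive lags beat negative lags; negative
lags anchor to the nearest upcoming onset.  This set of rules is the only
one consistent with both the one-h0-per-event convention and the equality
of h0 and h2 counts, and it makes labelling deterministic and
order-independent.

**Exact 1-D 2-means instead of iterative k-means.**  In one dimension both
clusters are intervals of the sorted values, so the global optimum is found
exactly by scanning all contiguous splits with prefix sums (values are
centered first to avoid cancellation).  Lloyd iterations from any seeding
can stall in local optima on adversarial inputs; the exact scan removes
that failure mode and is deterministic by construction.

**An in-package SMO solver for the linear SVM.**  Decoding trains hundreds
of thousands of small SVMs (500 subsamples x folds x lags x regions x
subjects).  The package implements the C-SVC dual with
maximal-violating-pair SMO in compiled code, reusing one Gram matrix of
the pooled training set across all subsamples of an ensemble; this makes
the full ensemble pipeline run in seconds where per-fit calls to an
external solver would dominate the runtime.  The solver is validated
against libsvm (via `e1071`) to 1e-3 on weights and bias in the test
suite, including the duplicated-data/cost-halving invariance implied by
the hinge-loss objective.

**Bias is averaged with the weights.**  The ensemble average treats the
intercept as a weight on a constant feature, which keeps the averaged
decoder a single affine function.

**Decision threshold 0.**  Volume-by-volume outcomes threshold the
decision value at the classifier's natural boundary; because every
ensemble member is trained on balanced classes, 0 is the calibrated
boundary between the two classes.

**Fold-level AUC averaging.**  Cross-validated performance is the mean of
per-fold AUCs over valid folds rather than the AUC of pooled decision
values, keeping folds exchangeable and robust to per-fold scale
differences of the decision values.

**Statistics.**  The vs-chance test is one-sided (only above-chance
decoding is interpretable as information); comparisons between groups or
labellings are two-sided.  Movie-vs-control comparisons are Welch
(different subject groups, unequal variances); relabelling comparisons are
paired (same subjects).  The FDR family is all region x lag cells of one
comparison table.  Degenerate cells - zero variance because, e.g., every
subject decodes perfectly - report a signed infinite t with the
corresponding limiting p value instead of aborting.

**Baseline window placement.**  The 30 s baseline starts at the first
retained volume (after any scanner-side discard), i.e. 15 volumes at
TR = 2 s.

**Recovery-study conditions.**  The planted-signal validation plants a 2 s
anticipatory lead in one region and asks the pipeline to flag h-2 and h0
there and nothing elsewhere.  Under convolution with the canonical 6 s
HRF, a neural window that *ends at the event* produces measurable BOLD
change mostly after the event - which is precisely why, in real data, a
report-time decodable signal implies neural activity several seconds
earlier.  A recovery test of the *analysis machinery* therefore uses a
fast-coupling HRF (peak 1 s, narrow dispersion) so that the information
window of the measured signal coincides with the configured lead, ten runs
per subject as in the movie-viewing design, and a signal amplitude
calibrated so pre-onset decodability sits at the reported qualitative
level (mean AUC between 0.7 and 0.8).  With those conditions the pipeline
flags h-2 (AUC ~0.74) and h0, leaves h-6 and the signal-free region at
chance, and the h-2 detector's detection-probability curve peaks at the
onset bin.

**Event process calibration.**  Candidate events are Poisson with a
dead-time-corrected intensity `r / (1 - r * gap)` (capped near the packing
bound) and thinned to the minimum gap, so the realized event count matches
the configured rate (verified to 3 +/- 0.2 over 1000 seeds) while
guaranteeing gap constraints.

## Numerical choices

* SMO stopping criterion 1e-6 on the KKT violation gap; iteration cap
  1e6; Gram matrices computed once per ensemble via BLAS.
* The HRF kernel is evaluated on a 0.1 s grid, normalized to unit peak,
  and convolution results are scaled by the grid step so they approximate
  the continuous-time integral; volume samples are means over each TR
  interval.
* AUC uses the rank-sum (midrank) identity, which equals pair counting
  with half-weight ties exactly.
* Zero-variance pooled traces raise a typed error from `binarize_trace()`;
  in pipeline context a run that was never manipulated simply yields no
  onsets because binarization pools all runs.
* All randomness flows through explicit seeds: generator streams are
  derived from the master seed by fixed offsets, and ensemble subsampling
  is seeded per (subject, region, lag, fold).

## Validation problem sizes

The shipped validation suite runs the complete pipeline at desk scale:
null calibration uses 20 replicate studies of 10 subjects x 6 runs with a
200-voxel region and 100-member ensembles (grand-mean h0 AUC within
0.5 +/- 0.05, FDR-flagged fraction within binomial slack of q); the
recovery study uses 8 subjects x 10 runs with two 200-voxel regions.
Ensemble-size stability is checked separately (mean AUC differences below
0.03 between 50- and 250-member ensembles), which is why reduced ensembles
are adequate for the simulation analogues.

## Known limitations

* Only TR = bin width = 2 s is supported for bin-volume alignment; other
  TRs would need resampling, which the package deliberately does not do.
* The searchlight and automatic voxel-selection variants of MVPA are out
  of scope; regions are consumed as given masks.
* The generator's laughter and marker traces are plausible but schematic;
  they exist to exercise the alternative-labelling machinery, not to model
  audience acoustics or facial kinematics.
* Real anatomical ROI definition, motion correction, slice timing and
  coregistration are upstream of this package.

## A worked example

```{r example, eval = FALSE}
library(humordec)

cfg <- analysis_config(
  simulate = synthetic_study_config(
    n_subjects = 8, n_runs = 10, seed = 5, generate_aux = FALSE,
    roi_spec = data.frame(roi_name = c("roiA", "roiB"),
                          n_voxels = c(200L, 200L),
                          informative = c(TRUE, FALSE)),
    signal_lead = 2, signal_amplitude = 0.05,
    hrf_params = hrf_parameters(peak_delay = 1, peak_dispersion = 0.25,
                                undershoot_delay = 8)),
  lags = c(-6, -4, -2, 0), n_ensemble = 100, seed = 17)

report <- run_full_analysis(cfg)
report$summary   # group AUC table with FDR flags
report$detection # detection-probability curves of the gated decoders
```
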