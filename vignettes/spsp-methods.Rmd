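---
title: "Spherical phase-space symbolisation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical phase-space symbolisation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsp)
```

## The model

`spsp` classifies trials of multichannel recordings by a three-stage
procedure: geometric reduction, symbolisation, and template matching.

**Geometric reduction.** An M-channel, N-sample trial is read as a
trajectory of N points in M-dimensional channel space; no time-delay
embedding is applied, the state vector is the instantaneous channel vector.
The trajectory is summarised by the radial-distance series
$d(n) = \lVert x(n) - \bar{x} \rVert_2$, where $\bar{x}$ is the
per-channel mean (the centre of the trajectory's bounding hypersphere).
The distance metric is the L2 norm: the partitioning shells are concentric
hyperspheres, and a hypersphere is the L2 ball. Centres are computed *per
trial*: each trial is reduced relative to its own geometry, never pooled
across trials or subjects. Consequences worth knowing: $d$ is invariant
to adding a constant offset per channel and to any orthonormal mixing of
the channels (both are verified as test properties), and the per-channel
mean minimises the sum of squared distances, so the shells are as tight as
any spherical summary can be.

**Symbolisation.** The distance axis is split into $S$ bins and each
sample is coded by its bin index. Two schemes are available:

* *uniform* — $S$ equal-width regions between $\min d$ and $\max d$;
* *maximum entropy* (ME, the default) — equal-frequency bins: after
  sorting the $N$ values ascending, edge $j$ sits at the order statistic
  of rank $\lfloor jN/S \rfloor$. On tie-free data every symbol then
  occurs $\lfloor N/S \rfloor$ or $\lceil N/S \rceil$ times, so the
  symbol-sequence entropy is maximal for the sample.

**Edge and tie conventions.** Bins are $(e_{j-1}, e_j]$: a value equal to
an edge takes the *lower* symbol, the first bin is open below, the last
open above, so every real value maps to exactly one symbol and the map is
order preserving. This follows directly from the equal-frequency
construction — the first $\lfloor N/S \rfloor$ sorted points *are* the
first bin, and the edge is the last of them. On data with heavy ties an
edge can collapse onto its neighbour; this raises a degenerate-partition
error naming the collapsed edges rather than silently merging bins,
because identical values must always share a symbol and a collapsed
partition signals that $S$ exceeds the resolvable structure (a constant
series likewise raises a hard error rather than returning $S = 1$: it
almost always indicates upstream data corruption).

**Alphabet-size selection.** With $H(k)$ the Shannon entropy (base 2) of
the sequence after $k$-symbol ME partitioning and $H(1) = 0$, the
increment $h(k) = H(k) - H(k-1)$ is compared to a threshold
$\varepsilon_h \in (0,1)$ starting at $k = 2$; the chosen alphabet size is
the smallest $k$ with $h(k) < \varepsilon_h$ (strict inequality — the
printed rule is "exit when below"). Because ME forces
$p_i \approx 1/k$, $h(k) \approx \log_2\!\big(k/(k-1)\big)$, which first
drops below the default $\varepsilon_h = 0.2$ at $k = 8$ — the selection
is essentially distribution-free on tie-free data, which is also why it is
a sharp, reproducible acceptance target. The loop is capped at
`k_max = 64` (the stopping rule as stated has no bound; with
$\varepsilon_h \ge 0.023$ the cap is never reached on tie-free data).

When a dataset has several trials, one global $S$ is used. The default
pools by averaging the per-trial increments $h(k)$ across trials before
thresholding (`S_selection = "average"`); a `"first_trial"` mode exists.
Under exact equal-frequency coding all trials give the same $h(k)$, so the
two modes coincide on clean data; averaging is the stabler choice when
ties perturb individual trials.

**Template classification.** The *index* (template) of a class is the
elementwise arithmetic mean of the training symbol sequences with that
label. Symbols enter as their raw integer codes 1..S — they are ordinal
(shell 3 *is* between 2 and 4), so integer coding preserves their meaning,
whereas a one-hot encoding would discard the ordering. Each test sequence
is assigned to the class whose template has maximal cosine similarity;
cosine is magnitude-insensitive, which suits code-valued vectors. Exact
ties are broken deterministically toward the earlier label in the
report's fixed label order, with a warning. By default every training
trial carries equal weight in the template (`index_weighting =
"per_trial"`); a `"per_subject"` mode first averages within subject so
subjects with many trials cannot dominate. Both coincide when every
subject contributes one trial per class.

**Evaluation.** Leave-one-subject-out: templates are rebuilt for every
fold from the remaining subjects only (a test verifies that corrupting the
held-out subject's data leaves its fold's templates bit-identical).
Reports carry both the mean of per-subject accuracies and the pooled
(micro) accuracy trace/total; with one trial per subject per class the two
coincide, and both are reported because protocols with unbalanced trial
counts make them diverge.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon_h` | 0.2 | entropy-increment threshold (bits); smaller → larger alphabets. 0.2 yields S = 8 on long tie-free series |
| `k_max` | 64 | cap on the alphabet search; termination guard only |
| `partition_scheme` | `max_entropy` | ME adapts shell widths to the distance distribution; `uniform` is available for comparison |
| `S_override` | unset | skip selection and force an alphabet size |
| `S_selection` | `average` | pool per-trial increments before thresholding |
| `index_weighting` | `per_trial` | template averaging weight |

## The synthetic generator

Real benchmark EEG corpora of this shape are access-restricted, and the
mapping from their trials to discrete emotion labels is unpublished, so the
package carries a generator whose *stated world* mirrors the geometry of
such a study: M = 32 channels sampled at 128 Hz, N = 8064 samples per
trial at full scale, with the default test scale reduced to 8 subjects and
N = 2048 to keep suites fast. Channel m of a trial of class $c$ is

$$x_m(n) = a_c(n)\, g_m(n) + \sigma\, \varepsilon_m(n),$$

where $g_m$ is a smooth per-subject base waveform (boxcar-filtered
Gaussian noise, window N/64, shared across that subject's trials — this is
the subject-level nuisance that makes LOSO genuinely harder than shuffled
CV), $\varepsilon$ is white Gaussian noise with the default
$\sigma = 1$, and $a_c(n) = 1 + \delta\, i_c\, w(n)$ is a class-specific
radial envelope with $w(n) = \tfrac12(1 + \sin(2\pi\,3n/N))$ a fixed slow
modulation and $i_c$ the 0-based class index. The class signal therefore
lives *only* in how the trajectory's distance from its centre is
distributed over time — exactly what the method symbolises — which makes
the generator a sharp test of the pipeline rather than a generic EEG
imitation. Deliberately not emulated: 1/f spectra, alpha rhythms,
artifacts, electrode correlation structure. A green synthetic test
establishes that the pipeline recovers radial class structure across
subjects; it does not establish performance on real EEG.

Calibration (run before the thresholds were frozen, over 20 seeds): at
separation $\delta = 2$, 8 subjects, N = 2048, LOSO accuracy was 1.0 on
every seed (criterion ≥ 0.95); at $\delta = 0$ the classes are
exchangeable by construction and measured accuracy averaged 0.506;
accuracy is non-decreasing along the grid $\delta \in \{0, 0.5, 1, 2\}$.
The defaults above (noise sd, subject variability 0.5, envelope frequency
3 cycles/trial) were chosen once at calibration and are not revisited.

## Numerical and statistical choices

* **Round-trip fidelity.** All numeric text output is printed with 17
  significant digits (`%.17g`), the shortest format that makes
  double → text → double the identity, so reruns are byte-comparable.
* **Run metadata.** `run_metadata.json` records config, selected S,
  package/R versions and input MD5 digests — but no timestamps, and digest
  keys use basenames, so identical config + seed reproduce outputs
  byte-for-byte.
* **Chance bands under dependence.** Within one LOSO replicate the
  trials share templates, so their successes are positively correlated and
  a plain binomial interval on the pooled count under-covers (measured
  replicate sd ≈ 1.3× the independent value). Module-level chance tests
  therefore use a 99% t-interval on the iid per-replicate accuracies;
  the binomial band is retained where a pooled check over independent
  seeds is explicitly the contract.
* **Ties in similarity.** Exact score ties (e.g., duplicated templates)
  predict the earlier label deterministically and set a flag; no random
  tie-breaking anywhere, so a seed fixes every output.
* **Degenerate inputs.** Constant distance series, fewer distinct values
  than bins, zero-norm vectors in cosine, empty classes, a subject missing
  a class in LOSO — all raise typed errors (`spsp_*_error`) rather than
  returning guesses; the CLI maps config errors to exit 2 and data or
  protocol errors to exit 3.

## Known limitations

* Distances discard all directional information in channel space; two
  states differing only in *where* on the shell the trajectory sits are
  indistinguishable by construction.
* Equal-length sequences are required for template averaging and cosine
  matching; there is no built-in resampling (a truncate-to-minimum mode
  was considered and rejected as silently lossy).
* The entropy-increment rule is nearly distribution-free under ME
  partitioning — a feature for reproducibility, but it means the selected
  S says little about the data beyond its tie structure.
* No EEG preprocessing (filtering, re-referencing, artifact removal) is
  included; recordings are taken as given.
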