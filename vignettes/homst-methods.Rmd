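---
title: "High-order minimum spanning tree functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-order minimum spanning tree functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homst)
```

## The model

`homst` classifies subjects from regional brain time series by looking at the
*dynamics* of functional connectivity rather than its static strength. The
pipeline, per subject with an $R \times M$ ROI-by-time matrix:

1. **Sliding windows.** The series is cut into $K = \lfloor (M-N)/S \rfloor + 1$
   overlapping windows of length $N$ at step $S$; in each window the
   $R \times R$ Pearson correlation matrix (the *low-order* network) is
   computed. At the full scale the package targets ($R = 90$, $M = 238$) the
   conventional window is $N = 90$, $S = 1$, giving $K = 149$.
2. **Correlation time series.** For each unordered ROI pair $(i, j)$, the
   sequence of its windowed correlations forms a series of length $K$. There
   are $P = R(R-1)/2$ such pair-nodes ($P = 4005$ at $R = 90$).
3. **High-order network.** The $P \times P$ matrix $H$ correlates every two
   pair-series: $H_{(i,j),(p,q)} = \mathrm{corr}(y_{ij}, y_{pq})$. An entry is
   large when two couplings *fluctuate together*, which involves up to four
   ROIs at once — information invisible to ordinary static connectivity.
4. **Strongest-weight spanning tree.** $H$ is dense and mostly noise; the
   descending-order Kruskal tree keeps the $P - 1$ strongest-weight edges
   that connect all pair-nodes without loops. (This is formally a
   maximum-weight spanning tree; the MST brain-network literature calls this
   strongest-connection backbone the "minimum spanning tree", and we keep
   the field's naming in the package title only.)
5. **Two feature families.**
   - *Local tree metrics* per pair-node: degree, eccentricity (hops) and
     betweenness centrality normalized over ordered pairs,
     $BC_i = \frac{1}{(n-1)(n-2)} \sum_{h \ne j,\, h,j \ne i} \rho_{hj}(i)/\rho_{hj}$,
     so a star center scores exactly 1. Metrics are screened by a two-sample
     Kolmogorov–Smirnov test per feature with Benjamini–Hochberg correction
     at $q = 0.05$.
   - *Discriminative subgraphs*: frequent connected subgraphs of each group's
     trees (gSpan, canonical minimum DFS codes), scored by
     $S(g_s) = fq(g_s \mid G_{pos}) - fq(g_s \mid G_{neg}) \in [-1, 1]$ and
     selected as the balanced top-$k$ per direction.
6. **Multikernel SVM.** A linear kernel on the standardized selected metrics
   and a Weisfeiler–Lehman subtree kernel on each subject's
   pattern-restricted tree subgraph are individually normalized to unit
   diagonal ($k^*(x,y) = k(x,y)/\sqrt{k(x,x)k(y,y)}$) and combined convexly,
   $k = a\,k_{vec} + (1-a)\,k_{graph}$, with $a$ chosen on the grid
   $0, 0.1, \dots, 1$ by an inner cross-validation; a soft-margin SVM on the
   precomputed kernel does the classification.

## Evaluation protocols

The default protocol is honest nested evaluation: an outer leave-one-out
loop in which feature selection, mining, pattern selection and kernel
construction are redone on each training fold, and an inner stratified CV
(5-fold by default) picks the kernel weight and SVM cost; ties resolve
toward the smaller weight and cost for determinism. A `whole_sample_selection` flag
instead performs selection and mining once on the whole sample and
cross-validates only the classifier — the protocol most older neuroimaging
studies report. It is optimistic because the held-out subject influences the
selected features and patterns; we expose it for comparability, never as
the default.

Two guards address a pathology specific to leave-one-out: the training
fold's majority class is always the class opposite to the held-out subject,
and that imbalance leaks into the fold in several ways at once — the gSpan
support bars differ between groups (a fractional threshold over 19 vs 20
graphs rounds to different effective bars), the discriminative-pattern pool
tilts, and the SVM geometry shifts — so near-uninformative kernels produce
systematically *below*-chance accuracy rather than chance. We therefore (a)
class-balance every outer training fold by dropping rotating members of the
larger class (the rotation is keyed to the held-out subject's identity, so
it is deterministic, order-invariant, and spreads the exclusions evenly),
and (b) use inverse-frequency class weights in the SVM. On null cohorts
(no injected effect) this restores mean leave-one-out accuracy to chance,
which we assert in the test suite.

A subject whose tree contains none of the selected patterns has an *empty*
pattern graph. The WL kernel represents it by a single virtual
"empty-state" node: two pattern-free subjects are identical in pattern
space (normalized similarity 1) while sharing nothing with pattern-bearing
subjects. Representing them as zero vectors instead would zero their kernel
rows and reduce their classification to the SVM bias term — the
training-majority vote, which under leave-one-out is always wrong.

## The synthetic cohort generator

No imaging data ships with the package; a seeded generator produces labeled
cohorts whose group difference lives exactly where the method looks — in the
dynamics of coupling:

- Every ROI starts as an independent standard normal series.
- For each configured effect pair $(i, j)$, ROI $j$ is replaced by the
  unit-variance mixture
  $\sqrt{1 - \lambda(t)^2}\, z_j(t) + \lambda(t)\, z_i(t)$.
- Group 1: $\lambda(t) = e \cdot \sin(2\pi t/(M/2) + \varphi)$ — amplitude
  $e$ (`effect_size`), two cycles over the series, one phase $\varphi$ per
  *subject* shared by all effect pairs. Group 0: $\lambda \equiv 0$, the
  modulator's time average.
- Independent Gaussian noise (`noise_sd`) on every ROI.

Three choices deserve justification:

- **Zero-mean modulation** makes the groups indistinguishable in static
  (whole-series) correlation; only windowed analysis can separate them, so
  passing tests certify the dynamic pathway, not a static shortcut.
- **A shared subject-level modulator phase** makes the effect pairs'
  correlation series cohere within a subject. This is what a
  correlation-of-correlations network detects: the high-order entries
  between effect pair-nodes approach $+1$ in group 1 while staying near 0 in
  group 0, so the effect nodes join the spanning tree together and become
  minable patterns. Physiologically this mimics a slow common modulator
  (e.g., arousal) driving several couplings coherently. With independent
  phases per pair the high-order entries would have random sign across
  subjects and *no* method of this family could recover the group.
- **Sinusoidal form** is a stand-in; real correlation dynamics are not
  claimed to be sinusoidal. What the generator emulates is group-modulated
  smooth coupling dynamics plus measurement noise; what it does not emulate
  includes autocorrelated hemodynamic noise, spatial correlation among
  non-effect ROIs, scanner drift and motion artifacts. Passing tests
  therefore show the pipeline recovers dynamic coupling differences under
  idealized noise, not that it would do so on clinical data.

Default study conditions: 20 subjects per group, $R = 10$, $M = 120$, three
effect pairs, `effect_size = 0.8`, `noise_sd = 0.2`. At this scale we window
with $N = 30$, $S = 3$ ($K = 31$): the window must be shorter than half the
modulation period ($M/4 = 30$) to resolve the oscillation, mirroring how the
$N = 90$ convention relates to slow dynamics at full scale.

## Numerical and algorithmic choices

- **Window-count formula.** The printed form of the segment-count relation
  is ambiguous about parenthesization; $K = \lfloor (M-N)/S \rfloor + 1$ is
  the only reading consistent with $N = 90, S = 1, K = 149$ at $M = 238$,
  and the floor covers non-divisible cases.
- **Zero-variance guards.** A ROI constant within a window, or a constant
  pair-correlation series, raises an error naming the offender instead of
  emitting NaN — a silent NaN would poison all $P^2$ downstream correlations.
- **Correlations are used raw** (no Fisher z-transform), and tree weights
  are raw signed correlations by default; `abs_weights = TRUE` switches to
  magnitude sorting.
- **Determinism.** Kruskal ties break by (smaller node, smaller node);
  top-$k$ pattern ties by larger pooled frequency then canonical key; inner
  grid-search ties toward smaller $a$ then smaller cost; inner folds are
  keyed to subject identifiers so results do not depend on subject order;
  all randomness flows through one seed recorded in the run manifest.
- **gSpan.** Node labels default to pair-node *identity*: subjects share a
  node universe and patterns stay anatomically decodable. With unique
  labels a connected pattern is exactly its edge set, so containment
  collapses to edge-set inclusion and the canonical form is the sorted edge
  list — this is what makes mining tractable at $P = 4005$. A general-label
  mode (e.g., degree labels) grows patterns from embeddings and
  canonicalizes by minimum DFS code; both modes are verified against
  brute-force connected-subgraph enumeration. Pattern size is capped at 10
  edges as a safety valve; the cap logs a message when it truncates.
  Mining thresholds default to the frequencies 0.286 (positive group) and
  0.211 (negative group) conventional for this method family, and are fully
  configurable.
- **Weisfeiler–Lehman kernel.** $h = 3$ refinement rounds by default with
  early stop once refinement no longer splits label classes; iteration-0
  labels are the node identities by default, with `degree_init = TRUE`
  reproducing the classical rule for unlabeled graphs. Label compression
  uses a dictionary filled in first-seen order over a fixed subject
  ordering, so kernel values are reproducible.
- **Vector kernel.** Linear on features standardized by training-fold mean
  and SD: with a few dozen subjects a linear kernel avoids a bandwidth
  hyperparameter; subjects with an empty pattern graph get a zeroed,
  unit-diagonal row after normalization (with a warning) rather than NaNs.
- **Kernels are normalized before combination and not re-normalized after**;
  a convex combination of unit-diagonal PSD matrices already has unit
  diagonal.
- **Classifier features.** The vector kernel uses the per-metric BH mask
  directly; the stricter "at least two significant metrics" rule is used
  only for the abnormal-node *report*, since the two uses answer different
  questions (classification vs anatomical localization). Both surfaces are
  exported.

## Problem sizes used by the test suite

Unit tests run the full pipeline at $R = 6$–$10$ ($P = 15$–$45$ pair-nodes),
where an exhaustive oracle can verify every algorithmic component: spanning
trees against enumeration over all edge subsets, betweenness against naive
path enumeration, gSpan against brute-force subgraph enumeration with an
independent (BLISS-based) canonical form, and the KS/BH and Relief
statistics against hand-traced cases. Structural full-scale checks build a
single $R = 90$ subject ($4005^2$ high-order matrix, 4004-edge tree). The
end-to-end recovery check uses the default study conditions above and nested
leave-one-out.

## Known limitations

- Identity-label mining is the only tractable mode at full scale; degree
  labels are exponential in the worst case and intended for small graphs.
- The KS test treats the three tree metrics marginally; joint effects
  spread thinly across many nodes can be missed while still being captured
  by the graph kernel.
- The high-order construction needs $K \ge 3$ windows and meaningful
  within-window variation; with $N = M$ the pipeline degenerates by design
  (guarded with an explicit error).
- Relief weights follow the classic unnormalized update
  $w_f \mathrel{+}= |x_f - \mathrm{miss}_f| - |x_f - \mathrm{hit}_f|$, so
  their scale depends on feature scale; they are reported for feature
  interpretation, not used inside the classifier.
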