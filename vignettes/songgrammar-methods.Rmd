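---
title: "songgrammar: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{songgrammar: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. From audio to strings

The front end turns a mono recording into *strings of feature vectors*,
one string per detected song region:

1. **Song regions.** Per 20 ms Hann-tapered DFT frame (10 ms hop) we
   compute the ratio `r` of spectral power in the 500–1500 Hz song band to
   power in the 0–8000 Hz total band. Maximal runs of frames with
   `r > 0.6` spanning at least 500 ms become regions. Because `r` is a
   ratio, region detection is invariant to amplitude scaling.
   Regions are half-open `[start, end)`; frames are assigned by their
   start time. "Every point" in the region criterion is interpreted
   per-frame (the DFT gives no finer granularity of `r`).
2. **Wideband envelope.** The signal is split into six bands
   (cutoffs 80, 260, 600, 1240, 2420, 4650, 7999 Hz), each band's analytic
   (Hilbert) signal magnitude is taken and the six narrowband envelopes
   are summed. *Numerical choice:* bands are isolated by ideal zero-phase
   spectral selection in the FFT domain rather than a Butterworth design —
   no filter-design library is assumed, the operation is exactly
   zero-phase (like forward–backward filtering), and the analytic signal
   falls out of the same FFT. Peak *timing*, the only quantity downstream
   code consumes, is unaffected; band-edge rolloff differs from a 4th-order
   IIR, which is second-order for an energy-sum envelope.
3. **Peaks.** A 300 ms window slides in 10 ms steps; each window's maximum
   is a candidate, except when the argmax sits on the window edge — a
   clipped rising or falling flank is not "the peak within the window",
   and accepting such candidates would let a bump's flank (proposed by an
   earlier window) suppress the true apex through the refractory rule. A
   candidate is accepted if its prominence (candidate minus window
   minimum, best over proposing windows) reaches the threshold (1.0
   envelope unit by default, on the raw PCM sample scale) and no
   *accepted* peak precedes it within 150 ms; rejected candidates do not
   suppress followers. Ties inside a window break to the earliest sample.
4. **MFCC strings.** Each peak contributes 13 MFCCs (c0–c12) of the 100 ms
   window starting at the peak: 26 triangular mel filters over 0–8000 Hz,
   log filter energies floored at 1e-10 (silent windows), orthonormal
   DCT-II, no pre-emphasis. Amplitude scaling of the audio shifts only c0.
   Windows overrunning the signal end are zero-padded. A peak's window may
   cross its region boundary; we allow it (the alternative, truncation,
   would make boundary vectors incomparable with interior ones).

## 2. The two generative models

Both models share one emission story: a latent discrete symbol per
data point, a multivariate Gaussian per symbol with a
normal–inverse-Wishart (NIW) prior — scale Ψ₀ = I, degrees of freedom
ν₀ = D − 1 + 0.001 (barely proper: near-uninformative about covariance
scale), κ₀ = ν₀, and m₀ set to the sample mean of all training vectors.
All Dirichlet-process and Beta concentrations are 1.

**HDP-PCFG with variable root.** Truncated stick weights β over K_β
non-terminals and γ over K_γ terminals; per non-terminal a Beta(1,1)
branch/emit switch, a Dirichlet(α_Br · ββᵀ) distribution over child pairs
and a Dirichlet(α_Em · γ) distribution over terminals; the root label is
drawn from Dirichlet(α · β) — variable roots let incomplete strings and
substrings be parsed as any constituent. Strings terminate because every
non-terminal may choose to emit: the branch/emit switch doubles as the
termination mechanism.

**HDP-HMM with variable initial state.** Truncated sticks ω over K_ω
states, initial and transition distributions Dirichlet(α · ω). The source
description is silent on how the HMM terminates strings; we add a
per-state Beta(1,1) stop probability so the HMM is generative over string
*lengths*, mirroring the PCFG's switch — a controlled comparison requires
both models to spend probability on termination. A `termination = FALSE`
mode scores fixed-length sequences instead; reports state which mode was
used.

Truncations default to the full analysis scale (K_β = 40, K_γ = 100,
K_ω = 100);
the test suites use desk-scale truncations (K_β = 8, K_γ = 10) — adequacy
is checked the same way at either scale, by counting components with
expected frequency above 0.05.

## 3. Variational inference

The posterior is approximated by a fully factorized distribution:
Dirichlet factors for all rule probabilities, NIW factors for emissions,
point-mass (degenerate) factors for the sticks, and a parse factor q(τ)
per string proportional to exp E_q[log p] — realized as inside–outside
under rule weights `exp(E_q[log φ])` (digamma differences) with leaf
scores `exp(E_q[log N(x | μ_s, Σ_s)])`.

A sweep updates, in order: q(τ) for all strings (E step), the rule
Dirichlets (base counts + expected counts), the NIW factors (conjugate
update from responsibilities), then the sticks. The ELBO is evaluated once
per sweep right after the E step — `Σ log Z + Σ (−KL(factor‖prior)) +
log p(sticks)` — so the per-sweep trace is a coordinate-ascent objective
and never decreases; the suite enforces ≥ −1e-6. Runs stop when the
improvement falls below 0.1 (read as absolute ELBO improvement) or at
300 sweeps; multiple restarts are launched from
seed-derived initializations and the best final ELBO wins.

Choices a maintainer should know:

* **Degenerate-stick update.** The referenced update for point-mass stick
  factors is not reproduced in the source; we re-optimize β, γ, ω by BFGS
  on their ELBO terms (truncated-GEM log prior plus the E_q[log p(φ |
  base(β))] terms) through a softmax parametrization, *accepting the
  result only if it improves the objective*. Accepted ascent preserves
  CAVI monotonicity by construction even when BFGS misbehaves.
* **Initialization.** Dirichlet pseudo-counts = base counts × (1 + 0.1·U);
  NIW means start at randomly chosen data vectors (mixture-model practice —
  jittering around the global mean m₀ leaves components off the data
  manifold and was observed to strand whole runs). Restarts alternate
  between this unstructured style and a *chain-seeded* style whose branch
  pseudo-counts are boosted on self-recursive `z → (y, z)` rules — the
  regular-grammar basin in the package's right-branching convention.
  Structured restart coverage exists because pure jitter reliably missed
  the chain basin even when its converged ELBO was strictly higher (a
  warm-started chain run beat the best of ten jittered restarts by ~75
  nats on one test corpus); cycling both styles lets the untouched
  best-ELBO selection choose between qualitatively different optima on the
  evidence. On centre-embedding corpora the chain-seeded restarts
  converge, lose by ELBO and are discarded — which is the intended
  behaviour. All draws come from the restart's child seed.
* **Numerical floors.** Digamma arguments ≥ 1e-10; emission scatter
  matrices symmetrized and ridged by 1e-8·I; near-singular Wishart draws
  (a consequence of the barely-proper ν₀) ridged the same way before
  inversion.
* **Scaling.** The inside chart runs in linear space with per-position
  leaf rescaling *and* per-node-type weight normalization: every parse of
  a length-l string has exactly l − 1 branch and l emit nodes, so the
  branch and emit weight matrices can be divided by their maxima with the
  log factors carried exactly. Without this, `exp(E log φ)` weights at
  realistic truncations (≈ e⁻⁶⁴ per branch rule early in a run) underflow
  by string length 10. The compiled kernel (`src/inside_outside.cpp`)
  mirrors a pure-R reference implementation that the tests compare it
  against. Viterbi runs in log space.
* **Viterbi tie-breaking.** Cell-local and deterministic: smallest split
  point, then smallest labels. Under exactly uniform weights this yields
  the right-branching chain. (A *global* "prefer RIGHT then LEFT" ordering
  cannot be expressed cell-locally; the two rules agree in every pinned
  case.)
* **Stopping-rule bookkeeping.** "Improvement in KL < 0.1" is implemented
  as absolute ELBO improvement < 0.1 — the two differ by a constant.

## 4. Posterior diagnostics

* **Expected parse counts.** For each string with l ≥ 3, the posterior
  mass of the unique left- and right-branching topologies is computed by
  an inside pass *constrained to that topology* (sum over labelings, not
  enumeration); non-regular mass is the remainder. Optimal counts
  accumulate the posterior probability of the Viterbi parse into its
  topology class. Strings with l < 3 have a single parse that is both
  regular topologies at once; they are reported separately, and optimal ≤
  total is enforced by construction. The uniform baseline is
  Σ 1/Catalan(l − 1) over l ≥ 3 — the mass any single parse would get were
  all topologies equiprobable. (The source's figure caption describes the
  baseline as "of the non-regular parses" while its text gives the
  reciprocal-count formula; we implement the formula and label the field
  accordingly.)
* **Predictive density.** Default plug-in estimator: posterior-mean rule
  probabilities with the NIW factors' multivariate Student-t predictive at
  the leaves, summed by inside (PCFG) or forward (HMM); reported per data
  point (divided by string length), with population-SD summaries (divisor
  N). A Monte-Carlo estimator over draws from q is provided and used as a
  cross-check; for length-1 strings the plug-in is exact because the
  expectation factorizes.
* **Compactness.** The expected token frequency of a rule is its Dirichlet
  parameter minus its DP base count (clamped at 0: the stick update moves
  bases slightly). Type counts apply 1[f ≥ 1] and tanh(f), per rule class
  and in total; occupied-component counts use the 0.05 threshold.

## 5. The synthetic world

No field recordings ship with the package, so all validation runs on
generated data with known truth:

* **Chain (regular) corpora** draw class sequences from a Markov chain
  with per-step stop probability 0.18 — P(l ≥ 4) = 0.82³ ≈ 0.55, the
  long-string proportion the generator is calibrated to — over classes
  placed `mean_sep`
  pooled standard deviations apart (recovery suites pin 5σ; identity
  covariance). Classes are i.i.d. by default (`switch_p = 0.5`). This is
  deliberate: left- and right-branching grammars are weakly equivalent,
  and any *sub-chunk regularity* in the class sequence (e.g. strict
  alternation ABAB…, an earlier draft of this fixture) makes a chunked
  non-regular analysis ((AB)(AB)…) strictly more compact than the chain —
  the fit then correctly prefers it, which is the compactness phenomenon
  itself, not a recovery failure. A fixture meant to validate "regular
  ground truth ⇒ regular parses" must therefore emit sequences whose most
  compact account *is* the chain; i.i.d. classes achieve that, and the
  direction (RIGHT) is then selected because the chain basin dominates the
  ELBO across restarts, with the Viterbi tie-break handling exact ties.
* **Centre-embedding corpora** are aᵐbᵐ over two classes with depth m
  geometric(0.5) truncated at 3 (observed embedding depth in corpora is
  ≤ 3), true parses centre-embedded, hence non-regular from l = 4.
* **Pulse-train audio** plants Hann-shaped in-band carrier bursts at known
  times over a noise floor, optionally on a sustained low-amplitude
  carrier "bed" spanning planted regions (bursts alone are shorter than
  the 500 ms region minimum, so region detection is untestable without a
  bed). Synthetic tests set the peak prominence threshold between the bed
  and burst amplitudes, consistent with the threshold being expressed in
  raw sample units.

What a green test does **not** establish: that real song satisfies the
Gaussian emission model, that MFCCs at envelope peaks are sufficient
statistics of syllables, or that desk-scale truncations and restart counts
match full-scale behaviour on real corpora. The synthetic generator emits
exactly the model family being fitted (plus known structure), so recovery
tests validate inference, not the model's fit to nature.

## 6. Known limitations

* Direction identifiability: left- and right-branching chain grammars
  assign identical likelihoods and rule counts; which basin a fit lands in
  is decided by restart seeds and ELBO comparison, not by the data.
* The per-node-type scaling bounds chart magnitudes but very long strings
  (l ≫ 25) with extremely diffuse rule posteriors can still underflow; the
  front end's region segmentation keeps realistic strings far from this.
* The whole-window MFCC (one 100 ms frame per peak) follows the source's
  description; libraries that average sub-frames will produce different
  but monotonically related coefficients.
* `compare_report` assumes both models were evaluated on the same corpus
  and only checks sizes, not contents.
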