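---
title: "Models and methods behind nerpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nerpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerpe)
```

This vignette documents the models, parameter choices and numerical
decisions in `nerpe`: the chemistry of the two alphabets, the generative
model behind the read simulator, the read-processing and statistical
definitions, and the kinetic fitting procedures. It is the place where
design choices that were genuinely open are recorded.

## Alphabets and sequencer encoding

A `chemistry_system()` is a 4-letter alphabet with Watson–Crick
complement rules: `A:U`/`D:U` and `C:G`. In the noncanonical system,
2,6-diaminopurine (D) replaces adenine and pairs with U through three
hydrogen bonds. Exactly 12 ordered template:product pairs per system are
non-complementary; these are the mismatch catalogue, enumerated in a
fixed order (template base major, alphabet order) so that downstream
tables are deterministic.

Sequencing happens in cDNA space: reverse transcription incorporates T
opposite both D and A, and U is read as T, so the sequencer letter map
is `A→A, D→A, U→T, C→C, G→G`. Within one declared system this map is
invertible, which is why every pipeline function takes the system as an
explicit argument: the read itself cannot distinguish D from A. One
consequence, accepted deliberately, is that a sequencing *error* that
produces an A inside a DUCG read decodes as D; this mirrors the
ambiguity of the real experiment and is not corrected for. `N` is kept
as an ambiguity marker and reads containing `N` in an analyzed region
are dropped rather than guessed.

## The hairpin construct

`construct_spec()` describes a read as
`handle5 + template(6N) + loop + product(0..6)`. Copying proceeds from
the template base adjacent to the primer, so the template appears in
the read in reverse copying order: templating position *i* sits at
template-region index `template_len − i + 1`. All statistics use
copying order, with position 1 the first incorporated nucleotide.

The default constant sequences (12-nt `handle5`, 20-nt `loop`) are
synthetic stand-ins, chosen once so that the two anchors share no 6-mer
(which keeps fixed-offset anchor matching unambiguous); real construct
sequences can be supplied to process published libraries. Products are
never modelled beyond the 6-nt template — the analysis window of
interest is positions 1–6.

## The generative copying model

`copying_model()` simulates position-wise incorporation with stalling:

* `template_dist` — base composition of the randomized region; default
  uniform, matching an unbiased 6N synthesis.
* `propensity` (W) — a strictly positive 4×4 matrix of relative
  incorporation weights, rows indexed by template base. Rows are
  normalized internally, so only ratios matter. The default gives the
  complementary base weight 1 and each mismatch 0.04 (25:1), which
  produces a per-incorporation mismatch probability of about 0.10 —
  an error rate in the range observed for nonenzymatic copying with
  activated substrates.
* `p_ext_initial` (0.5), `p_ext_after_match` (0.7),
  `p_ext_after_mismatch` (0.12) — per-step extension probabilities.
  The defaults yield position-1 extension near 50% falling off with
  position, similar in shape to measured yield curves, and a generator
  stalling factor `S_gen = 0.7/0.12 ≈ 5.8`, inside the 4–9-fold range
  that extension-past-pair measurements show.
* `post_mismatch_error_boost` (3) — multiplier on mismatch weights for
  the incorporation immediately after a mismatch, reproducing the
  observation that errors beget errors; 1 switches the effect off.
* `seq_error_rate` (0.001) — i.i.d. substitution probability per cDNA
  base, a typical short-read error rate.
* `rt_error_rate` (0) — probability that reverse transcription miscalls
  a D position. MMLV RT incorporates T opposite D with high fidelity;
  no quantitative misread rate is available, so the knob exists but
  defaults to zero rather than guessing.

A product is built left to right: extend (with the probability given by
the previous pair's status), then sample the incorporated base from the
(possibly boosted) propensity row. The chain is therefore Markov in the
terminal-pair status, which is what makes an exact analytic check
possible: the per-position probabilities of
{complementary, mismatch, unextended} follow a two-state forward
recursion over (extended-with-match, extended-with-mismatch). That
recursion is implemented independently in the test suite and in
`scripts/acceptance.R`, and the stochastic engine is required to agree
with it within 3 binomial standard errors at every position on a
50,000-read library.

Reads are emitted as single-end FASTQ with constant Q40 qualities. The
quality model is deliberately trivial — base-call quality is not the
subject of this analysis — and the paired-read error correction of the
original sequencing protocol is replaced by the anchor/quality filters
described next. What the simulator does *not* emulate: indels,
position- or context-dependent sequencing error, over-extension beyond
the template, chemistry-level intermediate formation and hydrolysis
(reaction conditions enter only as different parameter sets), and any
RT bias beyond the `rt_error_rate` knob. Passing the recovery tests
therefore shows the statistics are computed correctly under a
substitution-only error model, not that real libraries are free of
artefacts the filters cannot see.

## Read processing

`extract_regions()` verifies both anchors at their fixed offsets within
a Hamming distance of `max_anchor_mismatches` (default 1). Fixed-offset
matching (no indel alignment) is a documented limitation for real data;
it is exact under the simulator's substitution-only error model, and
the constant regions of the real construct make the offsets
deterministic when indels are rare. Filter precedence is
anchor → length → quality → ambiguity; a read's product region longer
than the template is a `length_anomaly`; any analyzed base below Q20
(default) fails `low_quality`; `N` fails `ambiguous_base`. Quality is
enforced only inside the two analyzed regions — errors in constant
regions are already policed by anchor matching. Reads failing any
filter are excluded from **all** statistics, matching the all-or-none
read accounting implied by frequencies that are normalized to 1 per
position.

## Statistical definitions and open choices

Several definitions in the source material admit more than one reading;
the package fixes each one explicitly:

* **Mismatch frequency *m*** uses positions 1–4 by default. The
  operational definition attached to the reported numbers is the 1–4
  window (the later positions carry few incorporations and mostly
  noise); the window is a parameter (`m_positions`) for anyone wanting
  the all-positions variant.
* **"Fully complementary"** for the product-base and bridged
  distributions means *every incorporated base is complementary*, not
  *all six positions copied*. This keeps partial but error-free
  products informative; conditioning on full-length products is
  available by filtering `n_incorporated == 6` upstream.
* **Bridged dinucleotides** are counted from overlapping adjacent pairs
  within fully complementary products and normalized to sum 1. An
  alternative normalization by template dinucleotide availability is
  deliberately not the default — the plain normalized distribution is
  reported, and availability correction can be done on the returned
  counts.
* **Stalling statistics** condition on position 1 by default
  (`stalling_position`), where counts are deepest; the functions accept
  any position. Mismatch labels never observed at the conditioning
  position are *absent* from the per-mismatch table, not reported as 0.
* **Undefined is not zero**: positions with no qualifying reads, ratio
  cells with zero denominators, and statistics with empty conditioning
  sets are `NA`/flagged/errors, never silently 0 or infinity.
* **System comparison** aligns bases by alphabet slot, so D (DUCG) is
  compared against A (AUCG); ratio tables are labelled in the numerator
  system's alphabet.

## Kinetics

The pseudo-first-order model is `F(t) = P(1 − e^(−kt))` with the
plateau *P* **fitted** and bounded in (0, 1], not fixed at 1: real
primer-extension end points rarely reach completion, and fixing P = 1
biases k downward whenever they do not. Starting values come from the
log-linear transform of `P̂ − F` with `P̂ = min(1.05·max F, 1)`.

The Michaelis–Menten fit is unweighted least squares on
`kobs(c) = kobs_max·c/(Km + c)`, initialized from the double-reciprocal
(Lineweaver–Burk) line — used only for initialization, never for the
estimate. Replicate concentrations enter as ordinary extra points. When
the data are strictly linear in concentration (no saturation) the two
parameters are not separately identifiable; the fit then reports the
identifiable specificity `kobs_max/Km` with an explicit wide-SE warning
instead of failing silently. Derived ratios are echoed at two
significant figures (e.g. 606.06 → 610) to match the reporting style of
the kinetic figures they reproduce.

`delta_delta_g()` uses `R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹` and defaults to
298.15 K (25 °C). Units are h⁻¹ for rate constants and mM for
concentrations throughout.

Both fitters use Levenberg–Marquardt least squares (`minpack.lm`),
which converges on zero-residual (noiseless) fixtures where Gauss–Newton
implementations can stall; noiseless recovery to 1e−6 is part of the
test suite.

## Problem sizes and tolerances

The validation suite uses library sizes chosen to make its binomial
bands meaningful: 50,000 reads for oracle agreement (3 binomial SE per
position), 100,000 reads for stalling-factor recovery (within 10% of
the configured ratio) and for the χ² null check of the post-mismatch
boost (α = 0.01), and 200 replicates for noisy kinetic recovery (median
relative parameter error under 10% at 5% multiplicative noise). Exact
structural checks (classification, round trips, catalogue sizes) use
exhaustive enumeration on a 2-nt mini-construct and read-for-read
comparison of an error-free 5,000-read library against its truth
sidecar. Normalized tables are required to sum to 1 within 1e−9.

## Known limitations

* Substitution-only alignment: indel-containing real reads fail the
  anchor filter rather than being rescued.
* Single-end emission; no paired-read error correction.
* The D/A ambiguity of cDNA space is resolved only by the declared
  system; cross-contamination between AUCG and DUCG libraries would be
  invisible.
* Stalling estimates at deeper positions are noisy in small libraries;
  the per-mismatch table reports counts so users can judge.
* The simulator's parameters describe observable behaviour
  (incorporation, stalling, error elevation), not mechanism; it cannot
  be used to infer chemistry-level quantities.
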