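---
title: "The sipreads simulation model: gradient physics, abundance and read generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sipreads simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipreads)
```

## Overview

`sipreads` simulates the read libraries recovered when density-gradient
fractions of a DNA stable-isotope-probing (SIP) experiment are shotgun
sequenced. The simulation has four stages: shearing references into
extraction fragments, placing each fragment in an isopycnic CsCl
gradient, computing its recovered abundance in each sequenced
buoyant-density (BD) window, and emitting paired-end reads. This
vignette records the model, its assumptions, the tunable parameters and
the design choices made where the design was genuinely open.

## Gradient physics

A fragment's unlabeled (theoretical) BD is linear in its G+C fraction,
`rho_t = 0.098 (G+C) + 1.66` g/ml, so the map from composition to
density covers exactly [1.66, 1.758]. Isotope incorporation shifts it by
`A * delta`, where `A` is the atom fraction excess and `delta` is the
full-label shift (0.036 g/ml for 13C, 0.016 for 15N). In the tube lumen
the fragment's BD is normally distributed around this mean with SD
`sigma = sqrt(rho R T / (beta^2 G M_c l))`: dispersion shrinks as
`1/sqrt(l)` with fragment length, so longer extraction fragments band
more sharply.

**Unit caveat.** The constants `beta = 1.14e9` and `G = 7.87e-10` are
the conventional CGS-system values, while the gas constant defaults to
the familiar 8.314 J/(mol K). A fully CGS-consistent diffusion term
would use R in erg/(mol K) (8.314e7), making sigma about 3000-fold
larger (about 2e-3 g/ml for a 10 kb fragment instead of about 7e-7). We
keep the conventional default but expose `gas_constant` in
`gradient_params()`; users who want diffusion to dominate profile width
should set `gas_constant = 8.314e7`. With the default, the width of
simulated gradient profiles is driven almost entirely by inter-fragment
G+C variation, which is the dominant term for realistic genomes in
either case.

The equilibrium radius of a fragment in the spinning rotor is
`x = sqrt(2 beta (rho - D) / omega^2 + I^2)`, with `I` the
isoconcentration point of the tube geometry. The *model gradient* — the
map from radius back to density — is implemented analytically as the
exact algebraic inverse, `rho = D + omega^2 (x^2 - I^2) / (2 beta)`,
rather than as an interpolated lookup table: the analytic form is exact,
trivially invertible (round-trip error is at machine precision, asserted
below 1e-9), and a tabulated variant (`model_gradient_table()`) is
provided for parity checks.

### Diffusive boundary layer geometry

During rotor deceleration the gradient reorients, and a thin diffusive
boundary layer (DBL) of DNA clinging to the tube wall ends up
contaminating the BD interval spanned by its wall footprint. For a
fragment banding at radius `x`, the footprint along the tube wall is
computed with a cylindrical-section formula or a rounded-bottom formula
for each end of the band. Two open geometric questions had to be
settled:

1. **Section crossover.** The switch between cylindrical and rounded
   formulas is derived from continuity at the junction circle of the
   cylindrical wall and the hemispherical cap: the lower (denser) bound
   switches at `x = r_max - r_t (1 + cos theta)` and the upper at
   `x = r_max - r_t (1 - cos theta)`. With these per-bound rules the two
   formula pairs agree *exactly* at their junctions (tested to 1e-6 cm,
   observed at 1e-15).

2. **Wall position to BD.** The paper trail for this conversion is a
   "model gradient table"; we implement it analytically by projecting a
   tube position `s` (measured from the tube bottom) onto the tube
   midline radius `r(s) = (r_max - r_t) + (r_t - s) sin theta` and
   applying the analytic model gradient. This inverts the midline of the
   cylindrical formulas exactly and guarantees the physically necessary
   bracketing property `rho_DBLmin < rho < rho_DBLmax` for every
   fragment banding above the tube tip (with default geometry, all
   densities up to about 1.787 g/ml; the property suite asserts it on
   [1.66, 1.78]). Fragments banding into the rounded tip itself have a
   one-sided footprint and the bracket may degenerate; such densities
   lie outside any realistic sequencing window.

The DBL mass fraction `p_dbl` (default 0.001) is a single user-supplied
scalar applied to all fragments: no validated empirical model of its
dependence on rotor properties exists, so the simulation keeps it
explicit and constant. DBL mass is spread uniformly over the footprint's
BD interval. When a window partially overlaps the interval, the window
width in the recovery ratio is clipped to the overlap; the literal
unclipped ratio can exceed the total DBL mass when the window is wider
than the interval, which is unphysical. The unclipped variant remains
available (`clip_dbl = FALSE` / `clip = FALSE`) for parity comparisons.

Default geometry (overridable via `gradient_params()` or the config
`gradient:` block) describes a TLA-110-class fixed-angle rotor: 55,000
rpm, T = 293.15 K, average density D = 1.70 g/ml, r_min = 2.6176 cm,
r_max = 4.8518 cm, tube radius 0.65 cm, tube angle 0.4992 rad (28.6
degrees). Config files may give the angle in degrees
(`tube_angle_degrees`), converted at load time; radians are used
everywhere internally.

## Window abundance

For a window `[rho_min, rho_max]`, a fragment of reference abundance
`alpha` contributes

- lumen: `alpha_L = alpha (1 - p_dbl) * p_LR`, with `p_LR` the normal
  CDF mass of `N(rho, sigma)` inside the window;
- DBL: `alpha_DBL = (clipped window width / DBL width) * alpha * p_dbl`;
- total: `alpha_f = alpha_L + alpha_DBL`.

Summing `alpha_f` over a contiguous fraction set that spans the
fragment's lumen mass (rho +/- 8 sigma) and its DBL interval recovers
`alpha` to a relative 1e-4 (conservation suite), and the same occupancy
is reproduced by a direct Monte-Carlo placement of one million molecule
positions within three binomial standard errors (oracle suite).
Fragments whose equilibrium radius falls outside the tube's radial
extent contribute zero DBL mass and are counted in an
`out_of_gradient` attribute rather than raising an error mid-pipeline.

The shotgun-control mode short-circuits all of this with
`alpha_f = alpha`, which equals the SIP result in the limit `p_dbl = 0`
with an all-encompassing window (asserted in tests).

## Fragmentation

Each reference is sheared by tiling every scaffold left-to-right with
lengths drawn from the configured size model (uniform, normal,
truncated-normal or skew-normal; truncation by rejection with a
1000-round cap, then clamping with a warning). Passes repeat until the
summed fragment length reaches `coverage` times the reference length,
stopping after the fragment that crosses the target, so total fragment
bases lie in `[cov * L, cov * L + max_bp]`. Each pass starts at position
zero: the randomness of the drawn lengths already decorrelates cut
points between passes, and a deterministic pass start keeps the coverage
bound exact — including the degenerate case of a constant length model,
where passes tile the scaffold perfectly. Trailing remainders shorter
than `min_bp` are merged into the preceding fragment; fragments never
span scaffold boundaries; circular chromosomes are treated as linear.
Coordinates are 0-based half-open internally; read headers print
1-based inclusive coordinates.

G+C is computed over unambiguous bases only (ambiguity codes are
excluded from the denominator); a fragment more than half ambiguous is
dropped with a warning, and an all-ambiguous window is an error.

## Communities, labeling and fractions

Community tables are long-format TSV (`sample_id`, `reference_id`,
`abundance`); abundances must sum to one (renormalized silently only
within 1e-3, with a logged message). The bundled generator draws a
lognormal rank-abundance curve (defaults: mean relative abundance 2.0%,
log-SD 0.8) and pairwise-permutes 10% of rank positions to emulate
between-replicate variation.

Atom percent excess is drawn **per fragment** from
`Normal(mean, sd)` (table units are percent; division by 100 happens at
draw time so `A = 1` produces the full delta shift). Per-fragment
independence smears labeled peaks slightly, which is the realistic
behaviour for partially labeled populations; a per-genome draw can be
emulated with `sd = 0`. Draws are clamped to [0, 100] rather than
rejected — rejection would bias the mean near the boundaries at the
case-relevant SD of 5 around a mean of 90. Non-incorporators get
exactly zero.

Fraction sets partition `[rho_min, rho_max]` into contiguous windows
whose widths default to `Normal(0.004, 0.0003)` g/ml truncated at
0.002, mimicking empirical fraction tables; the last window is truncated
at the gradient bound.

## Read generation

Read pairs are allocated to fragments in a single multinomial draw with
probabilities proportional to `alpha_r = alpha_f * l_f / (2 l_r)`, so
library depth is exact, not Poisson. Fragments shorter than the read
length are excluded from the normalization (logged). "Insert size"
means total template length (forward start to reverse end), the common
Illumina convention; one insert is drawn per pair from
`Normal(mean, sd)`, rounded and clamped to `[l_r, l_f]`, the template
start is uniform within the fragment, and a fair coin decides which
physical end is written as mate 1. Reverse reads are reverse
complemented. Headers carry full provenance —
`pair{n}|{reference}|{scaffold}:{start}-{end}({strand})|{window}` — so
every read can be re-extracted from its reference byte-for-byte (the
strand field is our one extension of the header grammar; without it the
reverse mate's provenance would be ambiguous).

Determinism: every stochastic stage derives its RNG stream from the
master seed plus a stable key (fragment coordinates, window label,
stage name), and fragments are put into a canonical order before
allocation. Consequently the emitted library is identical for any
worker count and any input row order; fraction-based mode generates
fragments once and reuses them across all fractions.

## Error model

FASTA output is error-free. FASTQ conversion applies a parametric
per-cycle substitution model: each base is substituted with its cycle's
probability to a uniformly chosen different base; ambiguous bases stay
untouched; read length never changes (no indels, by contract). Quality
scores are drawn per cycle from a normal around the Phred transform of
the cycle error rate, clamped to [2, 41], encoded Phred+33. The
platform presets (`flat`, `miseq-like`, `hiseq-like`, `novaseq-like`)
are simple parametric shapes — flat, linear ramp, logistic tail
degradation — chosen to be fully self-contained and testable rather
than replicas of any trained platform model; they capture the
first-order behaviour (3'-end degradation) and none of the sequence
context effects.

## What the synthetic generator does and does not emulate

`make_genome()` draws i.i.d. bases with a blockwise G+C drift
(piecewise-constant block targets, Gaussian jitter, default 10 kb
blocks), emulating intra-genomic G+C heterogeneity — the property that
makes fragment BD vary within one genome. It does not emulate codon
structure, repeats, skew, or oligonucleotide composition; passing tests
therefore demonstrate the gradient/abundance machinery, not robustness
to genomic repeat structure (which mainly stresses assemblers, not this
simulator). Realized whole-genome G+C lands within binomial error of
the target (about 0.2 percentage points at 50 kb).

## Numerical choices and degenerate inputs

- All physics in double precision; no test asserts below 1e-12.
- Round-trip position/density: asserted below 1e-9 over 1000 random
  densities (observed: exact).
- Infinite window bounds are legal and give total lumen probability 1;
  a window equal to the DBL interval recovers the full DBL mass.
- `sd = 0` draws (atom excess, insert size, fraction width) are treated
  as exact constants, not degenerate normals.
- Out-of-range equilibrium positions: scalar API raises a descriptive
  error; the vectorized abundance pipeline zeroes the DBL term and
  counts the fragment.
- Scaffolds shorter than `min_bp` become single whole-scaffold
  fragments with a warning; an empty reference is an error.
- Test problem sizes are chosen for desk-scale determinism: genomes of
  20-200 kb, libraries of 1e4-1e5 pairs, one million Monte-Carlo
  placements — large enough that every statistical assertion uses a 2-3
  standard-error band computed from first principles.

## Known limitations

- No gradient-formation kinetics, rotor acceleration profiles or
  thermal gradients: the gradient is at equilibrium by assumption.
- `p_dbl` is constant across fragments; no empirical DBL model exists.
- No long-read simulation, chimeras, PCR/optical duplicates, adapter
  read-through or indel errors.
- The DBL wall-footprint-to-BD mapping assumes the midline projection
  described above; fragments banding inside the rounded tube tip are
  outside its validity range.
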