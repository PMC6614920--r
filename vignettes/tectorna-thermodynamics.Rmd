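---
title: "Models and methods behind tectofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tectofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tectofit)
```

`tectofit` quantifies the self-assembly of tectoRNAs — designed RNA
monomers whose terminal loop docks into a complementary receptor on a
partner molecule, so that dimerization strength reports directly on a
single tertiary interaction. This vignette is the package's account of
the models it fits, the estimators it uses, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
user of the results should know about.

## The equilibrium models

### Homodimerization with an active fraction

Native gel-shift titrations measure the fraction of RNA migrating as a
dimer, `fD`, across a ladder of total RNA concentrations `M0`. For the
equilibrium 2&nbsp;M ⇌ D with dissociation constant `Kd` and an *active
fraction* `beta` — the maximum fraction of molecules competent to
dimerize, which absorbs misfolded or damaged material — mass action gives
the closed form

$$
f_D(M_0) \;=\; \frac{(4\beta M_0 + K_d) - \sqrt{8 M_0 \beta K_d + K_d^2}}{4 M_0}.
$$

That expression subtracts nearly equal terms when `4*beta*M0 << Kd`, so
`homodimer_fraction()` evaluates the algebraically identical rationalized
form

$$
f_D = \beta\,\frac{\sqrt{1+x}-1}{\sqrt{1+x}+1},
\qquad x = \frac{8\beta M_0}{K_d},
$$

which is stable over the full concentration range (it tends to
`2*beta*M0/Kd` at infinite dilution and to `beta` at saturation, and
equals exactly 1/2 at `M0 = Kd`, `beta = 1`). The test suite pins this
form against an independent mass-action root-finder to 1e-9 across a
grid spanning five decades of `Kd` and eight of `M0`.

### Equimolar heterodimer

For two different partners A + B ⇌ AB titrated together at equal total
concentration `C`, the free-monomer quadratic yields

$$
f = \frac{\sqrt{1+4C/K_d}-1}{\sqrt{1+4C/K_d}+1},
$$

the fraction of each partner in the dimer
(`heterodimer_fraction()`). At `C = Kd` this is `(3 - sqrt(5))/2
≈ 0.382`, an analytic landmark the tests assert to 1e-12.

### Free energies

`delta_g()` computes `ΔG = RT ln Kd` with `Kd` converted from nM to
mol/L and `R = 1.987e-3` kcal K⁻¹ mol⁻¹. Under this convention a
sub-molar `Kd` gives a negative `ΔG`, stronger binders are more
negative, and differences are

* `ddg(Kd_n, Kd_o, T) = RT ln(Kd_n / Kd_o)` — relative strength against
  a reference construct (the crystal-structure construct `4LVV` by
  default in the reporting layer);
* `ddg_fa(Kd_plusFA, Kd_minusFA, T) = RT ln(Kd⁺ᶠᴬ / Kd⁻ᶠᴬ)` — the
  folinic-acid-induced stability shift, negative when the ligand
  stabilizes assembly.

Note the sign care required here: binding free energies are sometimes
quoted as `−RT ln Kd` (the dissociation direction). `tectofit` uses
`+RT ln Kd` throughout because it is the convention under which the
ligand-stabilization energies computed from measured Kd pairs come out
negative for a stabilizing ligand — e.g. `ddg_fa(74, 3694, 280)` =
−2.18 kcal/mol — which is how such shifts are conventionally reported.
The two conventions differ only by a global sign; all package outputs are
internally consistent and recomputable from the Kd tables.

Temperatures are carried per row: gel-shift conditions default to 280 K
(7 °C) and lead-probing conditions to 293 K (20 °C), matching the assay
temperatures the defaults emulate.

## Fitting gel-shift titrations

`fraction_dimer_from_bands()` converts monomer/dimer band intensities to
`fD = I_D / (I_M + I_D)`. With trace labeled RNA the probability that a
labeled molecule is in a dimer equals the bulk fraction of molecules
dimerized, so no factor-of-two correction applies; the quantity is also
insensitive to per-lane loading differences because both bands share the
lane's scale factor.

`fit_homodimer()` minimizes the unweighted residual sum of squares of
observed versus model `fD`. Choices that matter:

* **Parameterization and bounds.** `Kd` is fitted on a log scale within
  [1e-2, 1e8] nM; `beta` within (0, 1]. The log scale makes the search
  well-conditioned across the five orders of magnitude the assay spans.
* **Multi-start.** Levenberg–Marquardt (via `minpack.lm`) is run from 5
  log-spaced `Kd` starting values spanning the ladder by a decade on
  each side, with `beta` started at the maximum observed `fD`. The best
  RSS wins; exact ties go to the smaller `Kd`. The grid is
  deterministic, so fits are reproducible without a seed.
* **Convergence.** `ftol = ptol = 1e-10`, at most 500 iterations; the
  optimizer status is surfaced as the `converged` flag.
* **Degenerate series.** If the maximum observed `fD` is below 0.05 the
  series is not fitted: the result carries a `no_assembly` flag with
  `Kd` set to the top of the ladder, which is only a lower bound. A
  fitted `Kd` below the detection limit (default 1 nM, the practical
  floor of the gel assay) sets `below_detection`; the fitted value is
  retained but the limit is the honest reportable bound.
* **Replicates.** Following how the assay is reported,
  `aggregate_replicates()` fits each replicate separately and averages
  the estimates (mean, sample sd, flags OR-combined) rather than pooling
  points into one fit; `fit_gelshift_table()` applies this per
  construct × condition group. A warning (not an error) is raised below
  three replicates.

`fit_heterodimer()` is the single-parameter analogue for equimolar
two-partner titrations.

## Lead-probing quantification

Lead(II) cleaves flexible, single-stranded backbone positions;
positions inside the loop–receptor interface are protected upon
dimerization while positions whose local geometry rearranges (such as a
bulged nucleotide at a ligand pocket) can be enhanced. `tectofit`
consumes an already-densitometered position × lane intensity table; an
optional helper, `integrate_band()`, integrates a band window from a raw
1-D lane trace after subtracting a local median baseline.

### Two-state normalization and the apparent Kd

Under a two-state (all monomer ⇌ all dimer) picture, a position's
intensity is a linear mix of its full-monomer and full-dimer levels.
`normalize_two_state()` anchors those levels at the observed extremes of
the concentration ladder: for a position whose cleavage falls upon
dimerization (`direction = "decreasing"`), `fM = (I − Imin)/(Imax −
Imin)`; for an enhanced position the mapping is inverted. Values are
clipped to [0, 1].

`fit_two_state()` then inverts `fM(M0) = 1 − fD(M0; Kd, beta = 1)`.
`beta` is fixed at 1 because the anchoring convention *defines* the
extremes as the pure states — a free plateau would be unidentifiable.
One estimator subtlety is important: when the ladder does not saturate
the dimer state (e.g. a 20 µM top lane against `Kd ≈ 1.6 µM` leaves
~18 % monomer), the observed minimum is not the true full-dimer level,
and fitting the raw model to min/max-anchored data underestimates `Kd`
by tens of percent. The anchored fit therefore treats the two anchor
levels as nuisance parameters: for each candidate `Kd` the best affine
calibration `y = a + b·fM(M0; Kd)` is profiled out by linear least
squares. On noiseless anchored data this recovers the generating `Kd`
exactly, and under 3 % intensity noise the residual bias is below 2 %
(versus ~11 % for the naive fit). Raw, unanchored `fM` series are
fitted against the model curve directly.

Series staying within 0.05 of full monomer are flagged `no_assembly`;
fits whose mean squared residual exceeds 0.01 are flagged `noisy` but
still returned.

### Protection calls

`call_protections()` compares two states position by position using the
ratio `r = I_monomer / I_dimer` with a pseudo-count of 1 % of the pooled
median intensity (preventing blow-ups at near-zero bands). `r ≥ 1.5`
(the default fold threshold, configurable) calls `PROTECTED_IN_DIMER`,
`r ≤ 1/1.5` calls `ENHANCED_IN_DIMER`, anything between is `UNCHANGED`;
the reported magnitude is `max(r, 1/r)`. Supplying the +ligand dimer
state adds `FA_SPECIFIC_*` calls from the dimer-versus-dimer comparison.
The default threshold is deliberately conservative: the underlying
measurements support qualitative calls, not calibrated effect sizes.

## Sequence-signature analysis

Loop–receptor variants are represented on a 23-position label scheme in
which labels, not integer indices, key the alignment: an inserted
nucleotide gets a fractional label ("6.1" sits between "6" and "7") and
a deleted position is an explicit `-`, so no variant ever needs
re-numbering. The stem connector (9, 10 or 11 bp, encoded in construct
names as `_9`/`_10`, default 11) is metadata, not sequence: it is a
variable-length spacer, and its length is orthogonal to the signature.

* `classify_pair()` implements the pairing classes: Watson–Crick (A:U,
  U:A, G:C, C:G), wobble (G:U, U:G), mismatch (everything else),
  unpaired (deleted partner).
* `pairing_profile()` classifies the five long-range pairs 8:22, 9:21,
  10:20, 11:19, 12:18 and counts G:C pairs among them.
* `point_mutation_distance()` counts differing alignment columns;
  residue-versus-deletion and one-sided insertions count 1, which makes
  deletions and insertions ordinary point mutations and keeps the
  distance a metric (verified by brute force over random triples).
* `family_components()` groups variants into the connected components of
  the "≤ 2 point mutations" graph, ordered largest-first.
* `consensus()` emits, per column, the majority symbol when its
  frequency is at least 0.75 (inclusive), else the smallest degenerate
  code among R (A/G), Y (C/U), W (A/U) covering every base at frequency
  ≥ 0.10, else N; columns with a gap majority emit `-`. The minor-allele
  floor of 10 % is a package choice (the conservation threshold alone
  does not determine which rare bases enter a degenerate code) and is
  configurable. Because a column whose top symbol reaches the threshold
  re-emits that symbol, the consensus of a consensus is itself.

### The synthetic variant panel

The shipped FASTA (`inst/extdata/thf_signatures_synthetic.fasta`,
regenerable with `make_variant_fixtures()`) is a **synthetic
reconstruction**, not a transcription of measured sequences. It anchors
a 23-position signature for the 980 loop–receptor and derives the other
named variants by their documented mutational relationships: 3SUX =
980 + C21U (creating the G9:U21 wobble), 593 = 980 + G10A/C20U, 148 =
980 + U3C, 158 = 980 + G7A, 4LVV differing from 980 at eight positions
including the U6/C14/del17 context, 894 carrying the G6.1 insertion, and
the artificial pairing variants (980.8, 980.11, 4LVV.1–.3, 488.1 with
four G:C pairs around an A:A mismatch). All pairwise distances and pair
classes that the analysis relies on are properties of these relationships
and are asserted in the tests; conclusions about the real panel's exact
residues should not be drawn from this file.

## The synthetic-data generator

The generator is the package's stand-in for the two assays and defines
the conditions under which the estimators are validated.

* **Gel shift** (`simulate_gelshift()`): ladder of two-fold steps from
  5 nM capped at 20 000 nM (13 lanes); true `fD` from the isotherm;
  additive Gaussian noise on `fD` with sd 0.02, clipped to [0, 1];
  band intensities back-computed with a per-lane lognormal loading
  factor (sdlog 0.05); 3 replicates. The default `beta` is 0.85 — a
  typical active fraction for gel-purified in-vitro transcripts.
* **Lead probing** (`simulate_lead_profiles()`): same ladder shape
  (5 nM–20 µM); per lane `fM = 1 − fD(M0; Kd, beta = 1)`; per position
  the linear two-state mix of `I_monomer` and `I_dimer` times
  `1 + N(0, 0.03)`, floored at 0; a ±ligand pair of profiles generated
  from a discrete `(Kd_noFA, Kd_FA)` pair. The ligand response is a Kd
  switch, not a dose–response curve, because only a single saturating
  ligand concentration is emulated.
* **Heterodimer** (`simulate_heterodimer()`): two-fold ladder 2–2000 nM
  per partner, Gaussian sd 0.02 on the bound fraction.

All generators take a seed, restore the caller's RNG state, and return
the generating parameters in `attr(, "truth")`.

What the generator does **not** emulate — and therefore what passing
recovery tests do and do not show about real data: gel smearing and band
overlap, position-dependent cleavage chemistry, lane-to-lane loading
drift beyond a scalar factor, correlated (gel-level versus
pipetting-level) replicate error, radiolabel decay, and any deviation
from the two-state assumption such as higher-order oligomers or
partially folded intermediates. Recovery results certify the estimators
under the stated noise model, not the assays themselves.

## Validation problem sizes

The package validates itself at sizes chosen to give stable summary
statistics while keeping the suite quick to run: parameter-recovery
properties use 50 simulated triplicate series per true `Kd` in
{26, 98, 1944, 3694} nM; the lead-probing and heterodimer recovery
checks and `scripts/acceptance.R` use 25 independent seeds per
condition; the oracle comparison covers a 162-point parameter grid. The
full test suite runs in well under a minute.

## Known limitations

* The two-state lead model ignores intermediate states; apparent Kd
  values from footprinting are interpretable only where the two-state
  picture holds (the package reports `noisy`/`no_assembly` flags but
  cannot detect a third state).
* Kd values below the lowest tested concentration are extrapolations:
  the tracer itself contributes a few nM that the stated `M0` may not
  include, so sub-tracer estimates should be read as bounds.
* `beta` and `Kd` are partially confounded when the ladder tops out
  below ~5× `Kd`; replicate averaging (the default reporting path)
  mitigates but does not remove the inflated variance there.
* Magnesium concentration and temperature are categorical condition
  annotations; the package fits no Mg²⁺- or temperature-dependence
  model, and the ligand effect is a discrete Kd pair rather than a
  binding polynomial.
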