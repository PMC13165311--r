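---
title: "Negative chemical space and quenching diagnostics: methods"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqdnegspace)
```

## The problem and the inversion

Selectivity studies of carbon quantum dot (CQD) fluorescence sensors report
two kinds of outcomes: the detected analyte (with its limit of detection,
LOD) and a panel of species "that do not interfere". Discussion usually
focuses on the positive outcomes only, a survivorship-bias blind spot. This
package inverts the perspective: every species listed in a selectivity panel
is an explicit experimental challenge with a binary outcome, *detected* or
*non-interfering*. Pooling those events across a literature corpus maps the
*negative chemical space* — the ions that are challenged again and again
without ever eliciting a response.

For every ion (canonical identity, see below):

- `tested_total` = detected + non-interfering challenges,
- `failure_ratio` = non-interfering / tested_total.

Only ions with `tested_total > 10` (strict, configurable) enter the map, so
single-case reports cannot masquerade as structure. Events are counted at
study level: one article contributes at most one detection event and one
non-interfering event per ion, regardless of repeated listings.

## Species canonicalization

Tables print the same chemical identity many ways (`Fe^3+`, `Fe^+2`,
dichromate vs `Cr^6+`). The grammar in `parse_species_token()` canonicalizes
metal redox forms by element plus oxidation state (`Fe(III)`, `Cr(VI)`), so
an oxoanion challenge of a tabulated oxidation state merges with the
cationic notation — the level at which the corpus tallies outcomes. Joint
tokens (`Fe^2+/Fe^3+`) expand to one event per alternative. Molecules keep
their lower-cased name and are excluded from the default `ions_only` scope;
anions (including polyatomic ones such as nitrate) count as ions. Printed
typos in the packaged corpus are transcribed verbatim (e.g. a `Na^2+` cell
becomes the — chemically fictitious — identity `Na(II)`); fidelity beats
correction, and the affected identities never reach the `tested_total > 10`
filter. One consequence of the kind invariants: a charged radical such as
superoxide (`O2^.-`) is classified by its charge (anion), with the radical
marker kept only in the raw token.

## The packaged corpus

`load_corpus("table1")` resolves a 60-study fixture transcribed from a
published comparative table of CQD metal-ion sensors (precursors, synthesis
route, analytes with LOD in µM, non-interfering panels). Two bookkeeping
oddities are preserved on purpose: one record prints an LOD of `10^6` µM
(loaded verbatim, flagged by a validation warning, never an error) and one
prints no LOD at all (loaded as absent). One record's interference cell is
free text ("Biosensor with reduced interference"); it maps to an empty
challenge panel plus a note.

On this corpus, Mg(II), Ca(II), Na(I), K(I) and Zn(II) are challenged 35-46
times each and never detected (failure ratio 1.0), while Fe(III) is detected
26 times out of 47 challenges (failure ratio ≈ 0.45).

## Ion annotation and the redox correlation

The built-in panel (`cqd_ion_panel()`) annotates 17 ions with:

- **HSAB class** after the classical Pearson classification (hard ions bind
  O-donors, soft ions S-donors, borderline between); Cd(II) is treated as
  soft and Pb(II) as borderline.
- **Standard reduction potential** (V vs SHE). Where a stable lower aqueous
  oxidation state exists the couple to that state is used (Fe3+/Fe2+
  +0.771 V; dichromate/Cr3+ +1.33 V); otherwise reduction to the metal. The
  couple is recorded per ion and the whole panel is overridable by CSV,
  because the couple choice is a genuine curation degree of freedom — the
  acceptance tests therefore also check that the correlation sign survives
  the alternative Fe3+/Fe couple (−0.037 V).
- **Paramagnetism** from the ground-state d-electron configuration of the
  aqua ion, and a **heavy-atom** flag for period ≥ 5 elements.

`correlate_potential_failure()` correlates potential with failure ratio over
the filtered table (Pearson default; Spearman exposed since ranks are robust
to the couple ambiguity). Ions passing the filter but absent from the panel
(on the packaged corpus: Ba(II) and Cr(III)) are dropped and listed in the
result. On the packaged corpus the correlation is distinctly negative
(Pearson ≈ −0.63, Spearman ≈ −0.71): ions with strongly negative potentials
are almost universally non-responsive, ions with positive potentials are
detected far more often.

## The detectability rule

`detectability_profile()` encodes the two-stage mechanism hierarchy:
coordination complementarity between the ion's HSAB class and the
precursor-derived donor sites (O/N/S, from `classify_precursor_donors()`
and its keyword lexicon) is *necessary but not sufficient*; a predicted
response additionally requires an electronic pathway — redox activity
(potential above a configurable 0 V threshold; the literature offers only a
qualitative positive/negative contrast, so the cutoff is a documented knob),
paramagnetism, or a heavy-atom effect. This reproduces the headline
contrasts: Fe(III) on an oxygen-rich surface is predicted responsive
(redox-active, paramagnetic), Zn(II) coordinates but has no pathway, Hg(II)
on a sulfur-doped surface responds via the heavy-atom channel. Known
limitation: Mn(II), hard and paramagnetic d5, is predicted responsive under
O-donors yet sits in the observed negative space — the rule set is a
first-order screen, not a quantitative model.

## Quenching-mechanism diagnostics

`stern_volmer_fit()` fits I0/I against quencher concentration. Curvature is
assessed by nested comparison with a quadratic model: the flag is set when
the quadratic term is positive and improves AIC by ≥ 2 (machine-precision
linear data never flags; exactly quadratic data always does). For combined
static + dynamic quenching, I0/I = (1 + K_D[Q])(1 + K_S[Q]), so the
quadratic coefficient is the product K_D·K_S.

`lifetime_profile()` compares tau0/tau with I0/I. The published rule set
distinguishes only "changed" vs "unchanged", but combined quenching
produces a lifetime that rises (dynamic component) without tracking the
full intensity loss (static component) — neither label fits, and calling it
"changed" would misroute the classifier to a pure-dynamic call. We
therefore return a third informative level, `"partial"`, alongside
`"absent"`. Tolerances (all configurable, stated once here): "unchanged" =
within 5% of unity everywhere; "tracks" = within 10% relative of I0/I;
temperature-trend flat band = 5%; IFE overlap threshold θ = 0.2.

`spectral_overlap_fraction()` replaces visual overlap assessment with a
number: the integral of the pointwise minimum of the normalized absorbance
and band curves over the band integral (trapezoid on the union grid).
`ife_attenuation()` uses the standard half-path correction
10^(−(A_ex + A_em)/2), which assumes a centered detection window; the
inverse is exposed as the correction multiplier.

`classify_mechanism()` runs a first-match rule cascade with lifetime
evidence ranked above everything (it is the one observable that cleanly
splits dynamic from static/IFE): (1) changed → dynamic; (2) unchanged +
overlap ≥ θ + dilution not refuted → IFE (a failed dilution test vetoes);
(3) unchanged + new ground-state absorption band → static; (4) unchanged +
Stern-Volmer slope falling on heating → static; (5) upward curvature with
partial lifetime change → mixed; (6) indeterminate. Upward curvature is
deliberately labelled "mixed" rather than ascribed to a specific
photophysical cause (claims in the literature attributing it to intersystem
crossing are nonstandard; the classifier records the ambiguity instead of
encoding the causal claim). The rationale field logs every rule inspected.

## The synthetic world

`gen_selectivity_corpus()` emulates the event model the statistic assumes:
independent Bernoulli challenge/detection coin flips per study and ion, so
the failure ratio converges to 1 − detect_prob with binomial error. No
study-level random effect is included by default (the pooled statistic also
ignores between-study heterogeneity); placeholder LODs are log-uniform
purely to satisfy the schema. `gen_titration()` uses the closed generative
forms above with multiplicative Gaussian intensity noise (relative noise
reflects fluorescence practice; 2% is the package's canonical noisy
condition, chosen to match the stated Stern-Volmer recovery tolerance) and
emits the side evidence a full workup would supply: overlapping spectra and
a positive dilution test for IFE, a new absorption band and a static
temperature trend for static quenching.

A green closed-loop test therefore establishes that the estimator and the
rules are consistent with the stated event and signal models — not that
real titrations are this clean. Real corpora have correlated challenge
panels, publication bias in what gets tabulated at all, and heterogeneous
definitions of "no significant response"; real titrations have
heteroscedastic noise, drift and mixed mechanisms in varying proportions.
None of that is simulated, which is exactly why the fixture recount (a
string-level oracle independent of the type system) is the ground truth for
the corpus statistics.

## Numerical choices and degenerate inputs

- Bootstrap: cluster bootstrap over studies (events within one article are
  dependent), percentile interval, type-6 quantiles; resamples containing
  no challenge of the target ion are dropped rather than imputed. Coverage
  at the default settings is near-nominal but slightly below 0.95 for small
  corpora, as expected for percentile intervals on proportions.
- Deterministic ordering everywhere (tables sorted by canonical id; ranking
  ties broken by tested_total then id) so outputs are byte-stable; all
  generators take explicit seeds and restore the global RNG state.
- Zero `tested_total` → explicit undefined-value error, never NaN; empty
  corpora tally to empty tables; unknown ions error with the known panel
  listed.

## Limitations

The statistic pools heterogeneous experiments without quality weighting and
cannot correct publication bias — it quantifies the reported negative
space, not the true one. Per-ion tallies behind the published
two-dimensional visualization are not printed anywhere, so the fixture
recount here is the only checkable ground truth. LODs are bookkept in µM as
printed, without unit forensics. Nernst/pH corrections of potentials,
FRET-distance modelling and decay fitting are out of scope.
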