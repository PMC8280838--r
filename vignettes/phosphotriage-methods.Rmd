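---
title: "Methods: two-screen kinase-substrate triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-screen kinase-substrate triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphotriage)
```

## The problem

A kinase knockout perturbs far more than the kinase's direct substrates.
In WT-vs-DKO phosphoproteomes of the ULK1/2 autophagy kinases, sites can
be depleted because a downstream kinase lost activity, because the
protein's abundance changed, or because of labelling artifacts — so a
single depletion screen has an unknowable false-positive rate (basal
phosphorylation cannot be measured in the knockout). `phosphotriage`
encodes a triage discipline: two orthogonal quantitative screens must
agree, sequence and network context annotate the survivors, and every
inclusion or exclusion decision is recorded with the rule that fired.

## SILAC depletion screen

Each experiment mixes heavy/light-labelled WT and DKO lysates in both
label orientations. Both orientations are stored as log2(DKO/WT) — the
reverse permutation is reciprocal-corrected at ingestion — so the two
values for a genuine depletion agree in sign.

* **Per-experiment call.** Default rule (`both_orientations`): depleted
  iff forward < −1.5 **and** reverse < −1.5, strictly. The alternative
  reading (`mean_of_orientations`): the fwd/rev average < −1.5. Both
  readings of the per-experiment rule are in circulation for this screen
  design, so both are implemented and a deposited data set can be
  evaluated under either; the both-orientations form is the default as
  the stricter of the two. The inequality is strict: a site at exactly
  −1.5 is not depleted.
* **Label-bias exclusion.** WT/WT control mixes should show no change;
  any control with |log2(WT/WT)| strictly greater than 0.5 marks the
  site label-biased and excludes it from the combined call. The printed
  band expression is read as "outside [−0.5, 0.5]"; the boundary value
  itself is accepted. With no controls observed a site cannot be
  excluded.
* **Combined call.** Depleted in ≥ `min_experiments` (default 1 of 3)
  experiments and not label-biased.
* **Protein-level flag.** A protein with ≥ 3 detected sites of which
  ≥ 80% are depleted is flagged as a probable protein-abundance change
  (the Sorbs2-type pattern: many depleted sites with mutually unrelated
  sequence contexts). The flag annotates, it never removes — the
  defaults are heuristics for a phenomenon the screen design describes
  only qualitatively, and both are configurable.

## Consensus-motif engine

The motif grammar mirrors the positional-scanning rendering: `[...]`
allowed residues, `{...}` forbidden residues, `-` position separators,
juxtaposed groups at one position read as a conjunction, `.` an
unconstrained position. The ULK1 consensus spans −3…+2:
`[M/L/Q/F]-{P}-{P}-[S/T]-[Y/I/M/S/F/V/W]{P}-[Y/S/H/I/W/M]{P}`. The
phosphoacceptor position is located as the unique group whose allowed
set is contained in {S, T}; the grammar therefore rejects motifs without
a position-0 group. The terminal pad character `_` fails every non-empty
allowed set (a truncated window cannot certify a required residue) but
passes forbidden-only positions (absence of a residue cannot violate an
exclusion).

Enrichment logos are computed as
`log2((f_fg + ε)/(f_bg + ε))` per residue and position over ±7, pads
excluded from the frequency denominators, with pseudocount ε = 0.01
keeping cells finite. The background defaults to all detected sites of
the same screen — the natural null for "what does depletion select
for?"; no background is prescribed by the design, so it is an argument.
The +1-proline split exists because proline-directed kinases dominate
starvation-responsive phosphoproteomes and would otherwise mask any
other signal in a logo.

## TMT time-course triage

Ten conditions (WT and DKO × 0/10/30/60 min starvation + refed) are kept
in a fixed order — WT segment then DKO segment — because the reference
correlation is computed over the concatenated vector and is
order-sensitive. Profiles not quantified in all 10 conditions are
removed before analysis. Three normalizations:

* `log10_raw` — contrast scale;
* `anchored_to_DKO0` — subtract the DKO 0-min value; profile plots and
  clustering. Anchored profiles are 0 at DKO 0 min exactly.
* `relative_log2` — log2 of intensity over the 10-condition mean; heat
  maps. Each profile satisfies Σ 2^value = 10 to machine precision.

The triage variables, in log10 units: `V1 = WT60 − WT0` (starvation
response), `V2 = WT60 − DKO60` (kinase dependence), `V3 = WT60 − WTRF`
(refeed reversal), `V4` = Pearson correlation with the Prkab2 S38
reference profile over all 10 conditions (all-10 rather than WT-only,
because the DKO segment carries the kinase-dependence information; the
reference can be any site in the table or an external profile). Tier
rule: `primary` iff V1, V2, V3 all ≥ their thresholds; else
`similarity_only` iff V4 > 0.7 (strict); else `none`. The contrast
thresholds default to 0.1 log10 units (≈ 26% intensity change) — the
original screen set them "by trial and error", so here they were
calibrated once on synthetic screens and are fully configurable; the
primary tier takes precedence as the more stringent criterion.

Clustering is hierarchical agglomerative with distance 1 − Pearson and
average linkage, cut at k = 6 — a deliberate, seedless choice: it is
deterministic, and the correlation distance groups profiles by shape
regardless of baseline. Zero-variance profiles have no defined
correlation and go to a dedicated `"flat"` cluster. Labels are
canonicalized by first appearance over sites sorted by `site_id`, making
the labelling invariant under input-row permutation. Rows are sorted
before `hclust` so that tie-breaking cannot depend on input order
either.

## Shortlist assembly

Default rule: `(combined_depleted AND tier ∈ {primary, similarity_only})
OR manual_include`, with manual exclusions dominating. Manual curation
is a config list of site ids with free-text reasons — reproducible
curation in place of automated judgement. Conservation against the human
ortholog window (fractional identity over non-pad positions, default
minimum 0.6 — the design names no number, only "particularly low
conservation") drops candidates whose human window lacks S/T at the
phosphoacceptor regardless of identity. PPI distance to ULK1/ULK2
(breadth-first over an undirected edge list, via igraph) is annotation
only, never a filter. Peptide-array design emits per site: WT, single
S→A phosphomutant, total S/T→A phosphomutant (only when the window
carries S/T beyond the centre — otherwise it would duplicate the single
mutant), and the murine window when divergent.

## Synthetic screens and what they show

`generate_screen()` plants five classes with known labels:

* `true_substrate` — motif-conforming windows; log2 depletion drawn from
  N(−2.5, 0.4) truncated above at −1.8 (a planted "depleted" site must
  genuinely sit below the −1.5 cutoff for the class label to be
  meaningful in the noiseless limit), shared by both orientations of all
  3 experiments with independent N(0, 0.4) orientation noise — this
  shared-effect structure reproduces the within-experiment fwd/rev
  concordance of real screens. TMT dynamics: WT rising
  +0/0.15/0.30/0.45 log10 over starvation, refed at +0.10, DKO flat at
  −0.5 log10 — the Prkab2-S38 pattern. A noiseless reference site
  `Prkab2_S38` is always included.
* `label_bias` — depleted-looking ratios plus a planted
  |log2 WT/WT| ∈ [0.7, 1.2] artifact in one control; the screen must
  reject them.
* `protein_level` — whole proteins (4 sites each) sharing one depletion
  offset, non-conforming windows, divergent human orthologs; caught by
  the protein-level flag and the conservation filter.
* `proline_background` — +1-proline windows with starvation-*suppressed*,
  genotype-independent dynamics: proline-directed phosphorylation in
  this setting is mTOR/CDK-driven, falling during starvation and
  recovering on refeeding identically in WT and DKO. They fail V1/V3 by
  sign and V2 by symmetry.
* `null` — centred noise; windows uniform over the 20 amino acids with
  S/T centres, so the motif-positive fraction has a closed form
  (`analytic_match_probability()`) that the generator is tested against.

Amino-acid backgrounds are uniform for analytic tractability; real
proteomes are not uniform, real missingness is intensity-dependent
rather than uniform, TMT ratio compression is not simulated, and SILAC
ratios arrive pre-normalized. Passing the planted-truth tests therefore
demonstrates that the *decision rules* are implemented correctly and are
robust at realistic noise (SILAC sd 0.4 log2 per orientation, TMT sd
0.05 log10 per condition), not that the thresholds are optimal for any
particular real data set.

Quantities are rounded at generation (ratios 4 decimals, intensities 3)
so that written tables round-trip byte-identically — matching the finite
precision of real search-engine exports.

## Problem sizes and numerical choices

Test and acceptance runs use screens of roughly 1,000–10,000 sites
(400–4,000 proteins), chosen so the full suite completes in well under a
minute while leaving every rate estimate dozens-to-hundreds of events
wide. The exhaustive motif check covers all 46,656 centre 6-mers over a
6-letter alphabet plus 10^5 random 15-mers against an independent regex
oracle. Degenerate inputs are handled explicitly: zero/negative
intensities are errors naming the offending condition, constant
reference profiles are errors (correlation undefined), missing
orientations yield `incomplete` calls rather than guesses, and absent
PPI targets get infinite distance rather than NA.

## Interfaces

The package's functions are the interface, composed by `run_all()`,
which validates all inputs before writing anything and embeds the full
configuration, its hash and the package version in `run_config.yaml`.
Configuration is nested YAML validated against the known key set —
unknown keys are rejected rather than silently ignored, so a typo cannot
silently revert a threshold to its default.
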