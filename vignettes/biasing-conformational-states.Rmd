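---
title: "Biasing template-based structure prediction toward conformational states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biasing template-based structure prediction toward conformational states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statefold)
```

## The problem

GPCRs switch between active and inactive conformations of their
seven-helix transmembrane bundle; kinases rearrange their DFG motif,
activation loop and alphaC helix between catalytically competent and
incompetent states. A structure predictor trained on the whole PDB tends
to return whichever state dominates its training data, which is often not
the state a drug-discovery project needs (DFG-out kinase models for
type-II inhibitor design, for example). statefold implements a protocol
that steers template-based prediction toward a requested state by
controlling the two information channels a predictor consumes:

* **templates** — candidate template chains are filtered by their
  conformational annotations (GPCRdb-style activation state; KLIFS-style
  DFG / alphaC-helix / salt-bridge labels) before the top-ranked
  survivors are handed to the predictor;
* **the MSA** — the evolutionary signal is deliberately weakened
  (shallow subsampling), removed over template-covered regions, or
  window-masked, so the state carried by the templates is not averaged
  away by deep genetic information.

Optionally the surviving template pool is *shuffled*: each model of the
ensemble receives an independent random subset of state-matched
templates, widening the sampled structural space without changing the
requested state.

## The record model and the selection procedure

Every template chain is one row of a `template_records` table: PDB id,
chain, sequence, the upstream template-search ranking score, percent
identity, family/subfamily, and the label blocks. A record is *typed* by
which block is populated: a GPCR record carries an activation state
(`Active`, `Inactive`, `Intermediate`, `G protein`, `Arrestin`), a kinase
record carries DFG (`in`, `out`, `out-like`), alphaC-helix (`in`, `out`)
and salt-bridge (`yes`, `no`) labels. Absent labels are stored as
`unknown`, never dropped.

A `state_query` fixes the criteria. In GPCR mode a record survives when
its state matches the query; a record annotated `G protein` or `Arrestin`
also satisfies an `Active` query by default, because transducer-bound
structures are in the active conformation (disable with
`signaling_as_active = FALSE`). In kinase mode the three feature criteria
combine conjunctively, with `"all"` as a per-feature wildcard; only
kinase-typed records can match, wildcards or not. Same-subfamily
templates are excluded by default in GPCR mode only — that guard exists
to stop trivially close homologs from dominating a benchmark, a concern
the kinase workflow does not share.

Survivors keep their input order, which carries the upstream search
ranking. `select_top_k()` takes a rank-ordered prefix (`rank_score`
descending; ties broken lexicographically by PDB id and chain so runs are
reproducible). The ranking key is the stored `rank_score`, *not*
recomputed sequence identity: upstream template searches rank by an
alignment score that is correlated with, but not identical to, raw
identity, and the package preserves that order rather than second-guess
it. `select_random_k()` draws a uniform subset without replacement; the
draw for model *i* is seeded from `(run_seed, i)` by a counter-based
derivation, so any single model's template set can be regenerated without
replaying the run, and draws for different models are independent
streams.

## MSA interventions

A3M alignments are query-anchored: the query row has no gaps, match
states are uppercase or `-`, lowercase letters are insertions and do not
count as columns. Three interventions are provided:

* `msa_subsample(x, n_clusters, n_extra)` — the shallow-MSA step. The
  contract is the two counts handed to the predictor: a cluster block of
  `n_clusters` rows (query always first) and a disjoint extra block of
  `n_extra` rows. Rows are drawn uniformly at random under the given
  seed; no similarity clustering is attempted, because only the counts
  are observable at the predictor interface. The extra block cannot
  contain the query (the blocks are disjoint and the query anchors the
  cluster block), so it is represented as an alignment block whose
  provenance records `query_included = FALSE`.
* `msa_remove_over_templates(x, covered)` — the noMSA step: every
  non-query row is gapped at the query columns covered by at least one
  selected template's footprint. The query row and uncovered columns are
  untouched; the operation is idempotent. The driver computes the
  footprint as the union of the selected templates' residue ranges in
  query numbering.
* `msa_speach_variants(x, window, stride)` — sliding-window masking.
  Default window 10 columns; the stride defaults to the window
  (non-overlapping tiling) with the final window right-aligned, so the
  placements jointly cover every query column. The stride is exposed
  because only the window width is fixed by the protocol.

All interventions preserve the query row exactly, and masking uses the
gap character: the predictor contract receives explicit per-column depth,
so a downstream encoding may translate gaps into whatever unknown-token
convention it uses.

## The ensemble driver and the predictor contract

`run_ensemble()` builds one recipe per model — template set x MSA variant
x recycle count — and dispatches it to a predictor, any function
`f(query_seq, msa, template_set, recycles, seed, model_index)` that is
deterministic given its inputs. Per-model seeds derive from
`(run_seed, model_index)`. Recipes are recorded in the returned manifest
and on each model, so every surviving model can be rebuilt exactly from
its own audit trail; failed models stay in the manifest with their error,
never silently dropped. Protocol defaults are 50 models, 8 + 16 MSA rows,
top 4 templates and 0 recycles in GPCR mode; 20 templates in kinase mode;
a 16 + 32, template-free configuration reproduces the MSA-only variant.

The packaged `mock_predictor()` realizes the premise the protocol rests
on — that a template-driven prediction lands near its templates — by
superposing all templates onto the first, averaging the aligned C-alpha
positions, and adding seeded Gaussian noise (`sigma`, default 0.5 A per
coordinate). Residues covered by no template are extrapolated as an ideal
helix continuation along the local chain direction. Confidence is a
monotone function of the deviation each residue actually realized
(template spread plus the drawn noise magnitude):
`plddt = 100 * exp(-deviation / 4)` and
`ptm = 1 / (1 + (mean_deviation / 1.24)^2)`. The constants were chosen
once so that a noiseless single-template rebuild scores ~100/1.0 and a
compact consensus over conformationally mixed templates remains clearly
above the unfolded floor while scoring visibly lower than a
single-state consensus. The mock is a test double for exercising the
pipeline offline; it does not emulate a neural network, and a real
predictor plugs in through the same contract.

`discard_unfolded()` operationalizes post-hoc ensemble cleaning, which
the protocol requires but does not define. A model is discarded when its
mean pLDDT falls below 40 or its radius of gyration exceeds 2.5x the
globular expectation `Rg = 2.2 N^0.38` A. Both thresholds are exposed;
the defaults are conservative (a straight-line chain exceeds the Rg
ceiling by construction, a confidently predicted compact model passes
both).

## Evaluation

`kabsch_superpose()` implements closed-form least-squares rigid
superposition (SVD of the cross-covariance with the determinant
correction, so reflections are never returned); selections of fewer than
three residues or collinear selections are rejected. `segment_rmsd()`
reports three numbers per model: TM-RMSD (C-alpha RMSD over the union of
TM segments after superposing on that union), loop RMSD, and global
RMSD. Loops are scored **in the TM-superposed frame** by default: the
quantity of interest is where the loops sit relative to the helical
bundle, not their internal geometry; `loop_frame = "independent"` gives
the separately superposed alternative. TM-RMSD and global RMSD use
different superposition frames, so neither bounds the other.

`ptm_rmsd_correlation()` is Spearman rank correlation with average-rank
ties; fewer than three finite pairs is an error and zero variance in
either variable returns `NA` rather than 0, because an undefined
correlation is not evidence of no correlation.

`classify_kinase_conformation()` assigns a model's activation-loop and
alphaC-helix in/out labels by nearest-reference motif RMSD: the model is
superposed on each labelled exemplar over the kinase core (everything
outside the motif segments), the feature's motif RMSD is measured in that
frame, and the nearest exemplar's label wins, with the margin to the best
differently-labelled exemplar reported. Near-ties (within 1e-6 A) resolve
to the earlier exemplar and warn. This classifier is a documented
stand-in: annotation databases label experimental structures, not
predicted models, so some explicit geometric rule is required, and
nearest-exemplar motif RMSD is the simplest auditable one. The exemplar
library ships as a fixture and is user-replaceable.

## The synthetic fixtures, and what they do and do not show

`make_conformer_pair()` builds cartoon structures: for GPCRs, seven ideal
alpha helices (2.3 A radius, 1.5 A rise, 100 degrees per residue; 24
residues each, 5-residue connecting loops) on a 14 A circle, with
"activation" a rigid 4 A outward swing of TM6 — a deliberate caricature
of the canonical activation motion. For kinases, a two-lobe cartoon with
designated alphaC-helix, DFG and activation-loop segments; the state flip
rigidly relocates DFG plus the activation loop by 6 A, and the alphaC
in/out alternative shifts that helix by the same amount. Because the
state difference is a pure rigid translation, the segment-restricted
deviation between the two states equals the requested displacement
exactly, giving closed-form expectations for the metric tests.
`make_annotation_fixture()` wraps per-record jittered copies (default
0.3 A) of these conformers in a complete annotation table, and
`make_toy_msa()` produces per-position-mutated homolog alignments whose
identity statistics follow a binomial expectation.

Passing tests on these fixtures demonstrate that the machinery — the
filters, the seeding, the interventions, the metrics, and the
bias-propagation logic from annotation to ensemble — behaves as
specified. They do not demonstrate anything about real predictors or real
proteins: the fixtures have no side chains, no realistic packing, no
correlation structure in the MSA, and the mock predictor has no
conformational preferences of its own. The benchmark composition also
differs from reality in one consequential way: the fixture template pool
is a balanced mix of the label combinations, whereas real structure
databases are heavily skewed toward particular states, so unbiased-run
statistics on fixtures reflect the balanced pool, not database bias.

## Numerical choices and degenerate inputs

* Residue numbering is 1-based with inclusive ranges everywhere;
  structures with insertion codes are rejected rather than silently
  renumbered, and altloc A is taken on read.
* Residue matching between two structures is by shared residue id; the
  fixture generator and mock predictor emit query numbering, and real
  structures must be renumbered to the query frame first.
* Superposition degeneracy is detected from the second singular value of
  the cross-covariance (relative threshold 1e-8).
* Seeds: every random draw derives from `(seed, counter)` through a
  single mixing function kept below 2^31; RNG state is always restored,
  so library calls never perturb a caller's stream.
* Rank-score ties break by `(pdb_id, chain_id)`; best-model ties break
  by model index; classification near-ties break toward the earlier
  exemplar, with a warning.

## Problem sizes

The test-suite and acceptance runs use 50-model ensembles (the protocol's
ensemble size) on ~200-residue GPCR and ~100-residue kinase cartoons,
with 10,000-draw uniformity checks for the seeded selection and
grid-refined brute-force oracles for superposition; the whole suite runs
in well under a minute on one CPU. These sizes were chosen as the
smallest that exercise every protocol constant at its documented value.

## Known limitations

* The mock predictor ignores MSA *content* (only its provenance and the
  counts participate), so MSA-vs-template balance effects cannot be
  studied with it — by design, that balance belongs to a real predictor.
* The GPCRdb/KLIFS API adapters normalize a documented minimal JSON
  schema and are exercised against a mocked transport; mapping the live
  endpoints' current schemas onto it is deployment configuration, and
  how ligand-complex entries map onto the `Intermediate` label is left
  to the adapter configuration rather than asserted.
* The kinase feature classifier depends on the exemplar library; with
  exemplars less separated than the motif noise level its margins become
  uninformative (the margin output exists to detect exactly that).
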