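---
title: "Draft genome-scale metabolic model reconstruction with gemdraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Draft genome-scale metabolic model reconstruction with gemdraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemdraft)
```

`gemdraft` implements the computational stages of genome-scale metabolic
model (GSMM) reconstruction — enzyme annotation, draft assembly, biomass
formulation, network auditing, compartment integration — together with the
alias-mediated comparison of draft and curated models. This vignette is the
package's methodological reference: the procedures, their assumptions, the
parameters that matter, and the design decisions taken where more than one
reasonable definition exists.

## The model container

A `metabolic_model` holds compartments, genes (unique locus tags, compared
case-insensitively but stored case-preserving), metabolites (with optional
Hill-notation formula and integer charge) and reactions (signed
stoichiometry, reversibility, flux bounds, optional pathway label and GPR
rule). GPR rules are boolean trees whose AND nodes encode enzyme complexes
and OR nodes isozymes; they are parsed from and rendered to the
conventional `"(g1 and g2) or g3"` text form. Referential integrity is
checked at construction: every metabolite's compartment, every reaction's
metabolites and every GPR leaf must be declared.

Reactions are classified structurally into *internal*, *transport*,
*exchange*, *sink* and *demand*:

* exchange — a single metabolite that lives in the designated boundary
  compartment, or a reaction id with the exchange prefix (`"EX_"` by
  default, configurable). Both signals are used because real models mark
  exchanges inconsistently;
* demand / sink — a single non-boundary metabolite, irreversible /
  reversible respectively. Distinguishing the two by reversibility is a
  convention of this package: the conventional definitions (demand
  irreversible, sink reversible) are applied because no structural signal
  distinguishes them otherwise;
* transport — metabolites in at least two compartments with some base
  species (id stripped of its `_<compartment>` suffix; the suffix
  convention is configurable by regex) appearing on both sides in
  different compartments;
* internal — everything else.

## SBML

`read_sbml()`/`write_sbml()` cover SBML level 3 versions 1 and 2 with the
`fbc` version-2 constructs: species formula and charge, flux bounds as
shared parameters, gene products, nested gene-product associations, and the
active objective. Level 2 dialects are deliberately out of scope; level 3
with `fbc` is the interoperable subset modern constraint-based tools
exchange. Identifiers follow the COBRA `M_`/`R_`/`G_` prefix convention;
locus tags ride in `fbc:label` so tags with characters outside the SBML
SId alphabet survive round trips. Bounds are serialized with 17 significant
digits so they read back bit-equal. Round trips preserve ids,
stoichiometry, bounds, compartments, formulas, charges and GPR tree
structure (up to argument order, which carries no meaning in a boolean
rule).

## Annotation scoring

For one gene with hits \(H\), each candidate label \(\ell\) (an EC number,
or a product string normalized by case folding and whitespace collapse —
the two are scored independently because product and EC are separable
choices) receives

\[
\mathrm{freq}(\ell) = \frac{|\{h \in H : \ell \in h\}|}{|H|},
\qquad
\mathrm{tax}(\ell) = \max_{h \ni \ell}
  \frac{\mathrm{sharedPrefix}(L_h, L_t)}{\max(|L_h|, |L_t|)},
\]

with \(L_h\) the hit's lineage and \(L_t\) the target organism's lineage
(root first), and the final score is the linear blend
\(\alpha\,\mathrm{freq} + (1-\alpha)\,\mathrm{tax}\). Candidates are ranked
by score, then frequency, then lexicographic label (a deterministic
tie-break), and the top candidate is committed when its score reaches
\(\tau\). Defaults \(\alpha = 0.5\), \(\tau = 0.5\) weight the two signals
equally and demand a majority-level consensus; both are exposed because the
right operating point is genome-dependent, and `tune_annotation()` grid
searches \((\alpha, \tau)\) against a labelled sample by F1. This blended
score is this package's committed definition of frequency-plus-taxonomy
scoring; published variants add further weights (e.g. penalties for
unreviewed database entries), so the curated-source flag is parsed but
unused by default.

The *automatic workflow* is simpler and deliberately so: hits are ranked by
the position of the first matching taxon in a user-ordered genus/species
priority list, then bitscore, then accession; genes whose hits match no
listed taxon fall back to the best bitscore and are flagged.

Scores are invariant under permutation of the hit table, reduce to pure
frequency ranking at \(\alpha = 1\) and pure taxonomy ranking at
\(\alpha = 0\), and are monotone in frequency at fixed taxonomy score.

## Template-based reconstruction

Orthologs are detected as bidirectional best hits: after discarding hits
with bitscore < 50 or e-value > 1e-5 (common practice for protein
searches; both configurable), \((a, b)\) is kept iff \(b\) is \(a\)'s top
surviving forward hit and \(a\) is \(b\)'s top reverse hit, "top" meaning
maximal bitscore with ties broken by minimal e-value then lexicographic
subject id. The implementation is verified against an \(O(n^2)\)
brute-force reciprocal-best search including tie cases.

GPR propagation replaces each template-gene leaf by the OR of its target
orthologs. Unresolved leaves are handled by policy:

* **strict** (default): an AND node with any unresolved child is itself
  unresolved; OR nodes drop unresolved children. Rationale: a complex
  should not be asserted when a subunit has no ortholog.
* **permissive**: AND nodes also drop unresolved children when at least
  one child resolves.

A reaction is inherited exactly when its propagated rule is non-absent;
orphan (GPR-less) template reactions are excluded by default since
inheritance is gene-led (an `include_orphans` flag copies them). Two
properties hold by construction and are tested: enlarging the ortholog map
never removes an inherited reaction (either policy), and the permissive
draft is a superset of the strict draft. A subtler point: the *satisfying
set* of a propagated rule (the gene sets that activate it) grows
monotonically with the map under the strict policy, but not under the
permissive one — an AND that dropped an unresolved child regains it as a
conjunct when the map grows, strictly shrinking the satisfying set. That
is inherent to any fill-in semantics, which is one reason strict is the
default.

When several templates are available, the package runs one template at a
time; merging is a union of single-template runs. Conflict-resolving
multi-template merges are out of scope.

## De novo assembly

Annotated ECs select catalogue entries by exact four-field intersection;
wildcard annotations (`"2.7.1.-"`) match nothing unless wildcard expansion
is explicitly enabled, because a wildcard match asserts strictly less
evidence. Each included reaction's GPR is the OR of its supporting genes;
complexes cannot be inferred from EC evidence alone, so `build_complex_gprs()`
rewrites listed reactions as OR-over-isoforms of AND-over-subunits from a
user/alignment-derived subunit table. All metabolites are placed in a
single configurable compartment; compartment refinement happens later.

## Biomass formulation

Compositions are estimated from the genome rather than copied from a
related organism. For protein, with optional non-negative expression
weights \(w_g\) (missing loci weight 1; uniform per-residue counting when
no weights are given):

\[
f_i = \frac{\sum_g w_g\, \mathrm{count}_i(g)}{\sum_g w_g\, \mathrm{len}(g)},
\qquad
c_i = \frac{1000\, f_i}{\sum_j f_j\, m^{res}_j} \;\; [\mathrm{mmol/g}],
\]

where \(m^{res}_j\) are average (not monoisotopic) residue masses, monomer
mass minus one water (18.0153 g/mol); the shipped table is overridable.
DNA frequencies are counted over both strands, so \(f_A = f_T\) and
\(f_G = f_C\) exactly; RNA is single-stranded with T read as U. Every
composition satisfies \(\sum_i c_i m^{res}_i = 1000\) to within 1e-6 — one
mmol-weighted gram of polymer per gram — and is invariant under scaling all
expression weights.

`build_biomass()` emits one polymerization pseudo-reaction per
genome-derived macromolecule (byproduct chemistry configurable: water
for protein, pyrophosphate for nucleic acids by default) and a biomass
equation \(\sum_k m_k\, \text{e-}M_k + \mathrm{GAM}\,(\mathrm{ATP} +
\mathrm{H_2O}) \rightarrow \text{biomass} + \mathrm{GAM}\,(\mathrm{ADP} +
\mathrm{P_i} + \mathrm{H^+})\). Macromolecule mass fractions \(m_k\)
(g/gDW, summing to 1 within 1e-3 unless renormalization is requested) and
GAM come from editable YAML templates per broad organism class
(Gram-negative, Gram-positive, fungus, plant); the shipped numbers are
literature-typical baselines that must be curated per organism, not
measurements. Lipid, carbohydrate and cofactor pools appear as
pseudo-metabolite sinks without synthesis reactions — deriving their
compositions from omics is out of scope. Pseudo-metabolites carry an
`e_` id prefix (displayed "e-") and are excluded from balance auditing.

## Compartment integration

Localization reports are normalized to per-gene `(compartment, score)`
rows with scores rescaled to \([0,1]\) by each dialect's declared maximum
(PSORTb-like 0–10, LocTree3-like 0–100, WoLF-PSORT-like vote counts
normalized per gene); a three-column generic TSV is the stable escape
hatch, since the third-party formats drift. A gene adopts its top-scoring
compartment when the score reaches the threshold, else the default
compartment. Each gene-associated reaction is re-homed to the majority
compartment of its GPR genes, ties going to the default — a committed rule
of this package, chosen over duplicating reactions into every predicted
compartment (single assignment keeps drafts small; duplication is a
possible future flag). The operation is idempotent at fixed inputs.
Multi-localized enzymes therefore contribute one location only.

## Network audits

Balance checking parses Hill formulas, sums coefficient × element count
per reaction, and reports per-element deficits (positive = excess on the
product side) plus charge imbalance; reactions citing any formula-less
metabolite are reported `unknown` rather than silently skipped, and
boundary pseudo-reactions are excluded.

Dead ends follow the admissible-direction definition: a metabolite is
never-produced when no reaction can create it in any allowed direction
(reversible reactions count both ways; exchanges count as both). Blocked
reactions are found by iterating removal to a fixpoint: a reaction is
removed when, direction-aware, every usable direction has a substrate that
is never produced or a product that is never consumed. This is a purely
topological relaxation of flux-variability analysis: *sound* (every flagged
reaction provably cannot carry steady-state flux, verified in the test
suite against an LP feasibility oracle) but *incomplete* — e.g. an isolated
reversible conversion `A <=> B` with no other producers or consumers
carries no steady-state flux yet is not flagged. The trade-off is
deliberate: no solver dependency and fully deterministic results; a
solver-backed checker can be layered on top.

## Benchmarking

Reaction comparison first removes transport, exchange, sink and demand
reactions from both sides (their identifier conversion is not reliable
across namespaces), then converts draft ids into the curated model's
namespace through a hub-keyed alias table (many-to-many; namespace matching
case-insensitive, id matching case-preserving). A draft reaction is a true
positive when any of its aliases is a curated internal reaction — it counts
once however many curated ids it matches, preventing double counting — and
a false positive otherwise; false negatives are curated internal reactions
hit by no draft reaction's alias set. This "hit" completion of the
per-side definitions keeps the three counts consistent and makes
self-comparison with identity aliases exactly perfect (F1 = 1, JD = 0),
which the suite asserts on random models. Gene comparison is a
case-insensitive locus-tag set comparison.

`compute_metrics()` applies the five formulas with explicit degenerate
conventions: precision 0 when TP+FP = 0, recall 0 when TP+FN = 0, F1 0
when both vanish, and the TP/FP ratio reported as 0 when TP = 0 and as
infinity (text `"inf"`, JSON `null`) when FP = 0 with TP > 0. The identity
\(1 - JD = TP/(TP+FP+FN)\) holds for every comparison produced.

## Synthetic fixtures and what they do (not) show

`make_toy_world()` writes a mutually consistent world — genome (FASTA +
GenBank), catalogue, template SBML, forward/reverse alignment tables,
annotation hits, alias table — with every planted truth (ortholog pairs,
EC assignments, the expected draft reaction set) recorded in a YAML
manifest, and is byte-identical for a fixed seed. `mutate_model()`
constructs drafts with known TP/FP/FN. The fixtures are *structural*:
sequences are random codons, bitscores and lineages are planted, and hit
tables are consistent with the planted orthology by construction. Passing
the planted-truth tests therefore demonstrates that the algorithms
implement their definitions exactly — not that the defaults are optimal on
real genomes, where alignment noise, paralogy, and annotation errors are
the dominant difficulties.

Test problem sizes are the package's own choice of desk-scale defaults:
toy worlds of 12–24 genes and 6–20 reactions, random models of ~10
metabolites and 12–16 reactions, 100-fold replication for property checks
(1000 for the metric formulas), which keeps the full suite in the order of
a minute while still exercising ties, empty cases and degenerate corners.

## Known limitations

* No automatic gap-filling; the audits flag curation targets only.
* Single-template inheritance per run; multi-template merging is manual.
* SBML level 2 dialects, GenBank export, and remote database access are
  out of scope.
* Blocked-reaction detection is incomplete (topological); sink/demand
  classification relies on the reversibility convention above.
* Biomass templates are baselines requiring per-organism curation; lipid,
  carbohydrate and cofactor pools are not derived from data.
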