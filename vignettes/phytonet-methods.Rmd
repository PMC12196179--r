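---
title: "Methods: from chromatogram to hub targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chromatogram to hub targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytonet)
library(dplyr)
```

`phytonet` models the computational chain used to characterize a
multi-component natural product: composition, drug-likeness, network
pharmacology, enrichment, in vitro analytics and docking summaries. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where reasonable alternatives existed. Nothing
here asserts an empirical result that the test suite or the acceptance
script does not itself compute.

## Retention indices and composition summaries

Retention indices place an analyte on the scale anchored by a homologous
n-alkane series: carbon number $n$ maps to index $100n$, and an analyte
eluting at $t_x$ between the alkanes at $t_n$ and $t_{n+1}$ gets

$$\mathrm{RI} = 100\left(n + \frac{t_x - t_n}{t_{n+1} - t_n}\right),$$

the linear interpolation appropriate to temperature-programmed elution.
`retention_index()` refuses to extrapolate: an analyte outside the ladder
span is an error, because the linearity assumption has no support there.
Identity confirmation (`confirm_identity()`) flags peaks whose experimental
index is within a tolerance of the literature value; the default window is
**10 index units**, a common working window for 5%-phenyl columns. The
matching window is method- and column-dependent and therefore exposed as a
parameter.

Class subtotals use a five-group controlled vocabulary. Free-text labels
are normalized by `normalize_chemical_class()`: aromatic monoterpene
hydrocarbons count as monoterpene hydrocarbons, alcohols and oxides of
either terpene family count as oxygenated, and non-terpenoids (such as
fatty-acid esters) fall into `other`. Two grand totals are reported
deliberately: the bundled oil's 19 peaks sum to 98.09% overall, while the
four terpene subtotals sum to 98.05% — the difference is exactly the 0.04%
ester, which belongs in the identified total but in none of the terpene
classes. Reporting both removes an ambiguity that a single "total
identified" figure would hide. Displayed values are rounded half-away-from-
zero at 2 decimals (`round_half_up()`), computed from full precision,
matching how analytical tables are printed; base R's round-half-to-even
would disagree on exact halves.

`compare_profiles()` matches compounds case-insensitively after synonym
normalization and supports grouped rows (e.g. pooling the 1R and 1S
α-pinene isomers, 15.97 + 5.29 = 21.26%) because historical references
often report racemic totals. One-sided compounds are flagged as absences
rather than dropped — the absence of a previously major constituent is
itself a finding.

## Drug-likeness screening

`lipinski_violations()` counts strict exceedances of the four rule-of-five
limits (MW > 500 Da, logP > 5, donors > 5, acceptors > 10); boundary values
do not violate. `screen_druglikeness()` passes a compound when violations
≤ `max_violations` **and** the oral bioavailability score ≥
`min_bioavailability` (default 0.5, the conventional Abbott cutoff). The
default violation budget is **1**, the allowance in the rule's original
formulation; "adherence" is sometimes read as zero violations, so strict
mode is a parameter away. Descriptors are ingested, not computed: logP and
H-bond counts come from whatever descriptor source the user trusts, which
keeps the screen free of heavyweight cheminformatics dependencies.

## Network pharmacology

### Construction

`build_ppi_network()` consumes STRING-style scored edge lists. Scores above
1 are auto-detected as the 0–1000 integer dialect and divided by 1000, so
the package has a single internal confidence unit. The confidence filter is
**strictly greater than** 0.4 by default; the convention "threshold of 0.4"
is ambiguous between > and ≥, so strictness is a flag. After filtering,
self-loops and parallel edges are collapsed (keeping the maximum
confidence) and nodes without any surviving edge are removed. "Disconnected
nodes" is read as *isolated* nodes only; restricting to the largest
connected component is available via `largest_component = TRUE` but is not
the default, since smaller components still carry interaction evidence.

### Centralities

`centralities()` implements the three metrics directly rather than
delegating, because the hub screen is the analytical core of the package
and its conventions must be pinned down exactly:

* **DC** — degree, incident edge count.
* **BC** — Brandes' shortest-path betweenness on the unweighted graph,
  each unordered pair counted once, endpoints excluded, **no
  normalization**. Raw pair counts are what median-threshold screens of
  this kind are quoted in (values in the thousands on networks of a few
  hundred nodes).
* **CC** — closeness normalized to $[0,1]$: with $r$ reachable nodes at
  total distance $S$, $\mathrm{CC} = (r/S)\cdot(r/(n-1))$, which is the
  standard $(n-1)/S$ on a connected graph and degrades gracefully on
  disconnected ones instead of being undefined.

Edge confidences are used only for filtering, never as path weights —
the same treatment network-topology plugins apply to STRING imports. The
implementation is verified two independent ways in the test suite: against
an exhaustive matrix-power path-counting oracle on all random graphs up to
10 nodes, and against igraph on larger graphs.

### The two-tier hub screen

Tier 1 (`tier1_screen()`) keeps nodes with DC at least `multiplier` ×
median(DC) (default 2), induces the subgraph and drops newly isolated
nodes. Tier 2 (`tier2_screen()`) **recomputes** BC, CC and DC on the
induced subnetwork and keeps nodes at or above all three medians
(inclusive, so a perfectly regular network keeps every node). Recomputing
on the subnetwork — rather than re-using the full-network values restricted
to surviving nodes — is a genuine design choice; it is the reading
consistent with published screens of this form, where the tier-2 degree
threshold exceeds the tier-1 cutoff, which can only happen if degrees are
re-derived on the denser core. For applying *recorded* thresholds to an
existing centrality table, `apply_hub_thresholds()` is exported separately.
Rankings break ties by degree descending, then betweenness descending, then
node name, so output order is deterministic.

`ct_degree_rank()` applies the same median logic to the compound–target
bipartite network: a compound's score is its count of distinct targets, the
cutoff is the median score, and the core is every compound at or above it.
On the bundled compound table this yields a median of 133 with exactly 10
core compounds.

## Enrichment statistics

`hypergeom_p()` evaluates $P[X \ge k]$ for the hypergeometric overlap of a
query of $n$ genes with a term of $K$ genes in a background of $N$,
computed via the log-space tail to remain finite at extreme enrichments
(the test suite checks it against exhaustive draw enumeration for
backgrounds up to 20 genes). `bh_adjust()` is the Benjamini–Hochberg
step-up. `enrich()` adjusts **within each annotation category separately**
(BP/CC/MF/KEGG), matching how annotation servers report; pooled adjustment
is a flag. The background defaults to the union of all catalog genes — the
only choice that is reproducible from the catalog alone — and can be
overridden. Term genes outside the background are dropped with a warning;
query genes outside it are an error, since they would silently deflate
every p-value. The conservative EASE variant (tail of $k-1$) is available
as an option for compatibility with DAVID-style scores.

## In vitro analytics

Viability is treated/control × 100 (`viability_percent()`). `fit_4pl()`
fits

$$V(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (c/\mathrm{IC}_{50})^{\mathrm{hill}}}$$

by bounded Levenberg–Marquardt least squares on $\log_{10} c$, with the
midpoint parameterized as $\log_{10}\mathrm{IC}_{50}$. Initialization is
multi-start over hill slopes $\{0.5, 1, 2, 4\}$ of both signs; bounds are
bottom ∈ [0, 50], top ∈ [50, 120] percent, loose enough for assay drift
above 100% but tight enough to keep the asymptotes identified on truncated
curves. The best start by residual sum of squares wins. `icq()` inverts the
fitted curve analytically for any inhibition level (IC25, IC50, ...).
Noiseless curves are recovered to better than $10^{-6}$ relative error;
with 3% replicate noise on the standard 9-point two-fold dilution ladder in
triplicate the median relative IC50 error is a few percent (both properties
are asserted in the tests at 1e−6 and 10% respectively).

The selectivity index is CC50(normal)/IC50(cancer). A printed formula
occasionally circulates with the ratio inverted; the implemented
orientation is the one consistent with SI > 1 meaning "safer on normal
cells", and with the bundled table (77.76/18.09 = 4.30). NCI activity is
inclusive (IC50 ≤ 30 µg/mL), selectivity strict (SI > 3), so the boundary
case (30, 3) is active but not selective. One published IC25 (0.70 µg/mL
against an IC50 of 18.09) implies an implausibly shallow curve and cannot
be reconciled without raw optical densities; `icq()` reports what the
fitted curve implies and makes no attempt to match that figure.

Annexin V/PI quadrant gating assigns events exactly on a gate to the
positive side; fractions always partition to 100. Cell-cycle gating
excludes the sub-G1 (hypodiploid) population from the three-phase
normalization and reports it separately, as cytometry practice dictates.
Wound closure is $100(A_0 - A_t)/A_0$ per arm; because "closure reduced to
62%" can mean either closure-relative-to-control or a percentage-point
drop, `wound_metrics()` emits both (`relative_closure_pct` and
`reduction_pp`) rather than guessing. Group comparisons use Welch's
unequal-variance t-test with the conventions p = 1 for two identical
zero-variance groups and p = 0 for separated ones.

## Docking summaries

Scores are binding free energies (kcal/mol, more negative = stronger).
`best_per_target()` reports per-target minima with explicit tie lists;
`relevance_flags()` applies the conventional −5.00 kcal/mol cutoff
*inclusively* (a score of exactly −5.00 is relevant), and a compound is
relevant if any target is. `select_best_pose()` takes the lowest energy
among poses with RMSD ≤ 2.0 Å — the usual pose-clustering convention, as
"acceptable RMSD" has no universal definition — and falls back to the
overall minimum with a warning when nothing qualifies. Docking execution,
receptor preparation and interaction typing are out of scope; the module
consumes score tables.

## The synthetic-data generators

Every pipeline input can be simulated with known ground truth
(`simulate_study()` produces the full set from one root seed, fanned out to
fixed per-generator child seeds so regenerating one piece never perturbs
another):

* **PPI networks** — preferential attachment with `attach_m` initially
  isolated seed nodes and attachment probability ∝ degree + 1, giving a
  connected graph with exactly `attach_m · (n − attach_m)` edges and a
  heavy-tailed degree distribution. Optional planted mega-hubs attach
  preferentially to a quarter of the network, so they occupy the dense
  core the way real high-degree regulators do; their labels travel with
  the network as ground truth. Edge confidences are uniform on
  [0.15, 1], spanning both sides of the 0.4 filter.
* **Target sets** — each compound shares a planted core (default 50 genes
  of 80 per compound across 19 compounds in a 2000-gene universe) and the
  disease set (90% of the universe) is forced to contain the core,
  guaranteeing a recoverable overlap.
* **Annotation catalogs** — planted terms embedded verbatim among random
  terms of 10–200 genes, GMT-serializable.
* **Dose–response** — 4PL mean plus Gaussian replicate noise truncated at
  zero on the standard 9-point ladder (100 down to 0.39 µg/mL by two-fold
  dilution), triplicate, 3% noise by default.
* **Flow events** — four bivariate Gaussian clusters on the log10
  intensity scale (quadrant gates are linear in log space), centers 0.7
  log-units from the gates with sd 0.15, so misclassification is
  negligible relative to multinomial sampling error. The treated-profile
  default weights (0.7239, 0.1502, 0.093, 0.0329) are the published
  quadrant percentages with the viable fraction as their complement.
* **Alkane ladders** — strictly increasing retention times with
  nondecreasing spacing, mimicking temperature-programmed elution.
* **Docking matrices** — uniform scores in [−6.9, −4.0] kcal/mol, the span
  typical of small terpenoids against protein targets.

What the generators deliberately do **not** emulate: mass spectra and peak
shapes (identification is assumed done), STRING's evidence-channel score
structure (confidences are exchangeable, not channel-derived), annotation
term overlap structure (random terms are independent draws), FCS binary
event files, and plate-reader raw output. Consequently, passing tests
demonstrate that the *algorithms* recover planted truth under realistic
sizes and noise — they do not validate instrument preprocessing, nor
database-dependent absolute results (network sizes, Venn counts and
specific enriched terms depend on database snapshots and are not
reproducible offline).

## Problem sizes and tolerances in the test suite

The suite runs in under a minute: centrality oracle checks on 50 random
graphs of up to 10 nodes (exhaustive enumeration) plus igraph agreement on
300-node scale-free graphs; 100-seed noisy 4PL recovery (median relative
IC50 error asserted ≤ 10%, calibrated well above the observed few
percent); a 1000-replicate global-null enrichment simulation (any-discovery
fraction ≤ 0.07, i.e. nominal 5% plus binomial slack); 20-seed
planted-hub and planted-term recovery; and 40,000–50,000-event quadrant
recovery within ±1 percentage point (≈4.6 multinomial standard errors).
These sizes were chosen as the smallest at which the sampling-error bounds
quoted are comfortably valid.

## Known limitations

* Centralities are exact but pure R; networks beyond a few thousand nodes
  would want a compiled backend.
* The 4PL fitter assumes homoscedastic replicate noise; strongly
  heteroscedastic assays would need weighting.
* Quadrant and cycle gates are user inputs, not estimated; automatic gate
  placement is out of scope.
* Enrichment results are only as meaningful as the catalog supplied;
  the package ships statistics, not an annotation database.
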