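---
title: "Methods: a comparative census of molecular traits across superkingdoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a comparative census of molecular traits across superkingdoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitvenn)
```

## The model

`traitvenn` analyses an organism × trait matrix of genomic abundance
counts.  A *trait* is a conserved molecular feature — in practice a SCOP
fold superfamily (FSF) domain or a terminal Gene Ontology (GO)
molecular-function term — and each organism belongs to one of the three
superkingdoms Archaea (A), Bacteria (B), Eukarya (E).  Two views of the
matrix drive everything:

* **occurrence** — presence/absence, derived as `abundance >= 1` and never
  stored separately, so the two views cannot drift apart;
* **abundance** — the redundant copy count, used as a relative-age proxy.

The analysis makes three assumptions, all inherited from the comparative
framework it implements:

1. Traits are conserved enough that their loss is costly and their
   presence is informative about deep ancestry (this motivates using
   structures and functions rather than sequences).
2. A trait shared *widely* by organisms of several superkingdoms — a high,
   balanced f-value — signals vertical descent; a trait nearly ubiquitous
   in one superkingdom but scarce in another signals horizontal flux or
   differential loss.
3. Older traits accumulate more genomic copies, so abundance ranks age.

None of these is testable from a single matrix; the package therefore
ships a simulator that makes them true by construction, which is what the
test suite exercises (see *What the simulator emulates*, below).

## Stages and their statistics

**Venn census.** Presence of a trait in a superkingdom is existential
(at least one organism), so each trait falls in exactly one of the seven
groups {A, B, E, AB, AE, BE, ABE}; labels concatenate the member letters in
fixed A < B < E order to keep outputs diffable.  No minimum-organism
threshold is applied here — spread is the f-value's job.

**Spread.** For trait *t* and superkingdom *S* with $n_S$ organisms,
$f_{t,S} = |\{o \in S : \text{abundance}(t,o) \ge 1\}| / n_S$.  Profiles
report f only for the superkingdoms in the trait's group label (elsewhere
it is identically 0 — this equivalence is asserted by a property test).
Summaries per (group, superkingdom) panel give quartiles plus the count of
widespread traits with strict $f >$ `tail_threshold` (default 0.8).  The
universal core demands strict presence in *every* organism; the
near-universal set uses the *overall* f across all organisms with strict
$f >$ 0.90.  Whether near-universality should be judged overall or
per-superkingdom is genuinely open; overall is the weaker and simpler
reading, and the per-superkingdom variant can be recovered from the
profiles if wanted.

**HGT rule.** Only the two-superkingdom groups are evaluated: a
three-superkingdom trait has no single donor/recipient pair, and
superkingdom-specific traits have nothing to compare.  With
$\Delta f = f_{\text{former}} - f_{\text{latter}}$ (letters in group-label
order), a call is emitted iff $|\Delta f| >$ `hgt_threshold` (default
0.6), donor = the higher-spread superkingdom.  Exact ties produce no call
(difference 0), and the strictness at the boundary is meaningful: a 0.8 vs
0.2 profile is *not* called.

**Abundance.** Per organism, abundance totals by Venn group always sum to
the organism's column total (audited at run time).  Panel summaries are
five-number summaries of $\log_{10}(x+1)$ with Tukey 1.5 × IQR outliers.

**Ontology mapping.** Only `is_a` edges are traversed — the level-1 parent
mapping is a hierarchy climb, and other OBO relationship types (part_of,
regulates) have different semantics.  "Terminal" status is taken from the
caller's trait list, not recomputed from DAG leaves, because terminal sets
come from annotation pipelines, not from the ontology's topology.  A
terminal with several level-1 ancestors counts once per ancestor, so the
breakdown table's total may exceed the mapped count.  A terminal that *is*
level-1 has no level-1 parent: it is reported unmapped with reason
`is_level1`, distinct from `disconnected` (no level-1 ancestor at all,
which in a validated single-rooted DAG can only be the root itself).

**Timelines.** For a leaf of a rooted trait tree, let $k$ be the number of
internal nodes on its root-to-leaf path (root included) and $K$ the
maximum over leaves; then $nd = (k-1)/(K-1)$, with $nd = 0$ for all leaves
of a star tree.  This anchoring makes a root-adjacent leaf exactly 0 and
the deepest leaves exactly 1, matching the convention that 0 is the most
ancient and 1 the most derived.  Whether the root node itself should be
counted is a convention with no observable consequence after the
$(k-1)/(K-1)$ rescaling; the package documents and fixes this one.  Branch
lengths are ignored entirely (nd counts cladogenic events, so it is
invariant to rescaling), and basal polytomies are legal — which is why
rootedness is checked structurally (every node has at most one parent)
rather than by degree of the root.  Ties in the most-ancient-per-group
lookup break by maximum total abundance, then trait id.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `coverage_threshold` | 0.5 | minimum GO-annotation coverage for retaining an organism; **inclusive** (an organism at exactly 50% is kept, since the filter's published phrasing does not state strictness and exclusion at equality would be arbitrary); organisms with unknown coverage are not penalised |
| `free_living_only` | FALSE | drop non-free-living organisms; lifestyle comes from the metadata curator, not from name heuristics, which are unreliable |
| `exclusion_list` | empty | trait ids removed before analysis (e.g. externally flagged HGT-derived terms) |
| `hgt_threshold` | 0.6 | strict f-difference bound for transfer calls |
| `tail_threshold` | 0.8 | strict f bound for "widespread" tail counts |
| `near_universal_threshold` | 0.90 | strict overall-f bound for near-universal traits |

## Numerical choices

* **Display precision truncates toward zero** (`report_precision()`):
  per-trait f at 3 decimals, percentages at 2.  Truncation, not rounding,
  is the convention because it never overstates the spread of a scarce
  trait: 1 organism of 652 reports as f = 0.001 (rounding would say
  0.002), and 1,871 of 1,924 mapped terms reports as 97.24% (rounding
  would say 97.25%).  All *decisions* — threshold comparisons, calls,
  core membership — use full precision; truncation is display only.
* **Boundary guard.** The HGT comparison uses
  `abs(diff) > threshold + 1e-9`: f-values are ratios of small integers
  and their difference can carry one ulp of representation error (e.g.
  `0.8 - 0.2` evaluates slightly above 0.6), which must not promote an
  exact-boundary profile to a call.
* **Quantiles** use R's default linear-interpolation convention (type 7)
  everywhere, stated here and held fixed so that summaries are
  reproducible across platforms.
* **Log transform** is $\log_{10}(x+1)$, keeping zero-abundance organisms
  on the scale instead of dropping them.
* **Determinism.** Timeline entries sort by (nd, trait id); group labels
  and column orders are canonical; the pipeline re-run on the same inputs
  is byte-identical (tested).

## What the simulator emulates — and what it does not

`simulate_repertoires()` encodes the diversification scenario the
comparative method is designed to detect:

* an **urancestral core** (`n_core`, default 150) born in epoch 0 and
  present in every organism;
* **early archaeal stem loss**: each core trait is removed from the whole
  archaeal block with probability `archaeal_loss_rate` (default 0.25),
  creating true BE traits — loss early on the stem is the parsimonious
  reading of a large BE excess;
* **ordered innovation**: Bacteria-specific traits appear in epoch 1,
  Archaea- and Eukarya-specific traits jointly in epoch 2 (the canonical
  pattern), with uneven within-block spread drawn from `specific_spread`;
* **duplication growth**: every present cell draws
  `1 + Geometric(mean = abundance_base_mean × duplication_growth^age)`, so
  expected abundance decays strictly with birth epoch.  A geometric draw
  is deliberately light-tailed: the age-proxy property being tested is
  about means and medians, and heavy tails would only add variance without
  changing the construction;
* **late bacterial reduction**: each bacterial genome is flagged with
  probability `late_bacterial_loss_rate` (default 0.05) and loses each
  trait independently with probability `reduction_severity` (default 0.3);
  planted HGT patterns are exempt so their construction stays exact;
* **planted HGT**: donor spread in [0.9, 1], recipient spread in [0, 0.2]
  with at least one recipient organism, guaranteeing an f-gap above 0.6 by
  interval arithmetic.

Default organism counts are (A = 70, B = 652, E = 259), the superkingdom
sample sizes of the structure dataset the method was developed on.  The
default trait counts (150 core, 10/60/120 specific, 10 transfers) are
scaled-down but preserve the ordering that matters: Eukarya-specific
novelties outnumber bacterial ones, which outnumber archaeal ones, and
transfers are sparse relative to the vertical signal.

What the simulator does **not** emulate: annotation bias between
superkingdoms (real GO coverage is richer for Eukarya), correlated loss
across related organisms (losses here are independent), intra-superkingdom
transfer, convergent origination of the same trait in two lineages, viral
contributions, and realistic branch lengths (the simulated tree encodes
only birth order).  Passing tests therefore demonstrate that the pipeline
*recovers planted signal of the assumed kind*, not that real datasets are
free of these confounders — on real data, differential loss can mimic an
HGT spread pattern, and the f-difference rule cannot distinguish them.

The simulated ontology (`simulate_ontology()`) is a three-level DAG (root,
level-1 categories, intermediates, terminals) with optional multi-parent
terminals and optional level-1 terminals; it exercises the mapper's
counting and unmapped-reason logic, not the breadth of a full GO release.

A note on one spread property: archaeal stem loss removes a trait from
*all* archaeal organisms, so the traits that remain ABE keep their f in A
unchanged — the loss signal lives in the growing set of core traits whose
f in A is zero.  The test suite therefore checks that the *mean* f in A
over the whole urancestral cohort (zeros included) strictly decreases with
the loss rate, while B and E medians are untouched.

## Test and verification scale

The suite validates each operation against an independent brute-force
oracle: explicit set algebra for the Venn census (random matrices up to
50 × 30, 200 of them), per-organism recount loops for f-values and group
abundances, and full transitive-closure ancestor enumeration for the
ontology mapper (random DAGs up to 500 nodes).  Simulation-based
properties (planted-transfer precision/recall, birth-order recovery,
abundance ordering) run at 10–20 fixed-seed replicates on blocks of a few
dozen organisms — sizes chosen so the whole suite stays fast while every
replicate still contains all seven Venn groups.  `scripts/acceptance.R`
re-runs the headline quantities at the full superkingdom sample sizes
(652/70/259) where the quantity depends on them.

## Known limitations

* The f-difference rule is direction-*suggesting*, not direction-proving:
  a high-f/low-f pattern is equally consistent with transfer into the
  low-f superkingdom and with near-complete loss there.
* Presence thresholds are existential; a single spurious annotation moves
  a trait between Venn groups.  Upstream assignment quality (HMM E-value
  cutoffs, GO evidence codes) is out of scope — the matrix is trusted.
* The OBO parser reads the `[Term]`/`id`/`name`/`is_a`/`is_obsolete`
  subset only; cross-products and non-is_a relationships are ignored by
  design.
* nd requires the trait tree as an input; reconstructing it (e.g. by
  maximum parsimony on abundance characters) is a separate, upstream
  problem.
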