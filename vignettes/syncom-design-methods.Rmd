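---
title: "Designing synthetic communities from qualitative metabolic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic communities from qualitative metabolic networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomdesign)
```

# The modelling framework

`syncomdesign` works entirely with *qualitative* genome-scale metabolic
networks: a species is a set of reactions, each a pair of non-empty
reactant and product compound sets with a reversibility flag.
Stoichiometric coefficients, kinetics and compartments are deliberately
outside the model. The price of this abstraction is that producibility
says nothing about rates or yields; the benefit is that every question
the package answers — what can be made, by whom, with whom — is decidable
exactly, so results can be checked against brute-force oracles, which the
test suite does throughout.

Two assumptions do real work and should be kept in mind:

* **Mixed-bag communities.** A community's metabolic potential is the
  expansion of the *union* of its members' reactions, as if membranes did
  not exist. This over-estimates cooperation (every intermediate is
  implicitly exchangeable) and is the standard meta-organism assumption
  of qualitative community modelling.
* **The medium is external.** Seed compounds count as available even
  when a species' network never mentions them; a growth medium is not a
  genome property.

# Network expansion

The scope of a network from a seed set is the least fixed point of
"fire every reaction whose reactants are already reachable". At load
time each reversible reaction is compiled into two irreversible rules,
which makes the fixed point manifestly independent of evaluation order.
The implementation is a worklist over compounds with per-rule
unmet-reactant counters (linear in total reaction arity); its contract
is equality with a naive repeated-sweep closure, which the tests assert
on more than one hundred random networks per run alongside monotonicity
in seeds and in reactions, and idempotence.

Both views of a scope are always reported: `full_scope` (seeds
included) and `producible` (seeds excluded). Figures of "newly
producible" compounds conventionally exclude the seeds while scope sizes
often include them; exposing both removes the ambiguity, and
`scope_statistics()` computes its size summaries on full scopes.

# Minimal communities

`enumerate_minimal_communities()` must return *every*
minimum-cardinality covering community, because essential-symbiont
classification is an intersection over all optima and is unsound
otherwise (a truncated enumeration therefore refuses to classify, and
`solve_minimal_community()` — which stops at one solution — marks its
result truncated for the same reason). The search is iterative
deepening over community size with three exactness-preserving aids:
species that cannot fire a single reaction even in the full mixed-bag
scope are discarded up front (they can contribute to no community); a
greedy set cover bounds the deepening; and subsets are explored in
lexicographic species order so output is deterministic. On the problem
sizes this package targets for validation (up to ~12 candidate species
after decoy removal) this is exact and fast; the test suite checks the
solver against exhaustive subset search over all `2^n` subsets on
dozens of generated instances per run.

Design choices here, made once:

* **Objective.** Minimize species cardinality only. Exchange
  minimization is a different (and much harder) objective and is out of
  scope.
* **Host semantics.** A host network joins the mixed bag during every
  coverage check but is never selectable and never counts toward
  community size.
* **Unproducible targets.** Targets beyond the reach of even the full
  community (plus host) are excluded from the covering constraint with
  a warning rather than an error — real target lists routinely contain
  unreachable compounds, and failing the whole solve would hide the
  useful answer. A target already present in the seed medium is
  trivially covered, so an all-seed target list yields the empty
  community of size zero.
* **Enumeration cap.** Default 1,000 optima; hitting it sets the
  `truncated` flag rather than silently under-reporting.

# Reverse-ecology seed sets and pairwise indices

The *seed set* of a species (not to be confused with the growth medium)
is what it must acquire from its environment: in the substrate→product
graph of its reactions (every reactant gets an edge to every product,
reversible reactions mirrored), take the condensation into strongly
connected components; the components with no incoming edge are the
sources, and their member compounds form the seed set, each weighted by
a confidence of `1/|component|` so that per-component confidences sum
to one. The SCC machinery is delegated to igraph; the test oracle is an
independent per-node reachability characterization (a compound is a
seed iff every node reaching it is reachable from it).

The four indices are all weighted fractions of the focal/consumer seed
set, hence in [0, 1]:

| index | numerator condition on a focal seed compound |
|---|---|
| competition | also a seed of the partner |
| complementarity | in the partner's compounds but not its seeds |
| BSS | anywhere in the supporter's compounds |
| MCI | identical to complementarity |

Choices made where usage in the field is ambiguous:

* **MCI = complementarity.** The metabolic complementarity index is the
  complementarity formula exposed under its host–microbe pairing name;
  implementing it twice would only invite silent divergence.
* **Weighting.** Indices are confidence-weighted on the focal side by
  default; `weighted = FALSE` gives plain set fractions, because
  published practice does not always state the weighting. The
  competitor-exclusion threshold applies to whichever variant the
  caller selects.
* **BSS counts supporter seeds.** A supporter compound supports the
  consumer even if the supporter itself imports it; the score measures
  presence, not net production.
* **No currency-metabolite exclusion by default.** An exclusion list
  may be passed to the graph construction, but the default is to
  exclude nothing, since no universal list exists.
* **Self-pairs** are defined (competition 1, complementarity 0, BSS 1)
  and kept on matrix diagonals.

# PGPT screening

Screening is deliberately dumb: exact, case-insensitive,
whitespace-trimmed symbol matching of annotation tables against a gene
catalog — the alignment/HMM work that produces annotations is upstream
of this package. The packaged catalog carries eight trait categories
totalling 91 unique symbols; its metadata records that the catalog's
published headline count (86) does not reconcile with the enumerated
symbols (93 printed, two duplicated), and every distinct printed symbol
— including the oddities `node`, `nod` and the `_like` variants — is
kept verbatim rather than silently edited. Users who prefer a curated
list can supply their own JSON catalog; a symbol in two categories is
rejected.

# The selection pipeline

`design_syncom()` chains the stages: enumerate optima for the hostless
instance and once per host; pool essentiality; prune competitors;
attach PGPT profiles and host-support scores for the survivors.

* **Pooling essentiality across hosts.** A species is retained when it
  is essential (present in all optima) in *at least one* run. The
  per-run breakdown is kept in the report so stricter poolings
  (essential in every run) can be applied downstream; the union rule
  was chosen because a species indispensable for any one host is worth
  keeping in a multi-host SynCom.
* **Competitor exclusion.** The threshold is strict (`> 0.6` by
  default). Removal is iterative, one species per round — the species
  in the most violating pairs, ties broken by greater mean off-diagonal
  competition, then by lexicographically *last* id — with the matrix
  recomputed after each removal. Iterative single removal generalizes
  the one-shot "drop the most competitive members and recompute"
  practice while keeping an auditable exclusion trail; the post-pruning
  matrix is asserted to have no violation. On instances small enough to
  check, the tests confirm the greedy trail removes no more species
  than necessary under the same rule sequence (rule-consistency, not a
  claim of global optimality).
* **Determinism.** Every container is sorted, every tie-break total, so
  identical inputs give byte-identical JSON reports; the tests compare
  file checksums.

# The synthetic-instance generator

`generate_instance()` plants ground truth by construction rather than
by search. For each target a linear pathway runs from fresh seed
compounds (two per pathway by default) through `chain_length` reactions
to the target; each pathway is cut at random points into contiguous
segments distributed over the hub species, so each hub member is the
sole carrier of at least one segment and is indispensable, while no
other species carries any pathway reaction. Consequently the planted
hub is the unique optimum — unless a competitor pair is planted, in
which case two extra species carry identical copies of one hub member's
reaction set, making the three copies interchangeable: the optima are
exactly the hub with that member substituted, competition among the
three copies is exactly 1, and the instance's `ambiguity` flag records
that the optimum is non-unique. Decoy species consume a compound
nothing produces, so they are provably inert; clutter reactions (two
per hub species by default) lead from a species' own products to fresh
dead-end compounds, adding realistic noise that provably cannot alter
minimality or seed sets. When host support is planted, the host carries
one hub member's pathway segments, so the optimum with host is strictly
smaller than without.

Default conditions — 10 species, 2 targets, chains of 4 reactions, a
4-species hub, 2 decoys (plus however many species slots remain), 2
seed compounds per chain — were chosen once to mirror the qualitative
structure of a real reduced community at desk scale: most species
dispensable, a few essential, occasional near-duplicate metabolisms.
All randomness derives from the single `rng_seed`, and generation is a
pure function of the configuration.

What the generator does *not* emulate: realistic genome sizes or
KEGG/MetaCyc reaction statistics, branched or cyclic pathways in the
planted core, partial pathway redundancy, or annotation noise.
Passing tests on generated instances therefore demonstrate algorithmic
correctness on networks with known structure, not predictive validity
on real GSMNs.

# Numerical and degenerate-input conventions

* Index comparisons against the exclusion threshold are exact floating
  comparisons on values that are small rational numbers; no epsilon is
  applied.
* An empty focal seed set makes the pairwise indices undefined and
  raises an error rather than returning 0/0.
* An empty network has an empty compound set, scope equal to its seeds,
  and an empty seed set; an empty seed medium is rejected at instance
  construction but `compute_scope()` itself accepts it and returns the
  empty scope.
* Validation problem sizes (chosen as the package's own testing
  conditions): expansion and seed-set oracles run on 100+ random
  networks of up to 50 reactions; the minimal-community oracle on 30+
  generated instances of 6–12 species; planted-recovery on 50 instances
  of 10 species with a competitor pair.

# Limitations

Qualitative expansion cannot see cofactor balance, energetics or
growth; the mixed-bag assumption ignores transport; seed-set detection
inherits every gap of the input reconstructions (a missing transporter
reaction creates a spurious seed); and symbol-matching PGPT screening
is only as good as the upstream annotation. The package is a design and
screening tool — candidate SynComs it proposes are hypotheses for the
lab, not predictions of community behaviour.
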