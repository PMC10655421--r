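# syncomdesign

In-silico design of synthetic microbial communities (SynComs) from
qualitative genome-scale metabolic networks (GSMNs).

## The problem

Plant-associated microbiomes contain hundreds of species, far too many to
assemble in the lab. Given one qualitative metabolic network per species
(reactions with reactants, products and reversibility — no
stoichiometry), a seed growth medium (for instance a root
exudate-mimicking medium) and a list of target compounds the community
should produce (amino acids, vitamins, phytohormones, ...), this package
reduces the community to a small, cooperative, plant-beneficial SynCom.
It is written for microbiome researchers who already have draft GSMNs
(e.g. from metagenome-assembled genomes) and want a reproducible,
testable selection pipeline.

## The methods at its core

- **Network expansion (scopes).** The metabolic potential of a network
  *N* under a seed set *S* is the least fixed point of
  `X ↦ X ∪ { products(r) : r ∈ N, reactants(r) ⊆ X }` starting from
  `X = S` (reversible reactions fire both ways). `compute_scope()` gives
  individual potentials, `community_scope()` the mixed-bag community
  potential (all reactions pooled, optionally with a host network), and
  `added_value()` the cooperation gain — compounds only the community
  can make.
- **Minimal communities.** `solve_minimal_community()` and
  `enumerate_minimal_communities()` find the minimum-cardinality species
  subsets whose mixed-bag scope covers every producible target
  (host-supported when a host is supplied), by exhaustive iterative
  deepening bounded by a greedy cover. Species in **every** optimum are
  *essential symbionts*; species in some but not all are *alternative
  symbionts* (`classify_symbionts()`).
- **Reverse ecology.** A species' *seed set* (distinct from the growth
  medium) is what it must take up exogenously: the source
  strongly-connected components of its substrate→product graph, each
  compound weighted by 1/|component| (`network_seed_set()`). From seed
  sets come the pairwise **competition** index (weighted seed-set
  overlap), **complementarity** index (seeds the partner can synthesize
  but does not itself require), **biosynthetic support score** (BSS:
  seeds present anywhere in the supporter's network) and **metabolic
  complementarity index** (MCI), all in [0, 1] via
  `pairwise_matrix()`.
- **PGPT screening.** `screen_genomes()` checks genome annotation tables
  against a packaged catalog of plant growth-promoting trait genes in
  eight categories (nitrogen fixation, EPS production, nodulation, ROS
  scavenging, iron acquisition, potassium transport, spermidine
  metabolism, IAA-related tryptophan metabolism) and reports
  per-category completeness.
- **SynCom selection.** `design_syncom()` chains everything: enumerate
  optima (hostless and per host), pool essential symbionts, then
  iteratively exclude species whose pairwise competition exceeds a
  threshold (default 0.6, strict) until no pair competes above it.
- **Planted-truth simulation.** `generate_instance()` builds synthetic
  instances whose minimal communities, competitor pairs and host effects
  are known by construction, so every stage is testable without any
  external data.

## Worked example

```r
library(syncomdesign)

# a 10-species instance: 4-species planted hub, inert decoys, and a
# competitor pair (two copies of one hub member)
si <- generate_instance(generator_config(
  n_species = 10, n_hub = 4, plant_competitor_pair = TRUE, rng_seed = 42))

res <- enumerate_minimal_communities(si$instance)
res
#> <mincom_result> optimum size 4; 3 optimal communities
#>   essential: hub01, hub02, hub03
#>   alternative: dup01, dup02, hub04
```

Four species are needed; because `hub04` has two identical copies
(`dup01`, `dup02`) there are three interchangeable optima, so only
`hub01`–`hub03` are essential. Competition among the essential species
is nil — each consumes different pathway intermediates:

```r
round(pairwise_matrix(si$instance$members[res$essential], "competition"), 2)
#>        partner
#> focal   hub01 hub02 hub03
#>   hub01     1     0     0
#>   hub02     0     1     0
#>   hub03     0     0     1

design_syncom(si$instance, threshold = 0.6)
#> <syncom_report>
#>   initial members:    10
#>   essential symbionts: hub01, hub02, hub03
#>   final SynCom:       hub01, hub02, hub03
```

The pipeline reports the 10-species community reduced to a 3-species
SynCom: the planted hub minus one member of the competitor trio, which
is exactly the planted ground truth (`si$truth`). Scope summaries work
the same way:

```r
scope_statistics(unname(si$instance$members), si$instance$seeds)
#> <scope_statistics> 10 species; scope sizes 4-8 (mean 4.7); core 4, union 11 compounds
```

A shell front end with `summarize`, `iscope`, `cscope`, `mincom`,
`seedset`, `indices`, `pgpt`, `design` and `simulate` subcommands is
installed at `inst/scripts/syncom`.

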