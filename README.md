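# mechsim — graph-based similarity of enzyme reaction mechanisms

Enzyme mechanisms are communicated as curly-arrow diagrams: per catalytic
step, a drawing of the active-site species with arrows tracing how
electrons move. `mechsim` makes those diagrams computable. It is aimed at
anyone who curates or mines mechanism collections (e.g. M-CSA-style
databases) and wants to ask: how similar are two mechanisms' chemistries,
which chemical events recur across unrelated families, and do similar
mechanisms live in similar folds?

## The method

The unit of comparison is the **arrow-environment**: the subgraph within a
fixed number of bond shells of one curly arrow's reaction centres (the
atoms touched by the arrow's tail or tip; bond endpoints count as both
atoms). Centres carry a two-digit code *ED* — *E* the number of moving
electrons (1 or 2), *D* = 1 tail, 2 tip, 3 both. Three definitions are
built in: *one-away* (one shell), *two-away* (two shells), and
*EzMechanism-like* (two shells with outermost-shell C and H treated as
equivalent). Each environment is canonicalized (colour refinement +
exhaustive tie-break) and serialized to a restricted SMARTS dialect, e.g.

```
[#6]-[#8&-:23].[#8]-[#6:22](-[#8])(-[#1])-[#6]
```

— a carboxylate oxygen (tail *and* tip, `:23`) attacking an anomeric
carbon (tip, `:22`). Key equality is exactly labelled-graph isomorphism.

Within a step, arrow B *follows* arrow A when B's tail touches an atom
touched by A's tip; arrows and follows-edges form a directed **step
graph**, whose edges are the **chains**. For steps or whole mechanisms
(sets pooled across steps), with `E` the env-key sets and `C` the chain
sets of the two sides:

- **unordered** similarity = J(E₁, E₂), the Jaccard index |E₁∩E₂|/|E₁∪E₂|;
- **ordered** similarity = ½ · (J(E₁, E₂) + J(C₁, C₂)),

with J(∅, ∅) := 1. Six scores in total (3 definitions × 2 methods), each
in [0, 1], displayed as integer percentages (half-up).

## Worked example

The shipped fixture pair encodes two retaining glycosidases — alpha-amylase
and endo-xyloglucan transferase, two catalytic steps of three arrows each,
identical first steps, different incoming nucleophile in the second:

```r
library(mechsim)
pair <- make_glycosidase_pair()
score_suite(pair$amylase, pair$xet)
#>         definition    method     score    j_envs  j_chains percent
#> 1         one_away unordered 0.4285714 0.4285714        NA     43%
#> 2         one_away   ordered 0.3809524 0.4285714 0.3333333     38%
#> 3         two_away unordered 0.5000000 0.5000000        NA     50%
#> 4         two_away   ordered 0.4166667 0.5000000 0.3333333     42%
#> 5 ezmechanism_like unordered 0.5000000 0.5000000        NA     50%
#> 6 ezmechanism_like   ordered 0.4166667 0.5000000 0.3333333     42%
```

Reading the two-away rows: the mechanisms share 4 of 8 distinct
arrow-environments (unordered 50%) and 2 of 6 distinct chains, so the
ordered score is mean(4/8, 2/6) = 41.7% ≈ 42%. The first arrow of the
first step serializes to the SMARTS shown above:

```r
step <- make_fig1_step()
to_smarts(extract_arrow_env(step, step$arrows[[1]], "one_away"))
#> [1] "[#6]-[#8&-:23].[#8]-[#6:22](-[#8])(-[#1])-[#6]"
```

Corpus-level drivers: `all_vs_all()` (pair-score tables),
`env_usage_stats()` (chemical-diversity catalogue: distinct envs,
singletons, common envs), `cluster_graph()` / `export_similarity_graph()`
(threshold clustering, GraphML/TSV), `ec_cath_breakdown()` (similar pairs
classified by CATH-superfamily-set and EC-subsubclass agreement).
Mechanisms are exchanged as a documented JSON format
(`inst/extdata/mechanism-schema-1.0.md`); a best-effort reader for a
subset of Marvin `.mrv` XML is included, as is a seeded synthetic-mechanism
generator (`random_mechanism()`, `mutate_mechanism()`) used by the
property tests.

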