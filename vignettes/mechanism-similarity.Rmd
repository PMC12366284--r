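---
title: "Comparing enzyme mechanisms through arrow-environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing enzyme mechanisms through arrow-environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechsim)
```

## The problem

Enzyme mechanisms are traditionally communicated as curly-arrow diagrams:
for each catalytic step, a drawing of the active-site species with arrows
showing how electron pairs (or, rarely, single electrons) move. These
diagrams carry precise chemistry — which bonds break, which form, which
lone pairs attack — but they are pictures, and pictures cannot be compared
at scale. `mechsim` turns each diagram into a labelled graph and defines a
quantitative similarity between catalytic steps and whole mechanisms, which
in turn supports corpus-wide questions: how chemically diverse is a set of
mechanisms, which chemical events recur across unrelated enzyme families
(convergent evolution of chemistry), and which similar mechanisms sit in
similar folds (divergence).

## Data model

A *catalytic step* is one concerted set of electron movements between two
stable states. Its *active-site state* is a simple graph: atoms (atomic
number, integer formal charge), bonds (single, double, triple, or aromatic
— aromatic is a first-class order and is never kekulized, so no equality
ever depends on a kekulization choice). Hydrogens are explicit wherever
they participate in the chemistry; no implicit-hydrogen expansion is
performed. A *curly arrow* moves 1 or 2 electrons from a source (a lone
pair/radical on an atom, or a bond) to a sink (an atom, an existing bond,
or an *incipient* bond between two atoms). A *mechanism* is an ordered
list of steps, optionally annotated with EC numbers and the CATH
superfamilies of its catalytic domains.

The *reaction centres* of an arrow are the atoms its tail or tip touch;
when an endpoint is a bond (existing or incipient), both bond atoms count.
An arrow therefore has between one and four centres.

## Arrow-environments

The unit of comparison is the *arrow-environment*: the subgraph induced by
all atoms within a fixed number of bond shells of an arrow's reaction
centres, with the centres annotated by a two-digit code — first digit the
electron count (1 or 2), second digit 1 for tail, 2 for tip, 3 for both.
Three definitions are built in:

* **one-away** — a single shell (bond distance ≤ 1);
* **two-away** — two shells (distance ≤ 2);
* **EzMechanism-like** — two shells, with carbon and hydrogen atoms in the
  *outermost* shell treated as interchangeable, on the reasoning that a C
  versus an H two bonds from the electron transfer contributes little to
  the reaction energetics.

Custom definitions (deeper shells, other outer-shell element classes) can
be built with `arrow_env_definition("custom", ...)`. Three choices here
were genuinely open and are worth recording:

* *Induced subgraph.* Bonds between two outermost-shell atoms are kept
  whenever both atoms are in the environment. Nothing forces this, but the
  reference serialization connects every included atom, and dropping such
  bonds would make two visibly different ring fragments equal.
* *Equivalence only at the outermost shell.* Centre and inner-shell C/H
  are never merged; the coarsening is explicitly a statement about the
  *periphery* of the electron transfer.
* *No cross-definition comparison.* A one-away key never equals a two-away
  key and comparing environments of different definitions is an error; a
  score always names the single definition it used.

Because a two-away environment determines its one-away sub-environment,
and the EzMechanism-like labelling is a function of the two-away
environment, equality under two-away implies equality under both coarser
definitions. The test suite checks this implication on random corpora.

## Canonical keys and SMARTS

Two environments are equal when a graph isomorphism between them preserves
element (or equivalence class), formal charge, the two-digit arrow code
and bond orders; chirality is deliberately ignored. To make equality a
string comparison, every environment gets a canonical atom order by
iterative neighbourhood-colour refinement followed by exhaustive
individualization over the first non-singleton colour cell, keeping the
lexicographically minimal serialization. Environments are small (rarely
more than ~15 atoms, with diverse labels), so the exhaustive tie-break is
cheap; it is also what makes the key *correct* rather than heuristic — the
suite cross-checks key equality against VF2 isomorphism with the same
label predicate on hundreds of random pairs.

The canonical SMARTS rendering is a deterministic function of that order:

* atoms as `[#8]`, `[#8&-]`, `[#6,#1]` (equivalence class, members in
  descending atomic number), with the arrow code as an atom map (`:23` =
  two electrons, both tail and tip); zero charges are never written;
* atoms are ranked unmapped-before-mapped, then heteroatoms by descending
  atomic number, then hydrogen, then carbon — so fragments start at a
  peripheral heteroatom when one exists and reaction centres come last;
* each connected fragment is rendered depth-first from its lowest-ranked
  atom, neighbours in rank order, all but the last child parenthesized;
  ring closures carry a bond symbol plus digit at both endpoints;
* fragments are joined with `.` in byte order.

The canonical key is simply the definition name joined to this string, so
key equality, SMARTS equality and labelled isomorphism coincide.
`parse_smarts_env()` reads the same dialect back (and only that dialect —
it is a round-trip format, not a general SMARTS engine).

## Chains and the two scores

Within one step, arrow B *follows* arrow A when B's tail touches an atom
touched by A's tip (bond endpoints expanded as above). Arrows and follows
relations form a directed *step graph* over canonical keys — arrows in a
concerted step are not temporally ordered, and the relation can form
branches or cycles, which is why a graph rather than a sequence is used.
The graph's edges are the *chains* (ordered key pairs). Two arrow
instances with the same key merge into one node (set semantics; the
multiplicity is kept as a diagnostic only); an edge between two distinct
instances sharing a key is kept as a loop, since discarding it would lose
a real follows relation.

For two steps or two mechanisms (mechanism level pools distinct keys and
chains across steps, with no step-to-step alignment):

* **unordered** similarity = Jaccard index of the two env-key sets;
* **ordered** similarity = mean of the env-set Jaccard and the chain-set
  Jaccard.

Jaccard of two empty sets is defined as 1; this is forced by reflexivity
(a chain-free mechanism must still score 1 against itself) and is the one
convention case of the method. With three definitions and two methods
there are six scores; `score_suite()` computes all of them. Step-level
ordered scores are computed with the same formula — an extension beyond
the mechanism-level use, flagged here because only mechanism-level values
have an external reference. For display, fractions are rounded half-up to
integer percentages (0.41667 → 42%); machine outputs keep the raw
fraction.

## The worked example

`make_glycosidase_pair()` encodes two retaining glycosidases, alpha-amylase
(hydrolysis) and endo-xyloglucan transferase (transglycosylation), each as
two steps of three arrows. The first steps are chemically identical
(carboxylate attacks the anomeric carbon, the glycosidic bond breaks, the
acid protonates the leaving oxygen); the second steps differ only in the
incoming nucleophile (water versus a sugar hydroxyl). Under the two-away
definition the pooled env sets are 6 and 6 with 4 shared (unordered 4/8 =
50%) and the pooled chain sets 4 and 4 with 2 shared, giving the ordered
score mean(4/8, 2/6) = 41.7% ≈ 42%. The constructor self-checks these
cardinalities and fails loudly if the encoding ever drifts.

```{r}
pair <- make_glycosidase_pair()
score_suite(pair$amylase, pair$xet)
```

Two encoding choices deserve a note. The figure-level drawings this pair
emulates condense each proton transfer into a single arrow so that each
step has exactly three arrows: in step 1 the leaving oxygen's lone pair is
drawn to the acid proton (an atom sink), and in step 2 the O–H bond is
drawn to the incipient bond with the base oxygen. Chemically both are
shorthand for a two-arrow proton transfer; structurally they preserve the
intended chain pattern — step 1 is a linear two-edge path, step 2 a
two-edge star in which the nucleophilic attack feeds both other arrows.
Second, the acceptor hydroxyl of the transferase's second step is encoded
as a generic sugar `CH(-O)(-C)` hydroxyl; any acceptor consistent with the
reference cardinalities is acceptable, and this is the minimal one. The
first arrow of the first step reproduces the reference serialization
exactly:

```{r}
step <- make_fig1_step()
to_smarts(extract_arrow_env(step, step$arrows[[1]], "one_away"))
```

(The reference text prints Unicode hyphens; the package emits ASCII `-`.)

## Synthetic mechanisms

`random_mechanism()` exists so that every property of the machinery can be
tested without any external corpus. Defaults: 1–3 steps, 1–3 arrows per
step, 6–12 atoms per state drawn from a C/O/N/H/S palette weighted towards
C, O and H (typical active-site composition), 10% chance of a ±1 formal
charge, half the arrows starting from bonds, mostly single bonds with
occasional doubles and a 5% chance per extra cycle-forming bond. These are
one-time choices of plausible magnitudes, not fitted to anything: the
generator emulates the *structure* of curly-arrow data (graph sizes, arrow
topology, label diversity), not real chemistry — no valence rules, no
thermodynamics, no conservation of electrons across a step. Consequently,
passing property tests on synthetic corpora demonstrates the algebra of
the method (canonicality, symmetry, coarsening, monotone decay under
perturbation), and the in-paper fixtures demonstrate agreement with the
reference chemistry; neither shows that scores on a real database are
chemically meaningful — that judgement stays with the user.

`mutate_mechanism()` applies seeded random edits (element swaps outside
reaction centres, charge edits, arrow-sink rewires) that never break
validity; mean unordered similarity to the original decays monotonically
with the number of edits in the suite's simulation (50 seeds per level).

## Numerical and scale choices

Everything is exact set arithmetic on canonical strings; there are no
tolerances in the method itself. Test problem sizes — pools of a few
hundred environments of ≤ 12 atoms, 150 + 50 isomorphism pairs, 100
mechanism pairs for score properties, 50 seeds × 4 mutation levels — keep
the full suite around a minute while leaving each property with enough
random mass to fail loudly if an invariant breaks. Determinism: every
random fixture is seeded; the generator saves and restores the caller's
RNG state.

## File formats

Mechanism JSON (version 1.0, schema in `inst/extdata/`) is the canonical
format: writing is byte-deterministic (sorted atoms and bonds, fixed key
order), so round-trip identity is testable at the byte level. The MRV
reader accepts a documented subset of Marvin documents — atom/bond arrays
(attribute or per-element form), bond orders 1/2/3/A, and `MEFlow` arrows
whose two endpoints reference an atom, a declared bond, or (sink only) an
atom pair read as an incipient bond; everything else is skipped and
reported in a warnings attribute. It is a best-effort bridge, not a full
Marvin parser: real-world dialect variants outside this subset are
rejected rather than guessed at. Similarity tables export as TSV and
GraphML threshold graphs (layout is left to downstream viewers).

## Known limitations

* A drawing choice the method cannot see through: the same electron flow
  drawn along the other side of an aromatic ring produces different
  arrow-envs; such alternative drawings are not canonicalized and will
  depress scores.
* No stereochemistry: steps differing only in chirality compare equal by
  design.
* No non-covalent context: stabilizing interactions and 3D residue
  placement are outside the representation.
* Scores are descriptive; no significance model is attached to them.
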