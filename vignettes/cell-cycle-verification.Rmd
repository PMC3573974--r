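---
title: "Verifying timing robustness of yeast cell-cycle Boolean models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying timing robustness of yeast cell-cycle Boolean models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclecheck)
library(dplyr)
```

## The biological question

The budding yeast cell cycle proceeds G1 → S → G2 → M and returns to a
resting G1 state.  At the end of each phase a checkpoint verifies that the
previous phase completed: DNA replication must finish before mitosis
begins, chromosomes must align before anaphase, and division must complete
before the cycle resets.  Discrete regulatory-network models capture this
machinery with a handful of regulators (Cln3, MBF, SBF, Cln2, Cdh1, Swi5,
Cdc20, Clb5, Sic1, Clb2, Mcm1), but a model that behaves correctly when
all reactions tick in lockstep can still fail when reaction speeds vary:
with asynchronous updates, an unfortunate ordering of two reactions can
fire a late-phase regulator before its checkpoint prerequisite.  Such an
ordering is a *hazard*, in the sense used for asynchronous digital
circuits.  `cyclecheck` provides the machinery to find hazards
exhaustively, to certify their absence, and to quantify the timing
robustness of a model and its mutants.

## Models and update rules

A model is a weighted signed digraph over discrete-level nodes.  Binary
nodes take levels {0, 1}; graded nodes (Clb2, and Swi5 in the revised
model) take {0, 1, 2}, representing negligible, low and high
concentration.  Two threshold rules are implemented.

**Binary rule** (`li_binary`): a node switches on when its weighted input
sum is positive, off when negative, and on a tie keeps its level — unless
it is flagged self-degrading, in which case it decays to 0.  All weights
are ±1.

**Graded rule** (`multilevel`): with current level $s$ and input sum
$\sigma = \sum_j w_{ij} S_j$, a node climbs to $s+1$ when
$\sigma \ge \theta_{s+1}$, decays to $s-1$ when $\sigma < \theta_s$, and
otherwise holds.  The level-entry thresholds default to
$\theta_1 = 1/2$ and $\theta_2 = 3/2$, and weights come from the alphabet
$\{\pm 1/3, \pm 1, \pm 3\}$.  Levels change by at most one per update; a
node at 0 never decays (equivalently $\theta_0 = -\infty$) and a node at
its maximum never climbs.

Because $1/3$ has no finite binary representation and the threshold
comparisons at exactly $1/2$ and $3/2$ must be reliable, all weights and
thresholds are carried as integer numerators over the common denominator
6, and every comparison is integer arithmetic.  Floating point never
enters the update rule.

Under the graded rule a node with zero input decays, so persistence must
be wired explicitly: the graded fixtures carry weight-1 self-loops on the
nodes that hold their state in the absence of input (MBF, SBF, Cdh1,
Sic1, Cdc20).  For a binary node with integer input weights, a weight-1
self-loop reproduces the binary rule's maintain-on-tie behaviour exactly,
so the graded fixtures restrict to the classical binary dynamics on the
shared part of the network.

## The three bundled fixtures

`yeast_model()` returns three models: `li`, the classical binary network
(2048 states, self-degradation on Cln3, Cln2, Swi5, Cdc20, Mcm1);
`mangla`, its graded timing-robust extension with three-valued Clb2
(3072 states); and `proposed`, the revised hazard-free model with
three-valued Clb2 and Swi5 (4608 states).  The revised model differs from
the graded base model in exactly four edges: Clb5→Mcm1 lowered to 1/3 (so
Mcm1 activation requires Clb2, closing the Clb2/Mcm1 positive feedback),
Cdc20→Swi5 strengthened to 3 and Clb2⊣Swi5 weakened to 1/3 (so Cdc20
activates Swi5 regardless of the Clb2 level), and Swi5→Sic1 weakened to
1/3 (so only fully activated Swi5 switches Sic1 on).

The two graded fixtures are transcriptions of published network diagrams
whose edge-weight rendering (line thickness) is not fully machine-readable
from the source we worked from.  The transcription was therefore pinned
down against its published numerical checksums — the exhaustive
synchronous basin tables of all three models — together with the published
qualitative dynamics (which regulators race after Clb5 activates, the
order in which Clb2, Mcm1, Swi5 and Cdc20 reach each level on the
synchronous trajectory, and the pass/fail pattern of the checkpoint
orderings and graded-activation responses).  The binary model's basin
table is reproduced exactly.  For the graded models the reconstruction
recovers all nine published attractor states of each model exactly, with
every qualitative constraint satisfied, while the individual basin counts
agree to within about one percent of the state space; the residual
indicates that some weight detail of the original diagrams remains
unidentified by the checks we can apply, and the test suite asserts
exactly what is reproduced rather than more.

```{r fixtures}
bundled_fixtures() |> lapply(glance) |> bind_rows()
```

## Attractors and basins

`synchronous_attractors()` iterates the deterministic synchronous map
from every state of the full space (at most 4608 states, enumerated
exactly; states are packed into mixed-radix integers so the whole update
is one matrix operation).  Attractors are detected by repeated squaring of
the successor permutation, which lands every state in its terminal fixed
point or cycle; basins are exact counts.

```{r attractors}
synchronous_attractors(yeast_model("proposed")) |> tidy()
```

All attractors of the three fixtures are fixed points; the dominant one
is the stationary G1 state (Cdh1 = Sic1 = 1), the cell's resting
condition, and its basin is largest in the revised model — stability
against state perturbations improves alongside timing robustness.

## Asynchronous semantics and the fairness reduction

Timing variation is modelled by full asynchrony: at each instant exactly
one node updates, chosen non-deterministically among those whose target
level differs from their current one.  The explicit transition graph from
an initial state (`reachable_graph()`) enumerates every reachable
ordering of reactions.

Liveness properties ("Cdc20 activation eventually leads back to G1")
require a fairness assumption, else the scheduler could starve a node
forever.  The package adopts the standard encoding in which the scheduler
may also pick nodes whose update is a no-op; fairness then demands only
that every node is *selected* infinitely often.  A cycle of the
(no-op-free) transition graph on which every node is stable in at least
one state can be decorated into a fair run by inserting stuttering
selections, so such cycles genuinely violate "every fair run eventually
reaches T".  The package checks the conservative operational form

> *the reachable graph has no cycle outside T and every maximal path ends
> in T*,

which treats **every** cycle outside T as a potential fair violation
(over-approximating in the rare case of a cycle along which some node's
update is enabled at every state, which only a strong-fairness assumption
would exclude).  This reduction replaces fair-CTL model checking with
reachability plus strongly-connected-component analysis, and it is what
`check_response()` and `check_global_attractor()` implement.  The
discussion applies to this encoding only; under a scheduler that may only
pick enabled nodes, fairness is a different (stronger) constraint.
`export_nusmv()` emits the corresponding SMV module — ranged variables, a
control variable, one FAIRNESS constraint per node, and the CTL formulas
— for optional cross-validation with an external symbolic model checker;
no analysis in the package depends on one.

## Checkpoint properties

The default property set renders the checkpoint conditions as ordering
and response properties over the async state space:

* S/G2: Clb5 activation precedes Clb2 activation.
* M-metaphase: Clb2 and Mcm1 activation precede Cdc20 activation.
* M-telophase: Cdc20 activation leads to full Swi5 activation; full Swi5
  activation leads to Sic1 activation; Cdc20 activation leads back to the
  stationary G1 state.
* Global attractor: stationary G1 is the unique fair fate of the
  stimulated G1 state.

"Activation" means reaching level ≥ 1 and "full activation" means the
node's own maximal level; both choices are configurable per property, and
the whole set is data (JSON-loadable via `load_properties()`), not code.
Because the exact published formalisation of the checkpoint list is not
reproduced in the main text we derived the defaults from, verdicts are
reported by checkpoint *group* rather than by a numbered property.

Precedence is checked by breadth-first search over the state space
augmented with one latched monitor bit ("the antecedent has held"); a
violation is a reachable state satisfying the consequent with the monitor
still false, and the witness returned is shortest by construction, which
makes counterexamples deterministic and readable.  Every failing verdict
carries a counterexample trajectory that `replay_counterexample()`
re-validates step by step against the asynchronous successor relation —
the test suite does this for every failure it asserts.

```{r hazards}
check_properties(yeast_model("mangla")) |> tidy()
```

In the graded base model the metaphase ordering fails — a concrete
trajectory fires Cdc20 while Clb2 is still off — and the telophase group
fails through the return-to-G1 response.  The revised model eliminates
every ordering hazard and satisfies the graded activation responses;
only the global-attractor property (and its whole-state return-to-G1
variant) fails, for all three models alike, for the structural reason
discussed below.

### Why the global-attractor property fails for every fixture

The strict global-attractor check cannot hold for any weight assignment
that reproduces the published attractor tables, because of an
irreducible race at the very start of the cycle.  The start signal Cln3
has no sustaining input, so its decay is enabled from the first instant;
if it decays after MBF has fired but before SBF has, the system lands in
the state (MBF = 1, Cdh1 = 1, Sic1 = 1) — which the published tables list
as an attractor, hence a fixed point, hence a wrong terminal state.
Giving Cln3 a sustaining loop (shut off by its two targets) eliminates
that race but creates a fair cycle through the stimulated state itself: a
deferred start signal lets the cell divide repeatedly, and at stimulated
G1 the Cln3 update is a no-op, so the cycle survives the fairness
reduction.  Either way the check fails.  The safety (ordering) properties
and the node-level responses quantify over what happens *after* their
trigger and are untouched by this early race; they are the informative
comparisons between the models, and the test suite treats them that way.

## Phase segmentation and duration statistics

Phase boundaries are data (`phase_config()`): an ordered list of entry
markers, latched along a trajectory so phases never revert within a
cycle.  Two configs ship because no single boundary definition
reconciles both published summary tables: a 2-segment config (S from the
stimulated G1 state; G2/M from the first Clb2 ≥ 1) for segment-length
statistics, and a 4-segment config (G1; S at Clb5 ≥ 1; G2 at Clb2 ≥ 1; M
at Cdc20 ≥ 1) for transition counting.

`phase_length_stats()` averages per-phase segment lengths over *all
distinct simple paths* of the async graph from stimulated to stationary
G1, each path weighted equally, reporting population variance (n
denominator).  When the graph minus the target is acyclic — true for all
three fixtures — the moments are computed exactly by dynamic programming
over the product of the DAG with the latched phase index, without
enumerating the (hundreds of thousands of) paths; a capped explicit
enumeration is the fallback for cyclic graphs, and the test suite checks
the two routes agree.  Equal path weighting is a modelling choice: the
alternative — weighting by the uniform scheduler's probability — is
available as `phase_length_stats_sampled()`, and the averaging population
behind the published duration table is not stated precisely enough to
decide between them, so the reproduced quantities are the package's own
operationalisation and the cross-model *patterns* (G2/M roughly twice S
in the revised model; identical pre-replication statistics where the
models share wiring) are the robust content.  The same caveat applies to
`phase_transition_counts()`, which counts distinct transitions of the
async graph grouped by the latched phase of the source state.

```{r phases}
phase_length_stats(yeast_model("proposed"))
phase_transition_counts(yeast_model("proposed"))
```

## Mutation robustness screening

`robustness_screen()` quantifies how much of a phase's wiring can be
perturbed without losing the global-attractor property.  Decisions made
where the procedure was underdetermined, all recorded here and
configurable:

* *Phase-related edges*: edges touching a node whose level changes during
  that phase segment of the reference synchronous trajectory, plus absent
  ordered pairs among those nodes (candidates for addition).  A
  user-supplied slot set can replace this default.
* *Mutation distance* = number of elementary edits (delete / add /
  re-weight), each on a distinct slot; mutants are sampled with
  replacement, so duplicates may occur, as in blind random generation.
* *Re-weighting* draws the magnitude uniformly from the weight alphabet
  and keeps the sign with probability 1/2, resampling until the weight
  changes.
* The screen generates its mutant count *per (phase, distance) cell*.

Exact robust fractions depend on the mutation sampler, which is not
published; the reproducible content is the pattern — the unmutated binary
model screens at 0 (it already fails the property), the unmutated revised
model at 1, and G2-phase mutants of the revised model stay robust more
often than those of the graded base model, reflecting the larger number
of viable transition orderings through G2 once the Clb2/Mcm1 feedback is
closed.

```{r screen, eval = FALSE}
robustness_screen(yeast_model("proposed"), phases = "G2", distances = 1,
                  n = 200, seed = 1)
```

## Numerical and engineering choices

* All level/threshold comparisons in integers (denominator 6); no
  tolerances anywhere.
* States are packed mixed-radix integers; full-space maps are single
  matrix products; reachable graphs are frontier-vectorised BFS with
  deterministic (packed-order) state numbering, so every output is stable
  across runs.
* Graph caps (`max_states`, default $10^6$) turn state-space explosion
  into an explicit error rather than an open-ended computation; the
  screening treats a capped mutant as non-robust and flags it.
* The asynchronous scheduler used for simulation picks uniformly among
  enabled nodes; no-op selections are collapsed (they only stutter; see
  the fairness reduction).
* Degenerate inputs: a trajectory already at the cycle end labels as an
  empty cycle; a fixed-point initial state yields a one-state graph; a
  precedence property whose antecedent and consequent first hold at the
  same instant counts as satisfied ("at some earlier or equal time").

Problem sizes are small by design — full spaces of 2048/3072/4608 states,
reachable graphs of a few hundred states, and path ensembles handled in
closed form — so every analysis in this vignette and in the test suite
runs in seconds on one core, and the default mutation screens (tens to
hundreds of mutants) in minutes.

## Limitations

The models are logical, not kinetic: update steps are not calibrated to
wall-clock minutes, and level 2 is "high", not a concentration.  The
update rules are threshold functions — arbitrary logical gates are out of
scope, as are stochastic-rate semantics and delay-annotated extensions.
The checkpoint property set is a rendering of the documented checkpoint
conditions, not a verbatim reproduction of any published formula list;
users with a different reading can load their own set.  Verification is
explicit-state by design (the spaces involved are tiny); no symbolic
representation is attempted.
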