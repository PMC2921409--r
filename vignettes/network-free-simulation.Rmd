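---
title: "Network-free kinetic Monte Carlo for rule-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-free kinetic Monte Carlo for rule-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulekmc)
```

## The problem

Protein--protein interaction systems are naturally described by *reaction
rules*: graph-rewriting schemas that say, for example, "any ligand with a
free binding site may bind any receptor with a free site, at single-site
rate constant $k_{+1}$".  Because multivalent binding and multisite
modification generate combinatorially many distinct complexes and
phosphoforms, the reaction network implied by even a handful of rules can
be astronomically large, and any simulator whose cost depends on network
size fails outright.  `rulekmc` simulates such models *network-free*:
rules are applied directly to individually tracked site-graph particles,
so the cost per event is independent of how many reactions the rules
imply.  The method is also *rejection-free*: every simulation step
executes a real reaction, so stiff systems (rate constants spread over
many decades) cost the same per event as benign ones.

## State representation and observables

Molecules are typed objects with named components; components may carry
an internal state (e.g. a phosphorylation flag) and at most one bond.  A
chemical species is a connected site graph of molecules; the system state
$\Sigma_c(t)$ is the full set of species instances -- every molecule,
every component state, every bond, tracked as particles.  `rulekmc`
stores this state in flat integer arrays (type, state and bond matrices)
inside an R environment, so rewrites are $O(1)$ array updates.

Observables are pattern graphs evaluated against the state by subgraph
embedding.  A `Molecules` observable counts *all* injections of its
pattern into the state (so a pattern with $m$ symmetric components
contributes $m!$ injections per matched site set); a `Species` observable
counts species instances with at least one injection.  Injections --
rather than automorphism-deduplicated images -- are the documented
convention here; patterns used in the bundled models are chosen so the
two notions coincide where it matters.

## The simulation cycle

With per-rule cumulative rates $r_1,\dots,r_N$ and
$r_\mathrm{tot}=\sum_i r_i$:

1. draw the waiting time $\tau = \ln(1/\rho_1)/r_\mathrm{tot}$,
   $\rho_1 \sim U(0,1)$;
2. pick the rule as the smallest $I$ with
   $\sum_{i\le I} r_i \ge \rho_2\, r_\mathrm{tot}$ (a deliberate linear
   scan; rule counts are small and profiling shows the scan is not
   limiting);
3. pick reactant instance(s) with probability proportional to their
   *distinct reaction-center counts*, then a concrete center uniformly;
4. apply the graph rewrite, split or merge species as connectivity
   dictates, and update every rule's rate and every observable
   incrementally.

The RNG deviate order per event is fixed (and documented in
`simulate_nf`): $\tau$, rule, instance(s), center(s); a fixed seed
reproduces a trajectory bit for bit.

## The five rate classes

Rules are classified at parse time; each class has an exact counting
formula.  Writing $v(l,s)$ for the number of distinct images in species
instance $s$ of the center component identified by pattern $l$ (distinct
*centers*, not matches -- a contextual constraint satisfiable several
ways around one center counts once):

* **State change** ($l \to \rho$, one component changes state):
  $r = k \sum_s v(l,s)$.
* **Dissociation** (one bond deleted): centers are bonded pairs whose
  deletion yields exactly the number of products the right-hand side
  demands (1 when a ring opens, 2 when the species falls apart).  A tree
  shortcut ($|E|=|V|-1$ means every bond is a bridge) avoids per-bond
  connectivity checks in acyclic aggregates.
* **Bimolecular association** ($l + l' \to \rho$): the uncorrected
  product $\bigl(\sum_s v(l,s)\bigr)\bigl(\sum_s v(l',s)\bigr)$
  over-counts pairs whose two centers sit in one instance; subtracting
  $\sum_s v(l,s)\,v(l',s)$ leaves exactly the ordered center pairs drawn
  from two *distinct* instances (molecularity 2).  When the two patterns
  are textually identical the symmetry factor $f=\tfrac12$ applies, which
  reproduces the mass-action form $k\,n(n-1)/2$ for $A+A$ rules.
* **Ring closure** (one bond created within a species), monogamous
  (both centers in one molecule) or non-monogamous (centers in different
  molecules of one species), declared by rule syntax: the rate is $k$
  times the number of distinct *unordered* center pairs satisfying the
  same-/different-molecule condition.  Counting unordered pairs is
  algebraically identical to counting ordered pairs and halving for
  symmetric half-patterns; the unordered form is used because it is also
  the natural unit for reactant selection.

All five contracts are pinned by mandatory equivalence tests against a
brute-force enumerator (`brute_force_rule_rate`) that shares no code with
the engine.

### Incremental maintenance

After initialization rates are never recomputed from scratch: when an
event removes instances, their stored contributions are subtracted; new
instances are matched against all rule patterns and added (including the
cross terms of two-pattern rules).  All stored quantities are *integer
center counts* held in doubles, so the increments are exact and the
incrementally maintained rates equal a de-novo recomputation to machine
identity -- comfortably inside the 1e-9 relative tolerance asserted in
the tests.  As a belt-and-braces guard against any future non-integer
bookkeeping, a full refresh still runs every $10^6$ events.

Matching cost per event is bounded by caching per-molecule pattern
assignments under a local signature (type, states, bond statuses).  In
aggregation models signatures repeat massively, so re-matching a large
aggregate after an event is a cache lookup per molecule.  Multi-molecule
patterns whose single explicit bond is the reaction center (the common
dissociation shape) are matched by enumerating actual bonds; anything
more exotic falls back to a generic backtracking matcher, which is also
the reference implementation used by `find_matches`.

### Reactant selection details

For two-pattern rules the molecularity-2 constraint is enforced *in the
sampling distribution*, not by rejection: the first instance is drawn
from the corrected marginal $v(l,s)\bigl(V' - v(l',s)\bigr)$, the second
from $v(l',s)$ with the first instance excluded.  Center eligibility for
the chosen instance is re-derived at event time rather than cached per
center; invalidation stays trivial and the cost is bounded by the
instance size.

## Conventions and degenerate inputs

* **Report times.** The jump process is right-continuous piecewise
  constant; the value reported at $t_r$ is the state after the last
  event at time $\le t_r$.
* **Absorbing states.** If $r_\mathrm{tot}=0$ the run jumps to `t_end`
  and the remaining report rows repeat the frozen state.
* **Pattern conventions.** A listed component with no `!` must be
  unbound; omitted components are wildcards; `!+` means bonded to
  anything, `!?` leaves the bond status unconstrained.  These follow
  standard BNGL semantics; the accepted dialect subset is exactly what
  the five rule classes require (no synthesis, degradation, compartments
  or functions).
* **Zero seeds** are legal (all rates 0); zero-rate rules are never
  selected.

## The reference oracle

Validation is generate-first: `generate_network` closes the species set
under all rules (canonical labels decide species identity), recording
per-reaction rate constants as $f\,k$ times the number of reaction paths
between fixed copies, so that `simulate_ssa_network` (Gillespie direct
method) and `integrate_ode_network` (mass-action ODEs via `deSolve`, rtol
1e-8) match the rule-level rates by construction.  The oracle duplicates
all combinatorics on its own nested species representation -- an oracle
sharing code with the system under test would prove nothing.

Canonical labelling uses iterative neighborhood refinement followed by a
lexicographically minimal ordered traversal, branching over refinement
ties and over permutations of identically named component slots.  This
is deliberately simple and adequate for oracle-scale species (dozens of
molecules); it is not a general-purpose canonicalizer, and a search
budget guards against pathologically symmetric inputs.

### Validating an unbounded network: the TLBR case

For the trivalent-ligand/bivalent-receptor (TLBR) model the implied
network is not enumerable at any realistic copy number -- the set of
acyclic aggregates over 50 ligands and 30 receptors is astronomically
large.  This is precisely the regime network-free simulation exists for,
but it leaves nothing for a generate-first oracle to enumerate.  The
package resolves this by comparing in a weak-crosslinking regime
($\beta = N_R k_{+2}/k_\mathrm{off} \approx 0.0015$) against a network
truncated at 8 molecules per species, and verifying *from the
network-free runs themselves* that no species ever reaches the cap: on
that event the truncated network is exact for the realized dynamics, so
the comparison is unbiased rather than approximately so.

## What the bundled models emulate

* `make_tlbr` -- multivalent ligand--receptor aggregation with the
  classic sol--gel (percolation) transition in $\beta$.  Acyclicity is
  enforced structurally: there is no ring-closure rule and dissociation
  demands two products, so cycle-closing events simply never occur.
  Defaults follow the benchmark conditions $N_R = 300$,
  $k_\mathrm{off} = 0.01\,\mathrm{s}^{-1}$ with $\beta$ set through
  $k_{+2}$; $N_L$, $k_{+1}$ and run lengths are package choices
  ($N_L = 300$ puts ligand sites in mild excess of receptor sites so
  that strong crosslinking can percolate).
* `make_multisite_phos` -- $n$ independent two-state sites on one
  substrate; the implied network has $2^n$ species, so it demonstrates
  the capability gap between generate-first and network-free at
  $n = 10$ while remaining exactly solvable (linear kinetics) for
  validation at $n \le 2$.
* `make_stiff` -- two first-order reactions with rate ratio $\varphi$;
  per-event cost must not depend on $\varphi$ for a rejection-free
  method.
* `make_dimerization` -- the minimal symmetric-association model pinning
  the $f = \tfrac12$ convention.

These synthetic models reproduce the structural features the simulator
must handle (symmetric sites, aggregates, stiffness, combinatorial
explosion) but not other features of real signalling data -- extrinsic
noise, unmodelled side reactions, parameter uncertainty -- so passing
tests certify the simulator, not any biological model.

## Problem sizes used by the test suite

Statistical checks compare means over repeated runs at 3 standard errors
with fixed seeds.  The suite uses: 200 randomized states per rule class
for oracle equivalence; 500 network-free vs 500 SSA runs (10 report
times) for 2-site phosphorylation ($n_0 = 50$, $k_p = k_d = 1$,
$t_\mathrm{end} = 2$), dimerization ($n_0 = 60$, $k_+ = 0.01$,
$k_- = 1$, $t_\mathrm{end} = 5$) and sub-gel TLBR ($N_L = 50$,
$N_R = 30$, $k_{+1} = 0.005$, $\beta = 0.0015$, $t_\mathrm{end} = 5$);
$10^4$ waiting-time samples; 1000 events of step-by-step incremental
vs de-novo rate comparison; 15000-event throughput measurements at
$\varphi \in \{1, 10^3, 10^6\}$; and single percolation runs at
$\beta = 0.03$ vs $\beta = 30$ with run lengths (150 s and 60 s) long
relative to the slowest relevant relaxation times.  ODE comparisons are
made only where copy numbers (or linear kinetics) make the deterministic
mean the exact expectation; for the nonlinear dimerization model at
$n_0 = 60$ the ODE mean differs from the stochastic mean at $O(1/n_0)$
and only the SSA comparison is used.

## Known limitations

* Rule vocabulary: exactly one state change, bond creation or bond
  deletion per rule; no synthesis, degradation, compartments, local
  functions or energy patterns.
* Mass-action rate laws only, with single-site rate constants (the
  bimolecular $k$ is the volume-scaled constant $k/(N_A V)$).
* A rule may not mix monogamous and non-monogamous ring closure; the
  class is declared by whether the two centers share a pattern molecule.
* `Molecules` observables count injections, including pattern
  automorphisms.
* The canonical labeller and the exhaustive generator are oracle-grade,
  not production tools: both are exponential in the worst case and
  guarded by explicit budgets.
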