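---
title: "Balanced complexes, forced balancing and differential lethality screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced complexes, forced balancing and differential lethality screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balcomplex)
```

## The model

A constraint-based metabolic model consists of a stoichiometric matrix
$N$ (species $\times$ reactions) and flux bounds; its steady-state flux
polytope is

$$S = \{\, v \mid N v = 0,\ v_{\min} \le v \le v_{\max} \,\}.$$

The multiset of species on one side of a reaction is a *complex*; the
empty side of an exchange reaction is the *zero complex*.  Writing $Y$
for the species composition of the complexes and $A$ for the incidence
matrix of the directed complex graph (one $-1$ and one $+1$ per
reaction column), the stoichiometric matrix factorises as $N = Y A$.
The *activity* of complex $C_i$ under a flux distribution $v$ is
$A^{i:} v$ — incoming minus outgoing flux.  A complex is

* **balanced** if its activity is zero on all of $S$, decided by two
  LPs (minimum and maximum of $A^{i:}v$ over $S$ both zero);
* **trivially balanced** if it contains a species occurring in no other
  complex (the species' steady-state balance then forces the activity
  to zero) — a structural test needing no LP;
* a **sink/source** if its incidence row is one-signed; such complexes
  cannot be balanced in a blocked-free network.

Two non-balanced complexes are **concordant** when their activities are
coupled, $A^{j:} v = \gamma\, A^{i:} v$ on all of $S$ with
$\gamma \neq 0$; concordance is an equivalence relation and partitions
the non-balanced complexes into *concordance modules*.

**Forced balancing** imposes $A^{i:} v = 0$ for a chosen non-balanced
$C_i$ and asks which other non-balanced complexes become balanced on
the restricted polytope.  That set $Q_i$ (excluding $C_i$) has size
equal to the *balancing potential* of $C_i$.  A member $C_j \in Q_i$
is *trivially* forcedly balanced when it is concordant with $C_i$;
otherwise it is *non-trivially* forcedly balanced of **type I** (every
reaction around $C_j$ is blocked under the constraint) or **type II**
(some incoming and some outgoing reactions still carry flux).  Because
concordance is inherited by subsets of $S$, membership in $Q_i$ is
uniform within each module and all members of a module share one
balancing potential — the implementation exploits both facts, solving
the balance check once per module and classifying types per member.

The bundled `toy_fig1()` network (11 species, 18 irreversible
reactions, 14 complexes: a TCA cycle with glyoxylate shunt) exercises
every part of this machinery:

```{r toy}
net <- toy_fig1()
dec <- build_decomposition(net)
st  <- find_balanced(net, dec)
part <- build_partition(net, dec, st)
force_balance(net, dec, "1*Oaa", part, st)
```

## Preprocessing

`preprocess_model()` applies, in this order:

1. **Blocked-reaction removal**: a reaction is blocked when its flux
   variability range lies within $[-\varepsilon, \varepsilon]$ with
   $\varepsilon = 10^{-9}$ (configurable); FVA runs on the model as
   given, with its original bounds (infinite bounds capped at
   `bound_cap`, default 1000).
2. **Reversible splitting**: each reversible reaction becomes a forward
   and a sign-flipped backward copy; all lower bounds are set to zero
   and all upper bounds to the maximum upper bound of the original
   model.

Afterwards $S$ is a bounded polytope containing $v = 0$, so every LP in
the pipeline is feasible and attains finite optima.  Note that the
common upper bound is a genuine relaxation of heterogeneous bounds; it
standardises the polytope across models derived from one parent
reconstruction, which is what the cross-model complex comparisons
assume.

Complex identity is scaling-sensitive, so the simple model dialects are
normalised to smallest integer stoichiometries (per-reaction gcd) on
read; SBML models, whose scaling is fixed by the source reconstruction,
are left untouched by default.  Species appearing with equal
coefficients on both sides of one reaction cancel when the matrix
column is formed, giving a deterministic complex for every reaction
side.

## Numerical choices

* **One zero tolerance.**  A single `zero_tol` (default $10^{-9}$, the
  same threshold used for blocked reactions and lethality) decides
  every "is this LP optimum zero" question; the simplex feasibility
  tolerance is kept at `zero_tol`/10.
* **The LP engine.**  All LPs are bounded-variable problems
  $\min/\max\ c^\top v$ s.t. $Nv = 0$, extra equality rows, and box
  bounds.  They are solved by a dense two-phase primal simplex on the
  slack-augmented standard form, with Dantzig pricing switching to
  Bland's rule after a fixed iteration count so that the degenerate
  polytopes arising here cannot cycle.  Unbounded statuses are treated
  as configuration errors: preprocessing caps all bounds.  The test
  suite certifies every returned solution against the constraints and
  cross-checks optima against an independent simplex implementation.
* **Concordance testing.**  $S$ contains $v = 0$, so the coupling
  ratio cannot be probed by normalising an activity to 1.  Instead the
  candidate $\gamma$ is computed from a stored witness flux (an LP
  solution certifying the representative's non-balancedness); if
  coupling holds the candidate is the unique possible ratio, and two
  LPs verifying $\min = \max = 0$ for $(A^{j:} - \gamma A^{i:})v$ make
  the test sound and complete.  Couplings with $|\gamma| \le$
  `zero_tol` are treated as non-concordant.
* **Determinism.**  Complexes are iterated in index order, module
  representatives are the lowest member indices, and all generators
  take explicit seeds, so repeated runs produce byte-identical tables.

## Balancing-potential distributions

Balancing potentials are counts, so they are modelled with the
*discrete* power law with exponential cut-off,
$P(X = x) \propto x^{-a} e^{-bx}$ on integers $x \ge x_{\min}$.
`fit_powerlaw_cutoff()` maximises the discrete likelihood (normalising
constant by truncated summation, truncation error below $10^{-12}$ of
the sum) with a bounded quasi-Newton search from three deterministic
starts; standard errors come from the observed information.  Defaults:
$x_{\min} = 1$, because $x^{-a}$ is undefined at 0 — zero potentials
(balanced complexes) are excluded from fitting and reported separately.

`compare_distributions()` fits four alternatives to the same sample:
the pure power law (nested: tested by a likelihood-ratio test with one
degree of freedom, conservative because the null pins $b$ to the
boundary of the parameter space) and the exponential, log-normal and
stretched-exponential families (non-nested: normalised Vuong
log-likelihood-ratio tests).  `sample_powerlaw_cutoff()` is the
simulation twin used to validate recovery: at $n = 10{,}000$ draws
from $a = 1.54$, $b = 0.003$ — the parameter regime reported for
genome-scale networks — the MLE recovers both parameters within three
standard errors, and the cut-off model is preferred over the pure
power law.  `ks_two_sample()` compares two empirical potential
distributions (ties are expected in integer data, hence the asymptotic
p-value).

## The differential screen

`lethality_screen()` computes the FBA optimum $z$ and, per non-balanced
complex, the optimum $z_i^*$ under $A^{i:}v = 0$; balancing is lethal
iff $z_i^* < 10^{-9}$ (strict).  $z_i^*$ is computed for every
non-balanced complex rather than once per module: the balanced *set*
is module-uniform, but an objective value is not provably so, and the
conservative choice costs one LP per complex.
`candidate_complexes()` intersects two screens by canonical complex
label (paired models share a species namespace) and calls a candidate
when forcing is lethal in the disease model yet preserves at least 90%
(`healthy_fraction`) of the healthy model's own optimum.
`essential_reactions()` uses the knockout definition (flux pinned to
zero, split pairs knocked out jointly and counted once);
`module_enrichment()` tests each concordance module's incident
reactions for enrichment in essential reactions with the two-sided
Fisher exact test.  `exchange_balancing()` implements the
transporter-engineering route: adding a (reversible, then split)
exchange reaction for an internal species can balance a complex
physiologically; for sinks and sources the outcome can differ from
direct forcing, since an exchange flux balances the activity without
blocking the surrounding reactions.

## What the generators emulate — and what they do not

`random_network()` produces small connected irreversible networks (a
chain backbone with uptake/export plus random one- or two-species
reaction sides) for property testing: the factorisation $N = YA$,
partition properties, potential bounds and the LP-versus-vertex-
enumeration equivalence hold on them by mathematics, not by tuning.
`planted_pair()` builds a disease/healthy pair in which a condensation
reaction makes the planted sink complex `1*P` non-balanced in both
models while only the healthy model carries a bypass to the biomass
precursor; the generator certifies all planted invariants by LP before
returning and refuses degenerate (identical-pair) specifications.

Neither generator reproduces the statistical texture of genome-scale
reconstructions: currency metabolites spanning hundreds of reactions,
compartments, heterogeneous uptake bounds, or the heavy-tailed
complex-degree distributions that give real models their 83–95%
nonzero-potential fractions.  Passing tests therefore certify the
*correctness* of the algorithms on polytopes small enough to verify
exhaustively, not the biological conclusions one would draw from real
reconstructions — those require the original model files.

## Problem sizes

The shipped suite runs the full pipeline on the 18-reaction worked
example, property checks on dozens of random networks of 8–14
reactions, brute-force vertex-enumeration equivalence on 20 networks
of 8–10 reactions, distribution recovery at $n = 10^4$ samples, and
screen recovery across 20 planted pairs — sizes chosen so the entire
suite certifies every contract in about two minutes on one CPU.  All
stages scale to genome-scale models in the obvious way (the LP count is
linear in complexes for detection and screening, and linear in modules
for potentials); for such models a compiled LP backend would be the
first thing to swap in behind `solve_lp()`.

## Known limitations

* The dense tableau simplex is sized for models up to a few hundred
  reactions; genome-scale work needs a sparse solver behind the same
  interface.
* SBML support reads Level 3 core plus FBC bounds; gene–protein-
  reaction rules, annotations and objectives are ignored (the
  objective is named explicitly at screen time).
* Only one complex is forced at a time, as the method defines;
  joint balancing of complex sets is out of scope.
* `x_min` is fixed (default 1) rather than selected by
  goodness-of-fit minimisation, and no bootstrap p-value is attached
  to the cut-off fit itself.
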