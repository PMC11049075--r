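---
title: "Modelling shared anticipations: the methods behind protentia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling shared anticipations: the methods behind protentia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protentia)
```

protentia studies how a group of agents, each running discrete active
inference over a model of a shared world, can come to hold compatible
anticipations of that world — and how to measure and repair the
disagreement when they do not. This vignette records the models, the
conventions, and the design choices behind the package, in the order the
layers stack.

## 1. The single-agent engine

### Generative model

An agent is a discrete POMDP over finite labelled sets: states $S$,
observations $O$, actions $U$. The parameters are the usual five tables
plus a precision:

* $A(o \mid s)$ — likelihood (column-stochastic, observations × states);
* $B_u(s' \mid s)$ — one transition map per action;
* $C(o)$ — preferences over observations, a categorical; log-preferences
  enter the objectives, and `preferences_from_log()` maps unnormalized
  log-preferences (e.g. $+3$ on a rewarding outcome) to $C$;
* $D(s)$ — prior over initial states;
* $E(u)$ — habit, a prior over actions;
* $\gamma \ge 0$ — precision of action selection.

Label order is the single source of truth for vector alignment. Every
operation refuses to align differently-labelled supports by position; this
makes relabelling bugs loud rather than silent.

### State inference

Beliefs are updated by minimizing variational free energy. On finite
supports the optimum is available in closed form, so `exact_posterior()`
performs plain Bayes, $q(s) \propto A(o \mid s)\,\mathrm{prior}(s)$, and the
divergence term of the free energy vanishes exactly at the optimum. We
deliberately do not iterate a fixed-point scheme: exactness is the tested
contract, and the approximation error of gradient schemes would only blur
the identities below.

`free_energy()` reports, for any candidate belief $q$:
$$F = \mathbb{E}_q[\ln q(s) - \ln A(o \mid s) - \ln \mathrm{prior}(s)],$$
together with its two standard readings — divergence minus log evidence,
and complexity minus accuracy. The three agree to machine precision by
construction, and $F \ge -\ln P(o)$ with equality exactly at the Bayesian
posterior. The test suite checks the identities to $10^{-9}$ and the bound
on hundreds of seeded random models.

A note on factorization: where beliefs over states and actions appear
jointly, the package factorizes $Q(s, u) = Q(u)\,Q(s \mid u)$ and computes
$F$ per conditioned branch; action selection then weighs the branches as
described below.

### Expected free energy

For a candidate action $u$, the one-step predicted state distribution is
$q_u = B_u q$, and `expected_free_energy()` evaluates
$$G(u) = \underbrace{D_{\mathrm{KL}}[q(o \mid u)\,\|\,C]}_{\text{risk}}
 + \underbrace{\mathbb{E}_{q_u}\!\left[H[A(\cdot \mid s)]\right]}_{\text{ambiguity}},$$
with $q(o \mid u) = A q_u$. The report also carries the epistemic/pragmatic
split $G = -\text{(information gain)} - \text{(expected value)}$. The two
decompositions are *identically* equal under one convention, which the
package fixes: the expectation runs over the predictive joint
$Q(o, s \mid u) = A(o \mid s)\, q_u(s)$, and the posterior-over-states term
inside the information gain is the exact Bayes posterior under that joint.
Any other choice of predictive density makes the two printed forms differ;
this one makes the rearrangement exact, which is what the identity tests
pin down.

Numerical conventions: probabilities are clamped to $10^{-16}$ before logs
inside the energy terms, so objectives stay finite on degenerate tables.
`kl_divergence()` alone is left unclamped and returns $+\infty$ on
absolute-continuity failure — it is a diagnostic, not an objective, and
hiding an infinite divergence would mask modelling errors.

### Action selection and habits

Actions are sampled from
$$P(u) = \sigma(\ln E - \gamma\,G(u)),$$
the softmax of negated precision-scaled expected free energy with the habit
as a log bias. With a uniform habit this reduces exactly to
$\sigma(-\gamma G)$, which is the compatibility guarantee the tests assert;
$\gamma = 0$ gives uniform action choice, and a degenerate habit dominates
any finite $G$. Ties in any argmax are broken by label order.

The per-step loop order is: observe → infer → evaluate $G$ → act →
propagate the prior through the chosen action's $B$. Nothing forces this
order in principle; it is fixed so that seeded runs are exactly
reproducible.

### Policies

`rollout_policies()` enumerates all action sequences to a given depth
(refusing beyond a cap rather than sampling silently) and accumulates $G$
additively, propagating the predicted state distribution marginally
through $B$ — no observation conditioning inside the rollout. This is the
standard discrete evaluation; its known blind spots (it cannot represent
"act on what you will have learned") are partly compensated by the
epistemic term, which is exactly what the T-maze fixture exercises.

## 2. The interface algebra

Agent boundaries are modelled as finite polynomials
$p = \sum_{i \in p(1)} y^{p[i]}$: positions are the configurations an
interface can adopt (actions, or emitted observations), and each position
carries its own set of admissible directions (sense data). The monomial
$A\,y^S$ recovers the classical Markov blanket, with total set of size
$|A| \cdot |S|$.

The algebra implemented is the minimal toolkit needed for multi-agent
composition: tensor (`poly_tensor()`, interfaces side by side), morphisms
with forward position maps and backward direction maps
(`poly_morphism()`, composition, identities), exhaustive enumeration
(`enumerate_morphisms()`), and the internal hom `poly_hom()`, whose
positions are the morphisms $p \to q$ — internalized patterns of
interaction. Backward maps may be stochastic (`stoch_map()` columns), which
is how feedback from a stochastic environment enters; a dynamical system on
an interface is then a state set with an output map to positions and
per-state update maps from directions (`dynamical_system()`,
`run_system()`). `to_stoch_poly()` rewrites a POMDP as such a system over
the monomial $O\,y^U$ and round-trips the tables exactly. The emission is
stochastic (sampled from $A$) because that is the faithful POMDP reading; a
deterministic output mode only makes sense for noiseless likelihoods.

Two design choices deserve a note:

* **Bundle sections.** A morphism $p \to y$ is equivalent to a section of
  the projection $\sum_i p[i] \to p(1)$, i.e. a choice of one direction per
  position; the enumeration tests assert $|\mathrm{Poly}(p, y)| =
  \prod_i |p[i]|$ exhaustively.
* **Isomorphism by cardinality profile.** The currying law
  $[p, [q, r]] \cong [p \otimes q, r]$ is certified by comparing position
  counts and direction-size multisets of the two sides
  (`curry_check()`), not by constructing a natural isomorphism. For finite
  polynomials profile equality is what the law predicts observably, and it
  is cheap: the profile of a hom is computed combinatorially (loop over
  forward maps, counting backward families in closed form), because the
  largest grid instances have on the order of $10^6$ morphisms — far past
  the enumeration cap of $10^5$, which exists to keep explicit enumeration
  honest (refuse, never subsample). The profile route is itself verified
  against explicit enumeration on small instances, and the law is checked
  over the full grid of polynomials with up to two positions and two
  directions per position.
* **Morphism equality** is on the nose (by labels), not up to
  relabelling; relabelling-invariance is instead made testable by keeping
  everything labelled.

## 3. Ensembles

In a group, each agent's model conditions the hidden dynamics on the
*joint* action: `agent_spec()` carries a model whose action set is the
product of every agent's own actions (labels joined with `|`, first
agent's component varying fastest, matching `poly_tensor()` pair labels),
while its observation set remains its own. The ensemble's joint interface
is the tensor of the agents' monomial boundaries
(`build_joint_interface()`).

Each step of `simulate_ensemble()`, every agent: observes through its
channel; infers by exact Bayes; predicts each companion's action
(`predict_other()`); marginalizes its joint-action $G$ over those
predictions; and samples its own action from
$\sigma(\ln E_{\mathrm{own}} - \gamma G_{\mathrm{own}})$. The world then
transitions on the realized joint action. The agent's next prior averages
its transition model over its predictions of the others, with its own
realized action held fixed — the agent knows what it did, not what the
others did.

Theory of mind is recursive with an explicit depth: at depth 0 a companion
is predicted from its habit alone; at depth $d$ its action selection is
simulated with depth-$(d-1)$ predictions of everyone else. Two assumptions
are fixed and documented rather than hidden:

* **Shared models**: agents hold veridical copies of one another's models.
  Misspecified theory of mind is representable (hand an agent any model
  you like) but is not part of the tested contract.
* **Common ground**: the predictor uses its own current posterior as its
  estimate of the companion's information state. With shared models and
  shared noiseless observations this is exact (and the tests assert the
  resulting beliefs never diverge); with private noisy channels it is the
  simplest defensible proxy.

`synchrony_trace()` reports, per step: mean pairwise symmetrized KL
between posterior beliefs; the mean log-score of each agent's predictions
of the others' realized actions (zero only for certain, correct
prediction); and the summed free energy — a group-level proxy whose
decline accompanies mutual predictability.

### The synchrony scenario and what it shows

`make_ensemble()` fixes the study conditions for the synchrony
experiments: a three-state world observed through one shared channel that
maps each state to a distinct preferred observation with probability 0.9
(each agent draws its own observation independently); sticky hidden
dynamics (`persistence = 0.7` toward staying put, because a world that
decorrelates every step leaves nothing for beliefs to converge on); and
initial priors that are the *only* thing differing between agents — each
peaked with mass 0.9 on a different state. Under these conditions two
agents' beliefs, divergent by construction at the start (pairwise KL
$\approx 1.1$), typically collapse onto each other within a few steps; the
median pairwise KL over a 100-step run is of order $10^{-3}$.

One measurement caveat is worth stating plainly. The *instantaneous*
pairwise KL at a fixed late step is a noisy statistic: with a 90%-accurate
channel, roughly one step in ten hands one agent a misleading observation
and the pair diverges sharply for a step before re-converging. A
single-snapshot comparison of step 100 against step 1 therefore fails in
roughly 15% of seeded runs even though the run-level synchronization is
unambiguous. The package reports both the snapshot statistic and the
run-median ratio; conclusions about synchrony should rest on the latter.

## 4. The sheaf layer

Agents' world models become comparable by indexing them over a shared
finite base space: a `cover()` assigns each agent a patch of sites, and a
`section()` holds one categorical vector per site of the patch.
Restriction maps are sub-indexing (identity on shared sites) — the minimal
faithful instance for finite covers; marginalization-style restrictions are
an extension point, not a tested feature.

* `disagreement()` quantifies the gluing obstruction as the summed squared
  Euclidean distance between owners' vectors over all overlapping pairs
  and shared sites. Squared Euclidean (not KL) is the energy because it
  decreases provably and monotonically under the consensus dynamics below;
  KL-based discrepancy remains available as a diagnostic in the per-pair
  breakdown.
* `check_gluing()` compares the maximum per-site total-variation
  discrepancy against a tolerance; total variation is the scale on which
  the fixtures' controlled perturbations are exact.
* `glue_sections()` builds the global section by per-site averaging
  (averages of normalized vectors are normalized; renormalization guards
  floating-point drift only), and restricting the result reproduces the
  local sections within tolerance.
* `consensus_step()` / `run_consensus()` implement synchronous mean
  diffusion: every owner of a site moves a fraction $\eta \in (0, 1]$
  toward the site's mean. Per site, the update contracts deviations from
  the mean by $(1 - \eta)$, so the energy trace is non-increasing and the
  two-agent single-site case decays geometrically by $(1-\eta)^2$ per
  step toward the renormalized midpoint — the closed form the tests check.
  No external consensus scheme is imported: the simplest provably
  convergent rule is canonical here.
* `validate_spatial_model()` enforces the one spatial constraint a
  site-indexed generative model must satisfy: zero likelihood mass on
  observations that cannot be made at a state's site.

The package's operationalization of *shared* anticipation is the
disagreement energy of sections built from agents' predictive beliefs over
a common base; no scalar "sharedness" index beyond this is defined,
because any such index would be an arbitrary compression of the
obstruction report.

## 5. Fixtures: what the generators emulate

All data are generated; nothing external is read.

* `random_model()` draws every table column from a symmetric Dirichlet
  (normalized gamma variates), so validity is guaranteed by construction
  and the concentration parameter moves smoothly between peaked and
  near-uniform tables.
* `make_tmaze()` builds the classic epistemic-foraging task: a junction,
  two absorbing arms (reward on one side, an aversive outcome on the
  other, determined by a latent context), and a cue site whose observation
  reveals the context with accuracy 0.98. Preferences are neutral
  everywhere except the arms (log-preferences $+3$ reward, $-4$ loss), so
  the cue's value is purely epistemic. Two non-obvious choices make the
  task sharp at depth 2: the *loss aversion* ($-4$ rather than $-3$) makes
  gambling on an unknown arm genuinely costly, and the cue site *bounces
  back* to the junction unless the agent commits to an arm, so the cue
  cannot be loitered at for repeated epistemic credit — a known pathology
  of marginal rollouts. Under these conditions exhaustive depth-2
  evaluation ranks cue-then-arm policies strictly below every policy that
  does not visit the cue first, by a margin of about 0.19 nats.
* `make_shared_world()` builds chained covers with controllable overlap
  and perturbs overlaps by an exact total-variation amount $\varepsilon$
  (mass $\varepsilon$ moved from the largest to the smallest coordinate),
  so gluing tolerances can be tested against a known ground truth.
  `perturb_sections()` instead mixes toward random vectors — identity at
  0, full replacement at 1, with energy non-decreasing in the weight.

What the generators do *not* emulate: learning of $A$/$B$ (no Dirichlet
updates), hierarchical or deep temporal models, misspecified or partially
shared models between agents, explicit communication channels, and
continuous state spaces. Results on these fixtures therefore show that the
inference, selection, and consensus machinery is correct and behaves as
the theory predicts on well-posed finite problems; they do not show
robustness to model misspecification or scale.

## 6. Problem sizes and tolerances

The shipped test suite exercises: 200-model sweeps for each free-energy
identity (tolerance $10^{-9}$; posterior optimality $10^{-10}$); the full
$\le 2$-position/$\le 2$-direction polynomial grid (216 triples) for the
currying law and 39 shapes for section counting; 20-seed, 100-step
ensemble runs for the synchrony experiments; 50 seeded consensus scenarios
for energy monotonicity ($10^{-12}$ slack); and exact (bit-identical)
reproducibility checks for every seeded generator and simulator. These
sizes were chosen so the entire suite completes in well under a minute on
a laptop while still exhausting the small combinatorial spaces involved.
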