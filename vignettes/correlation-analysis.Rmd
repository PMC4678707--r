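---
title: "Parameter correlation analysis for partially observed linear models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter correlation analysis for partially observed linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linident)
```

## The model and its assumptions

`linident` analyzes time-invariant linear state-space models

$$\dot{\mathbf x} = A\mathbf x + B\mathbf u, \qquad \mathbf x(0)=\mathbf x_0,
\qquad \mathbf y = C\mathbf x + D\mathbf u,$$

whose matrix entries are expressions in named rate parameters.  The
intended setting is compartment modelling: pools exchanging material at
first-order rates, driven by constant inputs, observed through a few
measured linear mixtures of the states.  Three assumptions frame every
statement the package makes:

* **Constant controls.** Each input is held at a constant value during an
  experiment.  An experiment ("dataset") is one initial condition plus one
  set of constant control values, observed as noise-free output time
  courses.
* **Noise-free data.** Identifiability verdicts are *necessary* conditions
  for estimation from real data: a parameter declared non-identifiable here
  cannot be recovered from any amount of perfect data, while a parameter
  declared identifiable may still be poorly determined once noise enters.
* **Time-invariant linear dynamics.** Bilinear terms with a constant input,
  such as a binding rate multiplied by a constant ligand concentration, can
  be absorbed into a single effective rate (the insulin-receptor fixture
  does exactly this with `p21u`); genuinely nonlinear kinetics are out of
  scope.

## From sensitivities to a finite linear system

Solving the state equation in the Laplace domain with the inverse written
as adjugate over determinant gives
$X(s) = \mathrm{adj}(sI-A)\,(B\,U(s) + x_0)/\Delta$ with
$\Delta = \det(sI - A)$.  The derivative of the output with respect to a
parameter splits into four blocks — through $A$ (via the state), through
$B$ (via the input), and directly through $C$ and $D$ — and every block
can be put over the single polynomial denominator $s^m\Delta^2$ ($m = 1$
when step inputs contribute a $1/s$).  The numerators, one polynomial
column vector $q_j(s)$ per parameter, are what the analysis works with:
linear dependence of sensitivities is unchanged by the common nonzero
scaling, so the denominator never needs to be tracked.

A dependence $\sum_j \alpha_j q_j(s) \equiv 0$ must hold coefficient by
coefficient in $s$, giving a homogeneous system $\beta\alpha = 0$ whose
entries are polynomials in the parameters and in the condition symbols
(the genericized nonzero entries of $x_0$ and $u$).  Everything the
package reports derives from the exact nullspace of this system over the
field of rational functions.

Two presentation conventions reduce the system before it is solved:

* **Common-factor cancellation.**  A polynomial factor shared by every
  entry of every column — typically the excitation factor $(U + x_{10})$
  or a spurious pole of an unreachable trap state — is divided out, since
  it cannot affect linear dependence.  The report records the cancelled
  factor.
* **Zero columns stay.**  A parameter whose column vanishes identically is
  simply unexcited by the design; it shows up as a one-parameter
  "group" with a free dependence weight.

## The input convention

The analysis treats each constant control as a free symbol $U$ rather
than substituting the literal step transform $u_0/s$
(`input_mode = "generic"`, the default).  The distinction matters: the
step transform carries the *extra knowledge that the input is exactly a
step*, which contributes one more coefficient row and can render a
correlation formally resolvable that is hopeless in practice.  In the
three-compartment two-path fixture with all initial states and the input
nonzero, the step convention yields a full-rank system whose smallest
singular value is five orders of magnitude below the rest — the direction
is resolvable only in infinite-precision arithmetic.  The generic
convention calls this case what it is: a practical non-identifiability
requiring two datasets.  Correlation statements in the compartmental
literature are written in the generic convention, and on the classic
benchmark cases the two modes agree (this is a test); `"step"` remains
available for studying exactly-known step inputs.

## Structural versus practical, and the dataset count

A correlated group is **structural** when its normalized nullspace vector
contains no condition symbols: the interrelationship holds whatever the
nonzero design values are, so no dataset of the same design can resolve
it.  It is **practical** when the vector depends on $x_0$ or $u$: datasets
generated under sufficiently different conditions impose independent
copies of the constraints, and stacking
$\lceil n_\max / n_y(2n_x-2) \rceil$ of them forces all $\alpha$ to zero
($n_\max$ = largest group size; $n_y(2n_x-2)$ is the bookkeeping
convention for the equations each dataset contributes when all correlated
parameters sit in $A$; the report also stores the empirically observed
independent row count, which can differ by one from the printed
convention).  `stacked_rank_check()` certifies any proposed condition set
numerically.

Classification combines the symbolic test with a two-draw re-randomization
of the condition symbols at fixed parameter values — a guard against
condition symbols that survive in unsimplified form but cancel
numerically.  Note that the classification is always *relative to the
zero pattern of the design*: in the trap-state fixture, the third rate is
structurally out of reach while $x_3(0)=0$, yet becomes identifiable the
moment the trap state is initially charged.  The same logic drives the
four-compartment example, where the five-parameter structural group under
$x_0 = 0$ dissolves entirely once every pool starts nonzero — one such
dataset then suffices (`datasets_for_unique_fit`).

For multi-output models, `output_correlations()` additionally analyzes
each output row alone.  The finer, single-output relations (for instance
the pairwise tie between the two elimination rates visible in the first
output of the four-compartment model) refine the joint picture and are
reported as minimal dependent sets (circuits) per output.  The joint
nullspace remains the authoritative object: relations that hold in one
output row need not annihilate the others, and the joint group can be
larger than any single-output relation suggests.

## Identifiable combinations

A function $\varphi(p)$ of the correlated parameters is estimable despite
the correlation exactly when its directional derivative along every
nullspace vector vanishes — a homogeneous linear first-order PDE.  The
package solves it with a polynomial ansatz: all monomials of total degree
up to `max_degree` (default 3) in the group parameters, with rational
constant coefficients.  After clearing the rational entries of the basis
vectors, the invariance condition becomes an exact linear system over
$\mathbb{Q}$, solved by rational row reduction.  The solution space is
then reduced to a canonical generating set:

1. candidates are reduced modulo products of already-selected invariants
   (so `p2*p3` is preferred over `p2*p3 + (p1+p2)^2`);
2. remaining candidates are ordered by total degree, then term count, then
   lexicographically;
3. a candidate is accepted only if it increases the numeric Jacobian rank
   of the selected set, until $k - r$ independent invariants are found
   (group size $k$, nullspace dimension $r$).

The ansatz finds *local* invariants — functions constant along the flow of
the dependence field.  The estimable quantities visible to a fitting
routine can be coarser: in the two-path three-compartment model the sums
of the two exit-rate pairs are each locally invariant, but the global
solution set of the fitting problem contains a second branch with the two
sums exchanged (their sum and product are fixed, so they are the two roots
of one quadratic).  A refit scan shows the two branches as two separated
point clouds.  The package reports the local generating set and leaves
branch bookkeeping to the scan; symmetric functions of the pair are
branch-free.

Degree-3 is sufficient for every published combination in the bundled
fixtures; the ansatz caps at a configurable monomial count and signals
rather than grinding when a group is too large.

## The exact kernel and its escape hatches

No computer-algebra dependency is used: the package carries an exact
sparse multivariate polynomial kernel (rational coefficients held as
numerator/denominator pairs in doubles, exact up to $2^{53}$; canonical
graded-lexicographic form; overflow aborts rather than rounding).  On top
of it sit rational functions in lowest terms, cofactor determinants and
adjugates, and the nullspace machinery.  Three design choices keep the
exact path fast:

* **Support restriction.**  The nullspace support is located first by
  seeded numeric evaluations (two draws, uniform on $[0.5, 2]$, default
  seed 20151214, rank threshold $10^{-10}$ relative); exact elimination
  then runs on the support columns only.
* **Fraction-free elimination.**  Gaussian elimination in the
  Bareiss/Montante form — every update is
  $(\text{piv}\cdot row - \text{entry}\cdot row_{piv})/\text{piv}_{prev}$
  with the division provably exact — keeps entries the size of minors
  instead of growing multiplicatively, with fewest-terms pivoting.
  Rational functions appear only in the final back-substitution.
* **gcd projection probes.**  Multivariate gcds (for cancellation and for
  keeping rational functions reduced) first project both inputs to one
  shared random-point univariate image per candidate variable; variables
  whose projected gcd is constant cannot occur in the true gcd, and in
  the overwhelmingly common coprime case the full recursive Euclid is
  skipped entirely.  All probes use fixed small integer points, so results
  are deterministic; a probe can only over-estimate, never fabricate, a
  factor.

When a system is both large and condition-dependent (the practical cases,
where entries mix ten or more symbols), the exact elimination is not worth
forcing: the nullspace is then characterized numerically, with the
structural/practical decision taken by comparing canonicalized numeric
bases across two condition draws — precisely the re-randomization test.
Such vectors are flagged, printed as numbers, and excluded from the
symbolic combination search.  Every bundled structural case stays on the
exact path.

## Numerical verification

* **Simulation** uses the matrix exponential of the augmented system
  $[A, Bu_0; 0, 0]$, exact for constant inputs, with one exponential per
  distinct time step (uniform grids need a single one).
* **Fitting** is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
  bounds $[10^{-6}, 10^3]$, function/step tolerances $10^{-12}$, up to 5
  seeded log-normal multi-starts.
* **Refit scans** fix one parameter at a sweep of values and warm-start
  each fit from the previous solution; rows whose residual ends far above
  the best row are re-fitted from the best neighbouring solution, which
  removes cold-start artefacts deterministically.
* **Sweep feasibility.**  A scan only makes sense where the correlation
  manifold has real, positive solutions.  Fixing the level sets of the
  invariants typically leaves a quadratic whose discriminant bounds the
  sweep: in the two-compartment model, case 1 requires the swept rate
  below 0.9 (one exit rate hits zero there) and case 2 requires it above
  0.45; in the four-compartment model the swept rate must stay above
  about 3.26.  The bundled scans sweep inside these regions.
* **The finite-difference rank oracle** (`fd_sensitivity_rank`, central
  differences, relative step $10^{-6}$) stacks time-domain output
  sensitivities and takes the numeric rank — a completely Laplace-free
  check that agrees with the symbolic nullspace dimension on every fixture
  and on seeded random models.

Default time grids for the fixtures: 100 points on $[0,10]$ for the
two-compartment model, 400 points on $[0,2]$ for the three-compartment
model (its published grid), 200 points on $[0,5]$ for the four-compartment
model, and around 120 points on $[0,12]$ for the insulin receptor model —
each spanning the dominant time constants at the fixture's rate values.
The test suite scales scans to 4–10 sweep points; the acceptance script
uses 5–6.  These sizes were chosen once as desk-scale defaults and are
caller-overridable.

## The random model generator

`random_compartment_model()` draws sparse first-order exchange networks:
a guaranteed transfer chain through all pools plus random extra transfers
(probability 0.3 each), one elimination path, a single input into pool 1,
identity observation of a chosen state subset, and true rates uniform on
$[0.5, 2]$ — the plausible-magnitude regime for the bundled fixtures.  It
emulates the *structure* that makes partial observation interesting
(sparse exchange, few outputs) and is used to property-test the analysis
against the finite-difference oracle.  It does not emulate measurement
noise, irregular sampling, time-varying inputs, model misspecification, or
wide rate scales; passing tests therefore certify the symbolic-numeric
machinery, not robustness of estimation on laboratory data.

## Known limitations

* Linear time-invariant models only; no SBML import; no reparameterization
  suggestions beyond the combination list.
* The practical-identifiability notion is the noise-free necessary
  condition; it says nothing about variance or estimability under noise.
* Exact arithmetic lives in 53-bit integers: enormous mixed systems fall
  back to the (clearly flagged) numeric characterization instead of
  exact basis vectors.
* Combination search is restricted to polynomial invariants of total
  degree at most 4; rational or transcendental invariants are not sought.
* Groups are reported as supports of exact dependence relations of the
  joint system.  Published per-output shorthand for multi-output models
  can suggest a finer decomposition than the joint algebra supports; the
  per-output view is available separately and the joint report is the
  one backed by the rank computations.
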