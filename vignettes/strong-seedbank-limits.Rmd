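---
title: "Strong seed banks and their separation-of-timescales limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strong seed banks and their separation-of-timescales limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedbanklim)
```

## The model

Many microbial populations maintain a *seed bank*: a reservoir of dormant
individuals that do not reproduce but may resuscitate much later.  When
dormancy periods are on the order of the population size (the coalescent
timescale), the frequency $(X(t), Y(t))$ of an allele in the active and
dormant sub-populations follows the **seed bank diffusion**

$$
\mathrm{d}X = c\,(Y - X)\,\mathrm{d}t + \sqrt{X(1 - X)}\,\mathrm{d}B,
\qquad
\mathrm{d}Y = Kc\,(X - Y)\,\mathrm{d}t,
$$

with $c > 0$ the switching (migration) rate between the two pools and
$K > 0$ the ratio of active to dormant population size.  Genetic drift acts
only on the active pool; the dormant pool is a noiseless memory relaxing
towards the active frequency.  Its genealogy is the **seed bank
coalescent**, whose block-counting process $(N(t), M(t))$ (active, dormant
ancestral lineage counts) is the Markov chain with conservative rates

* $(n,m) \to (n-1,m)$ at $\binom{n}{2}$ — coalescence of two active lines,
* $(n,m) \to (n-1,m+1)$ at $cn$ — a line initiates dormancy,
* $(n,m) \to (n+1,m-1)$ at $cKm$ — a dormant line resuscitates,

with the convention $\binom{n}{2} = 0$ for $n \le 1$, and dormant lines
never coalescing.  Forward and backward descriptions are linked by
**moment duality**,

$$
\mathbb{E}^{x,y}\!\left[X(t)^n Y(t)^m\right]
 = \mathbb{E}_{n,m}\!\left[x^{N(t)} y^{M(t)}\right],
$$

which this package exercises relentlessly: every simulator is checked
against an exact matrix-exponential computation on the dual side.

The **two-island** generalisation allows coalescence on the second island
at scale $\alpha' \binom{m}{2}$ (and scales the first island by $\alpha$);
the seed bank model is the special case $\alpha = 1$, $\alpha' = 0$.

## The super-evolutionary regime

Endospores can stay dormant for periods that are orders of magnitude
longer than the coalescent timescale.  That regime is reached by letting
$c \to 0$ while speeding time up by $1/c$.  On this *super-evolutionary*
clock, reproduction — and with it genetic drift and coalescence — acts
instantaneously, and the limits are degenerate in an interesting way:

* **Backward in time**, the block-counting chain converges (in
  finite-dimensional distributions) to the *ancient ancestral lines
  process*: all active lines coalesce instantly into at most one, after
  which dormancy and resuscitation drive the dynamics.  Its semigroup is
  the non-standard
  $$\Pi(t) = P e^{tG}, \quad t > 0, \qquad \Pi(0) = \mathrm{Id},$$
  where $P$ is the projection collapsing $(n, m) \mapsto (1, m)$ for
  $n \ge 1$ and $G$ satisfies $PG = GP = G$ but is *not* a rate matrix: it
  carries negative off-diagonal entries in rows that $P$ collapses.
  `build_aalp()` constructs the pair $(P, G)$; `aalp_semigroup()`
  evaluates $\Pi(t)$.  Note $\Pi(0^+) = P \ne \Pi(0)$: the semigroup is
  not standard, which is the signature of a separation of timescales.

* **Forward in time**, the rescaled diffusion converges to a
  **piecewise-deterministic jump process**: $X$ lives on $\{0, 1\}$
  (the active population is always momentarily fixed), flipping from 0 to
  1 at rate $Y(t)$ and from 1 to 0 at rate $1 - Y(t)$, while between
  flips $Y$ relaxes exponentially, $\mathrm{d}Y = K(X - Y)\,\mathrm{d}t$.
  At time $0^+$ the process jumps from a general start
  $(x, y) \in [0,1]^2$ to $X = 1$ with probability $x$ — the fixation
  probability of the instantaneous Wright–Fisher sweep.

* In the **imbalanced two-island** regime ($\alpha'$ decaying like $c$),
  island 1 coalesces instantaneously while island 2 keeps genuine
  migration, coalescence and (forward in time) genetic drift: the backward
  limit generator gains $\binom{m}{2}$ terms
  (`build_imbalanced_limit()`), the forward limit an extra
  $\tfrac12 y(1-y)\partial_y^2$ term (`simulate_limit_jumpdiffusion()`).

## The generic limit engine

The package separates the *machinery* from the *model*.  For any
continuous-time chain observed every $1/a$ time units, sped up by $b$:

1. `discretise(Q, a)` computes the one-step matrix $\Pi_a = e^{Q/a}$
   **exactly** (scaled Padé), not by the first-order probability
   expansion.  The expansion survives as a test assertion — entries agree
   with $\binom{n}{2}c^2$ etc. up to the expansion's own remainder — but
   the engine itself carries no uncontrolled error term.
2. `decompose(Pi, mask, b)` splits $\Pi_a = A + B/b$ along an explicit
   *fast-transition mask*.  The mask is an input, not inferred from entry
   magnitudes, so the engine is reusable for other models; the seed bank
   preset (`seedbank_fast_mask()`) flags coalescence moves
   $(n,m) \to (n-1,m)$ for $n \ge 2$ plus the diagonal.  The restriction
   to $n \ge 2$ matters: a single active line cannot coalesce, and the
   exact discretisation puts a genuine (tiny, higher-order, multi-jump)
   probability on $(1,m) \to (0,m)$ that belongs on the slow timescale.
   Flagging it as fast would let the powers of $A$ leak mass out of the
   $n = 1$ states and blur the projection.
3. `extract_projection(A, a)` computes $A^{\lceil C a\rceil}$ over a grid
   of constants $C$ by binary exponentiation, snaps the stabilised power
   to $\{0, 1\}$, and reports the decay of $\lVert A^r - P\rVert$ in the
   maximum-absolute-row-sum norm.  For the seed bank fast matrix the decay
   obeys the Markov-inequality bound $2(n_0 - 1)/C$.
4. `limit_generator(P, ...)` forms $G = \lim P B P$.  Two routes are
   offered: the exact product $P B_\infty P$ with the closed-form limit
   $B_\infty$ (`seedbank_B_limit()`, `structured_B_limit()`), which
   reproduces the limit generators *entrywise exactly* (the entries are
   integers and multiples of $K$; no rounding is involved), and a Cauchy
   diagnostic on a supplied schedule.  The Cauchy gaps decay like $c$, so
   at desk-scale schedule endpoints ($c \ge 0.005$) the diagnostic is run
   at a matched tolerance; the exact route is the one used for all
   identities.
5. `degenerate_semigroup(P, G, t)` evaluates $P e^{tG}$ and
   `check_exit_rate_ratio()` verifies that the maximal exit rate over the
   discretisation scale, $q/a$, shrinks along the schedule — the condition
   under which the discretised limit carries back to continuous time.

The double limit (first the schedule, then $C$) that defines the
projection can only ever be sampled on a finite grid; the shipped
diagnostics are finite-grid surrogates and say so in their documentation.

### State-space conventions

State spaces are the full grids $\{0, \dots, n_0+m_0\}^2$, enumerated
row-major in $n$ then $m$, including unreachable states — the bijective
indexing is worth the wasted rows.  Two boundary subtleties follow from
windowing an infinite-state definition onto a finite grid:

* Rows $(n \ge 1,\ m = n_0+m_0)$ of $G$ lose their out-of-grid dormancy
  move and are substochastic under $\Pi(t)$.  They are unreachable from
  any start with $n + m \le n_0 + m_0$; all reachable rows are probability
  vectors to $10^{-10}$ or better.
* The reduced chain on $\{0,1\} \times \{0,\dots,m_{\max}\}$
  (`build_reduced_chain()`) keeps the printed diagonal $-n - Km$
  everywhere and drops the dormancy move out of the cap, exactly
  mirroring the full-grid windowing.  This makes the restriction identity
  — restricted $P e^{tG}$ equals $e^{t\bar G}$ — hold to machine
  precision on the *entire* window, at the price of one substochastic,
  unreachable row $(1, m_{\max})$.  With the default cap
  $m_{\max} = m_0 + 1$ (the support bound of the limit process) that row
  is never entered from the canonical starts.

## Simulation schemes and numerical choices

**Jump chains.**  `gillespie_simulate()` draws exponential holding times
from the off-diagonal row sums and picks targets proportionally to rates;
it is exact, and its time marginals are tested against the matrix
exponential in total variation.

**Diffusions.**  `simulate_seedbank_sde()` and `simulate_twoisland_sde()`
use Euler–Maruyama in the interior and a *moment-matched two-point
increment* near the boundaries.  The obvious truncate-and-clamp scheme
(clamp the state to $[0,1]$ after a Gaussian step) fails here in an
instructive way: the square-root noise puts the boundary layer at scale
$x \sim \mathrm{d}t$, so in layer units the clamped chain is a unit-step
Euler scheme *independent of* $\mathrm{d}t$ — the clamping bias per unit
time never vanishes as the step shrinks, and on the stretched
super-evolutionary horizon it visibly distorts the flip rates of the
limit (we measured a conservation-law violation of $\approx 0.02$ per
ten time units that was flat across $\mathrm{d}t \in [2.5\times10^{-5},
4\times10^{-4}]$).  Instead, whenever the proposed mean $\mu$ sits
within four conditional standard deviations of a boundary, the increment
is drawn from the two-point law on $\{0,\ \mu + \sigma^2\mathrm{d}t /
\mu\}$ (mirrored at 1) that matches the conditional mean and variance
exactly.  Matching the mean preserves the martingale structure that
determines fixation probabilities, which is precisely what the limit
dynamics are made of; with this scheme the rescaled moments converge
onto the jump-process values and the conservation law holds to Monte
Carlo accuracy.  The corners $(0,0)$ and $(1,1)$ remain exactly
absorbing.  Residual weak bias away from the boundary is the ordinary
first-order Euler error; the duality pass tolerance
$4\,\mathrm{SE} + C_{\text{bias}}\,\mathrm{d}t$ with
$C_{\text{bias}} = 1$ (calibrated once by a step-halving study) covers
it at the default $\mathrm{d}t = 10^{-3}$, which is exposed everywhere
for refinement studies.  The inner loop is compiled; each replicate
draws from its own counter-seeded stream (`seed + replicate`), so a
single integer seed fixes every path regardless of execution order, and
a silent second island ($\alpha' = 0$) reproduces the seed bank
simulator path for path.

**The limit jump process.**  Because $Y$ relaxes exponentially between
flips, the cumulative flip hazard is available in closed form: with
initial hazard $h_0 = |y - \bar x|$ the total remaining hazard is
$h_0/K$, so an $\mathrm{Exp}(1)$ variable either exhausts it (the path is
absorbed and evaluated analytically ever after) or inverts to an exact
jump time.  `simulate_limit_pdmp()` therefore has *no discretisation
error*, which is why the limit duality tests carry no bias allowance.
The full-grid matrix $G$ is never used to drive simulation — its negative
off-diagonal entries are not rates — only inside matrix exponentials; the
paths come from the reduced chain (backward) or the hazard inversion
(forward), with the initial projection applied at $0^+$.  At $t = 0$ all
simulators report the raw initial state, mirroring $\Pi(0) = \mathrm{Id}$
versus $\Pi(0^+) = P$.

**The limit jump-diffusion.**  Only here (diffusive $Y$) is thinning
used: per-step flip probability $\lambda\,\mathrm{d}t$ with
$\lambda \in \{y, 1-y\}$, rejected outright when
$\mathrm{d}t \cdot \max\lambda \ge 0.1$.

**Verification policy.**  Monte-Carlo checks pass at
$|\hat\theta - \theta| \le 4\,\mathrm{SE}$ (two-sided false-alarm rate
$\approx 6\times10^{-5}$ per cell, under 1% across the full grids), with
fixed seeds.  Convergence metrics along a schedule allow at most one
inversion within twice the sampling noise floor, to keep the checks
sharp without being brittle.  Total-variation distances are computed on
the full finite state space — no binning.

## What the experiments emulate, and what they do not

The convergence experiments
(`convergence_experiment_backward()` / `_forward()`) re-enact the limit
theorems at desk scale: schedules $c \in \{0.2, 0.05, 0.01\}$, time
$t = 1$ on the rescaled clock, $10^4$ jump-chain replicates and
$5 \times 10^3$ diffusion replicates with $\mathrm{d}t = c \times
10^{-3}$ (the step shrinks with $c$ so the bias per unit of *rescaled*
time stays constant).  These sizes were chosen so the sampling noise
($\sim 10^{-2}$ in TV at $10^4$ replicates) sits well below the signal
and each experiment completes in minutes on one core.  The theory
guarantees convergence of finite-dimensional distributions with no rate
in $c$; the schedule endpoints and acceptance bands are engineering
choices, recorded in the tests.

The synthetic inputs are exactly the model's own objects — there is no
external data in this problem, and the fixture generator
(`generate_fixtures()`) emits small parameter grids
($(n_0, m_0) \in \{(1,1), (2,2), (3,3)\}$, $K \in \{0.5, 1, 2\}$,
$c \in [0.01, 1]$) of the canonical matrices.  Passing tests therefore
certify the implementation against the model's mathematics, not the
model against biological data: real microbial seed banks have
age-dependent resuscitation, environmental (simultaneous) switching and
selection, all outside this model class.

## Known limitations

* Only block (lineage) counts are modelled; partition-valued coalescents,
  tree topologies and mutation are out of scope, as are site-frequency
  statistics for the limit genealogy.
* Convergence statements are about marginals and moments
  (finite-dimensional distributions).  Path-space weak convergence fails
  in the usual topologies — the prelimit paths are continuous, the limit
  jumps — and is not tested.
* The Euler–Maruyama boundary scheme is first-order and its bias near
  absorbing corners is controlled empirically, not analytically; users
  probing tail functionals should run their own $\mathrm{d}t$ refinement.
* `extract_projection()` certifies stabilisation only on the supplied
  grid of constants; a chain with metastable states slower than the
  largest $C$ would need a larger grid.

## A compact worked example

```{r example, eval = FALSE}
library(seedbanklim)

# backward: exact degenerate semigroup of the limit genealogy
a <- build_aalp(sample_config(2, 2), K = 1)
Pi1 <- aalp_semigroup(a, 1)
Pi1["(2,2)", c("(1,1)", "(0,2)", "(1,2)")]

# forward: exact jump-process simulation, checked by duality
set.seed(1)
duality_check_limit(n = 1, m = 1, start = c(0.3, 0.7), K = 1, t = 1,
                    reps = 1e4)

# prelimit-to-limit convergence in total variation
set.seed(1)
convergence_experiment_backward(sample_config(2, 2), K = 1,
                                scaling_schedule(c(0.2, 0.05, 0.01)),
                                t = 1, reps = 1e4)
```
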