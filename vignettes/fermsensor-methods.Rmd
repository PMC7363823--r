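---
title: "Soft-sensor modelling with multi-output LSSVMs and cuckoo-search tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-sensor modelling with multi-output LSSVMs and cuckoo-search tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermsensor)
```

## The problem

In fed-batch fermentation the variables that actually describe the state of
the culture — cell concentration $X$, substrate concentration $S$ and
product concentration $P$ (all g/L) — cannot be measured online. They are
assayed offline every couple of hours, while easily measured auxiliary
signals (temperature, pH, stirrer speed, dissolved oxygen, glucose feed
rate, ammonia feed rate, air flow) stream in every few minutes. A *soft
sensor* is a regression model that maps the auxiliary signals to the
concentrations, so that all three state variables become available in real
time. Because the three outputs are strongly coupled — substrate is
consumed as cells grow, and product formation tracks growth — a
multi-output regressor that shares information across outputs is the
natural model class.

## The multi-output least-squares SVM

A single-output LSSVM replaces the SVM's inequality constraints by
equalities with squared slack, so training reduces to one linear system.
The multi-output extension keeps one weight vector per output but
decomposes it as $w_t = w_0 + v_t$: a mean vector $w_0$ shared by all
outputs (the correlation carrier) and per-output contrasts $v_t$. With
slack penalty $\gamma$ and contrast penalty $\lambda$ the KKT conditions
give the block system

$$\begin{pmatrix} 0 & P^T \\ P & H \end{pmatrix}
  \begin{pmatrix} b \\ \alpha \end{pmatrix} =
  \begin{pmatrix} 0_m \\ y \end{pmatrix},
\qquad
H = \Omega + \gamma^{-1} I_{ml} + \tfrac{m}{\lambda} Q ,$$

where $K$ is the RBF Gram matrix of the $l$ training inputs
($k(x,x') = \exp(-\lVert x - x'\rVert^2 / 2\sigma^2)$), $\Omega$ tiles $K$
in every $l \times l$ block, $Q = I_m \otimes K$, $P$ is the block
indicator of the $m$ bias terms, and $y$ stacks the output columns.
Targets and dual coefficients are stacked *output-major*
($y = (y_1^T,\dots,y_m^T)^T$); this matches the block structure of $P$ and
is fixed throughout the package. Predictions combine a term shared across
outputs with a per-output contrast term:

$$\hat y_t(x) = \sum_j \Big(\sum_i \alpha_{ij}\Big) k(x, x_j)
  + \tfrac{m}{\lambda} \sum_j \alpha_{jt}\, k(x, x_j) + b_t .$$

Two identities follow from the KKT conditions and are asserted all over
the test suite: each column of the dual matrix $A$ sums to zero, and the
training residual equals $A/\gamma$. With $m = 1$ and
$\lambda \to \infty$ the model collapses to the single-output LSSVM with
$g = \gamma$, which the package keeps as `lssvm()` for limit checks.

### Solving the system

The saddle-point system is solved by the standard positive-definite
two-stage route: $H\eta = P$, $Hv = y$, $S = P^T\eta$,
$b = S^{-1}\eta^T y$, $\alpha = v - \eta b$. Rather than factorizing the
full $ml \times ml$ matrix, `mlssvm()` exploits the Kronecker structure
$H = (1_m 1_m^T)\otimes K + \gamma^{-1}I + \tfrac{m}{\lambda} I_m\otimes
K$: an orthogonal change of basis across outputs (eigenbasis of
$1_m 1_m^T$) block-diagonalizes $H$ into one block
$(m + m/\lambda)K + \gamma^{-1}I$ and $m-1$ identical blocks
$(m/\lambda)K + \gamma^{-1}I$. Two $l \times l$ Cholesky factorizations,
computed once and reused for every right-hand side, therefore replace one
$(ml)^3$ factorization — a factor $\sim m^3/2$ saving that the
cross-validated tuning loop repays thousands of times over. The explicit
assembly (`assemble_mlssvm_system()`) and the full-matrix solve
(`solve_mlssvm()`) are retained, and the test suite checks all routes
against a plain dense LU solve of the saddle-point system.

Numerical choices worth stating:

* Kernel distances use the squared-Euclidean expansion; square Gram
  matrices are symmetrized and given an exact unit diagonal.
* No jitter beyond $\gamma^{-1}I$ is ever added. If Cholesky fails, the
  error is surfaced; silently regularizing would deform the objective
  landscape seen by the hyperparameter search.
* At extreme hyperparameters (e.g. $\gamma = 2^{15}$) the system's
  condition number reaches $\sim 10^8$ while $|\alpha|$ grows like
  $\gamma$; any double-precision solve then carries a forward error far
  above what the backward error suggests. The `refine` argument applies
  iterative refinement with compensated residuals (Dekker two-products
  with long-double accumulation), which polishes solutions to near machine
  accuracy; it materializes the full system and is meant for moderate $l$,
  e.g. solver-agreement studies. The default fit path leaves `refine = 0`:
  cross-validation fitness does not need twelve digits.

## Hyperparameter tuning by improved cuckoo search

The model has three hyperparameters — $\gamma$, $\lambda$, $\sigma$ — and
its accuracy is sensitive to all of them. They are tuned by minimizing a
leave-one-batch-out cross-validation objective over the continuous
log2-boxes $\gamma \in [2^{-5}, 2^{15}]$, $\lambda \in [2^{-10}, 2^{10}]$,
$\sigma \in [2^{-15}, 2^{3}]$ (the conventional grids read as range
statements; the metaheuristics search the boxes continuously, in exponent
coordinates, dimension 3). Cross-validation is at the *batch* level:
within a batch the ~15-min samples are strongly autocorrelated, so
leave-one-sample-out would leak and grossly flatten the objective. The
objective is the plain sum of squared errors on the normalized scale, so
the three outputs contribute comparably; a failed factorization during a
fold contributes a large finite penalty ($10^{12}$) rather than an
exception, so the search continues across degenerate regions.

Cuckoo search perturbs a population of candidate "nests" with
Lévy-flight steps (heavy-tailed, tail exponent $\mu = 1.5$, drawn by
Mantegna's algorithm), accepts proposals greedily against randomly chosen
nests, abandons nests at a discovery probability, and preserves the best
nest (elitism), so the best-so-far fitness trace is non-increasing by
construction. The *improved* variant makes the two fixed constants
iteration-adaptive over $N_i = 0,\dots,N_{max}$:

$$p_a(N_i) = p_{a,max} - \tfrac{N_i}{N_{max}}(p_{a,max} - p_{a,min}),
\qquad
\alpha(N_i) = \alpha_{max} e^{k N_i},\quad
k = \tfrac{1}{N_{max}}\ln\tfrac{\alpha_{min}}{\alpha_{max}} .$$

The step-size exponent is written here with the *decay* sign convention:
the schedule starts at $\alpha_{max}$ and shrinks to $\alpha_{min}$, which
is what an exploration-then-refinement schedule intends (the growth
variant is available behind `literal_step_growth` for comparison).
Defaults follow the published practice for this algorithm family:
$n = 24$ nests, $N_{max} = 150$, $p_{a,max} = 0.5$, $p_{a,min} = 0.05$,
$\alpha_{max} = 0.5$, $\alpha_{min} = 0.01$, $\mu = 1.5$. Per-dimension
steps are scaled by the box width so the search is unit-free; boundary
handling is clipping; ties keep the incumbent. Nest abandonment follows
the convention that a nest is replaced when a uniform draw *exceeds*
$p_a$, and the elite nest is never abandoned. All nests emit a proposal
each iteration (a literal one-cuckoo-per-iteration reading is available
via `single_cuckoo`). Standard CS (`mode = "standard"`) uses the textbook
fixed discovery probability 0.25 and a fixed step equal to
$\alpha_{max}$ — precisely the large-fixed-step regime whose slow late-
stage convergence the adaptive schedule addresses. Textbook global-best
PSO and a real-coded GA are included as comparison baselines; they run
$2N_{max}$ iterations so that every optimizer spends the same evaluation
budget $n(2N_{max}+1)$.

Model "correction" with validation batches is implemented as *model
selection*: the distinct per-iteration best hyperparameters from the
tuning trace are re-scored on the validation batches and the winner is
kept. Nothing is re-tuned against validation data, and test batches are
never seen by the normalizer, the objective, or the selection step.

## The synthetic campaign

No public fermentation campaign with this exact sampling design exists,
so the package ships a simulator whose *structure* matches the field's
practice: 72-h batches, auxiliary inputs every 15 min (289 points),
offline assays every 2 h (37 points) spline-resampled onto the fine grid.
The dynamics are a Monod / Luedeking–Piret fed-batch model —

$$\mu = \mu_{max}\tfrac{S}{K_s + S},\quad
\dot X = \mu X - \tfrac{F}{V}X,\quad
\dot S = -\tfrac{\mu X}{Y_{xs}} - m_s X + \tfrac{F S_{feed}}{V} - \tfrac{F}{V}S,$$
$$\dot P = (\alpha_p \mu + \beta_p) X - \tfrac{F}{V}P,\quad \dot V = F$$

— integrated with fixed-step RK4 on the 15-min grid (deterministic by
construction; stiffness is mild at these rates). Default kinetics
($\mu_{max} = 0.12\,h^{-1}$, $K_s = 0.3$, $Y_{xs} = 0.45$, $m_s = 0.01$,
$\alpha_p = 0.9$, $\beta_p = 0.015$, $S_{feed} = 400$ g/L, $X_0 = 0.8$,
$S_0 = 25$ g/L, $V_0 = 50$ L) are conventional magnitudes for an
amino-acid producer chosen once so that substrate depletes and product
accumulates within 72 h; they are synthetic values, not measurements.
Auxiliary channels are smooth transforms of the state plus sensor noise
(dissolved oxygen dips with the uptake proxy $\mu X$ and with biomass, pH
is regulated near 7 with excursions tied to growth and ammonia feed,
temperature sits near 30 °C, stirrer/air/feed profiles are piecewise
constant). Crucially, noise enters the measurement chain the way it does
in a plant: assay noise is added to the 2-h lab samples *before* the
spline resampling, so the training targets carry interpolated assay
error, not i.i.d. noise. Campaigns jitter initial conditions and profiles
batch-to-batch (default 10 batches, ±5%).

The spline dialect is Forsythe–Malcolm–Moler (`stats::spline`,
`method = "fmm"`): its non-natural end conditions reproduce cubic
polynomials exactly, which pins the interpolation step down to a testable
contract. Interpolated concentrations are clamped at zero, since a cubic
can undershoot near depletion.

What passing tests on this simulator do *not* show: real broths have
unmodelled oxygen-transfer limits, pH-control dynamics, assay biases and
sensor drift; the synthetic auxiliary channels are more informative about
the state than a real plant's may be. Results here demonstrate that the
pipeline recovers a nonlinear MIMO mapping under realistic sampling and
noise structure — not that any particular accuracy carries over to a
specific industrial process.

## Study sizes and reproducibility

The default end-to-end study uses a 10-batch campaign split 6/2/2
(train/validation/test), tuning-time fits on every 4th grid point
(30-min spacing) with the final refit on the full grid, and a reduced
search budget of 12 nests × 30 iterations for desk-scale runs; the
optimizer comparison repeats the whole build over ≥10 seeds per optimizer
at matched budgets and compares median test RMSE. All randomness flows
from explicit seeds — batch seeds derive from one campaign master seed,
each optimizer run takes its own seed — and the whole pipeline is
bit-reproducible, which the test suite asserts by running it twice.

Known limitations: exact-kernel training scales as $O(l^2)$ memory and
$O(l^3)$ time, so multi-campaign training sets need subsampling (no
sparse approximation is provided); the model is static (no recursive
update during a running batch); and metrics are honest only on held-out
*batches* — within-batch interpolation accuracy is much higher and should
not be quoted. One structural feature of the simulator deserves emphasis:
while Monod growth is saturated ($S \gg K_s$) the growth rate — and hence
every auxiliary channel — is insensitive to the substrate level, so in
the high-substrate phase $S$ is only weakly identifiable from the inputs
and its held-out RMSE sits on a generalization floor set by the
batch-to-batch variation of $S_0$, largely independent of the
hyperparameters. Optimizer comparisons on the substrate output are
therefore near-ties around that floor, whereas the cell and product
outputs separate the tuners clearly. Real plants share this blind spot
(it is precisely why substrate is hard to soft-sense), but quantitative
orderings on $S$ should be read with that floor in mind.
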