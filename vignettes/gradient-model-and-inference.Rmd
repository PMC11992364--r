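---
title: "Modeling and inferring surface pheromone gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inferring surface pheromone gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pherograd)
```

## The physical picture

A monolayer of yeast cells sits on glass under a thick agarose gel.
MATalpha emitter cells secrete alpha-factor at rate $r$ per cell; the
peptide diffuses through the gel with coefficient $D$ and is removed
almost exclusively by receptor-mediated uptake into MATa receiver cells
(a *bar1∆* background removes enzymatic degradation). Because production
and uptake both happen only at the cell layer, the steady state of

$$\partial_t c = D \nabla^2 c + r\rho_\alpha\,\delta(z)\,P(x) -
  \Omega \rho_A\,\delta(z)\,c$$

is a pure diffusion problem in the gel bulk with a reactive boundary at
$z = 0$. Here $\rho_\alpha, \rho_A$ are emitter/receiver surface
densities (cells/µm²), $\Omega$ (µm³/s) is the per-cell uptake strength,
and $P(x)$ is the production indicator — in the half-domain assay,
illumination restricts production to $x < 0$.

Two derived combinations carry all the physics visible in the data:

* the **decay length** $\lambda = D/(\Omega\rho_A)$ (µm), and
* the **far-field concentration** $c_{far} = r\rho_\alpha/(\Omega\rho_A)$,
  reported in EC50 units as $C = c_{far}/\mathrm{EC}_{50}$.

On the surface the half-domain steady state has the closed form
implemented by `source_profile()`,

$$f(x) = \Theta(-x) + \frac{\cos(x/\lambda)}{\pi}\,\mathrm{sign}(x)
  \Big(\frac{\pi}{2} - \mathrm{Si}\big(\tfrac{|x|}{\lambda}\big)\Big) +
  \frac{\sin(x/\lambda)}{\pi}\,\mathrm{Ci}\big(\tfrac{|x|}{\lambda}\big),
  \qquad c(x) = c_{far}\, f(x),$$

with three structural properties the package tests enforce at machine
precision: $f(x) + f(-x) = 1$ (so $c(0) = c_{far}/2$ exactly), a
monotone decrease across the border, and the heavy algebraic tail
$f(x) \to \lambda/(\pi x)$ — a direct consequence of quasi-2D diffusion
over an absorbing plane, and much longer-ranged than the exponential
decay familiar from one-dimensional morphogen models.

```{r profile}
sh <- gradient_shape(lambda = 735, C = 1.45)
x <- seq(-2500, 2500, by = 25)
plot(x, concentration(x, sh, "source"), type = "l",
     xlab = "x (um)", ylab = "c (EC50 units)")
abline(v = 0, lty = 3)
```

### Trigonometric integrals

`si_ci()` evaluates Si/Ci with the defining power series for $u \le 4$
and, for $u > 4$, a modified-Lentz continued fraction for the
exponential integral $E_1(iu)$, giving machine-precision accuracy over
the whole axis and vectorized speed. The joint fit evaluates the profile
at every bin center for every optimizer step — on the order of $10^6$
Si/Ci calls per recovery experiment — which is why the primitive is
implemented in vectorized form inside the package; tests cross-check it
against adaptive quadrature of the defining integrals and against an
independent implementation.

### The perfect-sink geometry

When Bar1 protease secretion is light-induced on $x > 0$ while
alpha-factor is produced everywhere, the saturating-degradation
idealization clamps $c = 0$ over the sink domain, and on the diffusion
side the profile is the antisymmetrized source solution

$$g(x) = 2 f(x) - 1 \quad (x < 0), \qquad g \equiv 0 \quad (x \ge 0),$$

with the *same* $\lambda$. This identity is worth being precise about,
because two distinct boundary-value problems hide behind the words
"perfect sink":

1. **Constant-rate balanced sink** — production $+r\rho_\alpha$ on the
   left, removal at the same constant areal rate on the right. By linear
   superposition its solution is exactly
   $c_{far}(f(x) - f(-x))$, i.e. $g(x)$ on the diffusion side (clamped
   at zero where the superposition would go negative). This is the
   construction the closed form realizes, and the numerical solver
   reproduces it to the same accuracy as the source profile
   (`balanced_sink_mask()`).
2. **Dirichlet clamp** — $c = 0$ imposed pointwise on the $x>0$
   surface, a Robin condition on $x<0$. This mixed problem has a
   genuinely different solution near the junction (locally
   $\sim r^{1/2}$ rather than $\sim u\log u$), and its converged surface
   profile sits measurably above $g(x)$ throughout the near-border
   region. The solver supports this mode too
   (`surface_masks(..., dirichlet_sink = )`), and the package tests the
   properties that hold for it — exact zero on the clamped domain,
   monotone rise, flux balance — but does not pretend it matches the
   closed form.

The closed-form $g$ is what the zero-parameter prediction
(`predict_sink_response()`) uses: every parameter
($\lambda, C, n_m, A_m, b_m$) is frozen at the source-experiment fit and
only the geometry changes.

## The response channels

Responses are Hill functions of local concentration in EC50 units,
$\theta_n(c) = c^n/(1+c^n)$, scaled into readout units as
$\hat\theta = A\,\theta + b$:

* **gene expression** (P_FUS1-driven GFP): non-cooperative, $n = 1$
  fixed;
* **morphology** (cell length): switch-like, integer $n_m \in 1..7$
  selected by the fit.

Because $C$ is of order 1, the response plateaus at
$C^n/(1+C^n) < 1$ — the far-field is *not* saturating, which is exactly
what makes $C$ identifiable from the plateau height once two channels
with different $n$ are fit jointly. `normalize_max()` divides this
plateau out for cross-channel comparison.

The gradient steepness at the border is finite only through a sensing
scale: the derivative of $f$ diverges logarithmically at $x=0$, so
`border_gradient()` defines the border gradient as a centered difference
over `delta = 5` µm, one cell diameter — the scale over which a cell
could compare receptor occupancy. The printed value is convention
dependent (one-sided vs centered, choice of `delta`) at the tens-of-percent
level; the package treats order-of-magnitude agreement as the meaningful
statement.

## The numerical oracle

`solve_steady()` discretizes the rectangle $[-L_x/2, L_x/2] \times
[0, L_z]$ with the 5-point Laplacian; all Neumann/Robin boundaries are
handled by ghost-node elimination (second order), with the surface
condition $D\,\partial_z c = \Omega\rho_A U(x)\, c - r\rho_\alpha P(x)$
carrying the reaction terms. The sparse system is solved directly
(Matrix LU), so the only errors are discretization and domain
truncation. Numerical choices that matter:

* **Half-weighted border node.** A node sitting exactly on a mask edge
  gets coverage 1/2; otherwise the effective border shifts by $dx/2$,
  which is the dominant error near the transition.
* **Domain size, not grid, limits accuracy.** With the heavy
  $1/x$ tail, the no-flux walls reflect noticeably: at
  $L_x = 12\lambda, L_z = 4\lambda$ the surface profile agrees with the
  infinite-domain closed form only to ~6% at $|x| = 3\lambda$,
  improving roughly linearly as both dimensions grow
  ($48\lambda \times 16\lambda$ reaches 1%). The wall artifact is
  itself asserted as a property — it is the numerical counterpart of
  the experimental practice of trimming cells near the stripe edge.
* **Sink comparison metric.** The sink profile crosses zero linearly at
  the border, so the pointwise relative error at the node nearest the
  border is a self-similar ~4% at *any* grid spacing (both the error and
  $g$ itself scale like $dx \log dx$ there). Oracle agreement for the
  sink geometry is therefore stated two ways: pointwise relative error
  outside the sub-resolution zone ($3\,dx \le |x| \le 3\lambda$), and
  amplitude-normalized error ($|c_{num} - c_{closed}|/c_{far}$) over the
  full range including the border nodes; both are held below 2%.
* **Scale-free comparisons.** Only $\lambda/dx$, $L_x/\lambda$ and
  $L_z/\lambda$ matter for the relative comparison, so oracle tests run
  at $\lambda = 200$ µm with $dx = 10$ µm on a
  $9600 \times 3200$ µm domain (~300k unknowns, tens of seconds) rather
  than at $\lambda = 735$ µm, which would need a 4-million-unknown
  system for the same ratios.
* The default gel thickness (2600 µm) reproduces the experimental
  volume: 0.5 cm³ of agarose over a 1.554-cm-diameter well.

## What the synthetic generator emulates

`simulate_experiment()` reproduces the *statistical structure the
inference assumes*: receiver positions i.i.d. uniform along a
±2,700 µm stripe (6,686 receivers by default — the analyzed count of
the half-domain experiment), GFP equal to the model mean times
unit-mean lognormal noise, and length equal to the model mean plus
Gaussian noise (`mean_field`) or a round/elongated Bernoulli mixture
whose elongation probability is the Hill response (`bimodal`).
Orientations are uniform on (0, 180]: shallow large-scale gradients do
not orient growth, and the generator encodes that null.

Defaults the data do not pin down were fixed once:

* `gfp_cv = 0.30` — typical yeast gene-expression variability; the
  single-cell scatter in such assays is wide but unquantified.
* `length_sd = 1.5` µm — manual length measurements of 5–30 µm cells.
* amplitudes/baselines `A_g = 1, b_g = 0.1` (a.u.),
  `A_m = 25, b_m = 5` µm — conventional readout scales around the 5 µm
  round-cell diameter; the study's fitted per-channel scale table is not
  reproduced here, so these are package conventions, not inferred
  values.

What the generator deliberately does **not** emulate: cell clumping and
segmentation artifacts, spatially varying density, illumination
inhomogeneity, prezygote/diploid morphologies, and any Bar1 transport
dynamics. Passing recovery tests therefore demonstrate estimator
correctness under the model's own assumptions — not robustness to the
full messiness of microscopy data.

## Inference design

`bin_cells()` bins receivers into contiguous 100-µm bins (SEM
$= sd/\sqrt{n}$, singletons get SEM 0 and are flagged) and drops one bin
width at the leftmost edge, where wall reflection distorts the real
assay. The default span yields 53 retained bins. Bin width is exposed —
the sink-geometry comparison uses ~180 µm bins (≈30 bins) to match the
coarser binning appropriate for that experiment's cell count.

`joint_fit()` scans $n_m = 1..7$ exhaustively; for each $n_m$ it
minimizes over $(\log\lambda, \log C)$ with L-BFGS-B inside
$\lambda \in [10, 5000]$ µm, $C \in [0.01, 100]$, from 8 log-grid
starts, profiling each channel's $(A, b)$ out by weighted linear least
squares at every step (they enter linearly, so this loses nothing and
removes four dimensions). Ties across $n_m$ (relative SSE within
$10^{-10}$) break toward the smaller coefficient — parsimony. Boundary-
pinned $\lambda$ or $C$ and degenerate $n_m$ selection (relative SSE
spread $< 10^{-6}$, e.g. a flat morphology channel) are flagged in the
diagnostics rather than silently returned.

**Channel weighting.** The classical procedure is plain SSE over both
channels' bin means. That is well defined only when the channels have
comparable numeric scales; with the package's fixture units the length
channel (span ~25 µm) outweighs the GFP channel (span ~0.7 a.u.) by
three orders of magnitude in squared units, and the fit then rides the
morphology channel's $n_m$–$\lambda$–$C$ degeneracy ridge: $n_m$ one
too high with $\lambda$ and $C$ inflated to compensate, while the
$n = 1$ channel that would pin them is ignored. The estimator used for
recovery experiments therefore weights each bin by $1/\mathrm{SEM}^2$
(`weighting = "sem"`), which is unit-free and statistically standard; a
plateau-amplitude scaling (`"plateau"`) is available when SEMs are not,
and `"none"` reproduces the plain procedure. This is an estimator
choice, not a data choice: the generator and its noise are never
adjusted per channel.

`recovery_experiment()` wraps the full loop — simulate, bin, fit —
over seeds and reports bias, RMSE and the selected-$n_m$ distribution;
the package's acceptance checks run it at the study scale (20 seeds,
6,686 cells, the noise defaults above) in a few minutes on one core.

## Known limitations

* The closed forms are infinite-domain, surface-only results; finite
  $L_x, L_z$ effects are quantified only through the numerical solver.
* The perfect-sink closed form is the superposition construction
  described above; the Dirichlet-clamp problem differs near the border,
  and no closed form for it is provided.
* Time dependence (gradient establishment) is out of scope; only steady
  states are computed.
* Concentrations stay in EC50 units end to end; conversion to molar
  units multiplies by an externally supplied EC50 and is intentionally
  not stored.
* The integer Hill-coefficient grid stops at 7; steeper switches would
  pin at the edge and are flagged through the SSE-by-$n$ table.
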