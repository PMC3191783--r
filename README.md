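# mcfseg

Level-set segmentation of a single object in a grayscale image by
**Riemannian mean curvature flow**, with two interchangeable numerical
engines and a synthetic-phantom evaluation harness.

## The problem and the model

Segmenting a structure (say, a skin lesion under epiluminescence microscopy)
can be cast as evolving a *segmentation function* u(x, τ) over the image
domain Ω = (0,1)² under the edge-weighted, ε-regularized curvature flow

    ∂u/∂τ = √(ε² + |∇u|²) ∇·( g(|∇I⁰|) ∇u / √(ε² + |∇u|²) ),
    u(x, 0) = u₀(x),   u = 0 on ∂Ω,

where I⁰ is the image, g(v) = 1/(1 + v²/β) is the Perona–Malik edge
detector (g ≈ 1 in flat regions, g ≪ 1 at edges), and u₀ is a smooth bump
over a user-supplied circle inside the object. As the scale τ grows, the
level sets of u diffuse outward and are arrested at the object boundary;
at the horizon T the half-maximum level line of u approximates the contour.

Two time discretizations of the same finite-volume spatial operator are
provided, mirroring the classic accuracy/efficiency trade-off:

* **semi-implicit** (first order in Δτ): one *linear* system
  (I + Δτ·A(u_{i−1})) u_i = u_{i−1} per scale step, solved by restarted
  GMRES preconditioned with an algebraic-multigrid V-cycle
  (smoothed aggregation, exact Galerkin coarse operators R·A·P);
* **implicit** (Crank–Nicolson, second order in Δτ): one *nonlinear*
  system per step, solved by Jacobian-free Newton–Krylov — GMRES on
  finite-difference Jacobian–vector products with Armijo line search.

Equal discretization error couples the two step sizes as
Δτ_SI = Δτ_I², and N = ⌈T/Δτ⌉ steps cover the horizon. Accuracy is scored
by the exact Hausdorff distance between the extracted contour (marching
squares, sub-cell interpolation) and the phantom's analytic ground truth.

## Worked example

```r
library(mcfseg)

ph  <- generate_phantom(n = 96, seed = 1)          # blob on 96x96, analytic truth
fit <- mcf_segment(ph, center = c(0.5, 0.5), radius = 0.12,
                   scheme = "semi_implicit", dtau = 0.16, T = 0.4)
summary(fit)
hausdorff_distance(fit, ph$truth_contour)
plot(fit)                                          # image + contour overlay
```

which prints:

```
Mean-curvature-flow segmentation (semi_implicit scheme)
  grid: 96 x 96, dtau = 0.16, T = 0.4 (3 step(s) planned)
  executed 3 step(s), status: completed
  final steady-state residual: 0.805
  contour: 195 points at level 0.00658

Convergence record:
 step k_gmres lv newton_steps f_evals   residual wall_time
    1      16  5           NA      NA 84.6646345     0.988
    2      13  5           NA      NA  2.9658253     0.082
    3      13  5           NA      NA  0.8046797     0.083

Hausdorff distance to ground truth: 0.00607 (= 0.58 cells)
[1] 0.006068427
```

Read: the three semi-implicit scale steps each needed 13–16
AMG-preconditioned GMRES iterations on a 5-level hierarchy (effort relaxes
as the flow settles), and the recovered contour lies within one cell of the
analytic truth. Running the implicit engine instead (`scheme = "implicit"`,
`dtau = 0.4` — the matched-error step, since 0.16 = 0.4²) lands within a
tenth of a cell of the same contour (Hausdorff distance 0.00078 between the
two schemes' contours, against 0.00618 to truth).

A command-line wrapper is installed at `inst/cli/mcfseg` with subcommands
`phantom`, `segment`, `evaluate` and `compare`, e.g.

```sh
Rscript inst/cli/mcfseg phantom --n 128 --seed 0 --out scratch/ph
Rscript inst/cli/mcfseg segment --image scratch/ph.tiff --scheme si \
        --dtau 0.16 --T 0.4 --radius 0.12 --out scratch/run
Rscript inst/cli/mcfseg evaluate scratch/run_contour.csv scratch/ph_truth.csv
```

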