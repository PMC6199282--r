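# heterogame

Monte Carlo simulator for the **weak prisoner's dilemma on a periodic square
lattice** in which each player lives in a heterogeneous environment and
chooses whom to imitate by preference selection.

Evolutionary game theorists use models of this kind to ask when cooperation
can survive among self-interested agents: on a lattice, cooperators persist
only by forming clusters, and mechanisms that help those clusters organise —
here, individual heterogeneity and preferential imitation of "attractive"
neighbours — can shift the balance dramatically. `heterogame` implements one
such mechanism end to end, with a compiled update kernel, a replicate/sweep
measurement protocol, exact one-step probability oracles for validating the
stochastic kernel, tidy tabular results, ggplot2 figures and a small CLI.

## Model

Each site `x` of an `L × L` torus (von Neumann neighbourhood, `k = 4`) holds
a strategy `s_x ∈ {C, D}` and a quenched heterogeneity value `h_x` drawn
uniformly from the 41 levels `{0.0, 0.1, …, 4.0}`. Payoffs follow the
single-parameter weak prisoner's dilemma

```
R = 1,  T = b > 1,  P = S = 0,
```

and a player's accumulated payoff `P_x` comes from playing all four
neighbours. The *environment* of `x` is the mean heterogeneity of its
neighbours,

```
H_x = (1/4) Σ_{y ∈ N(x)} h_y ,
```

and fitness mixes game income with environmental income through a weight
`u ∈ [0, 1]`:

```
F_x = (1 − u) P_x + u H_x .
```

Updates are asynchronous: one Monte Carlo step (MCS) performs `L²`
elementary updates, each picking a random focal player `x`, drawing an
imitation target `y` among its neighbours with softmax preference

```
Ω_y = exp(α h_y) / Σ_{z ∈ N(x)} exp(α h_z) ,
```

and adopting `s_y` with the Fermi probability

```
W = 1 / (1 + exp((F_x − F_y) / K)) ,   K = 0.1 .
```

`u = 0, α = 0` recovers the traditional spatial weak PD; `u = 1` makes
fitness purely environmental and the dynamics neutral between strategies.
The headline observable is the cooperator fraction `ρ_c`, averaged over the
final 10⁴ of 6×10⁴ MCS (with a stationarity check and automatic extensions)
and over 40 independent replicates at the reference scale.

## Worked example

```r
library(heterogame)

p <- sim_params(L = 50, b = 1.1, u = 0.5, alpha = 3,
                total_mcs = 3000, avg_window = 1000,
                n_replicates = 5, seed = 42)
ens <- run_ensemble(p)
ens
#> Spatial PD ensemble: 5 replicates at L = 50, b = 1.1, u = 0.5, alpha = 3
#>   rho_c = 0.8774 (sd 0.0235)
glance(ens)
#> # A tibble: 1 × 9
#>       L     b     u alpha     K rho_mean rho_sd n_replicates master_seed
#>   <int> <dbl> <dbl> <dbl> <dbl>    <dbl>  <dbl>        <int>       <int>
#> 1    50   1.1   0.5     3   0.1    0.877 0.0235            5          42
```

`rho_mean ≈ 0.88` says that with half of fitness coming from the
heterogeneous environment and a moderate preference strength, cooperators
hold ~88% of the lattice at a temptation (`b = 1.1`) that would wipe them
out in the traditional game (`u = 0, α = 0` gives `rho_mean = 0` at this
size). Sweeps chain the same way:

```r
sw <- run_sweep(sweep_spec(p, list(param = "b", values = seq(1.0, 1.5, 0.1))))
tidy(sw)        # tibble: b, rho_mean, rho_sd, n_replicates, seed, valid
autoplot(sw)    # cooperation curve; 2D sweeps draw a phase plane
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/heterogame.R run --b 1.05 --u 0 --alpha 0 --L 50 \
    --mcs 7000 --window 2000 --replicates 5 --seed 7 --out out/
Rscript inst/cli/heterogame.R sweep --axis b=1.0:1.5:0.05 --u 0.5 --alpha 3 ...
Rscript inst/cli/heterogame.R snapshots --times 0,10,100,10000 ...
Rscript inst/cli/heterogame.R reproduce optimal-alpha --seed 7
```

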