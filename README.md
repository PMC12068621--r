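# rdgeom

Rate–distortion geometry of latent representations in generative models.

Resource-limited systems — brains and artificial networks alike — must
compress what they encode. `rdgeom` studies *how* that compression warps
internal representations. It trains capacity-constrained beta variational
autoencoders (β-VAEs) on a fully synthetic image family and measures the
geometric distortions of their latent spaces under three pressures:
limited capacity (**prototypization**), imbalanced stimulus frequencies
(**specialization**), and classification objectives
(**orthogonalization**).

Everything is self-contained: the package generates its own data, trains
its own models on one CPU core in minutes, and computes every analysis it
reports.

## The model

Stimuli are 13×13 binary "Corridors" images: two noisy vertical corridors
(one per image section, split by an all-white divider row) whose integer
horizontal positions `(x_UC, x_LC) ∈ {0,…,12}²` are the only two
generative factors. Pixels around each corridor core are independent
Bernoulli draws with probability `exp(-(x-μ)²/(2σ²))`, σ = 1.2.

A β-VAE with a 5-D latent is trained with the capacity-constrained
objective

```
L = E_q[-log p(x|z)]  +  γ·|KL(q(z|x) ‖ p(z)) − C|  +  Σ_i CE(clf_i(z), y_i)
```

with C annealed from 0 to `Cmax ∈ {0.3, 1, 3, 6, 10}` nats (Adam,
lr 5e-5). Optional classifier heads (linear, 1024 hidden units, no
activations — or nonlinear, 1500 units, leaky ReLU) are trained jointly
on four position-defined tasks. Latent geometry is compared across models
with the distance-ratio statistic `ρ(u,v) = d₂(u,v)/d₁(u,v)` aggregated
into 169×169 item matrices and class matrices, plus metric-MDS
projections, per-channel activation maps and active-channel counts.

## Worked example

```r
library(rdgeom)

# the 25-class binning task labels positions (6, 11) as bin 2 / bin 4:
task_label("T4", 6, 11)
#> [1] 14

# a corridor's Bernoulli profile peaks at 1 on the core column:
round(corridor_profile(6), 3)
#>  [1] 0.000 0.000 0.004 0.044 0.249 0.707 1.000 0.707 0.249 0.044 0.004 0.000
#> [13] 0.000

# train the E2M1 hybrid (linear head, task x_UC <= x_LC) at 0.3 nats:
ds  <- generate_dataset(20000, seed = 21)
rec <- experiment_recipe("E2M1", c_max = 0.3, seed = 1)
m   <- train_vae(ds, rec$model_spec, rec$train_config)
ev  <- evaluate(m, ds)
round(c(F1 = unname(ev$f1), recon_mse = ev$recon_mse, kl = ev$kl), 3)
#>        F1 recon_mse        kl
#>     0.868     0.135     0.299
```

The held-out F1 of ~0.87 shows the 0.3-nat code carries the task; the
per-pixel reconstruction loss of ~0.14 sits between the no-information
floor (~0.155) and the perfect-information noise floor (~0.055),
reflecting how little position detail fits in 0.3 nats; and the KL is
pinned at the capacity target. `active_channel_count(m, ds)` reports 2
active latent channels, and `compare_models()` against a baseline β-VAE
quantifies the task-induced distortion.

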