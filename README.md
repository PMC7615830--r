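# pcnlearn

Learning in layered neural networks by **prospective configuration**: an
energy-based predictive coding network first relaxes its neural activity to
the pattern that would follow successful learning, and only then modifies
its weights — by simple Hebbian plasticity — to consolidate that pattern.
The package pairs this rule with a weight-matched **backpropagation**
baseline operating on the same network object, so that any difference
between the two is attributable to the credit-assignment principle alone.
It is intended for computational neuroscientists and machine-learning
researchers studying biologically plausible alternatives to
backpropagation.

## The model

A network has weights $w^1,\dots,w^L$ and activities
$x^1,\dots,x^{L+1}$, with layer $l+1$ receiving $w^l f(x^l)$ (presynaptic
activation, no biases). Prediction errors and the energy are

$$\varepsilon^l = x^l - w^{l-1} f(x^{l-1}), \qquad
  E = \sum_{l\ge 2} \tfrac12 \lVert \varepsilon^l \rVert^2 .$$

*Inference (relaxation):* with the input clamped to $s^{\mathrm{in}}$ and
target-clamped outputs fixed, unclamped activities descend the energy,
$\Delta x^l = \gamma\left(-\varepsilon^l + f'(x^l)\circ (w^l)^\top
\varepsilon^{l+1}\right)$, with an adaptive step ($\gamma_0 = 0.1$, halved
when energy stalls, early stop at the second halving, at most 128
sweeps).

*Learning (consolidation):* at the converged activities,
$\Delta w^l = \alpha\, \varepsilon^{l+1} (f(x^l))^\top$.

The backpropagation baseline minimizes
$L = \tfrac12\lVert s^{\mathrm{target}} - x^{L+1}\rVert^2$ by the chain
rule on the identical architecture. Around this core the package
provides: interference metrics (target alignment and a depth sweep over
random deep linear networks), the minimal 1-1-2 "bear" interference
example, a batched training loop on synthetic classification data,
simulations of two human learning experiments (contextual sensorimotor
adaptation; probabilistic reversal learning) with the analytic-scale grid
search fitting, and Q-learning with experience replay driven by either
rule.

## Worked example

The interference example: one cue predicts two outcomes, one of which
must be unlearned while the other is already correct.

```r
library(pcnlearn)

fx <- bear_fixture()           # 1-1-2 linear net, all weights 1
predict(fx$net, fx$pattern$s_in)
#> [1] 1 1

# one learning step of each rule, tracking the correct output's weight
pc <- pcn_learn(fx$net, fx$pattern$s_in, fx$pattern$s_target, fx$alpha)
bp <- bp_learn(fx$net,  fx$pattern$s_in, fx$pattern$s_target, fx$alpha)
c(pc = pc$weights[[2]][2, 1], bp = bp$weights[[2]][2, 1])
#>       pc       bp 
#> 1.044444 1.000000
```

Prospective configuration relaxes the hidden unit to its prospective
value 2/3, revealing a positive error of 1/3 on the correct output and
*strengthening* its weight ($1 + 0.2\cdot\tfrac13\cdot\tfrac23 =
1.0444$), while backpropagation leaves it untouched — the signature that
lets prospective configuration avoid dragging correct predictions down
while errors elsewhere are being fixed. The same contrast scales up:

```r
sw <- alignment_depth_sweep(depths = c(2, 10, 25), n_reps = 5, seed = 1)
round(tapply(sw$alignment, list(sw$depth, sw$rule), mean), 3)
#>       bp    pc
#> 2  0.885 0.988
#> 10 0.557 0.706
#> 25 0.333 0.569
```

Deeper networks interfere more under backpropagation (alignment falls
toward 0), while prospective configuration keeps the output moving much
closer to the direction of the target.

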