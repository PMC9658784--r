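---
title: "Encrypted neural-network inference over computation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encrypted neural-network inference over computation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhenet)
```

## The problem

Levelled homomorphic encryption (the CKKS scheme over fixed-point vectors)
lets an untrusted party evaluate additions and multiplications directly on
ciphertexts. That makes private neural-network *inference* possible — a
grower can send an encrypted sensor window to a forecasting service and get
an encrypted yield prediction back — but it imposes hard constraints that
ordinary deep-learning code violates everywhere:

* messages are packed into SIMD "slots" and can only be operated on as a
  whole vector, element-wise; a ciphertext cannot be folded onto itself to
  form a sum, and two ciphertexts multiply element-wise, never with cross
  terms;
* interacting ciphertexts must be identical containers — same parameters,
  same modulus chain position, same private key;
* each multiplication consumes one prime from a finite modulus-switching
  chain (one "level"); when the chain is gone, only an expensive refresh
  (bootstrapping, out of scope here) or a key rotation can continue;
* only abelian-compatible operations exist: no division, comparison, max,
  or branching on values — so softmax, argmax and max-pooling are off the
  encrypted path.

`fhenet` is a node-centric framework for building, costing and running
networks under these rules: a multi-directed computation graph with a
depth-first signal-propagation ("neuronal firing") algorithm, an automatic
CKKS parameteriser driven by longest-path analysis over node costs, and a
set of FHE-compatible layers. A deterministic simulated CKKS backend
enforces every constraint while computing exact arithmetic, so plaintext
and ciphertext runs are bit-identical and every depth or key mistake
surfaces as a typed error.

## Graphs and neuronal firing

A network is a `compgraph`: named nodes (computation objects with `forward`
and `backward` *receptors*) joined by directed edges that carry signals.
Parallel edges are distinct, with independent signal slots; a node with
several in-edges receives their signals stacked in edge-insertion order,
and a single in-edge is delivered unwrapped. A node activates only when
*all* of its gathered edges carry data (the blocking rule); firing is
depth-first from the stimulated node, so one pass of
`neuronal_firing(g, c("x", "y"), list(image, label), c("forward", "forward"))`
completes the whole forward computation. Nodes may return a
`signal_generator`, in which case successor edges receive successive items
instead of a broadcast — this is how one convolution node feeds each window
ciphertext to its own fold node.

Three behaviours are deliberate choices where the procedure's written form
was ambiguous:

* recursion continues on each *successor* of an activated node (the
  literal formulation would re-fire the current node forever);
* inbound signals are consumed on successful activation, so the next
  epoch's pass starts from a clean graph;
* self-loop edges are ignored by the traversal (a looping node manages its
  own termination), while any other cycle raises `fhe_cycle_error` via a
  visited-path check.

Backward firing reuses the same machinery with the edge roles mirrored.
One asymmetry is forced by the science: the prediction branch
(argmax → one-hot decode) is plaintext-only and produces no gradients, so a
strict "all successor edges must carry data" rule would deadlock the
decrypt node during backpropagation. Nodes therefore declare whether they
participate in backprop (`node_backprop()`), and backward gathering and
emission skip non-participating edges. Gradients fan-in by summation, the
standard chain rule for shared outputs.

## Automatic CKKS parameterisation

Choosing CKKS parameters by hand is the main usability barrier of levelled
FHE: too small a modulus chain and the circuit dies mid-way; too large and
every operation pays for slots and primes it never uses. The package
derives parameters from the graph itself.

Every node carries an integer cost — the number of multiplicative levels
its forward receptor consumes (cross-correlation 1, dense 1, the
polynomial activations 2, everything else 0; additions are free because
the scheme only rescales after multiplication). An edge into a node costs
that node's cost, so the depth a ciphertext experiences along a path is the
sum of edge weights, and the depth that must be provisioned is the
*longest* path between the points where ciphertexts are created and where
they are rotated or decrypted ("concern" nodes: `rotate_node`,
`decrypt_node`).

`autohe_discover()` walks the graph from each ciphertext ingress,
max-merging an accumulated cost label per source into each node's
metadata; a concern node terminates the current source and restarts as a
new source at cost zero, so each rotation segment is parameterised
independently. `autohe()` then groups sources: two sources whose labels
co-occur on any node interact there and must share parameters and key. The
printed form of this merge is iteration-order sensitive, so the package
implements it as a union-find over the co-occurrence relation, iterated in
caller order and node-insertion order — deterministic output, with
equivalence against `brute_force_group_cost()` (exhaustive simple-path
enumeration plus independent set-merging) as the correctness bar, checked
on 200 random multi-directed graphs in the test suite.

`parameterise_ckks(cost, scale_power, special_mult)` finally maps a group
cost to concrete parameters: a chain of `cost + 2` prime bit-sizes —
`scale_power` bits per consumable level, scale-stabilised special primes of
`floor(scale_power * special_mult)` bits at both ends — and the smallest
power-of-two polynomial degree whose bit budget (27 bits per 1024 degree)
covers the chain. Defaults are a scale of 2^40 and multiplier 1.5; scales
below 2^30 warn, since noise headroom and prime availability degrade.
Degree and slot capacity (half the degree) are non-decreasing in cost and
scale. For example, a group of cost 3 at the default scale gets the chain
`[60, 40, 40, 40, 60]` and degree 16384.

## The ciphertext meta-object

`ckks_ct` packs a message into a fixed slot vector (message left-justified,
zero-padded) and tracks scale, remaining chain, key id and a noise
estimate. Arithmetic goes through the ordinary `+`/`*` operators, so layer
code is written once and runs on plaintext vectors and ciphertexts
identically; `-` and `/` work only against plaintexts, and ciphertext–
ciphertext subtraction or division raises `fhe_compat_error`. On
multiplication the operand higher up the chain is swapped down
automatically, the result is relinearised and rescaled, and one prime is
consumed; an exhausted chain raises `fhe_depth_error`. `rotate()` is the
simulated decrypt/re-encrypt boundary with three modes: `refresh` (same
packing, fresh chain), `fold` (re-encrypts the slot-sum as a length-1
message — the only way to realise a sum-of-products), and `split`.

The backend is *noise-exact in values*: slot arithmetic is plain double
arithmetic with no injected error, so plaintext/ciphertext equivalence is
exact, which the tests exploit. Noise is tracked qualitatively, the only
contract the scheme's description supports: additions add one bit (a
doubling), multiplication doubles the bits and adds a constant before the
rescale subtracts the scale exponent; decryption warns within 10 bits of
the scale and errors above it. The constants are configurable via
`options(fhenet.noise_base=, fhenet.noise_mult_k=)`; only the ordering
(multiplication ≫ addition) is asserted. An optional
`options(fhenet.noisy_sd=)` adds seeded Gaussian slot noise for robustness
experiments. Key ids are opaque tokens — the simulator performs no real
cryptography and makes no security claims; when a real backend is plugged
in behind the same call surface, its parameter floors (128-bit security)
apply.

## FHE-compatible layers

**Cross-correlation with kernel masquerading.** A convolution window is
realised by merging the kernel with a zero mask into one input-shaped
sparse tensor (`masquerade()`), flattened to slot order: one whole-vector
Hadamard product per window, so the input ciphertext spends exactly one
level regardless of kernel size. The node emits one un-summed ciphertext
per valid window position (row-major layout, 0-based offsets, stride ≥ 1,
no padding) through a generator; downstream fold rotations complete each
window's sum. The bias is *commuted* into the product stage as `b/N` on the
window's support, so the fold reproduces `sum(x*w) + b` exactly — this
keeps the ordinary gradient rule `df/db = 1` after the fold. (The
alternative, adding `b` whole and compensating with `df/db = N·x`, is
algebraically equivalent; the commuted form is implemented.) Masks are
rebuilt from the current kernel at every forward pass, since the weights
are plaintext and train.

**Dense.** One weight per inbound branch; the node computes
`sum_i(x_i * w_i + b/N)` across its (shape-aligned) input sequence —
ciphertext additions are legal, so no rotation is needed here — or, for a
single packed input, the un-summed element-wise product for a later fold.

**Activations.** Two multiplicative levels each, in both cases arranged so
a plaintext coefficient rides along an existing product: the ReLU
approximation over a dynamic range `[-q, q]`,
`Ra(x) = 4/(3πq)·x² + x/2 + q/(3π)` with derivative `8/(3πq)·x + 1/2`, and
the static sigmoid approximation `0.5 + 0.197x − 0.004x³` (cubic computed
as `(−0.004x)·(x·x)`), with the exact logistic as plaintext reference. The
range `q` is updated during training by an exponential moving average
toward the batch magnitude, `q ← (1−α)q + α·max|x|` with `α = 0.1` — the
behaviour is named but no rule is given for it, so the EMA is this
package's choice, with a gradient step on `∂Ra/∂q = −4x²/(3πq²) + 1/(3π)`
available behind `q_update = "grad"`; neither is claimed to be the original
rule. The approximation error curves are pinned empirically in the tests:
`max|Ra − R|` on `[-q, q]` is `q/(3π)` (attained at 0), and
`max|σ − σa|` on `[−5, 5]` is 0.05103.

**Plaintext circuit.** Softmax (max-subtraction stabilised), categorical
cross-entropy (log clamped at 1e−12) with the combined gradient `p − y`
routed back through the softmax node, MSE, argmax/one-hot with ties broken
toward the lowest index. All of these raise `fhe_compat_error` on a
ciphertext: they need division or value comparison and run client-side
after decryption. Max-pooling is deliberately absent — context cannot be
read from a ciphertext — and strided convolution is the only
down-sampling; batch normalisation is likewise not implemented, with the
ReLU range tracker as the stabiliser.

## The two built networks

`build_sphira()` (classification): image → encrypt → masqueraded
cross-correlation (one filter) → per-window fold rotations → activation →
one dense node per class, each with its own activation → decrypt →
*prediction branch* (argmax → one-hot decode) and *loss branch*
(softmax → CCE, fed by the one-hot encoded label). `build_constellation()`
(regression): feature window → encrypt → 1D cross-correlation across time
(kernel spanning all features) → per-window folds → sigmoid → dense merge
across windows → sigmoid → decrypt → prediction output and MSE loss.
`autohe()` runs at build time; in the default mini classifier this yields
three groups — the ingress segment (cost 1: the convolution), the
fold-to-decrypt segment (cost 5: activation 2 + dense 1 + activation 2),
and the decrypt boundary — and configures each encrypt/rotation node with
its group's parameters and key.

Labels travel in plaintext to the loss circuit. The loss is necessarily
computed after decryption in either case, so encrypting the label ingress
would only add a decrypt step; both paths exist in the node set, and the
builders use the plaintext one.

Training (`train()`) is per-example signal firing — forward on `(x, y)`,
plaintext loss and gradient at the decrypted boundary, backward firing,
plain SGD — with weights plaintext throughout: encrypted *training* is out
of scope, the encrypted path is inference. An optional inverse-time decay
`lr/(1 + decay·(t−1))` counters the gradient-noise floor of single-example
updates; batch size 1 is the structural default since one firing is one
example. Training runs in plaintext mode for speed; because the simulated
backend is value-exact this changes nothing about the learned weights, and
the equivalence of encrypted and plaintext inference is asserted separately.

## What the synthetic data emulates — and what it does not

No real dataset ships with the package. Two seeded generators stand in,
and both are pure functions of their seed.

`gen_toy_images()` replaces the label+pixel-CSV image classification task:
K geometric prototypes (bars, cross, blob, diagonal, border) plus Gaussian
pixel noise, clipped to [0, 1], classes balanced to ±1. Images default to
8×8 rather than 28×28 so that encrypted runs stay desk-scale — a full
28×28 encrypted inference at realistic parameters needs tens of gigabytes
of ciphertext memory, which is precisely the regime this package's
simulator is designed to avoid. The prototypes are nearest-prototype
separable at the default noise (the Bayes classifier exceeds 99%), so a
learner that fails here is broken, but success here says nothing about
natural images.

`gen_yield_series()` emulates environmental yield forecasting: smooth
latent daily weather (temperature, light, humidity, wind speed and
one-hot direction, precipitation, irrigation schedule, soil moisture and
temperature), cut into *non-overlapping* `T_x`-day windows, with a positive
yield at a 7/14/21-day horizon. The yield is a documented saturating
function — a logistic link over a linear combination of the window's
degree-day accumulation, light accumulation and a moisture/heat stress
term, mapped into the band 0.4–1.0 — so the generator doubles as its own
recovery oracle: inverting the link and regressing on the reconstructed
accumulations recovers the map essentially exactly on noiseless data. The
band is kept away from zero because MAPE, the headline metric, degenerates
as targets approach zero. Standardisation constants are fixed population
values (calibrated once against a long simulation of the latent
processes), so the feature→target map is identical across seeds and sample
sizes. Multiplicative target noise scales linearly with the horizon,
making longer horizons genuinely harder by construction. Windows are
non-overlapping and a time-blocked split mode is provided, avoiding the
leakage that fully randomised overlapping sequences would allow. What the
generator does not emulate: real agronomy (cultivar effects, picking
schedules, spatial structure), heteroscedastic sensor failure, or any
distribution shift between seasons — passing tests on it demonstrates the
machinery, not field performance.

## Numerical and experimental choices

* **Problem sizes.** The mini classifier is 8×8/two-class (n = 200), the
  mini regressor 150 windows of 14 days × 12 features; the activation
  stability experiment trains 10 seeds per variant for 5 epochs on a
  noisier 2-class set (pixel noise 0.35, lr 0.2) so that training is
  non-trivial and instability can express itself. These sizes keep any
  single experiment in the minutes range on one CPU.
* **Optimisation.** lr 0.1 for the classifier; lr 0.3 with decay 0.02 and
  150 epochs for noiseless recovery (60 epochs on noisy horizons). The
  recovery target (held-out MAPE < 5%) sits well above the architecture's
  observed floor (~3%) and well below the mean-predictor baseline (~25%).
* **Stability experiment.** A diverged run (non-finite loss, which the
  dynamically ranged ReLU occasionally produces at this lr) scores chance
  accuracy rather than aborting the experiment; the sigmoid variant, a
  static bounded polynomial, does not diverge in this regime. The
  qualitative claim — comparable mean accuracy, higher variance for the
  ReLU variant — reproduces across seed sets; the exact variances are
  regime-dependent.
* **Ties, clamps, degenerate inputs.** Argmax ties break to the lowest
  index; CCE clamps log at 1e−12; the ReLU range is floored at 1e−3;
  empty messages encrypt to all-zero slots; a generator exhausted before
  its out-edges raises an arity error rather than recycling.

## Known limitations

Bootstrapping, real cryptographic security, encrypted training, an
FHE-compatible softmax, transformers and batch normalisation are all out
of scope. The simulated backend checks the scheme's structural rules but
not its numerics — fixed-point quantisation error and true noise growth
require a real CKKS library behind the `BackendInterface` seam
(`--backend plugin` in the command surface, registered via
`options(fhenet.backend=)`). Node costs count multiplicative depth only;
a backend with markedly different rescaling behaviour would need its own
cost model injected through the same parameteriser hook.
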