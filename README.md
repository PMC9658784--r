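# fhenet

Privacy-preserving neural-network inference over levelled homomorphic
encryption, organised around the computation graph itself.

Levelled CKKS encryption lets a third party evaluate additions and
multiplications on encrypted fixed-point vectors — enough, in principle,
to run a neural network on data its owner never reveals. In practice three
things stand in the way: every multiplication consumes one level of a
finite modulus-switching chain, interacting ciphertexts must share
parameters and keys, and nothing non-abelian (division, max, comparison)
can touch a ciphertext. `fhenet` treats all three as properties of a
graph:

* **Graph engine** — networks are multi-directed graphs of computation
  nodes joined by signal-carrying edges, activated by a depth-first,
  blocking *neuronal firing* traversal (`neuronal_firing()`). Nodes expose
  `forward`/`backward` receptors; parallel edges are first-class; a node
  fires only when every inbound edge carries data.
* **autoFHE** — each node declares its multiplicative-depth cost, so the
  depth a ciphertext experiences is a longest-path quantity between
  encryption, key-rotation and decryption boundaries. `autohe()` discovers
  interacting ciphertext sources and their maximal segment costs
  (`autohe_discover()`), and `parameterise_ckks()` turns a group cost `c`
  into concrete RNS-CKKS parameters: bit-size chain
  `[⌊1.5s⌋, s×c, ⌊1.5s⌋]` at scale `2^s` (default `s = 40`) and the
  smallest power-of-two polynomial degree whose 27-bits-per-1024 budget
  covers it. Slot capacity is half the degree.
* **Ciphertext meta-object** — `encrypt()` packs a message into a `ckks_ct`
  that enforces the scheme's rules on every `+`/`*`: automatic modulus
  swapping, relinearise-and-rescale per product, typed errors for key
  mismatches, chain exhaustion and noise overflow, `rotate()` for
  refresh/fold/split boundaries. The simulated backend is value-exact, so
  plaintext and encrypted runs of the same graph agree bit for bit.
* **FHE-compatible layers** — cross-correlation via *kernel masquerading*
  (kernel merged with a zero mask into one input-shaped Hadamard product
  per window, one level total) with the bias commuted as `b/N` into each
  product; dense merge nodes; polynomial activations
  `Ra(x) = 4/(3πq)x² + x/2 + q/(3π)` (ReLU, dynamically tracked range `q`)
  and `σa(x) = 0.5 + 0.197x − 0.004x³` (sigmoid); plaintext-side softmax,
  cross-entropy, MSE and argmax/one-hot prediction.
* **Networks, data, commands** — builders for an image classifier
  (`build_sphira()`) and a 1D environmental yield regressor
  (`build_constellation()`), `train()`/`infer()` drivers, `mape()`, seeded
  synthetic generators (`gen_toy_images()`, `gen_yield_series()`), a
  label+pixel CSV reader, and `cmd_parameterise()` / `cmd_generate()` /
  `cmd_train()` / `cmd_infer()` with a thin Rscript wrapper in
  `inst/cli/fhenet.R`.

## Worked example

Build the mini classifier, inspect what autoFHE provisioned, train on
synthetic images, and predict on a ciphertext:

```r
library(fhenet)

cfg <- network_config(input_shape = c(8, 8), kernel_shape = c(3, 3),
                      stride = 2, n_classes = 2, seed = 42)
g <- build_sphira(cfg)
g
#> <compgraph: 32 nodes, 48 edges>
g$groups
#> group 1 (cost 1): enc_x
#> group 2 (cost 5): fold_1, ..., fold_9
#> group 3 (cost 0): dec
g$nodes[["enc_x"]]$node$params
#> <fhe_params CKKS: depth 1, scale 2^40, degree 8192, chain [60,40,60]>
```

Three parameter groups: the ingress ciphertext only survives the
convolution (cost 1) before the fold rotations refresh it; the rotated
ciphertexts must cross activation (2) + dense (1) + activation (2) = cost
5 before decryption, and all nine share one group because they interact at
the dense nodes.

```r
ds <- gen_toy_images(200, K = 2, seed = 42, noise_sd = 0.1)
fit <- train(g, ds$images, ds$labels, epochs = 3, lr = 0.1)
fit$history
#>   epoch        loss accuracy
#> 1     1 0.043461139    0.995
#> 2     2 0.004545236    1.000
#> 3     3 0.002232083    1.000

infer(g, ds$images[1, , ], encrypted = TRUE)    # 0
infer(g, ds$images[1, , ], encrypted = FALSE)   # 0 — exactly equal, always
```

The packed-slot semantics are visible directly on the meta-object:

```r
ct <- encrypt(c(1, 2, 3, 4), parameterise_ckks(2))
ct
#> <ckks_ct: 4/4096 slots, key 'k0', 2 level(s) left, ~6 noise bits>
decrypt(ct * 4)        # 4 8 12 16  — element-wise, one level consumed
decrypt(fold_sum(ct))  # 10        — the sum needs a key rotation
decrypt(ct * ct)       # 1 4 9 16  — never the squared sum 100
```

The training history and predictions above are the package's actual
output for this seed.

## Scope

The simulator enforces CKKS's structural rules with exact arithmetic; it
performs no real cryptography (a real backend can be registered through
`fhe_backend()`). Bootstrapping, encrypted training, FHE softmax,
max-pooling and batch normalisation are out of scope — see the methods
vignette (`vignettes/encrypted-inference.Rmd`) for the model, the
parameterisation algorithm, the synthetic-data design and known
limitations.
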