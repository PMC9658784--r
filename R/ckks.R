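#' Heuristic RNS-CKKS parameter selection from a depth budget
#'
#' Builds the coefficient-modulus bit-size chain and polynomial modulus degree
#' for a ciphertext group whose maximal multiplicative depth is `cost`. The
#' chain holds `cost + 2` entries: a scale-stabilised special prime at each
#' end (`floor(scale_power * special_mult)` bits) and `cost` middle primes of
#' `scale_power` bits, one consumed per rescale. The polynomial modulus degree
#' is the smallest `1024 * 2^k` whose 27-bit-per-1024 budget covers the chain
#' sum; slot capacity is half the degree.
#'
#' @param cost non-negative integer multiplicative depth of the group.
#' @param scale_power integer scale exponent (ciphertext scale is
#'   `2^scale_power`). Default 40; values below 30 trigger an advisory warning
#'   (noise accumulation and prime availability suffer).
#' @param special_mult multiplier for the special primes, >= 1. Default 1.5.
#' @return an object of class `fhe_params`.
#' @examples
#' p <- parameterise_ckks(3)
#' p$coeff_mod_bit_sizes  # 60 40 40 40 60
#' p$poly_modulus_degree  # 16384
#' @export
parameterise_ckks <- function(cost, scale_power = 40, special_mult = 1.5) {
  if (length(cost) != 1L || is.na(cost) || cost < 0)
    stop(fhe_condition("fhe_value_error", "cost must be a non-negative integer"))
  cost <- as.integer(cost)
  if (special_mult < 1)
    stop(fhe_condition("fhe_value_error", "special_mult must be >= 1"))
  if (scale_power < 30)
    warning("scale_power below 30 is not advised: noise accumulation and ",
            "lack of prime availability", call. = FALSE)
  m <- rep(as.integer(scale_power), cost + 2L)
  m[1L] <- as.integer(scale_power * special_mult)
  m[length(m)] <- as.integer(scale_power * special_mult)
  b <- 27
  while (b < sum(m)) b <- b * 2
  structure(list(
    scheme = 2L,                       # CKKS
    scale = 2^scale_power,
    scale_power = as.integer(scale_power),
    special_mult = special_mult,
    cost = cost,
    coeff_mod_bit_sizes = m,
    poly_modulus_degree = as.integer(1024 * (b / 27)),
    slots = as.integer(1024 * (b / 27) / 2)
  ), class = "fhe_params")
}

#' @export
print.fhe_params <- function(x, ...) {
  cat(sprintf("<fhe_params CKKS: depth %d, scale 2^%d, degree %d, chain [%s]>\n",
              x$cost, x$scale_power, x$poly_modulus_degree,
              paste(x$coeff_mod_bit_sizes, collapse = ",")))
  invisible(x)
}

params_compatible <- function(a, b) {
  identical(a$poly_modulus_degree, b$poly_modulus_degree) &&
    identical(a$scale_power, b$scale_power) &&
    identical(a$coeff_mod_bit_sizes, b$coeff_mod_bit_sizes)
}

## Noise-model constants (the scheme gives only qualitative rules: additions
## double the noise -- +1 bit -- while multiplication grows it exponentially
## and is followed by a rescale that subtracts scale_power bits). Constants
## configurable via options(); the qualitative ordering is the contract.
noise_base <- function() getOption("fhenet.noise_base", 6)
noise_mult_k <- function() getOption("fhenet.noise_mult_k", 10)

## ---------------------------------------------------------------------------

#' Encrypt a message vector (simulated CKKS backend)
#'
#' The simulated backend is noise-exact in values: slot arithmetic is ordinary
#' double arithmetic, while the scale, modulus chain and a noise-bit estimate
#' are tracked exactly as a levelled CKKS ciphertext would, so depth and noise
#' misuse surface as errors without injecting numeric error. An optional noisy
#' mode (`options(fhenet.noisy_sd = )`) adds seeded Gaussian slot noise scaled
#' by the noise estimate, for robustness testing only.
#'
#' @param message numeric vector, length at most `params$slots`.
#' @param params an `fhe_params` object.
#' @param key_id opaque key identifier; ciphertexts interoperate only under
#'   the same key.
#' @return a `ckks_ct` ciphertext meta-object.
#' @export
encrypt <- function(message, params, key_id = "k0") {
  stopifnot(inherits(params, "fhe_params"))
  message <- as.numeric(message)
  if (length(message) > params$slots)
    stop(fhe_condition("fhe_capacity_error",
                       sprintf("message length %d exceeds slot capacity %d",
                               length(message), params$slots)))
  n <- length(params$coeff_mod_bit_sizes)
  chain <- if (n > 2L) params$coeff_mod_bit_sizes[2:(n - 1L)] else integer()
  structure(list(
    slots = c(message, numeric(params$slots - length(message))),
    msg_len = length(message),
    scale_log2 = params$scale_power,
    chain_remaining = chain,
    key_id = key_id,
    noise_bits = noise_base(),
    params = params
  ), class = "ckks_ct")
}

#' @export
print.ckks_ct <- function(x, ...) {
  cat(sprintf("<ckks_ct: %d/%d slots, key '%s', %d level(s) left, ~%.0f noise bits>\n",
              x$msg_len, length(x$slots), x$key_id,
              length(x$chain_remaining), x$noise_bits))
  invisible(x)
}

is_ct <- function(x) inherits(x, "ckks_ct")

check_interop <- function(a, b) {
  if (!identical(a$key_id, b$key_id))
    stop(fhe_condition("fhe_key_error",
                       "ciphertexts originate from different private keys"))
  if (!params_compatible(a$params, b$params))
    stop(fhe_condition("fhe_interop_error",
                       "ciphertexts must be identical containers (same parameters)"))
}

## Modulus swap: drop primes (no multiplication) until both operands sit at
## the same level; the operand higher up the chain is swapped down.
align_levels <- function(a, b) {
  la <- length(a$chain_remaining); lb <- length(b$chain_remaining)
  if (la > lb) a$chain_remaining <- a$chain_remaining[seq_len(lb) + (la - lb)]
  if (lb > la) b$chain_remaining <- b$chain_remaining[seq_len(la) + (lb - la)]
  list(a = a, b = b)
}

## Plaintext operands act on the message region only (padding stays zero);
## they must be scalar or match the message length. Whole-vector semantics:
## there is no sub-slot selection, every operation is element-wise over the
## packed message.
plain_operand <- function(ct, p) {
  p <- as.numeric(p)
  if (length(p) == 1L) p <- rep(p, ct$msg_len)
  if (length(p) != ct$msg_len)
    stop(fhe_condition("fhe_shape_error",
                       sprintf("plaintext operand length %d does not match message length %d",
                               length(p), ct$msg_len)))
  c(p, numeric(length(ct$slots) - ct$msg_len))
}

#' Homomorphic addition
#'
#' @param a a `ckks_ct`.
#' @param b a `ckks_ct` (same key and parameters) or a plaintext vector.
#' @return a `ckks_ct`; noise grows by one bit (a doubling), no chain
#'   consumption.
#' @export
ct_add <- function(a, b) {
  if (is_ct(b)) {
    check_interop(a, b)
    al <- align_levels(a, b); a <- al$a; b <- al$b
    a$slots <- a$slots + b$slots
    a$msg_len <- max(a$msg_len, b$msg_len)
    a$noise_bits <- max(a$noise_bits, b$noise_bits) + 1
  } else {
    a$slots <- a$slots + plain_operand(a, b)
    a$noise_bits <- a$noise_bits + 1
  }
  a
}

#' Homomorphic multiplication
#'
#' Element-wise product. The operand higher up the modulus chain is
#' automatically swapped down to match; the result is relinearised and
#' rescaled, consuming one chain prime. Multiplying two ciphertexts computes
#' the element-wise (Hadamard) product -- never cross terms: a packed
#' un-summed sequence multiplied by itself yields the per-slot squares, not
#' the square of its sum. Fold the ciphertext (see [rotate()]) first if a
#' genuine sum-of-products is required.
#'
#' @inheritParams ct_add
#' @return a `ckks_ct` one level down the chain.
#' @export
ct_mul <- function(a, b) {
  if (is_ct(b)) {
    check_interop(a, b)
    al <- align_levels(a, b); a <- al$a; b <- al$b
    if (length(a$chain_remaining) < 1L)
      stop(fhe_condition("fhe_depth_error",
                         "modulus chain exhausted: key rotation or refresh required"))
    a$slots <- a$slots * b$slots
    a$msg_len <- max(a$msg_len, b$msg_len)
    pre <- 2 * max(a$noise_bits, b$noise_bits) + noise_mult_k()
    a$noise_bits <- max(noise_base(), pre - a$scale_log2)
  } else {
    if (length(a$chain_remaining) < 1L)
      stop(fhe_condition("fhe_depth_error",
                         "modulus chain exhausted: key rotation or refresh required"))
    a$slots <- a$slots * plain_operand(a, b)
    pre <- 2 * a$noise_bits + noise_mult_k()
    a$noise_bits <- max(noise_base(), pre - a$scale_log2)
  }
  ## relinearise + rescale: consume one prime
  a$chain_remaining <- a$chain_remaining[-1L]
  a
}

#' Decrypt a ciphertext
#'
#' @param a a `ckks_ct`.
#' @param key_id key the caller holds; must match the ciphertext's.
#' @return the numeric message (zero padding stripped).
#' @export
decrypt <- function(a, key_id = a$key_id) {
  if (!identical(key_id, a$key_id))
    stop(fhe_condition("fhe_key_error", "decryption key does not match"))
  if (a$noise_bits > a$scale_log2)
    stop(fhe_condition("fhe_noise_error",
                       "noise exceeds the scale: decrypted message would be garbled"))
  if (a$noise_bits > a$scale_log2 - 10)
    warning("ciphertext noise approaching the scale; decryption loses precision",
            call. = FALSE)
  msg <- a$slots[seq_len(a$msg_len)]
  sd <- getOption("fhenet.noisy_sd", 0)
  if (sd > 0) msg <- msg + stats::rnorm(length(msg), 0, sd * a$noise_bits)
  msg
}

#' Key rotation (simulated decrypt / re-encrypt boundary)
#'
#' Rotation refreshes a ciphertext under (possibly new) parameters and key.
#' Modes: `"refresh"` keeps the packing and restores the full chain;
#' `"fold"` re-encrypts the slot-sum of the message as a length-1 message,
#' realising the sum a packed ciphertext cannot compute on itself; `"split"`
#' returns one ciphertext per requested slot range.
#'
#' @param a a `ckks_ct`.
#' @param new_params parameters for the re-encryption (default: current).
#' @param new_key_id key for the re-encryption (default: current).
#' @param mode one of "refresh", "fold", "split".
#' @param ranges for `"split"`: list of index vectors into the message
#'   (default: one singleton range per slot).
#' @return a `ckks_ct`, or a list of them for `"split"`.
#' @export
rotate <- function(a, new_params = a$params, new_key_id = a$key_id,
                   mode = c("refresh", "fold", "split"), ranges = NULL) {
  mode <- match.arg(mode)
  msg <- a$slots[seq_len(a$msg_len)]
  switch(mode,
    refresh = encrypt(msg, new_params, new_key_id),
    fold = encrypt(sum(msg), new_params, new_key_id),
    split = {
      if (is.null(ranges)) ranges <- as.list(seq_len(a$msg_len))
      lapply(ranges, function(ix) encrypt(msg[ix], new_params, new_key_id))
    })
}

## ---------------------------------------------------------------------------
## Array-conforming call surface: layers use ordinary `+` / `*` expressions,
## which run identically on plaintext arrays and ciphertexts. Only abelian
## operations exist between two ciphertexts; subtraction/division by a
## plaintext are sugar for addition/multiplication.

#' @export
Ops.ckks_ct <- function(e1, e2) {
  op <- .Generic
  if (missing(e2))
    stop(fhe_condition("fhe_compat_error",
                       paste0("unary '", op, "' is not defined for ciphertexts")))
  both <- is_ct(e1) && is_ct(e2)
  if (op == "+") {
    if (is_ct(e1)) return(ct_add(e1, e2))
    return(ct_add(e2, e1))
  }
  if (op == "*") {
    if (is_ct(e1)) return(ct_mul(e1, e2))
    return(ct_mul(e2, e1))
  }
  if (op == "-" && is_ct(e1) && !both) return(ct_add(e1, -as.numeric(e2)))
  if (op == "/" && is_ct(e1) && !both) return(ct_mul(e1, 1 / as.numeric(e2)))
  stop(fhe_condition("fhe_compat_error",
                     paste0("operation '", op,
                            "' is not abelian-compatible with FHE ciphertexts")))
}

#' Fold-sum a value
#'
#' Sums a packed ciphertext's message via a fold rotation (a ciphertext
#' cannot be folded onto itself homomorphically), or a plain vector with
#' `sum()`; part of the shared plaintext/ciphertext call surface.
#'
#' @param x a `ckks_ct` or numeric vector.
#' @param new_params,new_key_id optional re-encryption parameters/key for
#'   the rotation (default: current).
#' @export
fold_sum <- function(x, new_params = NULL, new_key_id = NULL) {
  if (is_ct(x)) {
    rotate(x,
           new_params = if (is.null(new_params)) x$params else new_params,
           new_key_id = if (is.null(new_key_id)) x$key_id else new_key_id,
           mode = "fold")
  } else sum(x)
}

value_length <- function(x) if (is_ct(x)) x$msg_len else length(x)

## ---------------------------------------------------------------------------
## Pluggable backend seam

#' Declare a real-CKKS backend
#'
#' The simulated backend is the default; a real CKKS implementation can be
#' registered by supplying the full operation contract as named functions
#' and storing the result in `options(fhenet.backend = )`, after which the
#' command surface accepts `backend = "plugin"`. The contract mirrors the
#' meta-object's operations; each function must be total over ciphertext
#' meta-objects.
#'
#' @param ops named list with functions `encrypt`, `decrypt`, `add`,
#'   `multiply`, `relinearise`, `rescale`, `refresh`.
#' @return the validated backend, classed `fhe_backend`.
#' @export
fhe_backend <- function(ops) {
  needed <- c("encrypt", "decrypt", "add", "multiply", "relinearise",
              "rescale", "refresh")
  missing_ops <- setdiff(needed, names(ops))
  if (length(missing_ops))
    stop(fhe_condition("fhe_value_error",
                       paste0("backend contract incomplete, missing: ",
                              paste(missing_ops, collapse = ", "))))
  for (nm in needed)
    if (!is.function(ops[[nm]]))
      stop(fhe_condition("fhe_value_error",
                         paste0("backend operation is not a function: ", nm)))
  structure(ops[needed], class = "fhe_backend")
}
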