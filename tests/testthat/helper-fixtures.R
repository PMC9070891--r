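# Shared fixtures for the suite; everything is built in code.

base_inputs <- function(...) default_model_inputs(structural = list(...))

# point values with named overrides
values_with <- function(inputs = base_inputs(), ...) {
  v <- base_values(inputs)
  ov <- list(...)
  for (k in names(ov)) v[[k]] <- ov[[k]]
  v
}

# inputs whose base values are overridden (ranges widened to stay valid)
inputs_with_base <- function(inputs = base_inputs(), ...) {
  ov <- list(...)
  for (k in names(ov)) {
    s <- inputs$params[[k]]
    inputs$params[[k]] <- dist_spec(s$family, ov[[k]],
                                    min(s$low, ov[[k]]),
                                    max(s$high, ov[[k]]))
  }
  validate_inputs(inputs)
}

# inputs where every parameter is pinned to its base (no sampling noise)
all_fixed_inputs <- function(inputs = base_inputs()) {
  inputs$params <- lapply(inputs$params, function(s) dist_spec("fixed", s$base))
  inputs
}

# a parameter set where i-CBT and f-CBT share every clinical rate
neutral_ratio_values <- function() {
  values_with(base_inputs(),
              rr_accept_icbt = 1, rr_adhere_icbt = 1,
              rr_recovery_icbt = 1, rr_deterioration_icbt = 1)
}

# random (but valid) dense stochastic matrices with a real root, for
# matrix_root property tests: M uniform-ish, then P = M %^% k
random_stochastic_with_root <- function(n, k, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n), n, n)
  M <- M + n * diag(n)  # diagonal dominance keeps eigenvalues positive
  M <- M / rowSums(M)
  P <- diag(n)
  for (i in seq_len(k)) P <- P %*% M
  list(M = M, P = P)
}
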