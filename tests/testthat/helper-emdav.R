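# Shared fixtures: everything is generated in code at test time.

# A small raw dataset with planted structure, cheap enough for most tests.
toy_dataset <- function(n = 80, p = 10, k = 2, seed = 42, ...) {
  synth_expression(synth_spec(n_samples = n, n_features = p,
                              n_informative = k, seed = seed, ...))
}

# A scaled dataset with a known feature count, ready for fitness evaluation
# and evolution (scaling only: the filters are exercised in their own tests).
toy_scaled <- function(n = 80, p = 10, k = 2, seed = 42, ...) {
  ds <- toy_dataset(n, p, k, seed, zero_feature_frac = 0, ...)
  scale_dataset(ds)
}

# Cheap training configuration for fitness tests.
fast_train <- function(epochs = 60, ...) {
  train_config(max_epochs = epochs, batch_size = 32, dropout_rate = 0, ...)
}

# Build an expression_dataset directly from a matrix.
ds_from_matrix <- function(m, target = seq_len(nrow(m)), stage = "raw") {
  expression_dataset(m, target = target, stage = stage)
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# Independent table-driven genome decoder used as an oracle: converts bit
# fields through strtoi() on pasted strings, sharing no code with the
# package's decoder.
oracle_decode <- function(bits, nf, lb, nb) {
  s <- paste(bits, collapse = "")
  mask <- substring(s, 1:nf, 1:nf) == "1"
  validation <- if (substring(s, nf + 1, nf + 1) == "0") "holdout" else "kfold"
  L <- strtoi(substring(s, nf + 2, nf + 1 + lb), base = 2) + 1
  base <- nf + 1 + lb
  hidden <- vapply(seq_len(L), function(i)
    strtoi(substring(s, base + (i - 1) * nb + 1, base + i * nb), base = 2) + 1,
    numeric(1))
  list(feature_mask = mask, validation = validation, hidden_layers = hidden)
}
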