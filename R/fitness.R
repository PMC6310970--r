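#' Fitness of a phenotype: repeated hold-out or k-fold validation
#'
#' The adaptation value minimised by the evolutionary search is the mean
#' test MSE of the phenotype's network across validation repetitions.
#'
#' `fitness_holdout()` repeats, `n_repetitions` times: draw a fresh random
#' 50/25/25 train/validation/test split, initialise fresh weights, train
#' with RMSprop and early stopping on the validation subset, and score MSE
#' and R-squared on the untouched test subset.
#'
#' `fitness_kfold()` scores each of `k` disjoint test folds once, holding
#' out 25% of the remaining training portion for early stopping.
#'
#' An infeasible phenotype (empty feature mask) is not trained at all: it
#' receives the worst-fitness sentinel `1e9`, far above any achievable MSE
#' on a `[0, 1]`-scaled target.
#'
#' @param phenotype a decoded [decode_genome()] phenotype.
#' @param ds a scaled [expression_dataset()].
#' @param config a [train_config()] for the inner RMSprop training.
#' @param n_repetitions number of hold-out repetitions.
#' @param seed integer seed controlling splits, inits, batches, dropout.
#' @return An object of class `fitness_record`: list with `phenotype`,
#'   `method`, `mse` and `r2` vectors (one entry per repetition or fold),
#'   `mean_mse` (the adaptation value), `mean_r2`, and `n_repetitions`.
#' @name fitness
NULL

WORST_FITNESS <- 1e9

#' @noRd
sentinel_record <- function(phenotype, method) {
  structure(list(phenotype = phenotype, method = method,
                 mse = WORST_FITNESS, r2 = NA_real_,
                 mean_mse = WORST_FITNESS, mean_r2 = NA_real_,
                 n_repetitions = 0L),
            class = "fitness_record")
}

#' @noRd
make_record <- function(phenotype, method, mse, r2) {
  structure(list(phenotype = phenotype, method = method, mse = mse, r2 = r2,
                 mean_mse = mean(mse), mean_r2 = mean(r2),
                 n_repetitions = length(mse)),
            class = "fitness_record")
}

# Train on one split and score the test portion.
#' @noRd
train_and_score <- function(X, y, itrain, ival, itest, hidden, config) {
  m <- mlp_init(c(ncol(X), hidden, 1L), seed = child_seed())
  cfg <- config
  cfg$seed <- NULL      # inherit the ambient stream; caller controls it
  fit <- train_mlp(m, X[itrain, , drop = FALSE], y[itrain],
                   X[ival, , drop = FALSE], y[ival], cfg)
  ev <- mlp_evaluate(fit$model, X[itest, , drop = FALSE], y[itest])
  c(ev$mse, ev$r2)
}

#' @rdname fitness
#' @export
fitness_holdout <- function(phenotype, ds, config = train_config(),
                            n_repetitions = 20, seed = NULL) {
  stopifnot(inherits(phenotype, "phenotype"),
            inherits(ds, "expression_dataset"))
  if (!phenotype$feasible) return(sentinel_record(phenotype, "holdout"))
  X <- ds$values[, phenotype$feature_mask, drop = FALSE]
  y <- ds$target
  n <- nrow(X)
  with_seed(seed, {
    res <- vapply(seq_len(n_repetitions), function(rep) {
      idx <- sample.int(n)
      n_tr <- floor(0.5 * n)
      n_va <- floor(0.25 * n)
      train_and_score(X, y, idx[1:n_tr], idx[(n_tr + 1):(n_tr + n_va)],
                      idx[(n_tr + n_va + 1):n], phenotype$hidden_layers, config)
    }, numeric(2))
    make_record(phenotype, "holdout", res[1L, ], res[2L, ])
  })
}

#' @param k number of folds.
#' @rdname fitness
#' @export
fitness_kfold <- function(phenotype, ds, config = train_config(), k = 10,
                          seed = NULL) {
  stopifnot(inherits(phenotype, "phenotype"),
            inherits(ds, "expression_dataset"))
  if (k < 2) stopf("k must be >= 2")
  if (!phenotype$feasible) return(sentinel_record(phenotype, "kfold"))
  X <- ds$values[, phenotype$feature_mask, drop = FALSE]
  y <- ds$target
  n <- nrow(X)
  if (n < k) stopf("cannot make %d folds from %d samples", k, n)
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), n))
    res <- vapply(seq_len(k), function(f) {
      itest <- which(fold == f)
      rest <- which(fold != f)
      rest <- rest[sample.int(length(rest))]
      n_va <- max(1L, floor(0.25 * length(rest)))
      train_and_score(X, y, rest[-seq_len(n_va)], rest[seq_len(n_va)],
                      itest, phenotype$hidden_layers, config)
    }, numeric(2))
    make_record(phenotype, "kfold", res[1L, ], res[2L, ])
  })
}

#' Fitness of a genome under the expression-data objective
#'
#' Decodes the genome and dispatches on its validation gene: hold-out
#' phenotypes are scored with [fitness_holdout()] (`n_repetitions`
#' repetitions), k-fold phenotypes with [fitness_kfold()] (`k` folds).
#'
#' @param bits genome bit vector.
#' @param encoding an [encoding_spec()].
#' @inheritParams fitness
#' @return A `fitness_record`.
#' @export
genome_fitness <- function(bits, encoding, ds, config = train_config(),
                           n_repetitions = 20, k = 10, seed = NULL) {
  p <- decode_genome(bits, encoding)
  if (p$validation == "holdout")
    fitness_holdout(p, ds, config, n_repetitions, seed)
  else
    fitness_kfold(p, ds, config, k, seed)
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("Fitness (%s, %d reps): mean MSE %.6g | mean R2 %.4g\n",
              x$method, x$n_repetitions, x$mean_mse, x$mean_r2))
  invisible(x)
}
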