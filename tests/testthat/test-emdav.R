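# Shared tiny fit used across the front-end tests (built once; ~seconds).
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- toy_scaled(n = 100, p = 8, k = 2, seed = 2)
      cache <<- emdav(ds, denoise = FALSE,
                      encoding = encoding_spec(n_feature_bits = 8,
                                               layer_field_bits = 1,
                                               node_field_bits = 4),
                      ga = ga_config(population_size = 6, max_generations = 3,
                                     stall_generations = 100, seed = 4),
                      training = fast_train(40),
                      final_training = train_config(optimizer = "rprop_plus",
                                                    dropout_rate = 0,
                                                    max_epochs = 200),
                      n_repetitions = 1, k = 3, seed = 4)
    }
    cache
  }
})

test_that("the fitting front-end returns a complete classed fit", {
  fit <- tiny_fit()
  expect_s3_class(fit, "emdav")
  expect_s3_class(fit$evolution, "emdav_evolution")
  expect_s3_class(fit$best_phenotype, "phenotype")
  expect_s3_class(fit$model, "mlp")
  expect_true(all(fit$selected %in% fit$feature_ids))
  expect_identical(fit$dataset$stage, "scaled")
  expect_output(print(fit), "Evolved predictive model")
  expect_output(summary(fit), "selected features")
})

test_that("predictions return on the original target scale", {
  fit <- tiny_fit()
  pred <- predict(fit)
  y <- emdav:::unscale_target(fit$dataset$target, fit$scaling)
  expect_length(pred, nrow(fit$dataset$values))
  # fitted values live in the plausible range of the original target
  expect_lt(mean((pred - y)^2), var(y) * 2)
  expect_equal(residuals(fit), y - fitted(fit), tolerance = 1e-12)

  # prediction on the training matrix in original units reproduces fitted()
  ds0 <- synth_expression(synth_spec(n_samples = 100, n_features = 8,
                                     n_informative = 2, seed = 2,
                                     zero_feature_frac = 0))
  pred2 <- predict(fit, newdata = ds0$values)
  expect_equal(pred2, pred, tolerance = 1e-10)
})

test_that("coef() exposes signed Olden importances of the selected features", {
  fit <- tiny_fit()
  cf <- coef(fit)
  expect_named(cf, fit$selected)
  expect_true(all(is.finite(cf)))
})

test_that("fits are reproducible under the same master seed", {
  ds <- toy_scaled(n = 60, p = 6, k = 2, seed = 10)
  args <- list(ds, denoise = FALSE,
               encoding = encoding_spec(6, 1, 3),
               ga = ga_config(population_size = 4, max_generations = 2,
                              stall_generations = 100, seed = 6),
               training = fast_train(15), n_repetitions = 1, k = 3, seed = 6,
               final_training = train_config(optimizer = "rprop_plus",
                                             dropout_rate = 0, max_epochs = 50))
  a <- do.call(emdav, args)
  b <- do.call(emdav, args)
  expect_identical(a$evolution$generations, b$evolution$generations)
  expect_equal(a$model$W, b$model$W, tolerance = 1e-15)
  expect_identical(a$selected, b$selected)
})

test_that("the formula interface agrees with the matrix interface", {
  ds <- synth_expression(synth_spec(n_samples = 100, n_features = 5,
                                    n_informative = 2, seed = 12,
                                    dispersion = 2, zero_inflation = 0.02,
                                    zero_feature_frac = 0))
  df <- as.data.frame(ds)
  shared <- list(denoise = FALSE, encoding = encoding_spec(5, 1, 3),
                 ga = ga_config(population_size = 4, max_generations = 2,
                                stall_generations = 100, seed = 8),
                 training = fast_train(15), n_repetitions = 1, k = 3, seed = 8,
                 final_training = train_config(optimizer = "rprop_plus",
                                               dropout_rate = 0,
                                               max_epochs = 50))
  f1 <- do.call(emdav, c(list(target ~ ., data = df), shared))
  f2 <- do.call(emdav, c(list(as.matrix(df[, -ncol(df)]), df$target), shared))
  expect_identical(f1$selected, f2$selected)
  expect_equal(f1$best_fitness$mean_mse, f2$best_fitness$mean_mse)
})

test_that("the evolution trace plots without error", {
  fit <- tiny_fit()
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  imp <- olden_aggregate(list(fit$model), fit$selected)
  expect_silent(plot(imp))
})

test_that("multi-execution runs consolidate a ranked report", {
  ds <- toy_scaled(n = 60, p = 6, k = 2, seed = 20)
  runs <- run_emdav(ds, n_executions = 2,
                    encoding = encoding_spec(ncol(ds$values), 1, 3),
                    ga = ga_config(population_size = 4, max_generations = 2,
                                   stall_generations = 100),
                    training = fast_train(15), n_repetitions = 1, k = 3,
                    seed = 14)
  expect_length(runs$results, 2)
  expect_length(unique(runs$seeds), 2)
  expect_true(!is.unsorted(runs$report$mse))
  expect_true(all(c("generations", "evaluations", "n_features", "validation",
                    "hidden_layers", "mse", "r2") %in% names(runs$report)))
})
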