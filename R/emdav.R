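#' Evolutionary model search: feature subset, architecture and validation
#'
#' `emdav()` is the fitting front-end. It takes an expression table (samples
#' in rows), preprocesses it (presence and low-information filters,
#' optional discrete Meyer wavelet denoising, range scaling), then runs a
#' binary genetic algorithm whose genome jointly encodes the input-feature
#' mask, the validation method (hold-out vs k-fold) and the hidden-layer
#' sizes of a deep MLP. Each genome is scored by training its network with
#' RMSprop under the encoded validation scheme and taking the mean test MSE
#' as the (minimised) adaptation value. The best phenotype is finally
#' refitted on the full data with Rprop+ (resilient backpropagation with
#' weight backtracking, no dropout) to give the predictive model used by
#' `predict()`, `fitted()`, `residuals()` and the Olden importance methods.
#'
#' @param x samples-by-features numeric matrix or data frame, or an
#'   [expression_dataset()] (raw or already scaled).
#' @param y numeric target vector (ignored when `x` is an
#'   `expression_dataset`).
#' @param data for the formula method, a data frame holding predictors and
#'   response.
#' @param formula model formula such as `smad7 ~ .`.
#' @param preprocess_data logical; run filters/denoising/scaling. Scaled
#'   datasets are passed through untouched.
#' @param denoise apply wavelet denoising during preprocessing.
#' @param encoding an [encoding_spec()]; `NULL` derives one from the
#'   post-filter feature count with the default 6/10 layer/node field
#'   widths.
#' @param ga a [ga_config()].
#' @param training a [train_config()] for the inner RMSprop trainings.
#' @param n_repetitions hold-out repetitions per fitness evaluation.
#' @param k folds per k-fold fitness evaluation.
#' @param final_training a [train_config()] for the final Rprop+ refit;
#'   the default disables dropout and trains full-batch.
#' @param seed master seed; fixes the whole run.
#' @param ... passed between methods.
#'
#' @return An object of class `emdav`: list with `evolution` (the
#'   [evolve()] trace), `best_phenotype`, `best_fitness` (a
#'   `fitness_record`), `model` (the final Rprop+-trained `mlp`),
#'   `feature_ids` (the post-filter candidate features), `selected`
#'   (features in the best mask), `scaling`, `dataset` (the scaled
#'   training dataset) and `call`.
#' @examples
#' \donttest{
#' ds <- synth_expression(synth_spec(n_samples = 120, n_features = 12,
#'                                   n_informative = 3, seed = 2))
#' fit <- emdav(ds, denoise = FALSE,
#'              ga = ga_config(population_size = 8, max_generations = 4),
#'              training = train_config(max_epochs = 60, dropout_rate = 0),
#'              n_repetitions = 1, k = 3, seed = 9)
#' print(fit)
#' head(predict(fit))
#' }
#' @export
emdav <- function(x, ...) UseMethod("emdav")

#' @rdname emdav
#' @export
emdav.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1L, drop = FALSE]
  fit <- emdav.default(as.matrix(x), y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname emdav
#' @export
emdav.default <- function(x, y, ...) {
  ds <- expression_dataset(as.matrix(x), target = y)
  fit <- emdav.expression_dataset(ds, ...)
  fit$call <- match.call()
  fit
}

#' @rdname emdav
#' @export
emdav.expression_dataset <- function(x, preprocess_data = TRUE, denoise = TRUE,
                                     encoding = NULL, ga = ga_config(),
                                     training = train_config(),
                                     n_repetitions = 20, k = 10,
                                     final_training = train_config(
                                       optimizer = "rprop_plus",
                                       dropout_rate = 0),
                                     seed = 1L, ...) {
  ds <- x
  scaling_params <- attr(ds, "scaling")
  if (ds$stage != "scaled") {
    if (preprocess_data) {
      pp <- preprocess(ds, denoise = denoise)
      ds <- pp$dataset
      scaling_params <- pp$scaling
    } else {
      stopf("dataset must be scaled (or set preprocess_data = TRUE)")
    }
  }
  if (is.null(encoding))
    encoding <- encoding_spec(n_feature_bits = ncol(ds$values))
  if (encoding$n_feature_bits != ncol(ds$values))
    stopf("encoding expects %d features, dataset has %d",
          encoding$n_feature_bits, ncol(ds$values))
  ga$seed <- ga$seed %||% seed
  # every genome is scored on the same random splits (common random numbers):
  # fitness differences then reflect the phenotypes, not the draw of splits
  fitness_seed <- with_seed(seed, child_seed())
  fitness_fn <- function(bits)
    genome_fitness(bits, encoding, ds, training, n_repetitions, k,
                   seed = fitness_seed)$mean_mse
  evo <- evolve(fitness_fn, encoding$genome_length, ga,
                init_fn = function() random_genome(encoding))
  best_p <- decode_genome(evo$best_bits, encoding)
  best_rec <- with_seed(seed + 1L,
    if (best_p$validation == "holdout")
      fitness_holdout(best_p, ds, training, n_repetitions, seed = child_seed())
    else
      fitness_kfold(best_p, ds, training, k, seed = child_seed()))
  model <- with_seed(seed + 2L,
                     train_final(best_p, ds, final_training))
  structure(list(evolution = evo, best_phenotype = best_p,
                 best_fitness = best_rec, model = model,
                 encoding = encoding, feature_ids = ds$feature_ids,
                 selected = ds$feature_ids[best_p$feature_mask],
                 scaling = scaling_params, dataset = ds,
                 training = training, final_training = final_training,
                 seed = seed, call = match.call()),
            class = "emdav")
}

#' Refit a phenotype on the full dataset with Rprop+
#'
#' Trains the phenotype's network on 75% of the samples with the remaining
#' 25% as early-stopping validation, full-batch Rprop+ and (by default) no
#' dropout — the protocol used for the final predictive model and for the
#' importance runs.
#'
#' @inheritParams fitness
#' @param config a [train_config()], normally `optimizer = "rprop_plus"`.
#' @return The trained `mlp` (best-validation snapshot).
#' @export
train_final <- function(phenotype, ds, config = train_config(
                          optimizer = "rprop_plus", dropout_rate = 0),
                        seed = NULL) {
  stopifnot(inherits(phenotype, "phenotype"))
  if (!phenotype$feasible) stopf("cannot refit an infeasible phenotype")
  X <- ds$values[, phenotype$feature_mask, drop = FALSE]
  y <- ds$target
  with_seed(seed, {
    n <- nrow(X)
    idx <- sample.int(n)
    n_va <- max(1L, floor(0.25 * n))
    ival <- idx[seq_len(n_va)]
    itr <- idx[-seq_len(n_va)]
    m <- mlp_init(c(ncol(X), phenotype$hidden_layers, 1L), seed = child_seed())
    cfg <- config
    cfg$seed <- NULL
    fit <- train_mlp(m, X[itr, , drop = FALSE], y[itr],
                     X[ival, , drop = FALSE], y[ival], cfg)
    fit$model
  })
}

#' Repeated evolutionary executions with a consolidated report
#'
#' Runs the full evolutionary search `n_executions` times with independent
#' seeds derived from `seed`, and consolidates the best phenotypes into a
#' ranked report (ascending mean MSE) with, per run: the generation and
#' evaluation bookkeeping, the selected-feature count, validation method,
#' hidden-layer spec, MSE and R-squared.
#'
#' @inheritParams emdav.expression_dataset
#' @param ds a scaled [expression_dataset()].
#' @param n_executions independent executions.
#' @param top keep the `top` best rows in the report.
#' @return An object of class `emdav_runs`: list with `results` (one
#'   `emdav` fit per execution), `report` (data frame), `seeds`.
#' @export
run_emdav <- function(ds, n_executions = 20, encoding = NULL,
                      ga = ga_config(), training = train_config(),
                      n_repetitions = 20, k = 10, seed = 1L, top = 10) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_executions))
  results <- lapply(seq_len(n_executions), function(i) {
    cfg <- ga
    cfg$seed <- seeds[i]
    emdav.expression_dataset(ds, preprocess_data = FALSE, encoding = encoding,
                             ga = cfg, training = training,
                             n_repetitions = n_repetitions, k = k,
                             seed = seeds[i])
  })
  report <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(execution = i, seed = seeds[i],
               generations = nrow(r$evolution$generations),
               evaluations = r$evolution$evaluations,
               n_features = sum(r$best_phenotype$feature_mask),
               validation = r$best_phenotype$validation,
               hidden_layers = paste(r$best_phenotype$hidden_layers,
                                     collapse = ":"),
               mse = r$best_fitness$mean_mse, r2 = r$best_fitness$mean_r2,
               stringsAsFactors = FALSE)
  }))
  report <- report[order(report$mse), , drop = FALSE]
  report <- utils::head(report, top)
  rownames(report) <- NULL
  structure(list(results = results, report = report, seeds = seeds),
            class = "emdav_runs")
}

#' @export
print.emdav_runs <- function(x, ...) {
  cat(sprintf("Evolutionary search: %d executions\n", length(x$results)))
  print(x$report)
  invisible(x)
}

#' @export
print.emdav <- function(x, ...) {
  cat("Evolved predictive model (GA over features / architecture / validation)\n")
  cat(sprintf("  features: %d of %d candidates selected\n",
              length(x$selected), length(x$feature_ids)))
  cat(sprintf("  architecture: %s | validation: %s\n",
              paste(x$best_phenotype$hidden_layers, collapse = ":"),
              x$best_phenotype$validation))
  cat(sprintf("  fitness: mean MSE %.6g, mean R2 %.4g (%d reps)\n",
              x$best_fitness$mean_mse, x$best_fitness$mean_r2,
              x$best_fitness$n_repetitions))
  cat(sprintf("  evolution: %d generations, %d evaluations (%s)\n",
              nrow(x$evolution$generations), x$evolution$evaluations,
              x$evolution$termination))
  invisible(x)
}

#' @export
summary.emdav <- function(object, ...) {
  print(object)
  ev <- mlp_evaluate(object$model,
                     object$dataset$values[, object$best_phenotype$feature_mask,
                                           drop = FALSE],
                     object$dataset$target)
  cat(sprintf("  final Rprop+ refit on full data: MSE %.6g, R2 %.4g\n",
              ev$mse, ev$r2))
  cat("  selected features:\n")
  cat(strwrap(paste(object$selected, collapse = ", "), width = 70,
              prefix = "    "), sep = "\n")
  invisible(object)
}

#' Predict from an evolved model
#'
#' New data are mapped through the stored feature scaling, passed through
#' the final Rprop+ network, and predictions are returned on the original
#' target scale (inverting the `[0, 1]` target scaling). Note that wavelet
#' denoising is a cohort-level transform (it smooths each feature across
#' samples) and is not applied to new data.
#'
#' @param object an `emdav` fit.
#' @param newdata matrix or data frame with the candidate feature columns;
#'   `NULL` returns fitted values for the training data.
#' @param scale_newdata set to `FALSE` if `newdata` is already on the
#'   scaled `[-1, 1]` feature scale; predictions are then returned on the
#'   `[0, 1]` target scale.
#' @param ... unused.
#' @export
predict.emdav <- function(object, newdata = NULL, scale_newdata = TRUE, ...) {
  mask <- object$best_phenotype$feature_mask
  if (is.null(newdata)) {
    Xs <- object$dataset$values[, mask, drop = FALSE]
    pred <- mlp_forward(object$model, Xs)
    return(if (is.null(object$scaling)) pred
           else unscale_target(pred, object$scaling))
  }
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_ids %in% colnames(newdata)))
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  if (ncol(newdata) != length(object$feature_ids))
    stopf("newdata has %d columns; expected the %d candidate features",
          ncol(newdata), length(object$feature_ids))
  if (scale_newdata) {
    if (is.null(object$scaling)) stopf("fit carries no scaling parameters")
    newdata <- scale_apply_features(newdata, object$scaling)
  }
  pred <- mlp_forward(object$model, newdata[, mask, drop = FALSE])
  if (scale_newdata && !is.null(object$scaling))
    unscale_target(pred, object$scaling)
  else pred
}

#' @export
fitted.emdav <- function(object, ...) predict.emdav(object)

#' @export
residuals.emdav <- function(object, ...) {
  y <- if (is.null(object$scaling)) object$dataset$target
       else unscale_target(object$dataset$target, object$scaling)
  y - fitted.emdav(object)
}

#' @export
coef.emdav <- function(object, ...) {
  imp <- olden(object$model)
  names(imp) <- object$selected
  imp
}

#' Fitness-trajectory plot
#'
#' @param x an `emdav` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.emdav <- function(x, ...) {
  g <- x$evolution$generations
  graphics::plot(g$generation, g$best, type = "s", lwd = 2,
                 xlab = "generation", ylab = "MSE (adaptation value)",
                 main = "Best and mean fitness by generation", ...)
  graphics::lines(g$generation, g$mean, lty = 2, col = "grey40")
  graphics::legend("topright", legend = c("best", "population mean"),
                   lty = c(1, 2), lwd = c(2, 1), col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}
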