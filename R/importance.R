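#' Olden connection-weight importance
#'
#' The signed importance of input `i` is the sum over all input-to-output
#' paths of the product of connection weights along the path — equivalently
#' the `i`-th entry of the chained product of all weight matrices (biases
#' excluded, activations ignored). Sign is preserved: a large positive
#' value marks an input whose excitation raises the prediction, a negative
#' one an input acting repressively. For networks with more than one hidden
#' layer the product simply chains every layer matrix, the natural
#' extension of the single-hidden-layer connection-weights scheme.
#'
#' @param m a trained `mlp` with at least one hidden layer.
#' @return `olden()`: numeric vector of signed importances, one per input.
#' @examples
#' m <- mlp_init(c(2, 1, 1))
#' m$W[[1]][] <- c(2, -1); m$W[[2]][] <- 3
#' olden(m)   # 6 -3
#' @export
olden <- function(m) {
  stopifnot(inherits(m, "mlp"))
  if (length(m$W) < 2L) stopf("Olden importance needs at least one hidden layer")
  drop(Reduce(`%*%`, m$W))
}

#' Aggregate Olden importances over repeated training runs
#'
#' Averages the signed importances of independently trained models of the
#' same phenotype, then renormalises the features with positive mean
#' importance to percentages summing to 100% — the "relative importance in
#' the positive direction" table. Features with non-positive mean are kept
#' in the table with their signed mean but carry no percentage.
#'
#' @param models list of trained `mlp` objects sharing the input feature
#'   list.
#' @param feature_ids character vector naming the inputs.
#' @return An object of class `importance_table`: data frame with columns
#'   `feature_id`, `mean_signed`, `positive_relative_pct` (NA for
#'   non-positive means), `rank` (by descending percentage), ordered by
#'   descending percentage then descending mean; attribute `"runs"` holds
#'   the per-run signed importance matrix.
#' @export
olden_aggregate <- function(models, feature_ids = NULL) {
  stopifnot(length(models) >= 1L)
  imps <- lapply(models, olden)
  n_in <- length(imps[[1L]])
  if (any(vapply(imps, length, 1L) != n_in))
    stopf("models disagree on the number of inputs")
  runs <- do.call(rbind, imps)
  mean_signed <- colMeans(runs)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(n_in))
  if (length(feature_ids) != n_in)
    stopf("%d feature ids for %d inputs", length(feature_ids), n_in)
  pos <- mean_signed > 0
  pct <- rep(NA_real_, n_in)
  if (any(pos)) pct[pos] <- 100 * mean_signed[pos] / sum(mean_signed[pos])
  ord <- order(-replace(pct, is.na(pct), -Inf), -mean_signed)
  tbl <- data.frame(feature_id = feature_ids, mean_signed = mean_signed,
                    positive_relative_pct = pct,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  tbl$rank <- seq_len(n_in)
  rownames(tbl) <- NULL
  colnames(runs) <- feature_ids
  structure(tbl, class = c("importance_table", "data.frame"),
            runs = runs, n_runs = length(models))
}

#' @export
print.importance_table <- function(x, digits = 4, ...) {
  cat(sprintf("Olden connection-weight importance (%d runs)\n",
              attr(x, "n_runs")))
  df <- as.data.frame(x)
  df$positive_relative_pct <- ifelse(is.na(df$positive_relative_pct), "",
                                     sprintf("%.2f%%", df$positive_relative_pct))
  print(df, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Ensemble importance for an evolved model
#'
#' Retrains the best phenotype `n_runs` times with Rprop+ (no dropout),
#' runs differing only by seed, and aggregates the Olden importances.
#'
#' @param object an `emdav` fit.
#' @param n_runs number of independent trainings.
#' @param config training configuration for each run.
#' @param seed master seed for the ensemble.
#' @return An `importance_table` over the selected features.
#' @export
olden_ensemble <- function(object, n_runs = 20,
                           config = object$final_training, seed = 1L) {
  stopifnot(inherits(object, "emdav"))
  models <- with_seed(seed, lapply(seq_len(n_runs), function(i)
    train_final(object$best_phenotype, object$dataset, config,
                seed = child_seed())))
  olden_aggregate(models, object$selected)
}

#' Rank recovery of planted features
#'
#' Harness for synthetic data: reports where the planted informative
#' features land in an aggregated importance table, and whether the sign of
#' their mean importance agrees with the planted effect direction.
#'
#' @param table an `importance_table`.
#' @param truth the `"truth"` attribute of a synthetic dataset (or any list
#'   with `informative_ids` and `effect_weights`).
#' @return Data frame with one row per planted feature: `feature_id`,
#'   `planted_weight`, `rank`, `mean_signed`, `sign_agrees`.
#' @export
importance_recovery <- function(table, truth) {
  stopifnot(inherits(table, "importance_table"))
  idx <- match(truth$informative_ids, table$feature_id)
  data.frame(feature_id = truth$informative_ids,
             planted_weight = truth$effect_weights,
             rank = table$rank[idx],
             mean_signed = table$mean_signed[idx],
             sign_agrees = sign(table$mean_signed[idx]) ==
               sign(truth$effect_weights),
             stringsAsFactors = FALSE)
}

#' @rdname olden
#' @param x an `importance_table`.
#' @param top plot at most this many features.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.importance_table <- function(x, top = 25, ...) {
  df <- utils::head(as.data.frame(x[!is.na(x$positive_relative_pct), ]), top)
  graphics::barplot(rev(df$positive_relative_pct),
                    names.arg = rev(df$feature_id), horiz = TRUE, las = 1,
                    xlab = "relative importance (%)",
                    main = "Positive-direction Olden importance", ...)
  invisible(x)
}
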