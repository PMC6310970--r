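#' Presence filter: drop features with no expression anywhere
#'
#' Removes features whose expression is exactly zero in every sample (rule
#' `all_zero`). Samples with a zero target are reported in the filter report
#' but never dropped.
#'
#' @param ds an [expression_dataset()], stage `"raw"` or `"filtered"`.
#' @return A list with elements `dataset` (stage `"filtered"`) and `report`
#'   (a `filter_report`).
#' @seealso [filter_low_information()]
#' @export
filter_presence <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!ds$stage %in% c("raw", "filtered"))
    stopf("presence filter expects a raw or filtered dataset, got '%s'", ds$stage)
  drop <- which(colSums(ds$values != 0) == 0L)
  rules <- rep("all_zero", length(drop))
  names(rules) <- ds$feature_ids[drop]
  report <- filter_report(removed_ids = ds$feature_ids[drop], rule_per_id = rules,
                          kept_count = ncol(ds$values) - length(drop),
                          input_count = ncol(ds$values),
                          zero_target_samples = which(ds$target == 0))
  out <- drop_features(ds, drop)
  list(dataset = advance_stage(out, "filtered"), report = report)
}

#' Low-information filter: third-quartile and zero-mode rules
#'
#' A feature is removed iff its third quartile is below `q3_threshold`
#' (rule `q3_below_2`), or its mode equals zero and the mode accounts for
#' more than `mode_freq` of the samples (rule `zero_mode_frequent`). The
#' first matching rule, in that order, is the one reported. Quartiles use
#' linear interpolation between order statistics (the type-7 convention);
#' the mode is taken over values rounded to `mode_digits` decimals so that
#' exact zeros — the case the rule targets — compare reliably.
#'
#' @inheritParams filter_presence
#' @param q3_threshold expression level the third quartile must reach.
#' @param mode_freq maximum tolerated frequency of a zero mode, as a
#'   fraction of samples.
#' @param mode_digits decimals used when tabulating the mode.
#' @return A list with elements `dataset` and `report`.
#' @export
filter_low_information <- function(ds, q3_threshold = 2, mode_freq = 0.15,
                                   mode_digits = 6) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!ds$stage %in% c("raw", "filtered"))
    stopf("low-information filter expects a raw or filtered dataset, got '%s'",
          ds$stage)
  n <- nrow(ds$values)
  rules <- character(0)
  drop <- integer(0)
  for (j in seq_len(ncol(ds$values))) {
    x <- ds$values[, j]
    if (stats::quantile(x, 0.75, type = 7, names = FALSE) < q3_threshold) {
      drop <- c(drop, j); rules <- c(rules, "q3_below_2"); next
    }
    tab <- table(round(x, mode_digits))
    mode_val <- as.numeric(names(tab)[which.max(tab)])
    if (mode_val == 0 && max(tab) / n > mode_freq) {
      drop <- c(drop, j); rules <- c(rules, "zero_mode_frequent")
    }
  }
  names(rules) <- ds$feature_ids[drop]
  report <- filter_report(removed_ids = ds$feature_ids[drop], rule_per_id = rules,
                          kept_count = ncol(ds$values) - length(drop),
                          input_count = ncol(ds$values),
                          quantile_type = 7)
  out <- drop_features(ds, drop)
  list(dataset = advance_stage(out, "filtered"), report = report)
}

#' @noRd
drop_features <- function(ds, idx) {
  if (length(idx) == 0L) return(ds)
  if (length(idx) == ncol(ds$values)) stopf("filter would remove every feature")
  ds$values <- ds$values[, -idx, drop = FALSE]
  ds$feature_ids <- ds$feature_ids[-idx]
  ds
}

#' @noRd
filter_report <- function(removed_ids, rule_per_id, kept_count, input_count, ...) {
  structure(list(removed_ids = removed_ids, rule_per_id = rule_per_id,
                 kept_count = kept_count, input_count = input_count, ...),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: kept %d / %d features, removed %d\n",
              x$kept_count, x$input_count, length(x$removed_ids)))
  if (length(x$rule_per_id))
    print(table(unname(x$rule_per_id)))
  if (length(x$zero_target_samples %||% integer(0)))
    cat(sprintf("  %d samples with zero target (reported, not dropped)\n",
                length(x$zero_target_samples)))
  invisible(x)
}

#' Advisory collinearity screen
#'
#' Flags all feature pairs whose absolute Pearson correlation reaches
#' `r_threshold`. Purely advisory: nothing is removed. On typical filtered
#' expression panels the expected outcome is an empty set, confirming the
#' absence of exact linear relationships among predictors.
#'
#' @inheritParams filter_presence
#' @param r_threshold absolute correlation at or above which a pair is
#'   flagged.
#' @return A data frame with columns `feature_a`, `feature_b`, `r`, ordered
#'   by decreasing `|r|`.
#' @export
collinearity_report <- function(ds, r_threshold = 0.95) {
  stopifnot(inherits(ds, "expression_dataset"))
  cm <- suppressWarnings(stats::cor(ds$values))
  cm[!is.finite(cm)] <- 0
  cm[lower.tri(cm, diag = TRUE)] <- 0
  hit <- which(abs(cm) >= r_threshold, arr.ind = TRUE)
  out <- data.frame(feature_a = ds$feature_ids[hit[, 1L]],
                    feature_b = ds$feature_ids[hit[, 2L]],
                    r = cm[hit], stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Full preprocessing pipeline
#'
#' Applies, in order: presence filter, low-information filter, per-feature
#' discrete Meyer wavelet denoising (sample order taken as the series
#' order), and range scaling of features and target.
#'
#' @inheritParams filter_presence
#' @param denoise logical; apply wavelet denoising.
#' @param wavelet a [wavelet_spec()].
#' @param scaling a [scaling_spec()].
#' @return A list with elements `dataset` (stage `"scaled"`),
#'   `presence_report`, `low_information_report`, and `scaling` (the stored
#'   scaling parameters).
#' @export
preprocess <- function(ds, denoise = TRUE, wavelet = wavelet_spec(),
                       scaling = scaling_spec()) {
  p1 <- filter_presence(ds)
  p2 <- filter_low_information(p1$dataset)
  out <- p2$dataset
  if (denoise) {
    out$values <- apply(out$values, 2L, meyer_denoise, spec = wavelet)
    out <- advance_stage(out, "denoised")
  }
  out <- scale_dataset(out, scaling)
  list(dataset = out, presence_report = p1$report,
       low_information_report = p2$report, scaling = attr(out, "scaling"))
}
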