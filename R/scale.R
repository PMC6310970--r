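#' Range scaling of features and target
#'
#' Features are mapped to `[-1, 1]` so that they sit in the sensitive range
#' of the logistic hidden units; the target is mapped to `[0, 1]`, the range
#' the (linear-output) network is asked to predict. Two feature methods are
#' provided:
#'
#' * `"minmax"` (default): `2 * (x - min) / (max - min) - 1`, which
#'   guarantees the stated `[-1, 1]` range for any column;
#' * `"mean_anchored"`: `(x - mean(x)) / (max(x) - mean(x))`, the
#'   mean-anchored variant; note that for asymmetric columns its lower end
#'   falls below -1, so it does not in general achieve the nominal range —
#'   it is kept selectable for comparability.
#'
#' The target always uses `(y - min) / (max - min)`. Scaling parameters are
#' stored on the result (attribute `"scaling"`) so the transform can be
#' inverted exactly.
#'
#' @param ds an [expression_dataset()]; constant feature columns are an
#'   error (run the filters first).
#' @param spec a [scaling_spec()].
#' @return The scaled dataset (stage `"scaled"`) carrying attribute
#'   `"scaling"`.
#' @export
scale_dataset <- function(ds, spec = scaling_spec()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(spec, "scaling_spec"))
  x <- ds$values
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  means <- colMeans(x)
  const <- which(maxs == if (spec$method == "minmax") mins else means)
  if (length(const))
    stopf("degenerate (constant) feature column(s): %s",
          paste(ds$feature_ids[const], collapse = ", "))
  if (ds$target_id != "" && max(ds$target) == min(ds$target))
    stopf("degenerate target: all values equal")
  scaled <- if (spec$method == "minmax")
    sweep(sweep(x, 2L, mins), 2L, maxs - mins, "/") * 2 - 1
  else
    sweep(sweep(x, 2L, means), 2L, maxs - means, "/")
  tmin <- min(ds$target); tmax <- max(ds$target)
  ds$values <- scaled
  ds$target <- (ds$target - tmin) / (tmax - tmin)
  ds <- advance_stage(ds, "scaled")
  attr(ds, "scaling") <- list(method = spec$method, feature_min = mins,
                              feature_max = maxs, feature_mean = means,
                              target_min = tmin, target_max = tmax)
  ds
}

#' @param method feature scaling method, `"minmax"` or `"mean_anchored"`.
#' @rdname scale_dataset
#' @export
scaling_spec <- function(method = c("minmax", "mean_anchored")) {
  structure(list(method = match.arg(method)), class = "scaling_spec")
}

#' @rdname scale_dataset
#' @return `inverse_scale()`: the dataset with values and target restored to
#'   their original units (stage left at `"scaled"`-derived provenance is
#'   dropped; the object is returned with stage `"scaled"` but original
#'   units, for inspection).
#' @export
inverse_scale <- function(ds) {
  sc <- attr(ds, "scaling")
  if (is.null(sc)) stopf("dataset carries no scaling parameters")
  x <- ds$values
  ds$values <- if (sc$method == "minmax")
    sweep(sweep((x + 1) / 2, 2L, sc$feature_max - sc$feature_min, "*"),
          2L, sc$feature_min, "+")
  else
    sweep(sweep(x, 2L, sc$feature_max - sc$feature_mean, "*"),
          2L, sc$feature_mean, "+")
  ds$target <- ds$target * (sc$target_max - sc$target_min) + sc$target_min
  attr(ds, "scaling") <- NULL
  ds
}

# Apply / invert the stored scaling to new data (prediction path).
#' @noRd
scale_apply_features <- function(x, sc) {
  if (sc$method == "minmax")
    sweep(sweep(x, 2L, sc$feature_min), 2L, sc$feature_max - sc$feature_min,
          "/") * 2 - 1
  else
    sweep(sweep(x, 2L, sc$feature_mean), 2L, sc$feature_max - sc$feature_mean,
          "/")
}

#' @noRd
unscale_target <- function(y, sc) y * (sc$target_max - sc$target_min) + sc$target_min
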