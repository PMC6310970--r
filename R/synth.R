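#' Specification of a synthetic expression dataset
#'
#' Describes a zero-inflated, right-skewed expression matrix in which a small
#' planted subset of features drives the target through a (possibly
#' sigmoidal) response with signed effect weights, negative weights playing
#' the role of repressive regulators. The shape mimics miRNA expression
#' tables: nonnegative magnitudes with a long right tail, a fraction of
#' structural zeros per feature, and a few features with no expression at
#' all so that the presence filter has work to do.
#'
#' @param n_samples,n_features matrix dimensions.
#' @param n_informative number of planted features driving the target.
#' @param zero_inflation probability in `[0, 1)` that any single expression
#'   value is a structural zero.
#' @param dispersion `sdlog` of the log-normal magnitude draw; values above
#'   1 give the pronounced right skew typical of expression data.
#' @param effect_weights signed weights of the informative features. The
#'   default assigns magnitudes decreasing from 2 to 1 and makes every third
#'   feature repressive (negative).
#' @param noise_sd standard deviation of Gaussian noise added to the target.
#' @param link response link: `"sigmoid"` (logistic, matching the network's
#'   representable family) or `"linear"` (identity).
#' @param zero_feature_frac fraction of features generated identically zero.
#' @param seed integer seed; generation is a pure function of the spec.
#'
#' @return An object of class `synth_spec`.
#' @seealso [synth_expression()]
#' @export
synth_spec <- function(n_samples = 1000, n_features = 120, n_informative = 6,
                       zero_inflation = 0.1, dispersion = 1.5,
                       effect_weights = NULL, noise_sd = 0.05,
                       link = c("sigmoid", "linear"),
                       zero_feature_frac = 0.05, seed = 1L) {
  link <- match.arg(link)
  for (nm in c("n_samples", "n_features", "n_informative"))
    if (!is_count(get(nm))) stopf("`%s` must be a positive integer", nm)
  if (n_informative > n_features)
    stopf("n_informative (%d) exceeds n_features (%d)", n_informative, n_features)
  if (zero_inflation < 0 || zero_inflation >= 1)
    stopf("zero_inflation must lie in [0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (is.null(effect_weights)) {
    mag <- seq(2, 1, length.out = n_informative)
    sgn <- rep(1, n_informative)
    sgn[seq_len(n_informative) %% 3 == 0] <- -1
    effect_weights <- mag * sgn
  }
  if (length(effect_weights) != n_informative)
    stopf("effect_weights must have length n_informative (%d)", n_informative)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 zero_inflation = zero_inflation, dispersion = dispersion,
                 effect_weights = effect_weights, noise_sd = noise_sd,
                 link = link, zero_feature_frac = zero_feature_frac,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# The scale the planted response acts on: standardised log expression.
# Regulatory effects in expression data act multiplicatively (fold changes),
# so the dose a planted feature delivers is its z-scored log1p value; raw
# magnitudes would concentrate against the minimum under their heavy tail
# and leave almost no planted signal.
#' @noRd
scale_dose <- function(x) {
  lx <- log1p(x)
  s <- stats::sd(lx)
  if (s == 0) return(rep(0, length(x)))
  (lx - mean(lx)) / s
}

#' Generate a synthetic expression dataset
#'
#' Draws expression magnitudes log-normal(`0`, `dispersion`) and multiplies
#' by a Bernoulli(`1 - zero_inflation`) mask; a `zero_feature_frac` fraction
#' of non-informative features is set identically to zero. The target is
#' `link(sum_i w_i * s(x_i)) + N(0, noise_sd)` where `s()` is the
#' standardised log expression (`log1p`, then z-scored per feature):
#' regulatory doses act on the fold-change scale, as they do in real
#' expression data.
#'
#' @param spec a [synth_spec()].
#' @return An [expression_dataset()] (stage `"raw"`) with an attribute
#'   `"truth"` recording the informative feature ids and indices, the effect
#'   weights, the link, and the seed.
#' @examples
#' ds <- synth_expression(synth_spec(n_samples = 50, n_features = 10,
#'                                   n_informative = 2, seed = 7))
#' attr(ds, "truth")$informative_ids
#' @export
synth_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; p <- spec$n_features
    ids <- sprintf("mir%03d", seq_len(p))
    x <- matrix(stats::rlnorm(n * p, meanlog = 0, sdlog = spec$dispersion), n, p)
    mask <- matrix(stats::runif(n * p) >= spec$zero_inflation, n, p)
    x <- x * mask
    n_zero <- min(round(spec$zero_feature_frac * p), p - spec$n_informative)
    informative <- sort(sample.int(p, spec$n_informative))
    zero_pool <- setdiff(seq_len(p), informative)
    zero_feats <- if (n_zero > 0) sort(sample(zero_pool, n_zero)) else integer(0)
    x[, zero_feats] <- 0
    # guard against an informative feature drawn constant (degenerate scale)
    for (j in informative) if (length(unique(x[, j])) < 2L)
      x[1L, j] <- x[1L, j] + 1
    s <- vapply(informative, function(j) scale_dose(x[, j]), numeric(n))
    eta <- drop(s %*% spec$effect_weights)
    y <- switch(spec$link, sigmoid = 1 / (1 + exp(-eta)), linear = eta)
    y <- y + stats::rnorm(n, sd = spec$noise_sd)
    ds <- expression_dataset(x, ids, y, target_id = "target", stage = "raw")
    attr(ds, "truth") <- list(informative_ids = ids[informative],
                              informative_idx = informative,
                              effect_weights = spec$effect_weights,
                              zero_feature_ids = ids[zero_feats],
                              link = spec$link, seed = spec$seed)
    ds
  })
}
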