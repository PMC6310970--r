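#' Expression dataset container
#'
#' A light container for a samples-by-features expression matrix together
#' with the regression target (e.g. the mRNA-Smad7 expression vector), the
#' feature identifiers and a provenance stage. The stage only moves forward
#' through `raw -> filtered -> denoised -> scaled`, mirroring the
#' preprocessing pipeline.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param feature_ids character vector of unique feature names; defaults to
#'   the column names of `values`.
#' @param target numeric vector of length `nrow(values)`.
#' @param target_id name of the target variable.
#' @param stage provenance stage, one of `"raw"`, `"filtered"`,
#'   `"denoised"`, `"scaled"`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `feature_ids`, `target`, `target_id`, `stage`.
#' @examples
#' m <- matrix(rexp(20), 5, 4, dimnames = list(NULL, paste0("mir", 1:4)))
#' ds <- expression_dataset(m, target = rnorm(5))
#' ds
#' @export
expression_dataset <- function(values, feature_ids = colnames(values),
                               target, target_id = "target",
                               stage = c("raw", "filtered", "denoised", "scaled")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) == 0L || ncol(values) == 0L)
    stopf("`values` must be a non-empty numeric matrix")
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(values))
    stopf("%d feature ids for %d columns", length(feature_ids), ncol(values))
  if (anyDuplicated(feature_ids))
    stopf("duplicate feature ids: %s",
          paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (length(target) != nrow(values))
    stopf("target length %d != %d samples", length(target), nrow(values))
  if (anyNA(values) || anyNA(target))
    stopf("missing values are not supported; impute or drop before building the dataset")
  colnames(values) <- feature_ids
  structure(list(values = values, feature_ids = feature_ids,
                 target = as.numeric(target), target_id = target_id,
                 stage = stage),
            class = "expression_dataset")
}

.stage_order <- c(raw = 1L, filtered = 2L, denoised = 3L, scaled = 4L)

# Move the provenance stage forward; backwards transitions are a usage error.
#' @noRd
advance_stage <- function(ds, to) {
  if (.stage_order[[to]] < .stage_order[[ds$stage]])
    stopf("cannot move stage backwards (%s -> %s)", ds$stage, to)
  ds$stage <- to
  ds
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d samples x %d features (stage: %s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  target: %s  [%.4g, %.4g]\n", x$target_id,
              min(x$target), max(x$target)))
  show <- utils::head(x$feature_ids, 6L)
  cat("  features: ", paste(show, collapse = ", "),
      if (length(x$feature_ids) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' @export
as.data.frame.expression_dataset <- function(x, ...) {
  df <- as.data.frame(x$values)
  df[[x$target_id]] <- x$target
  df
}

#' Read / write expression tables
#'
#' Tables are plain TSV or CSV with a header row of feature identifiers and
#' one row per sample; the target variable is one named column (by default
#' the last). The delimiter is auto-detected between tab and comma.
#'
#' @param path file path.
#' @param target_id name of the target column; `NULL` takes the last column.
#' @param stage provenance stage to record on the dataset that is read.
#' @return `read_expression()` returns an [expression_dataset()];
#'   `write_expression()` invisibly returns `path`.
#' @export
read_expression <- function(path, target_id = NULL,
                            stage = c("raw", "filtered", "denoised", "scaled")) {
  stage <- match.arg(stage)
  if (!file.exists(path)) stopf("no such file: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(gregexpr("\t", header)) >= lengths(gregexpr(",", header)))
    "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(target_id)) target_id <- names(df)[ncol(df)]
  if (!target_id %in% names(df)) stopf("no column named '%s' in %s", target_id, path)
  target <- df[[target_id]]
  df[[target_id]] <- NULL
  expression_dataset(as.matrix(df), names(df), target, target_id, stage)
}

#' @param ds an [expression_dataset()].
#' @param sidecar optional path for a JSON sidecar holding dataset metadata
#'   (used by the synthetic generator to record the planted truth).
#' @rdname read_expression
#' @export
write_expression <- function(ds, path, sidecar = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- as.data.frame(ds)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar)) {
    meta <- attr(ds, "truth") %||% list()
    meta$target_id <- ds$target_id
    meta$stage <- ds$stage
    meta$n_samples <- nrow(ds$values)
    meta$n_features <- ncol(ds$values)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
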