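#' Save / load an MLP checkpoint as JSON
#'
#' Checkpoints store the layer sizes, the flattened weights and biases, and
#' optional metadata (feature ids, phenotype), in plain JSON so they can be
#' reloaded by the importance tooling or inspected by hand.
#'
#' @param m an `mlp`.
#' @param path file path for the JSON checkpoint.
#' @param meta optional named list of metadata stored verbatim.
#' @return `write_mlp()` invisibly returns `path`; `read_mlp()` returns a
#'   list with `model` (`mlp`) and `meta`.
#' @export
write_mlp <- function(m, path, meta = NULL) {
  stopifnot(inherits(m, "mlp"))
  obj <- list(sizes = m$sizes,
              weights = lapply(m$W, function(w) as.numeric(w)),
              biases = lapply(m$b, as.numeric),
              meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  nl <- length(sizes) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(as.numeric(obj$weights[[l]]), sizes[l], sizes[l + 1L])
    b[[l]] <- as.numeric(obj$biases[[l]])
  }
  list(model = structure(list(sizes = sizes, W = W, b = b), class = "mlp"),
       meta = obj$meta)
}
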