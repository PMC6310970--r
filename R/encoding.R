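#' Genome encoding for the evolutionary search
#'
#' Each individual is a fixed-length binary string laid out as:
#' `n_feature_bits` feature-mask bits, 1 validation bit (0 = hold-out,
#' 1 = k-fold), `layer_field_bits` bits giving the number of hidden layers
#' (binary value + 1, so zero layers cannot occur), then one
#' `node_field_bits` field per possible hidden layer giving its node count
#' (binary value + 1). Only the first `L` node fields are decoded — the
#' remainder is carried as neutral genetic material, so variation operators
#' stay closed over fixed-length strings while the decoded individual is
#' effectively variable-length. Numeric fields are most-significant-bit
#' first.
#'
#' The defaults (99 feature bits, 6 layer bits, 10 node bits) give a maximum
#' genome of `99 + 1 + 6 + 64 * 10 = 746` bits: up to 64 hidden layers of up
#' to 1024 nodes.
#'
#' @param n_feature_bits number of candidate input features.
#' @param layer_field_bits bits encoding the hidden-layer count.
#' @param node_field_bits bits encoding each layer's node count.
#' @return `encoding_spec()`: an object of class `encoding_spec` with
#'   derived fields `max_layers`, `max_nodes` and `genome_length`.
#' @name encoding
#' @examples
#' spec <- encoding_spec()
#' spec$genome_length   # 746
#' g <- random_genome(spec)
#' decode_genome(g, spec)
NULL

#' @rdname encoding
#' @export
encoding_spec <- function(n_feature_bits = 99, layer_field_bits = 6,
                          node_field_bits = 10) {
  for (nm in c("n_feature_bits", "layer_field_bits", "node_field_bits"))
    if (!is_count(get(nm))) stopf("`%s` must be a positive integer", nm)
  max_layers <- 2L^layer_field_bits
  structure(list(n_feature_bits = as.integer(n_feature_bits),
                 layer_field_bits = as.integer(layer_field_bits),
                 node_field_bits = as.integer(node_field_bits),
                 max_layers = max_layers,
                 max_nodes = 2L^node_field_bits,
                 genome_length = as.integer(n_feature_bits + 1L +
                   layer_field_bits + max_layers * node_field_bits)),
            class = "encoding_spec")
}

# MSB-first binary-to-decimal
#' @noRd
bin2dec <- function(bits) sum(bits * 2^((length(bits) - 1L):0))

#' @noRd
dec2bin <- function(x, width) {
  bits <- integer(width)
  for (i in width:1) { bits[i] <- x %% 2L; x <- x %/% 2L }
  bits
}

#' Decode a genome into its phenotype
#'
#' @param bits integer 0/1 vector of length `spec$genome_length`.
#' @param spec an [encoding_spec()].
#' @return An object of class `phenotype`: list with `feature_mask`
#'   (logical), `validation` (`"holdout"` or `"kfold"`), `hidden_layers`
#'   (integer vector of node counts), and `feasible` (`FALSE` when the
#'   feature mask is empty).
#' @rdname encoding
#' @export
decode_genome <- function(bits, spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (length(bits) != spec$genome_length)
    stopf("genome has %d bits; spec requires %d", length(bits), spec$genome_length)
  nf <- spec$n_feature_bits
  mask <- bits[seq_len(nf)] == 1L
  validation <- if (bits[nf + 1L] == 0L) "holdout" else "kfold"
  lb <- spec$layer_field_bits
  L <- bin2dec(bits[(nf + 2L):(nf + 1L + lb)]) + 1L
  base <- nf + 1L + lb
  nb <- spec$node_field_bits
  hidden <- vapply(seq_len(L), function(i) {
    field <- bits[(base + (i - 1L) * nb + 1L):(base + i * nb)]
    as.integer(bin2dec(field) + 1L)
  }, integer(1))
  structure(list(feature_mask = mask, validation = validation,
                 hidden_layers = hidden, feasible = any(mask)),
            class = "phenotype")
}

#' Write a phenotype back into genome bits
#'
#' The inverse of [decode_genome()]: writes the active region (feature mask,
#' validation bit, layer count, and the first `L` node fields); the inactive
#' tail is zero-filled.
#'
#' @param p a `phenotype`.
#' @rdname encoding
#' @export
encode_phenotype <- function(p, spec) {
  stopifnot(inherits(p, "phenotype"), inherits(spec, "encoding_spec"))
  L <- length(p$hidden_layers)
  if (L < 1L || L > spec$max_layers)
    stopf("hidden layer count %d outside [1, %d]", L, spec$max_layers)
  if (any(p$hidden_layers < 1L | p$hidden_layers > spec$max_nodes))
    stopf("node counts must lie in [1, %d]", spec$max_nodes)
  if (length(p$feature_mask) != spec$n_feature_bits)
    stopf("feature mask length %d != %d", length(p$feature_mask),
          spec$n_feature_bits)
  bits <- integer(spec$genome_length)
  bits[seq_len(spec$n_feature_bits)] <- as.integer(p$feature_mask)
  bits[spec$n_feature_bits + 1L] <- if (p$validation == "kfold") 1L else 0L
  lb <- spec$layer_field_bits
  bits[(spec$n_feature_bits + 2L):(spec$n_feature_bits + 1L + lb)] <-
    dec2bin(L - 1L, lb)
  base <- spec$n_feature_bits + 1L + lb
  nb <- spec$node_field_bits
  for (i in seq_len(L))
    bits[(base + (i - 1L) * nb + 1L):(base + i * nb)] <-
      dec2bin(p$hidden_layers[i] - 1L, nb)
  bits
}

#' Active length of a phenotype's encoding
#'
#' Number of genome bits actually decoded for a phenotype with `L` hidden
#' layers: `n_feature_bits + 1 + layer_field_bits + L * node_field_bits`.
#'
#' @rdname encoding
#' @export
active_length <- function(p, spec) {
  stopifnot(inherits(p, "phenotype"), inherits(spec, "encoding_spec"))
  spec$n_feature_bits + 1L + spec$layer_field_bits +
    length(p$hidden_layers) * spec$node_field_bits
}

#' Draw a uniform random genome
#'
#' Bits are i.i.d. fair coin flips; a genome whose feature mask decodes to
#' the empty set is repaired at creation by setting one random feature bit,
#' so initial populations never contain structurally infeasible
#' individuals.
#'
#' @rdname encoding
#' @export
random_genome <- function(spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  bits <- as.integer(stats::runif(spec$genome_length) < 0.5)
  if (!any(bits[seq_len(spec$n_feature_bits)] == 1L))
    bits[sample.int(spec$n_feature_bits, 1L)] <- 1L
  bits
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("Phenotype: %d features | %s validation | hidden layers %s%s\n",
              sum(x$feature_mask), x$validation,
              paste(x$hidden_layers, collapse = ":"),
              if (x$feasible) "" else " [INFEASIBLE: empty feature mask]"))
  invisible(x)
}
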