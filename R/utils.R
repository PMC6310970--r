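# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw a fresh 31-bit child seed from the current RNG stream.  Used to give
# nested stochastic steps (splits, weight inits, repetitions) their own
# reproducible seeds while keeping the parent stream intact.
#' @noRd
child_seed <- function() sample.int(.Machine$integer.max, 1L)

# Run `expr` under a local RNG state: seeds with `seed` when non-NULL and
# restores the caller's .Random.seed afterwards, so seeded calls do not
# perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

#' @noRd
bits_to_string <- function(bits) paste(bits, collapse = "")

#' @noRd
string_to_bits <- function(s) as.integer(strsplit(s, "")[[1]])
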