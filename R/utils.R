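#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All seeded operations in the package go through
# this so that library calls never perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive `n` independent substream seeds from a master seed. Kept below 2^31.
derive_seeds <- function(master_seed, n, labels = NULL) {
  seeds <- with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(labels)) names(seeds) <- labels
  seeds
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_jita <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "jitaema_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
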