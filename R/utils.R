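# Internal helpers shared across modules.

# Population standard deviation (divisor I, French PCA convention).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Deterministic derivation of sub-seeds from one master seed; values stay
# below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647)
  as.integer((s * 48271 + as.double(k) * 8191 + 1) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Completions duplicate donor rows, so full-rank MFA configurations routinely
# carry zero-eigenvalue padding; that is expected inside the pipeline and the
# rank warning is muffled there (zero columns do not change cross-products).
muffle_rank_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("exceeds (numerical|compromise) rank", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
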