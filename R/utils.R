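# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
# NULL the expression uses (and advances) the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation. All pipeline randomness flows from
# one master seed; each (stage, index) pair gets its own stream so that adding
# a method or a noise level never perturbs the draws of another stage.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage)) %% 997L
  ((as.integer(seed) %% 100000L) * 10007L + stage_code * 131L + as.integer(index)) %%
    2147483647L
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

default_gene_ids <- function(n) paste0("G", seq_len(n))
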