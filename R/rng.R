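# Seeded sub-streams: every stochastic operation draws from a seed derived
# from (config seed, operation name), so rerunning one stage never perturbs
# another. The derived seed stays below 2^31 - 1.

op_seed <- function(seed, op) {
  codes <- utf8ToInt(op)
  h <- sum(codes * seq_along(codes)) %% 99991L
  (as.integer(seed) %% 20000L) * 100003L + h
}

# Evaluate `expr` under a derived seed, restoring the caller's RNG state.
with_op_seed <- function(seed, op, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(op_seed(seed, op))
  expr
}
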