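# Internal helpers shared across modules.

# Per-operation RNG streams: every stochastic operation draws from its own
# stream derived from a user seed plus a fixed operation offset, so adding a
# step to a pipeline never perturbs the draws of the steps after it.
.op_offsets <- c(
  reference  = 101L,
  strain     = 211L,
  plant      = 307L,
  reads      = 401L,
  family_db  = 503L,
  cog_db     = 601L,
  counts     = 701L
)

with_op_seed <- function(seed, op, code) {
  stopifnot(op %in% names(.op_offsets))
  seed <- (as.integer(seed) + .op_offsets[[op]]) %% .Machine$integer.max
  withr::with_seed(seed, code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# paste a vector for error messages
.oxford <- function(x, max = 5L) {
  x <- as.character(x)
  if (length(x) > max) x <- c(x[seq_len(max)], "...")
  paste(x, collapse = ", ")
}
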