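# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so package functions never leak global
# RNG state. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stage label, so a
# single pipeline seed fans out deterministically (kept below 2^31).
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.integer(seed) * 1009L + as.integer(h %% 104729)) %% 2147483587L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# One-sided exact binomial p-values, vectorised (equivalent to
# binom.test(x, n, p, alternative)$p.value but usable on long vectors).
pbinom_less <- function(x, n, p) pbinom(x, n, p)
pbinom_greater <- function(x, n, p) pbinom(x - 1, n, p, lower.tail = FALSE)

# Clopper-Pearson interval for an aggregate count.
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}
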