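# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a master seed
#'
#' Every randomized stage draws its own seed deterministically from the run's
#' master seed and a short stage key, so a single `--seed` reproduces the whole
#' pipeline while stages stay statistically decoupled.
#'
#' @param seed Master integer seed.
#' @param key Character stage key (e.g. `"iforest"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer((abs(seed) %% m * 7919 + h) %% m)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Statistical mode of a vector, ignoring NA; ties broken by sorted order.
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tab <- sort(table(x), decreasing = TRUE)
  nm <- names(tab)[tab == tab[1]]
  out <- sort(nm)[1]
  if (is.numeric(x)) as.numeric(out) else out
}

fmt_num <- function(x, digits = 1) formatC(x, format = "f", digits = digits)
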