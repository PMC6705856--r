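# internal helpers

#' @keywords internal
"_PACKAGE"

# round half away from zero, as tables in the clinical literature are printed
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
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
  force(code)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# split n into integer counts proportional to probs (largest remainder)
quota_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}
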