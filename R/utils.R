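# Internal helpers shared across modules.

# Largest-remainder rounding of positive reals to integers with a fixed sum.
# Every result is >= `floor_min` (values are bumped up and the excess taken
# from the largest entries). Errors if the constraint is infeasible.
largest_remainder <- function(values, total, floor_min = 1L) {
  stopifnot(length(values) >= 1L, all(values > 0), total >= floor_min * length(values))
  scaled <- values * (total / sum(values))
  base <- floor(scaled)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(scaled - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  # enforce the floor by taking bases from the largest pieces
  while (any(base < floor_min)) {
    i <- which(base < floor_min)[1L]
    need <- floor_min - base[i]
    donors <- order(base, decreasing = TRUE)
    for (j in donors) {
      if (need == 0) break
      give <- min(need, base[j] - floor_min)
      if (give > 0) {
        base[j] <- base[j] - give
        base[i] <- base[i] + give
        need <- need - give
      }
    }
    if (need > 0) stop("cannot satisfy minimum piece size ", floor_min)
  }
  as.integer(base)
}

# Reverse complement of a plain character string.
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Sample `n` bases at a given GC fraction.
random_bases <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# 1-based inclusive interval overlap length.
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# run an expression under a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_log <- function() list()

log_count <- function(prefix, what, n) {
  if (n > 0) message(sprintf("[%s] %s: %d", prefix, what, n))
  invisible(n)
}
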