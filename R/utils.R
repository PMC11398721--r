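# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Wrap angles into [0, 2*pi).
wrap_phase <- function(x) {
  y <- x %% (2 * pi)
  y[y < 0] <- y[y < 0] + 2 * pi
  y
}

# Adjusted Rand index between two labelings (used to score recovery of
# planted modules by community detection).
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Spearman rank correlation without the exact-test machinery.
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  stats::cor(rank(x[ok]), rank(y[ok]))
}

# Most frequent value; ties resolved by the median of the tied values.
consensus_value <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  stats::median(modes)
}
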