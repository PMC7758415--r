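# Independent oracles and small builders shared across the suite.

# Brute-force evaluation of the TOPSIS closed form with explicit loops,
# kept independent of the package implementation.
topsis_oracle <- function(R, directions, weights = rep(1, ncol(R))) {
  w <- weights / sum(weights)
  k <- ncol(R)
  ideal <- anti <- numeric(k)
  for (j in seq_len(k)) {
    col <- R[, j]
    if (directions[j] == "benefit") {
      ideal[j] <- max(col); anti[j] <- min(col)
    } else {
      ideal[j] <- min(col); anti[j] <- max(col)
    }
  }
  C <- numeric(nrow(R))
  for (i in seq_len(nrow(R))) {
    sp <- sm <- 0
    for (j in seq_len(k)) {
      sp <- sp + (w[j] * (R[i, j] - ideal[j]))^2
      sm <- sm + (w[j] * (R[i, j] - anti[j]))^2
    }
    C[i] <- sqrt(sm) / (sqrt(sp) + sqrt(sm))
  }
  C
}

# Textbook sum-formula Pearson correlation.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

two_rung_ladder <- function() tibble::tibble(carbon = 10:11, rt = c(10, 12))

quiet_panel <- function(...) suppressWarnings(suppressMessages(generate_panel(...)))

small_config <- function(...) {
  sim_config(n_accessions = 12, n_volatiles = 10, ...)
}
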