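# Independent oracles and fixture builders shared across tests.

# Brute-force distance correlation straight from the definition, written with
# explicit loops so it shares no code path with the package implementation.
dcor_brute <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n)
  b <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      a[i, j] <- abs(x[i] - x[j])
      b[i, j] <- abs(y[i] - y[j])
    }
  }
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
      B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
    }
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# Textbook one-way ANOVA by hand from sums of squares.
anova_by_hand <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# Minimal complete cohort data.frame with all canonical columns; recall
# components consistent with the wave totals.
make_toy_cohort <- function(n, seed = 1) {
  cat33 <- activity_catalog()
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    w1 <- sample(2:18, n, replace = TRUE)
    w2 <- pmax(0L, pmin(20L, w1 + sample(-3:2, n, replace = TRUE)))
    imm1 <- pmin(10L, pmax(0L, w1 - 10L + sample(0:5, n, replace = TRUE)))
    imm1 <- pmin(imm1, w1)
    imm2 <- pmin(10L, pmax(0L, w2 - 10L + sample(0:5, n, replace = TRUE)))
    imm2 <- pmin(imm2, w2)
    df <- data.frame(
      id = sprintf("T%03d", seq_len(n)),
      age_years = sample(65:89, n, replace = TRUE),
      education_years = sample(8:20, n, replace = TRUE),
      recall_immediate_w1 = imm1, recall_delayed_w1 = w1 - imm1,
      recall_immediate_w2 = imm2, recall_delayed_w2 = w2 - imm2,
      memory_w1 = w1, memory_w2 = w2,
      stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(cat33))) {
      df[[cat33$key[i]]] <- sample(0:(cat33$n_levels[i] - 1L), n,
                                   replace = TRUE)
    }
    class(df) <- c("memtrend_cohort", "data.frame")
    df
  })
}

# A cohort guaranteed to populate all five age groups.
make_grouped_cohort <- function(n_per_group = 12, seed = 1) {
  df <- make_toy_cohort(5 * n_per_group, seed = seed)
  df$age_years <- rep(c(66L, 72L, 77L, 82L, 87L), each = n_per_group)
  df
}
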