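# Independent oracles: deliberately written as textbook matrix algebra /
# direct recursion, not sharing code with the implementation they check.

# Weighted least squares through the origin via normal equations.
wls_origin_oracle <- function(g, G, sy) {
  X <- matrix(g, ncol = 1)
  W <- diag(1 / sy^2, nrow = length(sy))
  xtwx <- t(X) %*% W %*% X
  beta <- drop(solve(xtwx, t(X) %*% W %*% G))
  se_fixed <- sqrt(drop(solve(xtwx)))
  r <- G - drop(X %*% beta)
  q <- drop(t(r) %*% W %*% r)
  J <- length(g)
  list(beta = beta, se_fixed = se_fixed,
       se_random = se_fixed * max(1, sqrt(q / (J - 1))), q = q)
}

# Weighted least squares with intercept via normal equations, on the
# positive-exposure orientation, with the multiplicative overdispersion floor.
wls_egger_oracle <- function(g, G, sy) {
  flip <- ifelse(g < 0, -1, 1)
  X <- cbind(1, g * flip)
  y <- G * flip
  W <- diag(1 / sy^2, nrow = length(sy))
  xtwx <- t(X) %*% W %*% X
  coefs <- drop(solve(xtwx, t(X) %*% W %*% y))
  covm <- solve(xtwx)
  r <- y - drop(X %*% coefs)
  J <- length(g)
  phi <- max(1, sqrt(drop(t(r) %*% W %*% r) / (J - 2)))
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = sqrt(covm[1, 1]) * phi,
       se_slope = sqrt(covm[2, 2]) * phi)
}

# "Repeatedly take the best remaining p and delete its r2-neighbours",
# written as direct recursion.
clump_oracle <- function(data, ld, r2_max) {
  if (nrow(data) == 0L) return(data)
  ord <- order(data$pval, -abs(data$beta), data$variant_id)
  best <- data[ord[1], , drop = FALSE]
  rest <- data[ord[-1], , drop = FALSE]
  if (nrow(rest) > 0L) {
    r2 <- ld[best$variant_id, rest$variant_id]
    rest <- rest[r2 <= r2_max, , drop = FALSE]
  }
  dplyr::bind_rows(best, clump_oracle(rest, ld, r2_max))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), 1e-300)

# Random instrument set for oracle-equivalence checks.
random_instruments <- function(J, seed) {
  withr::with_seed(seed, {
    g <- rnorm(J, 0, 0.1)
    g[g == 0] <- 0.05
    tibble::tibble(
      variant_id = sprintf("v%02d", seq_len(J)),
      beta_exposure = g,
      se_exposure = runif(J, 0.005, 0.05),
      beta_outcome = 0.4 * g + rnorm(J, 0, 0.05),
      se_outcome = runif(J, 0.02, 0.1),
      eaf_exposure = runif(J, 0.05, 0.95))
  })
}

# Random symmetric r-squared matrix with unit diagonal.
random_ld <- function(ids, seed) {
  withr::with_seed(seed, {
    n <- length(ids)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    m
  })
}
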