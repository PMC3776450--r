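## Independent oracles used across the suite. These deliberately avoid the
## package's decoding/estimation code paths.

## log density of a multivariate normal, written from the definition
mvn_logpdf <- function(y, mu, cov) {
  k <- length(y)
  -0.5 * (k * log(2 * pi) + log(det(cov)) +
            t(y - mu) %*% solve(cov) %*% (y - mu))[1, 1]
}

## Brute-force trellis oracle: enumerate all 4^P sequences of P = M + 1
## template positions, score each by per-position priors plus per-stage
## state emissions, and marginalize.
brute_force_trellis <- function(emissions, base_priors = NULL) {
  M <- nrow(emissions)
  P <- M + 1L
  if (is.null(base_priors)) base_priors <- matrix(0.25, P, 4)
  lp <- log(base_priors)
  seqs <- as.matrix(expand.grid(rep(list(1:4), P)))
  n <- nrow(seqs)
  lj <- numeric(n)
  for (p in seq_len(P)) lj <- lj + lp[p, ][seqs[, p]]
  for (i in seq_len(M)) {
    st <- 4L * (seqs[, i] - 1L) + seqs[, i + 1L]
    lj <- lj + emissions[i, ][st]
  }
  tot <- max(lj) + log(sum(exp(lj - max(lj))))
  post <- matrix(0, P, 4)
  for (p in seq_len(P)) for (b in 1:4) {
    sel <- seqs[, p] == b
    post[p, b] <- exp(max(lj[sel]) + log(sum(exp(lj[sel] - max(lj[sel])))) - tot)
  }
  list(post = post, argmax = unname(seqs[which.max(lj), ]), loglik = tot)
}

## random model-derived emission matrix for a short read, plus the template
random_trellis_instance <- function(L, noise_sd = 0.15) {
  tpl <- sample.int(4L, L + 1L, replace = TRUE)
  beta <- runif(1, 0, 0.2)
  K <- default_crosstalk() + matrix(runif(16, -0.02, 0.02), 4, 4)
  Sigma <- diag(4) * noise_sd^2
  alpha <- runif(1, 0, 0.1)
  dbar <- c(0, runif(L - 1, 0, 0.05))
  dprod <- cumprod(1 - dbar)
  lam <- runif(1, 0.7, 1.3)
  X16 <- softcall:::effective_signal_matrix(beta)
  Y <- matrix(0, L, 4)
  for (i in seq_len(L)) {
    st <- state_index(tpl[i], tpl[i + 1L])
    mu <- lam * dprod[i] * as.numeric(K %*% X16[st, ])
    if (i > 1) mu <- mu + alpha * Y[i - 1, ]
    Y[i, ] <- mu + lam * dprod[i] * sqrt(sum(X16[st, ]^2)) * rnorm(4, sd = noise_sd)
  }
  em <- softcall:::emission_matrix(Y, seq_len(L), lam, K, Sigma, alpha, beta, dprod)
  list(emissions = em, template = tpl)
}

## small standard tiles used by several files
clean_config <- function(reads = 40, cycles = 16, seed = 1, d = 0,
                         K = diag(4)) {
  sim_config(reads = reads, cycles = cycles, p = phasing_params(0, 0),
             K = K, Sigma = matrix(0, 4, 4), alpha = 0, d = d,
             sigma_lambda = 0, lambda_cv = 0, seed = seed)
}

read_ids_for <- function(tile) softcall:::read_ids(tile$meta)
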