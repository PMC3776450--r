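test_that("crosstalk initialization recovers identity and dominant mixing", {
  tile_id <- simulate_tile(clean_config(reads = 60, cycles = 6, seed = 21))
  K_id <- init_crosstalk(tile_id$intensities)
  expect_equal(unname(normalize_crosstalk(K_id)), diag(4), tolerance = 1e-8)

  tile_k <- simulate_tile(clean_config(reads = 120, cycles = 6, seed = 22,
                                       K = default_crosstalk()))
  Kn <- normalize_crosstalk(init_crosstalk(tile_k$intensities))
  Kn_true <- normalize_crosstalk(default_crosstalk())
  expect_lt(norm(Kn - Kn_true, "F") / norm(Kn_true, "F"), 0.02)

  ## stability across seeds under mild noise
  est <- lapply(c(31, 32), function(s) {
    cfg <- sim_config(reads = 150, cycles = 6, Sigma = diag(4) * 0.01,
                      p = phasing_params(0, 0), alpha = 0, d = 0,
                      sigma_lambda = 0, lambda_cv = 0, seed = s)
    normalize_crosstalk(init_crosstalk(simulate_tile(cfg)$intensities))
  })
  expect_lt(norm(est[[1]] - est[[2]], "F") / norm(est[[1]], "F"), 0.05)
  expect_error(init_crosstalk(tile_id$intensities[1:5]), "at least 10")
})

test_that("initialization recovers droop and covariance scale", {
  ## no droop, noise-free: retention ratio 1 maps to droop 0
  tile0 <- simulate_tile(clean_config(reads = 40, cycles = 10, seed = 23))
  init0 <- init_sigma_droop(tile0$intensities, init_crosstalk(tile0$intensities))
  expect_equal(init0$dbar, rep(0, 10), tolerance = 1e-9)

  ## known droop, noise-free
  tiled <- simulate_tile(clean_config(reads = 40, cycles = 12, seed = 24, d = 0.05))
  initd <- init_sigma_droop(tiled$intensities, init_crosstalk(tiled$intensities))
  expect_equal(initd$dbar[-1], rep(0.05, 11), tolerance = 0.005)

  ## covariance scale within 30% at a realistic training size
  cfg <- sim_config(reads = 250, cycles = 8, Sigma = diag(4) * 0.02,
                    p = phasing_params(0, 0), K = diag(4), alpha = 0, d = 0,
                    sigma_lambda = 0, lambda_cv = 0, seed = 25)
  tile <- simulate_tile(cfg)
  init <- init_sigma_droop(tile$intensities, init_crosstalk(tile$intensities))
  expect_true(all(abs(diag(init$Sigma) - 0.02) / 0.02 < 0.3))
  expect_error(init_sigma_droop(tile$intensities, matrix(0, 4, 4)), "singular")
})

test_that("the scale quadratic matches truth, scales linearly, and solves the 1-D MLE", {
  ## noise-free read generated at a known scale, tiny covariance
  cfg <- sim_config(reads = 1, cycles = 10, p = phasing_params(0, 0),
                    K = default_crosstalk(), Sigma = matrix(0, 4, 4),
                    alpha = 0, d = 0, sigma_lambda = 0, lambda_cv = 0,
                    lambda_mean = 2, seed = 26)
  tile <- simulate_tile(cfg)
  tpl <- softcall:::dna_to_idx(tile$truth$template[1])
  th <- list(alpha = 0, beta = 0, K = default_crosstalk(), Sigma = diag(4) * 1e-12)
  lam <- estimate_lambda(tile$intensities[[1]], tpl, th, 1:6, rep(1, 6))
  expect_equal(lam, 2, tolerance = 1e-8)

  set.seed(27)
  neg_ll <- function(lam, Y, calls, th, cycles, dprod) {
    tot <- 0
    X16 <- softcall:::effective_signal_matrix(th$beta)
    for (m in seq_along(cycles)) {
      i <- cycles[m]
      nxt <- if (i + 1 <= length(calls)) calls[i + 1] else calls[i]
      x <- X16[state_index(calls[i], nxt), ]
      Yb <- Y[i, ]; if (i > 1) Yb <- Yb - th$alpha * Y[i - 1, ]
      mu <- lam * dprod[m] * as.numeric(th$K %*% x)
      cov <- (lam * dprod[m])^2 * sum(x^2) * th$Sigma
      tot <- tot + log(det(cov)) + mahalanobis(Yb, mu, cov)
    }
    tot
  }
  for (t in 1:10) {
    Y <- matrix(abs(rnorm(40, 1, 0.5)), 10, 4)
    calls <- sample(1:4, 11, replace = TRUE)
    th <- list(alpha = runif(1, 0, 0.1), beta = runif(1, 0, 0.2),
               K = default_crosstalk(), Sigma = diag(4) * runif(1, 0.01, 0.05))
    dprod <- cumprod(1 - c(0, runif(9, 0, 0.05)))
    cyc <- 3:8
    lam <- estimate_lambda(Y, calls, th, cyc, dprod[cyc])
    ## linear homogeneity in the observations
    expect_equal(estimate_lambda(3 * Y, calls, th, cyc, dprod[cyc]), 3 * lam,
                 tolerance = 1e-10)
    opt <- optimize(neg_ll, c(1e-3, 30), Y = Y, calls = calls, th = th,
                    cycles = cyc, dprod = dprod[cyc], tol = 1e-10)
    expect_equal(lam, opt$minimum, tolerance = 1e-6)
  }
})

test_that("importance-sampling scale moments converge to quadrature", {
  cfg <- sim_config(reads = 5, cycles = 12, seed = 28)
  tile <- simulate_tile(cfg)
  reads <- tile$intensities
  boot <- lapply(reads, function(Y) max.col(Y %*% t(solve(default_crosstalk()))))
  th <- list(alpha = cfg$alpha, beta = 0.02, K = default_crosstalk(),
             Sigma = cfg$Sigma)
  span <- 1:12
  dbar_span <- rep(0.03, 12); dbar_span[1] <- 0
  lam0 <- vapply(seq_along(reads), function(k)
    estimate_lambda(reads[[k]], boot[[k]], th, 1:6, cumprod(1 - dbar_span)[1:6]),
    numeric(1))
  set.seed(29)
  terms <- softcall:::e_step_first(reads, boot, th, span, dbar_span, 1,
                                   lam0, n_is = 5000, proposal_var = 0.1)
  ## quadrature oracle over the per-read scale posterior
  Dvec <- cumprod(1 - dbar_span)
  X16 <- softcall:::effective_signal_matrix(th$beta)
  Sinv <- solve(th$Sigma)
  for (k in 1:5) {
    Y <- reads[[k]]
    calls <- boot[[k]]
    nxt <- c(calls[2:12], calls[12])
    xk <- state_index(calls[span], nxt)
    A <- B <- C <- 0
    for (m in seq_along(span)) {
      x <- X16[xk[m], ]; s <- sum(x^2)
      Yb <- Y[m, ]; if (m > 1) Yb <- Yb - th$alpha * Y[m - 1, ]
      A <- A + (t(Yb) %*% Sinv %*% Yb)[1] / (Dvec[m]^2 * s)
      B <- B + (t(th$K %*% x) %*% Sinv %*% Yb)[1] / (Dvec[m] * s)
      C <- C + (t(th$K %*% x) %*% Sinv %*% (th$K %*% x))[1] / s
    }
    grid <- seq(max(lam0[k] - 1.5, 1e-3), lam0[k] + 1.5, length.out = 8000)
    lt <- -0.5 * (8 * 12 * log(grid) + A / grid^2 - 2 * B / grid + C)
    w <- exp(lt - max(lt)); w <- w / sum(w)
    idx <- which(terms$read == k)[1]
    expect_equal(terms$m1[idx], sum(w / grid), tolerance = 0.01)
    expect_equal(terms$m2[idx], sum(w / grid^2), tolerance = 0.02)
    ## weights are normalized per read (moments of 1/lambda^0 sum to 1)
    expect_equal(sum(terms$w[terms$read == k]) / 12, 1)
  }
})

test_that("posterior-weighted E-step weights are normalized and exact for point masses", {
  cfg <- clean_config(reads = 15, cycles = 16, seed = 30, K = default_crosstalk())
  tile <- simulate_tile(cfg)
  th <- list(alpha = 0, beta = 0, K = default_crosstalk(), Sigma = diag(4) * 1e-6)
  dbar <- rep(0, 16)
  terms <- softcall:::e_step_posterior(tile$intensities, th, 7:12, dbar,
                                       rep(1, 15), pad = 4, decoder = "fb")
  ## per (read, cycle) the four hypothesis weights sum to one
  key <- paste(terms$read, terms$cycle)
  sums <- tapply(terms$w, key, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  ## noise-free decoding concentrates all weight on the true base
  for (k in 1:5) {
    tpl <- softcall:::dna_to_idx(tile$truth$template[k])
    sel <- terms$read == k
    top <- terms$xidx[sel][terms$w[sel] > 0.999]
    expect_equal(sort(unique(state_first(top))), sort(unique(tpl[7:12])))
  }
})

test_that("the M-step objective is monotone and keeps truth near a fixed point", {
  cfg <- sim_config(reads = 60, cycles = 12, seed = 31)
  tile <- simulate_tile(cfg)
  fitT <- sim_params_fit(cfg)
  th <- fitT$params[[1]]
  dbar <- fitT$dbar
  terms <- softcall:::e_step_posterior(tile$intensities, th, 1:12, dbar,
                                       rep(1, 60), pad = 0, decoder = "fb")
  ms <- m_step(terms, th, 1:12, dbar[1:12], 1, eps = 0.003)
  ## trace non-decreasing up to numerical tolerance
  expect_true(all(diff(ms$trace) > -1e-6 * abs(ms$trace[-length(ms$trace)])))
  ## parameters stay close to the generative truth
  expect_lt(abs(ms$alpha - cfg$alpha), 0.05)
  expect_lt(abs(ms$beta - th$beta), 0.05)
  expect_lt(norm(normalize_crosstalk(ms$K) - normalize_crosstalk(cfg$K), "F") /
              norm(normalize_crosstalk(cfg$K), "F"), 0.05)
  expect_lt(max(abs(ms$dbar_span[-1] - cfg$d)), 0.03)
})

test_that("windowed online EM is reproducible and recovers parameters", {
  cfg <- sim_config(reads = 120, cycles = 12, seed = 32)
  tile <- simulate_tile(cfg)
  fit1 <- train_basecaller(tile, train_reads = 80, seed = 7)
  fit2 <- train_basecaller(tile, train_reads = 80, seed = 7)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$lambda_hat, fit2$lambda_hat)
  ## parameter error decreases with training size
  cfg2 <- sim_config(reads = 300, cycles = 12, seed = 33)
  tile2 <- simulate_tile(cfg2)
  kerr <- vapply(c(30, 250), function(R) {
    fit <- train_basecaller(tile2, train_reads = R, seed = 8)
    Kn <- normalize_crosstalk(fit$params[[1]]$K)
    Kt <- normalize_crosstalk(cfg2$K)
    norm(Kn - Kt, "F") / norm(Kt, "F")
  }, numeric(1))
  expect_lt(kerr[2], kerr[1] + 0.01)
  expect_lt(kerr[2], 0.05)
})

test_that("fitted parameters serialize and reload exactly", {
  cfg <- sim_config(reads = 60, cycles = 12, seed = 34)
  tile <- simulate_tile(cfg)
  fit <- train_basecaller(tile, train_reads = 40, seed = 9)
  pf <- tempfile(fileext = ".txt")
  write_params(fit, pf)
  back <- read_params(pf)
  expect_equal(back$params, fit$params, tolerance = 1e-14)
  expect_equal(back$dbar, fit$dbar, tolerance = 1e-14)
  expect_equal(back$lambda_hat, fit$lambda_hat, tolerance = 1e-14)
  expect_equal(back$scale, fit$scale, tolerance = 1e-14)
  expect_identical(back$schedule, fit$schedule)
  ## calls from a reloaded fit are identical
  c1 <- call_tile(tile, fit, "fb")
  c2 <- call_tile(tile, back, "fb")
  expect_identical(c1$base, c2$base)
})

test_that("supervised priors follow the match/mismatch splitting rules", {
  cfg <- clean_config(reads = 12, cycles = 10, seed = 35, K = default_crosstalk())
  tile <- simulate_tile(cfg)
  ## reference containing every (padded) template: all calls map perfectly
  ref <- paste(tile$templates_full, collapse = "")
  calls <- bustard_call(tile)
  pri <- supervised_priors(calls, ref)
  for (k in seq_along(pri)) {
    expect_true(all(pri[[k]] %in% c(0, 1)))
    expect_equal(rowSums(pri[[k]]), rep(1, 11))
  }
  ## a forced mismatch splits mass between called and reference base
  calls2 <- calls
  i1 <- which(calls2$read == calls2$read[1] & calls2$cycle == 4)
  truth_b <- calls2$base[i1]
  calls2$base[i1] <- setdiff(c("A", "C", "G", "T"), truth_b)[1]
  pri2 <- supervised_priors(calls2, ref, trust = 0.7)
  P <- pri2[[calls2$read[1]]]
  expect_equal(sort(P[4, P[4, ] > 0]), c(0.3, 0.7))
  expect_equal(P[4, match(truth_b, base_letters())], 0.7)
  ## unmapped read falls back to uniform priors with a warning
  expect_warning(
    pu <- supervised_priors(calls[calls$cycle <= 10 & calls$read == calls$read[1], ],
                            paste(rep("A", 500), collapse = "")),
    "uniform")
  expect_equal(pu[[1]], matrix(0.25, 11, 4))
})
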