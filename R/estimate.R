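## Windowed online EM for the emission-model parameters. Window 1 is
## initialized from the early cycles and uses an importance-sampling E-step
## over the per-read scale; later windows use posterior-weighted E-steps with
## base marginals from trellis decoding. The M-step is cyclic coordinate
## descent (closed forms for K, Sigma, alpha; 1-D solves for the droop
## factors; a grid search for beta).

seq2 <- function(a, b) if (b < a) integer(0) else seq.int(a, b)

psd_floor <- function(M, eps = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, eps)) %*% t(e$vectors)
}

#' Initial crosstalk estimate from the first two cycles
#'
#' Calls the first two bases of every read by the maximum channel, collects
#' each read's first-two intensity vectors as estimates of the corresponding
#' crosstalk columns, aggregates column-wise by the elementwise median, and
#' refines by 5 iterations of invert / re-call / re-estimate (with the
#' column-mean added to the diagonal before each inversion, a standard
#' regularization of the classical procedure).
#'
#' @param reads List of `N x 4` intensity matrices (at least 10 reads).
#' @return 4 x 4 crosstalk estimate (columns on the intensity scale).
#' @export
init_crosstalk <- function(reads) {
  if (length(reads) < 10) stop("need at least 10 reads to estimate crosstalk")
  Y1 <- t(vapply(reads, function(Y) Y[1, ], numeric(4)))
  Y2 <- t(vapply(reads, function(Y) Y[2, ], numeric(4)))
  calls1 <- max.col(Y1, ties.method = "first")
  calls2 <- max.col(Y2, ties.method = "first")
  estimate <- function(c1, c2) {
    K <- matrix(NA_real_, 4, 4)
    for (b in 1:4) {
      rows <- rbind(Y1[c1 == b, , drop = FALSE], Y2[c2 == b, , drop = FALSE])
      if (nrow(rows) == 0)
        stop("crosstalk estimation error: base ", BASES[b],
             " never observed in cycles 1-2")
      K[, b] <- apply(rows, 2, stats::median)
    }
    K
  }
  K <- estimate(calls1, calls2)
  for (it in 1:5) {
    Kreg <- K
    diag(Kreg) <- diag(K) + colMeans(K)
    Kinv <- solve(Kreg)
    calls1 <- max.col(Y1 %*% t(Kinv), ties.method = "first")
    calls2 <- max.col(Y2 %*% t(Kinv), ties.method = "first")
    K <- estimate(calls1, calls2)
  }
  dimnames(K) <- list(BASES, BASES)
  K
}

#' Scale a crosstalk matrix to unit column maxima
#'
#' Convenience for comparing estimated and true crosstalk up to per-column
#' gain.
#'
#' @param K 4 x 4 matrix.
#' @return Column-normalized matrix.
#' @export
normalize_crosstalk <- function(K) sweep(K, 2, apply(abs(K), 2, max), `/`)

#' Initial covariance and droop estimates
#'
#' The base covariance is estimated from the residuals of the first two
#' cycles against the called crosstalk column (per-read outer products,
#' aggregated by the elementwise median and floored to the PSD cone). The
#' per-cycle droop factors come from the per-read ratio of consecutive
#' total corrected signals: the median ratio across reads is a retention
#' factor, stored as droop `1 - retention`. Leakage and pre-phasing mixing
#' are negligible in early cycles and are initialized at zero by the caller.
#'
#' @param reads List of `N x 4` intensity matrices.
#' @param K_hat Crosstalk estimate, e.g. from [init_crosstalk()].
#' @return List: `Sigma` (4 x 4), `dbar` (length-`N` droop vector,
#'   `dbar[1] == 0`).
#' @export
init_sigma_droop <- function(reads, K_hat) {
  Kinv <- tryCatch(solve(K_hat), error = function(e) stop("singular crosstalk matrix"))
  N <- nrow(reads[[1]])
  resid <- lapply(reads, function(Y) {
    X <- Y[1:2, , drop = FALSE] %*% t(Kinv)
    calls <- max.col(X, ties.method = "first")
    r1 <- Y[1, ] - K_hat[, calls[1]]
    r2 <- Y[2, ] - K_hat[, calls[2]]
    (tcrossprod(r1) + tcrossprod(r2)) / 2
  })
  Sig <- apply(simplify2array(resid), c(1, 2), stats::median)
  ## median aggregation of two-sample second moments is biased low by the
  ## median of a chi-square(2)/2 variate (= ln 2); rescale to debias
  Sig <- psd_floor(Sig / log(2), 1e-8)
  tot <- t(vapply(reads, function(Y) rowSums(Y %*% t(Kinv)), numeric(N)))
  ratio <- tot[, -1, drop = FALSE] / tot[, -N, drop = FALSE]
  ratio[!is.finite(ratio)] <- NA
  retention <- apply(ratio, 2, stats::median, na.rm = TRUE)
  dbar <- c(0, pmin(pmax(1 - retention, 0), 0.5))
  list(Sigma = Sig, dbar = dbar)
}

## effective signal for an arbitrary hypothesis pair index (1..16) at beta
hyp_signal_matrix <- function(beta) effective_signal_matrix(beta)

#' Per-read scale from the window quadratic
#'
#' The scale maximizing the window log-likelihood given calls and parameters
#' solves, summed over the window's cycles,
#' `4 lambda^2 + b_i lambda - c_i = 0` with
#' `b_i = (K X_i)' Sigma^-1 Ybar_i / (D_i ||X_i||^2)` and
#' `c_i = Ybar_i' Sigma^-1 Ybar_i / (D_i^2 ||X_i||^2)`, where `Ybar` is the
#' leakage-corrected observation and `D_i` the cumulative droop product.
#' The positive root is returned.
#'
#' @param Y `N x 4` intensity matrix.
#' @param calls Integer base indices for at least the window's cycles (the
#'   position after the last cycle falls back to the last call when absent).
#' @param theta List or [window_params()] with `alpha`, `beta`, `K`, `Sigma`.
#' @param cycles Integer vector of window cycle numbers.
#' @param dprod Cumulative droop products `D_i` for `cycles`.
#' @return Positive scalar scale estimate.
#' @export
estimate_lambda <- function(Y, calls, theta, cycles, dprod) {
  stopifnot(length(cycles) >= 1, length(dprod) == length(cycles))
  Sinv <- chol2inv(chol(theta$Sigma))
  n <- length(cycles)
  nxt <- calls[pmin(cycles + 1L, length(calls))]
  bad <- !(nxt %in% 1:4)                 # beyond read end or not yet called
  nxt[bad] <- calls[cycles][bad]
  xidx <- state_index(calls[cycles], nxt)
  X16 <- effective_signal_matrix(theta$beta)
  X <- X16[xidx, , drop = FALSE]
  s <- rowSums(X^2)
  KX <- X %*% t(theta$K)
  Yb <- Y[cycles, , drop = FALSE]
  prev <- cycles > 1
  Yb[prev, ] <- Yb[prev, , drop = FALSE] -
    theta$alpha * Y[cycles[prev] - 1L, , drop = FALSE]
  YS <- Yb %*% Sinv
  b <- rowSums(YS * KX) / (dprod * s)
  cc <- rowSums(YS * Yb) / (dprod^2 * s)
  B <- sum(b); C <- sum(cc); A <- 4 * n
  disc <- B^2 + 4 * A * C
  if (C <= 0 || disc < 0) stop("scale estimation error: no positive root (C=", C, ")")
  (-B + sqrt(disc)) / (2 * A)
}

## ---------------------------------------------------------------------------
## Weighted-term objective
##
## Every E-step produces a flat table of weighted likelihood terms. Term t has
## a read index, a cycle, a 16-level hypothesis index for the (S_i, S_{i+1})
## pair, a weight, and the read's lambda moments E[1/lambda^2], E[1/lambda],
## E[log lambda] under the E-step distribution (point mass or importance
## sample). The window objective is
##   O = -1/2 sum_t w_t [ 8 m0 + 8 log D_i + 4 log s_x + log det Sigma
##                        + q1 m2 / (D_i^2 s_x) - 2 q2 m1 / (D_i s_x)
##                        + q3 / s_x ]
## which every coordinate update below maximizes in closed or 1-D form.
## ---------------------------------------------------------------------------

make_terms <- function(read, cycle, xidx, w, m2, m1, m0, Y, Yprev) {
  list(read = read, cycle = cycle, xidx = xidx, w = w,
       m2 = m2, m1 = m1, m0 = m0, Y = Y, Yprev = Yprev, n = length(w))
}

## D_i per term given the span's droop factors and the pre-span product
term_dprod <- function(terms, span, dbar_span, Dpre) {
  Dvec <- Dpre * cumprod(1 - dbar_span)
  Dvec[match(terms$cycle, span)]
}

obj_value <- function(terms, K, Sigma, alpha, beta, span, dbar_span, Dpre,
                      parts = NULL) {
  if (is.null(parts)) parts <- obj_parts(terms, K, Sigma, alpha, beta)
  D <- term_dprod(terms, span, dbar_span, Dpre)
  L <- 8 * terms$m0 + 8 * log(D) + 4 * parts$logs + parts$ldS +
    parts$q1 * terms$m2 / (D^2 * parts$s) -
    2 * parts$q2 * terms$m1 / (D * parts$s) +
    parts$q3 / parts$s
  -0.5 * sum(terms$w * L)
}

obj_parts <- function(terms, K, Sigma, alpha, beta) {
  Sinv <- chol2inv(chol(Sigma))
  ldS <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  Yb <- terms$Y - alpha * terms$Yprev
  YS <- Yb %*% Sinv
  X16 <- effective_signal_matrix(beta)
  KX16 <- X16 %*% t(K)
  G16 <- KX16 %*% Sinv
  s16 <- rowSums(X16^2)
  q3_16 <- rowSums(G16 * KX16)
  Xs <- X16[terms$xidx, , drop = FALSE]
  KXs <- KX16[terms$xidx, , drop = FALSE]
  q1 <- rowSums(YS * Yb)
  q2 <- rowSums(YS * KXs)
  s <- s16[terms$xidx]
  list(q1 = q1, q2 = q2, q3 = q3_16[terms$xidx], s = s, logs = log(s),
       Yb = Yb, YS = YS, X = Xs, KX = KXs, Sinv = Sinv, ldS = ldS)
}

## one full cycle of coordinate updates; returns updated parameters.
cd_cycle <- function(terms, K, Sigma, alpha, beta, span, dbar_span, Dpre,
                     beta_grid, first_window) {
  obj <- function(K., S., a., b., d.)
    obj_value(terms, K., S., a., b., span, d., Dpre)
  cur <- obj(K, Sigma, alpha, beta, dbar_span)

  ## K: weighted least squares (independent of Sigma)
  D <- term_dprod(terms, span, dbar_span, Dpre)
  X16 <- effective_signal_matrix(beta)
  Xs <- X16[terms$xidx, , drop = FALSE]
  s <- rowSums(X16^2)[terms$xidx]
  Yb <- terms$Y - alpha * terms$Yprev
  w1 <- terms$w * terms$m1 / (D * s)
  w2 <- terms$w / s
  M1 <- crossprod(Yb * w1, Xs)
  M2 <- crossprod(Xs * w2, Xs)
  Knew <- tryCatch(M1 %*% solve(M2), error = function(e) K)
  cand <- obj(Knew, Sigma, alpha, beta, dbar_span)
  if (is.finite(cand) && cand >= cur) { K <- Knew; cur <- cand }

  ## Sigma: weighted residual second moment, floored to the PSD cone
  KXs <- Xs %*% t(K)
  wm2 <- terms$w * terms$m2 / (D^2 * s)
  wm1 <- terms$w * terms$m1 / (D * s)
  w0 <- terms$w / s
  A1 <- crossprod(Yb * wm2, Yb)
  A2 <- crossprod(KXs * wm1, Yb)
  A3 <- crossprod(KXs * w0, KXs)
  Snew <- psd_floor((A1 - A2 - t(A2) + A3) / sum(terms$w), 1e-8)
  cand <- obj(K, Snew, alpha, beta, dbar_span)
  if (is.finite(cand) && cand >= cur) { Sigma <- Snew; cur <- cand }

  ## droop factors: 1-D solves per span cycle (cycle 1 has no droop)
  for (m in seq_along(span)) {
    if (span[m] == 1L) next
    f <- function(d) {
      ds <- dbar_span; ds[m] <- d
      -obj(K, Sigma, alpha, beta, ds)
    }
    op <- stats::optimize(f, c(0, 0.3), tol = 1e-5)
    if (-op$objective >= cur) { dbar_span[m] <- op$minimum; cur <- -op$objective }
  }

  ## alpha: 1-D quadratic over leakage (cycle-1 terms carry no leakage)
  Sinv <- chol2inv(chol(Sigma))
  has_prev <- terms$cycle > 1
  if (any(has_prev)) {
    Yp <- terms$Yprev
    uS <- Yp %*% Sinv
    a2 <- sum((terms$w * terms$m2 / (D^2 * s) * rowSums(uS * Yp))[has_prev])
    b1 <- sum((terms$w * (-2 * terms$m2 / (D^2 * s) * rowSums(uS * terms$Y) +
                           2 * terms$m1 / (D * s) * rowSums(uS * KXs)))[has_prev])
    if (a2 > 0) {
      anew <- min(max(-b1 / (2 * a2), 0), 0.9)
      cand <- obj(K, Sigma, anew, beta, dbar_span)
      if (is.finite(cand) && cand >= cur) { alpha <- anew; cur <- cand }
    }
  }

  ## beta: grid search
  vals <- vapply(beta_grid, function(b) obj(K, Sigma, alpha, b, dbar_span),
                 numeric(1))
  if (max(vals, na.rm = TRUE) >= cur) {
    beta <- beta_grid[which.max(vals)]
    cur <- max(vals, na.rm = TRUE)
  }

  list(K = K, Sigma = Sigma, alpha = alpha, beta = beta,
       dbar_span = dbar_span, objective = cur)
}

#' Coordinate-descent M-step
#'
#' Maximizes the weighted window objective by cycling K -> Sigma -> droop ->
#' alpha -> beta until the relative objective change drops below `eps`.
#' Closed-form weighted-least-squares updates are used for K, Sigma and
#' alpha; droop factors use bounded 1-D solves; beta uses a grid search
#' (default `[0, 0.5]` in steps of 0.005). Every update is accepted only if
#' it does not decrease the objective, so the trace is monotone.
#'
#' @param terms Weighted term table from an E-step (internal format).
#' @param theta List with `K`, `Sigma`, `alpha`, `beta` starting values.
#' @param span Integer cycles covered by the optimization.
#' @param dbar_span Starting droop factors for `span`.
#' @param Dpre Cumulative droop product over cycles before `span`.
#' @param eps Relative-change stopping threshold (default 0.003).
#' @param max_iter Safety cap on coordinate cycles.
#' @param beta_grid Grid for the beta search.
#' @return List: updated `K`, `Sigma`, `alpha`, `beta`, `dbar_span`,
#'   `objective`, and the per-cycle objective `trace`.
#' @export
m_step <- function(terms, theta, span, dbar_span, Dpre, eps = 0.003,
                   max_iter = 50, beta_grid = seq(0, 0.5, by = 0.005)) {
  obj0 <- obj_value(terms, theta$K, theta$Sigma, theta$alpha, theta$beta,
                    span, dbar_span, Dpre)
  trace <- obj0
  K <- theta$K; Sigma <- theta$Sigma; alpha <- theta$alpha; beta <- theta$beta
  prev <- obj0
  for (it in seq_len(max_iter)) {
    upd <- cd_cycle(terms, K, Sigma, alpha, beta, span, dbar_span, Dpre,
                    beta_grid, first_window = span[1] == 1L)
    K <- upd$K; Sigma <- upd$Sigma; alpha <- upd$alpha; beta <- upd$beta
    dbar_span <- upd$dbar_span
    trace <- c(trace, upd$objective)
    if (it == 1 && upd$objective < prev - 1e-9 * abs(prev))
      warning("non-improving first coordinate cycle; keeping input parameters")
    if (abs(upd$objective - prev) < eps * abs(prev)) { prev <- upd$objective; break }
    prev <- upd$objective
  }
  list(K = K, Sigma = Sigma, alpha = alpha, beta = beta,
       dbar_span = dbar_span, objective = prev, trace = trace)
}

## ---------------------------------------------------------------------------
## E-steps
## ---------------------------------------------------------------------------

## Window-1 E-step: hypotheses fixed at the baseline calls; the expectation
## over the read scale is taken by self-normalized importance sampling with a
## Gaussian proposal centered at the current scale estimate.
e_step_first <- function(reads, boot_calls, theta, span, dbar_span, Dpre,
                         lambda_hat, n_is = 500, proposal_var = 0.1) {
  R <- length(reads)
  n <- length(span)
  Dvec <- Dpre * cumprod(1 - dbar_span)
  Sinv <- chol2inv(chol(theta$Sigma))
  ldS <- as.numeric(determinant(theta$Sigma, logarithm = TRUE)$modulus)
  X16 <- effective_signal_matrix(theta$beta)
  KX16 <- X16 %*% t(theta$K)
  s16 <- rowSums(X16^2)
  q3_16 <- rowSums((KX16 %*% Sinv) * KX16)
  m2 <- m1 <- m0 <- numeric(R)
  rows_Y <- matrix(0, R * n, 4); rows_Yp <- matrix(0, R * n, 4)
  xidx <- integer(R * n); cyc <- integer(R * n); rd <- integer(R * n)
  sdp <- sqrt(proposal_var)
  for (k in seq_len(R)) {
    Y <- reads[[k]]
    calls <- boot_calls[[k]]
    nxt <- ifelse(span + 1L <= length(calls), calls[pmin(span + 1L, length(calls))],
                  calls[span])
    xk <- state_index(calls[span], nxt)
    Yb <- Y[span, , drop = FALSE]
    prev <- span > 1
    Yb[prev, ] <- Yb[prev, , drop = FALSE] -
      theta$alpha * Y[span[prev] - 1L, , drop = FALSE]
    YS <- Yb %*% Sinv
    sk <- s16[xk]
    q1 <- rowSums(YS * Yb)
    q2 <- rowSums(YS * KX16[xk, , drop = FALSE])
    A <- sum(q1 / (Dvec^2 * sk))
    B <- sum(q2 / (Dvec * sk))
    C <- sum(q3_16[xk] / sk) + sum(4 * log(sk) + 8 * log(Dvec)) + n * ldS
    lam_s <- stats::rnorm(n_is, lambda_hat[k], sdp)
    ok <- lam_s > 1e-8
    logtar <- rep(-Inf, n_is)
    logtar[ok] <- -0.5 * (8 * n * log(lam_s[ok]) + A / lam_s[ok]^2 -
                            2 * B / lam_s[ok] + C)
    logw <- logtar - stats::dnorm(lam_s, lambda_hat[k], sdp, log = TRUE)
    if (all(!is.finite(logw))) stop("degenerate importance weights for read ", k)
    w <- exp(logw - logsumexp(logw))
    m2[k] <- sum(w[ok] / lam_s[ok]^2)
    m1[k] <- sum(w[ok] / lam_s[ok])
    m0[k] <- sum(w[ok] * log(lam_s[ok]))
    ii <- (k - 1L) * n + seq_len(n)
    rows_Y[ii, ] <- Y[span, , drop = FALSE]
    rows_Yp[ii, ] <- rbind(if (span[1] == 1L) 0 else Y[span[1] - 1L, ],
                           Y[span[-n], , drop = FALSE])
    xidx[ii] <- xk
    cyc[ii] <- span
    rd[ii] <- k
  }
  ii_all <- seq_len(R * n)
  make_terms(rd, cyc, xidx, rep(1, R * n),
             m2[rd], m1[rd], m0[rd], rows_Y, rows_Yp)
}

## Subsequent-window E-step: base-marginal posterior weights from trellis
## decoding at the current parameters and per-read scale estimates.
e_step_posterior <- function(reads, theta, span, dbar_full, lambda_hat,
                             pad = 5, decoder = c("fb", "sova"),
                             priors = NULL) {
  decoder <- match.arg(decoder)
  R <- length(reads)
  N <- nrow(reads[[1]])
  n <- length(span)
  spanpad <- span[1]:min(span[length(span)] + pad, N)
  dprod_all <- cumprod(1 - dbar_full)
  Tn <- R * n * 4L
  rows_Y <- matrix(0, Tn, 4); rows_Yp <- matrix(0, Tn, 4)
  xidx <- integer(Tn); cyc <- integer(Tn); rd <- integer(Tn); w <- numeric(Tn)
  m2 <- numeric(Tn); m1 <- numeric(Tn); m0 <- numeric(Tn)
  calls_store <- matrix(0L, R, n + 1L)
  for (k in seq_len(R)) {
    Y <- reads[[k]]
    em <- emission_matrix(Y, spanpad, lambda_hat[k], theta$K, theta$Sigma,
                          theta$alpha, theta$beta, dprod_all[spanpad])
    pr <- if (is.null(priors)) NULL else
      trellis_priors(length(spanpad),
                     priors[[k]][spanpad[1]:(spanpad[length(spanpad)] + 1L), ,
                                 drop = FALSE])
    dec <- if (decoder == "fb") forward_backward(em, pr) else sova(em, pr)
    bp <- dec$base_post
    calls_all <- c(max.col(bp, ties.method = "first"),
                   which.max(dec$final_base_post))
    calls_store[k, ] <- calls_all[seq_len(n + 1L)]
    for (m in seq_len(n)) {
      ii <- (k - 1L) * n * 4L + (m - 1L) * 4L + 1:4
      rows_Y[ii, ] <- matrix(Y[span[m], ], 4, 4, byrow = TRUE)
      rows_Yp[ii, ] <- if (span[m] > 1)
        matrix(Y[span[m] - 1L, ], 4, 4, byrow = TRUE) else 0
      xidx[ii] <- state_index(1:4, calls_all[m + 1L])
      cyc[ii] <- span[m]
      rd[ii] <- k
      w[ii] <- bp[m, ]
      m2[ii] <- 1 / lambda_hat[k]^2
      m1[ii] <- 1 / lambda_hat[k]
      m0[ii] <- log(lambda_hat[k])
    }
  }
  terms <- make_terms(rd, cyc, xidx, w, m2, m1, m0, rows_Y, rows_Yp)
  terms$calls <- calls_store
  terms
}

#' Window schedule for online estimation
#'
#' Tiles cycles `1..N` with windows of length `W`; a final partial window is
#' merged into the preceding one. Optimization for window `l` spans windows
#' `l` and `l + 1` (the last window is optimized alone).
#'
#' @param N Number of cycles.
#' @param W Window length (default 6).
#' @return Tibble: `window`, `start`, `end`, `opt_end`.
#' @export
window_schedule <- function(N, W = 6) {
  stopifnot(N >= W)
  W <- as.integer(W); N <- as.integer(N)
  starts <- seq.int(1L, N, by = W)
  ends <- pmin(starts + W - 1L, N)
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1L) < W) {
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
    ends[length(ends)] <- N
  }
  nw <- length(starts)
  tibble::tibble(window = seq_len(nw), start = starts, end = ends,
                 opt_end = c(if (nw > 1) ends[-1] else NULL, ends[nw]))
}

#' Train the base-calling model by windowed online EM
#'
#' Fits per-window emission parameters on a random training subset of a
#' tile. Window 1 is initialized from the early cycles ([init_crosstalk()],
#' [init_sigma_droop()]) and fitted with the importance-sampling E-step over
#' the per-read scale, using baseline (Bustard-style) calls as sequence
#' hypotheses; each later window is initialized from its predecessor and
#' fitted with posterior-weighted E-steps whose weights come from trellis
#' decoding. Each window's optimization spans the window and its successor
#' to prevent over-fitting; after a window converges the per-read scales are
#' refreshed from its calls via [estimate_lambda()].
#'
#' Intensities are pre-scaled so that the tile-median initial scale is 1;
#' the factor is recorded in the fit and applied automatically by
#' [call_tile()].
#'
#' @param x An `intensity_set`, `sim_tile`, or list of intensity matrices.
#' @param train_reads Training-set size (default 250).
#' @param W Window length in cycles (default 6).
#' @param pad Extra decoded cycles beyond each window (default 5).
#' @param decoder E-step decoder, `"fb"` or `"sova"`.
#' @param n_is Importance-sample count for window 1 (default 500).
#' @param proposal_var Variance of the window-1 scale proposal (default 0.1
#'   on the normalized intensity scale).
#' @param eps EM and coordinate-descent stopping ratio (default 0.003).
#' @param max_em_iter Cap on EM iterations per window.
#' @param seed Optional seed controlling training-read selection and the
#'   importance sampler.
#' @param priors Optional supervised priors: a list of `(N + 1) x 4` base
#'   prior matrices named by read id (see [supervised_priors()]); reads
#'   without an entry use uniform priors.
#' @param verbose Print per-window progress.
#' @return Object of class `softcall_fit`: window `schedule`, per-window
#'   `params`, global `dbar`, training-read scales `lambda_hat`, intensity
#'   `scale`, objective `trace` tibble, and bookkeeping fields.
#' @export
train_basecaller <- function(x, train_reads = 250, W = 6, pad = 5,
                             decoder = c("fb", "sova"), n_is = 500,
                             proposal_var = 0.1, eps = 0.003,
                             max_em_iter = 8, seed = NULL, priors = NULL,
                             verbose = FALSE) {
  decoder <- match.arg(decoder)
  xs <- as_intensity_set(x)
  N <- nrow(xs$intensities[[1]])
  if (!is.null(seed)) set.seed(seed)
  R_all <- length(xs$intensities)
  idx <- if (R_all > train_reads) sort(sample.int(R_all, train_reads)) else seq_len(R_all)
  ids <- read_ids(xs$meta)[idx]
  reads_raw <- xs$intensities[idx]
  R <- length(reads_raw)

  ## baseline calls for the training reads (sequence hypotheses, window 1)
  boot <- bustard_call(xs)
  boot_idx_all <- split(match(boot$base, BASES),
                        factor(boot$read, levels = unique(boot$read)))
  boot_calls <- boot_idx_all[read_ids(xs$meta)[idx]]

  ## normalize the intensity scale: tile-median corrected cycle-1 signal -> 1
  K0 <- unname(init_crosstalk(reads_raw))
  x1 <- vapply(reads_raw, function(Y) sum(solve(K0, Y[1, ])), numeric(1))
  scale <- stats::median(x1)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  reads <- lapply(reads_raw, function(Y) Y / scale)
  K0 <- K0 / scale

  init <- init_sigma_droop(reads, K0)
  dbar <- init$dbar
  theta <- list(K = K0, Sigma = init$Sigma, alpha = 0, beta = 0)
  sched <- window_schedule(N, W)
  pr_list <- if (is.null(priors)) NULL else
    lapply(ids, function(id) {
      if (!is.null(priors[[id]])) priors[[id]] else matrix(0.25, N + 1L, 4L)
    })

  dprod_all <- cumprod(1 - dbar)
  lambda_hat <- vapply(seq_len(R), function(k)
    estimate_lambda(reads[[k]], boot_calls[[k]], theta,
                    cycles = sched$start[1]:sched$end[1],
                    dprod = dprod_all[sched$start[1]:sched$end[1]]),
    numeric(1))

  params <- vector("list", nrow(sched))
  trace <- list()
  for (l in seq_len(nrow(sched))) {
    span <- sched$start[l]:sched$opt_end[l]
    Dpre <- prod(1 - dbar[seq2(2L, span[1] - 1L)])
    dbar_span <- dbar[span]
    if (span[1] == 1L) dbar_span[1] <- 0
    obj_prev <- -Inf
    for (it in seq_len(max_em_iter)) {
      terms <- if (l == 1L) {
        e_step_first(reads, boot_calls, theta, span, dbar_span, Dpre,
                     lambda_hat, n_is = n_is, proposal_var = proposal_var)
      } else {
        dbar_tmp <- dbar; dbar_tmp[span] <- dbar_span
        e_step_posterior(reads, theta, span, dbar_tmp, lambda_hat,
                         pad = pad, decoder = decoder, priors = pr_list)
      }
      ms <- m_step(terms, theta, span, dbar_span, Dpre, eps = eps)
      theta <- list(K = ms$K, Sigma = ms$Sigma, alpha = ms$alpha, beta = ms$beta)
      dbar_span <- ms$dbar_span
      trace[[length(trace) + 1L]] <-
        tibble::tibble(window = l, iteration = it, objective = ms$objective)
      if (verbose)
        message(sprintf("window %d iter %d: objective %.4f beta %.3f alpha %.3f",
                        l, it, ms$objective, theta$beta, theta$alpha))
      if (is.finite(obj_prev) && abs(ms$objective - obj_prev) < eps * abs(obj_prev))
        break
      obj_prev <- ms$objective
    }
    params[[l]] <- theta
    dbar[span] <- dbar_span
    dprod_all <- cumprod(1 - dbar)
    ## refresh per-read scales from this window's calls and parameters
    win_cycles <- sched$start[l]:sched$end[l]
    calls_now <- window_calls(reads, theta, dbar, lambda_hat, span, pad,
                              decoder, pr_list)
    lambda_hat <- vapply(seq_len(R), function(k) {
      tryCatch(estimate_lambda(reads[[k]], calls_now[[k]], theta,
                               cycles = win_cycles,
                               dprod = dprod_all[win_cycles]),
               error = function(e) lambda_hat[k])
    }, numeric(1))
  }
  fit <- list(schedule = sched, params = params, dbar = dbar,
              lambda_hat = stats::setNames(lambda_hat, ids),
              scale = scale, trace = dplyr::bind_rows(trace),
              W = W, pad = pad, decoder = decoder, cycles = N,
              train_ids = ids)
  class(fit) <- "softcall_fit"
  fit
}

## hard calls over a span (full-length call vector; positions outside the
## decoded span are zero and unused by downstream per-window consumers)
window_calls <- function(reads, theta, dbar, lambda_hat, span, pad, decoder,
                         pr_list) {
  N <- nrow(reads[[1]])
  spanpad <- span[1]:min(span[length(span)] + pad, N)
  dprod_all <- cumprod(1 - dbar)
  lapply(seq_along(reads), function(k) {
    em <- emission_matrix(reads[[k]], spanpad, lambda_hat[k], theta$K,
                          theta$Sigma, theta$alpha, theta$beta,
                          dprod_all[spanpad])
    pr <- if (is.null(pr_list)) NULL else
      trellis_priors(length(spanpad),
                     pr_list[[k]][spanpad[1]:(spanpad[length(spanpad)] + 1L), ,
                                  drop = FALSE])
    dec <- if (decoder == "fb") forward_backward(em, pr) else sova(em, pr)
    calls <- integer(N + 1L)
    calls[spanpad] <- max.col(dec$base_post, ties.method = "first")
    calls[spanpad[length(spanpad)] + 1L] <- which.max(dec$final_base_post)
    calls[calls == 0L] <- 1L
    calls
  })
}

#' @export
print.softcall_fit <- function(x, ...) {
  cat(sprintf("<softcall_fit> %d windows (W=%d, pad=%d) over %d cycles, %d training reads\n",
              nrow(x$schedule), x$W, x$pad, x$cycles, length(x$lambda_hat)))
  b <- vapply(x$params, `[[`, numeric(1), "beta")
  cat("  beta by window:", paste(sprintf("%.3f", b), collapse = " "), "\n")
  cat("  mean droop:", sprintf("%.4f", mean(x$dbar[-1])), "\n")
  invisible(x)
}
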