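## Generative and approximate signal models: phasing Markov chain, strand-length
## profile, two-term effective signal, and the per-cycle Gaussian emission.

#' Phasing / pre-phasing parameters
#'
#' In each chemistry cycle a strand fails to incorporate a base with
#' probability `p_ii` (phasing) and incorporates an extra base with
#' probability `p_cf` (pre-phasing). At most two incorporations per cycle are
#' modeled.
#'
#' @param p_ii Probability of no incorporation, in `[0, 1)`.
#' @param p_cf Probability of an extra incorporation, in `[0, 1)`.
#' @return An object of class `phasing_params`.
#' @export
#' @examples
#' phasing_params(0.002, 0.01)
phasing_params <- function(p_ii = 0, p_cf = 0) {
  if (!is.numeric(p_ii) || length(p_ii) != 1 || is.na(p_ii) || p_ii < 0 || p_ii >= 1)
    stop("p_ii must be a probability in [0, 1)")
  if (!is.numeric(p_cf) || length(p_cf) != 1 || is.na(p_cf) || p_cf < 0 || p_cf >= 1)
    stop("p_cf must be a probability in [0, 1)")
  structure(list(p_ii = p_ii, p_cf = p_cf), class = "phasing_params")
}

#' @export
print.phasing_params <- function(x, ...) {
  cat(sprintf("<phasing_params> p_ii = %g, p_cf = %g\n", x$p_ii, x$p_cf))
  invisible(x)
}

#' Strand-length transition matrix of the phasing Markov chain
#'
#' Builds the `(L + 1) x (L + 1)` matrix `P` over strand lengths `0..L`:
#' in one cycle a strand of length `i` stays at `i` with probability `p_ii`,
#' extends to `i + 1` with probability `(1 - p_ii) (1 - p_cf)` and to `i + 2`
#' with probability `p_cf (1 - p_ii)`. Length `L` is absorbing, and the
#' penultimate row's two-step mass is folded onto `L` so every row remains
#' stochastic.
#'
#' @param p A [phasing_params()] object.
#' @param L Template length (`>= 1`).
#' @return `(L + 1) x (L + 1)` numeric matrix; rows index current length
#'   `0..L`, columns next length.
#' @export
#' @examples
#' transition_matrix(phasing_params(0.1, 0.2), L = 5)[3, 3:5]  # 0.1 0.72 0.18
transition_matrix <- function(p, L) {
  stopifnot(inherits(p, "phasing_params"))
  if (!is.numeric(L) || length(L) != 1 || L < 1 || L != round(L))
    stop("L must be a positive integer")
  L <- as.integer(L)
  P <- matrix(0, L + 1L, L + 1L)
  stay <- p$p_ii
  one  <- (1 - p$p_ii) * (1 - p$p_cf)
  two  <- p$p_cf * (1 - p$p_ii)
  for (i in seq_len(L + 1L) - 1L) {  # current length i (0-based)
    r <- i + 1L
    if (i >= L) {
      P[r, r] <- 1            # absorbing end
    } else if (i == L - 1L) {
      P[r, r] <- stay         # overflow two-step mass folded onto L
      P[r, r + 1L] <- 1 - stay
    } else {
      P[r, r] <- stay
      P[r, r + 1L] <- one
      P[r, r + 2L] <- two
    }
  }
  P
}

#' Strand-length profile over cycles
#'
#' Row `i` is the distribution of the strand length after `i` cycles:
#' `E[i, j] = [P^i]` evaluated at initial length 0 and target length `j`
#' (`j = 1..L`; the length-0 column is dropped since an unextended strand
#' emits no signal). Computed by iterated vector-matrix products.
#'
#' @param P Transition matrix from [transition_matrix()].
#' @param N Number of cycles (`>= 1`).
#' @return `N x L` matrix of probabilities; row `i` sums to 1 minus the
#'   (typically negligible) probability of remaining at length 0.
#' @export
phasing_profile <- function(P, N) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P), N >= 1)
  L <- nrow(P) - 1L
  v <- c(1, rep(0, L))  # start at length 0
  E <- matrix(0, N, L)
  for (i in seq_len(N)) {
    v <- as.numeric(v %*% P)
    E[i, ] <- v[-1L]
  }
  E
}

#' Two-term effective signal of a trellis state
#'
#' The finite-memory approximation keeps, at cycle `i`, only the template
#' positions `i` and `i + 1`: the expected signal is
#' `(1 - beta) * onehot(first) + beta * onehot(second)` for the state
#' `(first, second)`, where `beta` is the cycle's pre-phasing mixing weight.
#'
#' @param state Integer state index in 1..16.
#' @param beta Mixing weight in `[0, 1)`.
#' @return Length-4 signal vector summing to 1 (channel order A, C, G, T).
#' @export
#' @examples
#' effective_signal(state_index(1, 2), 0.3)  # 0.7 0.3 0 0
effective_signal <- function(state, beta) {
  stopifnot(length(state) == 1, state %in% 1:16)
  if (beta < 0 || beta >= 1) stop("beta must be in [0, 1)")
  x <- numeric(4)
  x[state_first(state)] <- x[state_first(state)] + (1 - beta)
  x[state_second(state)] <- x[state_second(state)] + beta
  x
}

## 16 x 4 matrix of effective signals for all states at one beta
effective_signal_matrix <- function(beta) {
  X <- matrix(0, 16, 4)
  f <- state_first(1:16); s <- state_second(1:16)
  X[cbind(1:16, f)] <- X[cbind(1:16, f)] + (1 - beta)
  X[cbind(1:16, s)] <- X[cbind(1:16, s)] + beta
  X
}

#' Per-window model parameters
#'
#' The emission model for a window of cycles is parameterized by a leakage
#' scalar `alpha` (carry-over of the previous cycle's observation), a
#' pre-phasing mixing weight `beta`, a 4 x 4 crosstalk matrix `K`, a 4 x 4
#' positive-definite base covariance `Sigma`, and per-cycle droop factors
#' `dbar` (fraction of signal lost entering each cycle).
#'
#' @param alpha Leakage scalar, `[0, 1)`.
#' @param beta Pre-phasing mixing weight, `[0, 1)`.
#' @param K Invertible 4 x 4 crosstalk matrix.
#' @param Sigma Symmetric positive-definite 4 x 4 covariance.
#' @param dbar Numeric vector of per-cycle droop factors in `[0, 1)`.
#' @return An object of class `window_params`.
#' @export
window_params <- function(alpha = 0, beta = 0, K = diag(4), Sigma = diag(4),
                          dbar = numeric(0)) {
  stopifnot(is.matrix(K), all(dim(K) == 4), is.matrix(Sigma), all(dim(Sigma) == 4))
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (beta < 0 || beta >= 1) stop("beta must be in [0, 1)")
  if (length(dbar) && (any(dbar < 0) || any(dbar >= 1)))
    stop("droop factors must be in [0, 1)")
  if (abs(det(K)) < 1e-12) stop("K must be invertible")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  structure(list(alpha = alpha, beta = beta, K = K, Sigma = Sigma, dbar = dbar),
            class = "window_params")
}

#' @export
print.window_params <- function(x, ...) {
  cat(sprintf("<window_params> alpha = %.4g, beta = %.4g, %d droop factor(s)\n",
              x$alpha, x$beta, length(x$dbar)))
  invisible(x)
}

#' Log emission density of one cycle's intensity vector
#'
#' The observation at cycle `i` given state `(S_i, S_{i+1})`, read scale
#' `lam` and cumulative droop `D_i = prod_{j=2}^{i} (1 - dbar_j)` is Gaussian
#' with mean `lam * D_i * K %*% X_i + alpha * y_prev` (the leakage term is
#' absent at cycle 1) and covariance `(lam * D_i)^2 * ||X_i||^2 * Sigma`,
#' where `X_i` is the state's [effective_signal()].
#'
#' @param y 4-vector observed at this cycle.
#' @param y_prev 4-vector observed at the previous cycle, or `NULL` iff
#'   `cycle == 1`.
#' @param state Trellis state index in 1..16.
#' @param theta [window_params()] for this cycle's window.
#' @param lam Positive read scale.
#' @param cycle Cycle number (`>= 1`); `theta$dbar` must cover cycles
#'   `2..cycle` when `droop_prod` is not supplied.
#' @param droop_prod Optional precomputed cumulative droop product `D_i`;
#'   overrides `theta$dbar`.
#' @return Scalar log density.
#' @export
emission_log_density <- function(y, y_prev, state, theta, lam, cycle,
                                 droop_prod = NULL) {
  stopifnot(inherits(theta, "window_params"), lam > 0, cycle >= 1)
  if (cycle == 1 && !is.null(y_prev)) stop("y_prev must be NULL at cycle 1")
  if (cycle > 1 && is.null(y_prev)) stop("y_prev required for cycle > 1")
  D <- if (!is.null(droop_prod)) droop_prod else {
    if (cycle == 1) 1 else prod(1 - theta$dbar[2:cycle])
  }
  x <- effective_signal(state, theta$beta)
  mu <- lam * D * as.numeric(theta$K %*% x)
  if (cycle > 1) mu <- mu + theta$alpha * y_prev
  s2 <- (lam * D)^2 * sum(x^2)
  cov <- s2 * theta$Sigma
  ch <- chol(cov)
  r <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (4 * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
}

## Emission log-density matrix for one read over a cycle range.
##
## Y: N x 4 intensity matrix (full read); cycles: integer vector of cycle
## numbers (consecutive); lam: read scale; K, Sigma, alpha: window-level
## parameters; beta: scalar or one value per cycle in `cycles`; dprod: the
## cumulative droop product D_i for each cycle in `cycles`.
## Returns length(cycles) x 16 matrix of log e_state(Y_i).
emission_matrix <- function(Y, cycles, lam, K, Sigma, alpha, beta, dprod) {
  M <- length(cycles)
  if (length(beta) == 1) beta <- rep(beta, M)
  stopifnot(length(dprod) == M, length(beta) == M)
  Sinv <- chol2inv(chol(Sigma))
  ldS <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  ## leakage-corrected observations
  Yb <- Y[cycles, , drop = FALSE]
  prev <- cycles > 1
  Yb[prev, ] <- Yb[prev, , drop = FALSE] - alpha * Y[cycles[prev] - 1L, , drop = FALSE]
  q1 <- rowSums((Yb %*% Sinv) * Yb)                      # per-cycle Ybar' Sinv Ybar
  out <- matrix(0, M, 16)
  ub <- unique(beta)
  for (b in ub) {
    sel <- which(beta == b)
    X <- effective_signal_matrix(b)                      # 16 x 4
    KX <- X %*% t(K)                                     # 16 x 4, rows = (K x)'
    G <- KX %*% Sinv                                     # 16 x 4
    q3 <- rowSums(G * KX)                                # 16
    s  <- rowSums(X^2)                                   # 16
    q2 <- Yb[sel, , drop = FALSE] %*% t(G)               # |sel| x 16
    lD <- lam * dprod[sel]
    quad <- sweep(q1[sel] / lD^2 - 2 * q2 / lD, 2, q3, `+`)
    quad <- sweep(quad, 2, s, `/`)
    norm <- outer(8 * log(lD), 4 * log(s) , `+`)         # logdet cov pieces
    out[sel, ] <- -0.5 * (4 * log(2 * pi) + ldS + norm + quad)
  }
  out
}
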