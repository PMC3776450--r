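## Trellis decoding in the natural-log domain: exact posterior marginals by
## forward-backward, the MAP path by Viterbi, and approximate per-base
## posteriors by a soft-output Viterbi (SOVA) with 3-edge path deviations.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## column-wise logsumexp of a matrix
col_logsumexp <- function(A) {
  m <- apply(A, 2, max)
  fin <- is.finite(m)
  out <- m
  if (any(fin)) {
    out[fin] <- m[fin] +
      log(colSums(exp(sweep(A[, fin, drop = FALSE], 2, m[fin], `-`))))
  }
  out
}

#' Per-position base priors for trellis decoding
#'
#' Decoding accepts soft priors as an `(M + 1) x 4` matrix of per-template-
#' position base probabilities (stage `i` of an `M`-stage trellis covers
#' positions `i` and `i + 1`). State priors follow by the product rule: the
#' prior of state (b1, b2) at stage `i` is `prior[i, b1] * prior[i + 1, b2]`,
#' and the transition into a stage-`i + 1` state is weighted by the prior of
#' its second base at position `i + 2`. Uniform rows reproduce the
#' "all valid transitions equally likely" default.
#'
#' @param M Number of trellis stages.
#' @param base_priors Optional `(M + 1) x 4` matrix of priors (rows
#'   normalized); `NULL` for uniform.
#' @return An object of class `trellis_priors` with log-domain components.
#' @export
trellis_priors <- function(M, base_priors = NULL) {
  stopifnot(M >= 1)
  if (is.null(base_priors)) {
    base_priors <- matrix(0.25, M + 1L, 4L)
  }
  stopifnot(is.matrix(base_priors), nrow(base_priors) == M + 1L,
            ncol(base_priors) == 4L, all(base_priors >= 0))
  base_priors <- base_priors / rowSums(base_priors)
  lp <- log(base_priors)
  f <- state_first(1:16); s <- state_second(1:16)
  init <- lp[1L, f] + lp[2L, s]                    # stage-1 state log priors
  structure(list(M = M, log_base = lp, log_init = init,
                 first = f, second = s),
            class = "trellis_priors")
}

## log transition matrix into stage i+1 (16 x 16): -Inf off the valid mask,
## log prior of the successor's second base (position i + 2) on it.
## Rows are already normalized because each state's four successors cover the
## four possible second bases once and prior rows sum to one.
log_trans_into <- function(priors, stage_next) {
  pos <- stage_next + 1L
  lp <- if (pos <= nrow(priors$log_base)) priors$log_base[pos, ] else rep(log(0.25), 4)
  valid <- transition_mask()
  A <- matrix(-Inf, 16, 16)
  full <- matrix(lp[priors$second], 16, 16, byrow = TRUE)  # [k, l] = lp[second(l)]
  A[valid] <- full[valid]
  A
}

#' Forward-backward posterior decoding on the 16-state trellis
#'
#' Computes exact state and base posterior marginals from per-stage log
#' emission scores. All recursions run in the log domain; the backward pass
#' is initialized with a constant end-state weight so the posteriors agree
#' exactly with brute-force marginalization of the joint likelihood.
#'
#' @param emissions `M x 16` matrix of log emission densities (stage by state).
#' @param priors A [trellis_priors()] object for `M` stages, or `NULL` for
#'   uniform priors.
#' @return List of class `trellis_decode`: `state_post` (`M x 16`),
#'   `base_post` (`M x 4`, first-symbol marginals), `final_base_post`
#'   (length-4 marginal of position `M + 1` from the last stage's second
#'   symbol), `log_forward`, `log_backward`, `loglik`.
#' @export
forward_backward <- function(emissions, priors = NULL) {
  stopifnot(is.matrix(emissions), ncol(emissions) == 16)
  M <- nrow(emissions)
  if (is.null(priors)) priors <- trellis_priors(M)
  stopifnot(inherits(priors, "trellis_priors"), priors$M == M)
  if (any(!is.finite(apply(emissions, 1, max))))
    stop("decoding error: a stage has no finite emission score")
  f <- matrix(-Inf, M, 16)
  b <- matrix(0, M, 16)
  f[1, ] <- priors$log_init + emissions[1, ]
  if (M > 1) {
    for (i in seq_len(M - 1L)) {
      A <- log_trans_into(priors, i + 1L)
      f[i + 1L, ] <- emissions[i + 1L, ] + col_logsumexp(f[i, ] + A)
    }
    for (i in rev(seq_len(M - 1L))) {
      A <- log_trans_into(priors, i + 1L)
      ## b[i, k] = logsumexp_l A[k, l] + e[i+1, l] + b[i+1, l]
      B <- sweep(A, 2, emissions[i + 1L, ] + b[i + 1L, ], `+`)
      b[i, ] <- apply(B, 1, logsumexp)
    }
  }
  g <- f + b
  loglik <- logsumexp(f[M, ])
  post <- exp(sweep(g, 1, apply(g, 1, logsumexp), `-`))
  res <- list(state_post = post,
              base_post = base_posteriors(post),
              final_base_post = base_posteriors(post[M, , drop = FALSE],
                                                symbol = "second")[1, ],
              log_forward = f, log_backward = b, loglik = loglik)
  class(res) <- "trellis_decode"
  res
}

#' Collapse state posteriors to base posteriors
#'
#' The posterior of base `b` at position `i` is the sum of the four stage-`i`
#' state posteriors whose first (default) symbol is `b`.
#'
#' @param state_post `M x 16` matrix of normalized state posteriors.
#' @param symbol `"first"` (position `i` of stage `i`) or `"second"`
#'   (position `i + 1`).
#' @return `M x 4` matrix of base posteriors; rows sum to 1.
#' @export
base_posteriors <- function(state_post, symbol = c("first", "second")) {
  symbol <- match.arg(symbol)
  stopifnot(is.matrix(state_post), ncol(state_post) == 16)
  idx <- if (symbol == "first") state_first(1:16) else state_second(1:16)
  out <- matrix(0, nrow(state_post), 4)
  for (bb in 1:4) out[, bb] <- rowSums(state_post[, idx == bb, drop = FALSE])
  out
}

#' Viterbi decoding on the 16-state trellis
#'
#' Returns the valid state path maximizing the joint log score. Ties are
#' broken toward the lowest state index (stable, documented).
#'
#' @inheritParams forward_backward
#' @return List: `path` (length-`M` state indices), `bases` (length `M + 1`
#'   base indices spelled by the path), `logjoint`, and the max-message
#'   matrix `v` (`M x 16`).
#' @export
viterbi_path <- function(emissions, priors = NULL) {
  stopifnot(is.matrix(emissions), ncol(emissions) == 16)
  M <- nrow(emissions)
  if (is.null(priors)) priors <- trellis_priors(M)
  if (any(!is.finite(apply(emissions, 1, max))))
    stop("decoding error: a stage has no finite emission score")
  v <- matrix(-Inf, M, 16)
  bp <- matrix(0L, M, 16)
  v[1, ] <- priors$log_init + emissions[1, ]
  if (M > 1) {
    for (i in seq_len(M - 1L)) {
      A <- log_trans_into(priors, i + 1L)
      cand <- v[i, ] + A                       # 16 x 16: pred x succ
      bp[i + 1L, ] <- apply(cand, 2, which.max)  # lowest index on ties
      v[i + 1L, ] <- emissions[i + 1L, ] + cand[cbind(bp[i + 1L, ], 1:16)]
    }
  }
  path <- integer(M)
  path[M] <- which.max(v[M, ])
  if (M > 1) for (i in rev(seq_len(M - 1L))) path[i] <- bp[i + 1L, path[i + 1L]]
  list(path = path,
       bases = c(state_first(path), state_second(path[M])),
       logjoint = max(v[M, ]),
       v = v)
}

#' Soft-output Viterbi decoding (SOVA)
#'
#' The hard path is the Viterbi path. For each template position the four
#' base hypotheses are scored by the best-scoring path constrained to agree
#' with the optimal path outside a deviation of at most 3 trellis edges:
#' changing the base at position `i` requires replacing the states at stages
#' `i - 1` and `i`, which is exactly a 3-edge deviation, so the competitor
#' for each alternative base is unique and available in closed form from the
#' optimal path score and local emission/prior swaps. Path metrics are
#' normalized into posteriors by a softmax over the four hypotheses.
#'
#' @inheritParams forward_backward
#' @return List of class `trellis_decode`: `path`, `bases` (as in
#'   [viterbi_path()]), `base_post` (`M x 4` approximate posteriors over the
#'   first `M` positions), `final_base_post` (position `M + 1`), `logjoint`.
#' @export
sova <- function(emissions, priors = NULL) {
  M <- nrow(emissions)
  if (is.null(priors)) priors <- trellis_priors(M)
  vit <- viterbi_path(emissions, priors)
  path <- vit$path
  bases <- vit$bases
  lp <- priors$log_base
  lpb <- function(pos) if (pos <= nrow(lp)) lp[pos, ] else rep(log(0.25), 4)
  score <- matrix(-Inf, M + 1L, 4L)         # metric of best path with base b at pos
  for (i in seq_len(M + 1L)) score[i, bases[i]] <- vit$logjoint
  for (i in seq_len(M + 1L)) {
    for (b in setdiff(1:4, bases[i])) {
      if (i == 1L) {
        ## replace stage-1 state (b, bases[2]); only stage 1 changes
        k <- state_index(b, bases[2])
        delta <- (emissions[1, k] - emissions[1, path[1]]) +
          (lpb(1)[b] - lpb(1)[bases[1]])
      } else if (i == M + 1L) {
        ## final position: replace stage-M state (bases[M], b)
        k <- state_index(bases[M], b)
        delta <- (emissions[M, k] - emissions[M, path[M]]) +
          (lpb(M + 1L)[b] - lpb(M + 1L)[bases[M + 1L]])
      } else {
        ## replace stages i-1 and i: (bases[i-1], b) and (b, bases[i+1])
        k1 <- state_index(bases[i - 1L], b)
        k2 <- state_index(b, bases[i + 1L])
        e_old <- emissions[i - 1L, path[i - 1L]] + emissions[i, path[i]]
        e_new <- emissions[i - 1L, k1] + emissions[i, k2]
        delta <- (e_new - e_old) + (lpb(i)[b] - lpb(i)[bases[i]])
      }
      score[i, b] <- vit$logjoint + delta
    }
  }
  post <- exp(sweep(score, 1, apply(score, 1, logsumexp), `-`))
  res <- list(path = path, bases = bases,
              base_post = post[seq_len(M), , drop = FALSE],
              final_base_post = post[M + 1L, ],
              logjoint = vit$logjoint)
  class(res) <- "trellis_decode"
  res
}
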