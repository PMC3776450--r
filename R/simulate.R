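## Generative tile simulator: clonal-cluster signals under the comprehensive
## model (full strand-length profile, per-read decaying scale, crosstalk,
## leakage, signal-proportional Gaussian noise). The decoder deliberately uses
## the two-term finite-memory approximation instead, so simulation-based tests
## exercise the same model mismatch a sequencer would.

#' Default crosstalk matrix for simulations
#'
#' A diagonally dominant 4 x 4 mixing matrix with spectral overlap within the
#' A/C and G/T fluorophore pairs, the qualitative pattern of GA-class optics.
#' Columns are emitting bases (A, C, G, T), rows detection channels.
#'
#' @return 4 x 4 numeric matrix with unit diagonal.
#' @export
default_crosstalk <- function() {
  matrix(c(1.00, 0.35, 0.02, 0.01,
           0.22, 1.00, 0.01, 0.02,
           0.01, 0.02, 1.00, 0.30,
           0.02, 0.01, 0.42, 1.00),
         4, 4, byrow = FALSE,
         dimnames = list(BASES, BASES))
}

#' Simulation configuration
#'
#' Bundles every knob of the generative model. Defaults describe a moderate-
#' noise tile: small phasing, 1% pre-phasing, 3% droop, 5% scale
#' volatility, mild leakage and 15%-scale multiplicative channel noise —
#' together yielding overall error rates from a few tenths of a percent up
#' to a couple of percent over 36 cycles, the magnitude real sequencing
#' lanes show.
#'
#' @param reads Reads per tile.
#' @param cycles Number of observed cycles `N`.
#' @param p [phasing_params()].
#' @param K 4 x 4 crosstalk matrix applied to the generated signal.
#' @param Sigma 4 x 4 base covariance of the multiplicative noise
#'   (`cov(Y_i) = ||X_i||^2 Sigma`).
#' @param alpha Inter-cycle leakage scalar.
#' @param d Constant droop factor of the per-read scale process.
#' @param sigma_lambda Volatility of the scale process: the per-cycle scale
#'   follows `lambda_i | lambda_{i-1} ~ N((1-d) lambda_{i-1},
#'   (1-d)^2 lambda_{i-1}^2 sigma_lambda^2)`.
#' @param lambda_mean Mean initial per-read scale.
#' @param lambda_cv Coefficient of variation of the initial scale across reads.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(reads = 250, cycles = 36,
                       p = phasing_params(0.002, 0.01),
                       K = default_crosstalk(),
                       Sigma = diag(4) * 0.15^2,
                       alpha = 0.05,
                       d = 0.03,
                       sigma_lambda = 0.05,
                       lambda_mean = 1,
                       lambda_cv = 0.1,
                       seed = 1L) {
  stopifnot(inherits(p, "phasing_params"), reads >= 1, cycles >= 2,
            d >= 0, d < 1, sigma_lambda >= 0, lambda_mean > 0, lambda_cv >= 0)
  structure(list(reads = as.integer(reads), cycles = as.integer(cycles),
                 p = p, K = K, Sigma = Sigma, alpha = alpha, d = d,
                 sigma_lambda = sigma_lambda, lambda_mean = lambda_mean,
                 lambda_cv = lambda_cv, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d reads x %d cycles | p_ii=%g p_cf=%g ",
                     "d=%g alpha=%g sigma_lambda=%g seed=%d\n"),
              x$reads, x$cycles, x$p$p_ii, x$p$p_cf, x$d, x$alpha,
              x$sigma_lambda, x$seed))
  invisible(x)
}

#' Draw random template sequences
#'
#' @param reads Number of templates.
#' @param length Template length.
#' @param seed Optional seed; when supplied the draw is reproducible.
#' @return Character vector of `reads` uniform random A/C/G/T sequences.
#' @export
simulate_templates <- function(reads, length, seed = NULL) {
  stopifnot(reads >= 1, length >= 1)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(reads),
         function(i) paste(sample(BASES, length, replace = TRUE), collapse = ""),
         character(1))
}

## lambda trajectory: AR(1) decay with multiplicative Gaussian innovations,
## floored at 1e-6 to keep the scale positive.
simulate_lambda <- function(cfg, n) {
  lam <- numeric(n)
  lam[1] <- max(stats::rnorm(1, cfg$lambda_mean, cfg$lambda_cv * cfg$lambda_mean), 1e-6)
  for (i in seq_len(n)[-1]) {
    m <- (1 - cfg$d) * lam[i - 1]
    lam[i] <- max(stats::rnorm(1, m, abs(m) * cfg$sigma_lambda), 1e-6)
  }
  lam
}

#' Simulate one read's intensity matrix
#'
#' Generates `Y_i ~ N(K X_i + alpha Y_{i-1}, ||X_i||^2 Sigma)` where
#' `X_i = lambda_i * sum_j E[i, j] S_j` uses the full strand-length profile
#' (not the decoder's two-term approximation) and `lambda_i` follows the
#' decaying AR scale process.
#'
#' @param template Template sequence (character); must cover the phasing
#'   lookahead, i.e. be at least as long as `cfg$cycles` (it is padded with
#'   random bases if shorter).
#' @param cfg A [sim_config()]. The RNG state is used as-is; seed handling
#'   is the caller's (see [simulate_tile()]).
#' @param E Optional precomputed [phasing_profile()] for the template length.
#' @return List with `Y` (`cycles x 4` matrix), `lambda` (per-cycle realized
#'   scale) and `template` (possibly padded).
#' @export
simulate_read <- function(template, cfg, E = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  N <- cfg$cycles
  tpl <- dna_to_idx(template)
  if (length(tpl) < N + 2L) {
    tpl <- c(tpl, sample.int(4L, N + 2L - length(tpl), replace = TRUE))
  }
  L <- length(tpl)
  if (is.null(E)) E <- phasing_profile(transition_matrix(cfg$p, L), N)
  S <- matrix(0, 4, L)
  S[cbind(tpl, seq_len(L))] <- 1
  Z <- E %*% t(S)                       # N x 4 noiseless unit-scale signal
  lam <- simulate_lambda(cfg, N)
  X <- Z * lam                          # rows scaled by per-cycle lambda
  noisy <- any(cfg$Sigma != 0)
  ch <- if (noisy) chol(cfg$Sigma) else NULL
  Y <- matrix(0, N, 4)
  for (i in seq_len(N)) {
    mu <- as.numeric(cfg$K %*% X[i, ])
    if (i > 1) mu <- mu + cfg$alpha * Y[i - 1, ]
    Y[i, ] <- mu
    if (noisy) {
      sd_scale <- sqrt(sum(X[i, ]^2))
      Y[i, ] <- Y[i, ] + sd_scale * as.numeric(stats::rnorm(4) %*% ch)
    }
  }
  list(Y = Y, lambda = lam, template = idx_to_dna(tpl))
}

#' Simulate a full tile
#'
#' Draws templates of length `cycles + 10` (so phasing mass cannot run off
#' the template end within the observed cycles), simulates every read from a
#' single tile-seeded RNG stream, and optionally writes the intensity TSV and
#' a truth FASTA holding the first `cycles` bases of each template.
#'
#' @param cfg A [sim_config()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_int.txt` (intensity TSV) and `<prefix>_truth.fa`.
#' @return Invisible list of class `sim_tile`: `intensities` (list of
#'   `cycles x 4` matrices), `truth` (tibble: read id, template, true
#'   first-cycle lambda), `lambdas` (matrix reads x cycles), `meta`
#'   (tibble lane/tile/x/y), `config`, and any file paths written.
#' @export
simulate_tile <- function(cfg, out_prefix = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  N <- cfg$cycles
  L <- N + 10L
  templates <- simulate_templates(cfg$reads, L)
  E <- phasing_profile(transition_matrix(cfg$p, L), N)
  reads <- vector("list", cfg$reads)
  lambdas <- matrix(0, cfg$reads, N)
  for (r in seq_len(cfg$reads)) {
    sim <- simulate_read(templates[r], cfg, E = E)
    reads[[r]] <- sim$Y
    lambdas[r, ] <- sim$lambda
  }
  meta <- tibble::tibble(lane = 1L, tile = 1L,
                         x = seq_len(cfg$reads), y = rep(1L, cfg$reads))
  truth <- tibble::tibble(read = read_ids(meta),
                          template = substr(templates, 1L, N),
                          lambda1 = lambdas[, 1])
  out <- list(intensities = reads, truth = truth, lambdas = lambdas,
              templates_full = templates, meta = meta, config = cfg)
  if (!is.null(out_prefix)) {
    int_path <- paste0(out_prefix, "_int.txt")
    fa_path <- paste0(out_prefix, "_truth.fa")
    write_intensities(reads, meta, int_path)
    writeLines(as.character(rbind(paste0(">", truth$read), truth$template)), fa_path)
    out$int_path <- int_path
    out$truth_path <- fa_path
  }
  class(out) <- "sim_tile"
  invisible(out)
}

#' @export
print.sim_tile <- function(x, ...) {
  cat(sprintf("<sim_tile> %d reads x %d cycles (seed %d)\n",
              length(x$intensities), x$config$cycles, x$config$seed))
  invisible(x)
}

read_ids <- function(meta) {
  paste(meta$lane, meta$tile, meta$x, meta$y, sep = "_")
}

#' Fit object implied by a simulation's true parameters
#'
#' Converts a [sim_config()] into the windowed parameter set a perfectly
#' informed caller would use: the true crosstalk, leakage and droop, the
#' per-window pre-phasing mixing implied by the full strand-length profile
#' (lead-mass fraction of the two retained terms), and the true base
#' covariance floored to the positive-definite cone. Useful for decoding
#' simulated tiles with known parameters and for regression tests.
#'
#' @param cfg A [sim_config()].
#' @param W Window length (default 6).
#' @param pad Extra decoded cycles per window (default 5).
#' @return A `softcall_fit`.
#' @export
sim_params_fit <- function(cfg, W = 6, pad = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  N <- cfg$cycles
  sched <- window_schedule(N, W)
  L <- N + 10L
  E <- phasing_profile(transition_matrix(cfg$p, L), N)
  beta_cyc <- vapply(seq_len(N), function(i)
    E[i, i + 1L] / (E[i, i] + E[i, i + 1L]), numeric(1))
  Sig <- psd_floor(cfg$Sigma, 1e-8)
  params <- lapply(seq_len(nrow(sched)), function(l)
    list(K = cfg$K, Sigma = Sig, alpha = cfg$alpha,
         beta = mean(beta_cyc[sched$start[l]:sched$end[l]])))
  fit <- list(schedule = sched, params = params,
              dbar = c(0, rep(cfg$d, N - 1L)),
              lambda_hat = numeric(0), scale = 1,
              trace = tibble::tibble(window = integer(0),
                                     iteration = integer(0),
                                     objective = numeric(0)),
              W = W, pad = pad, decoder = "fb", cycles = N,
              train_ids = character(0))
  class(fit) <- "softcall_fit"
  fit
}
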