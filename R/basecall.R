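## Tile-level calling pipeline: intensity TSV dialect, Bustard-style baseline
## (crosstalk inversion, droop renormalization, phasing-profile pseudo-inverse,
## per-cycle argmax), windowed model-based calling via forward-backward or
## SOVA, and Phred+33 FASTQ output.

#' Read an intensity file
#'
#' The intensity dialect is a tab-separated table with a header row:
#' columns `lane`, `tile`, `x`, `y`, then `4 * N` intensity columns in
#' cycle-major channel order `A1, C1, G1, T1, A2, ...`.
#'
#' @param path Path to the TSV file.
#' @return An object of class `intensity_set`: `intensities` (list of
#'   `N x 4` matrices, one per read) and `meta` (tibble lane/tile/x/y).
#' @export
read_intensities <- function(path) {
  if (!file.exists(path)) stop("intensity file not found: ", path)
  df <- tryCatch(
    suppressWarnings(                      # malformed fields surface below, by row
      readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE)),
    error = function(e) stop("intensity parse error: ", conditionMessage(e)))
  need <- c("lane", "tile", "x", "y")
  if (!all(need %in% names(df))) stop("intensity file missing metadata columns")
  vals <- as.matrix(df[setdiff(names(df), need)])
  if (ncol(vals) %% 4 != 0) stop("intensity file must have 4*N value columns")
  bad <- which(!stats::complete.cases(vals) | rowSums(!is.finite(vals)) > 0)
  if (length(bad)) stop("intensity parse error: non-finite values at row ", bad[1])
  N <- ncol(vals) %/% 4
  ints <- lapply(seq_len(nrow(vals)), function(r)
    matrix(vals[r, ], nrow = N, ncol = 4, byrow = TRUE))
  structure(list(intensities = ints,
                 meta = tibble::tibble(lane = as.integer(df$lane),
                                       tile = as.integer(df$tile),
                                       x = as.integer(df$x),
                                       y = as.integer(df$y))),
            class = "intensity_set")
}

#' Write an intensity file
#'
#' @param intensities List of `N x 4` intensity matrices.
#' @param meta Tibble with columns lane, tile, x, y (one row per read).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intensities <- function(intensities, meta, path) {
  stopifnot(length(intensities) == nrow(meta))
  N <- nrow(intensities[[1]])
  vals <- t(vapply(intensities, function(Y) as.numeric(t(Y)), numeric(4L * N)))
  colnames(vals) <- paste0(rep(BASES, N), rep(seq_len(N), each = 4))
  df <- dplyr::bind_cols(meta, tibble::as_tibble(vals))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

as_intensity_set <- function(x) {
  if (inherits(x, "intensity_set")) return(x)
  if (inherits(x, "sim_tile"))
    return(structure(list(intensities = x$intensities, meta = x$meta),
                     class = "intensity_set"))
  if (is.list(x) && !is.null(x$intensities) && !is.null(x$meta))
    return(structure(x[c("intensities", "meta")], class = "intensity_set"))
  if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
    meta <- tibble::tibble(lane = 1L, tile = 1L, x = seq_along(x),
                           y = rep(1L, length(x)))
    return(structure(list(intensities = x, meta = meta), class = "intensity_set"))
  }
  stop("cannot interpret input as an intensity set")
}

#' @export
print.intensity_set <- function(x, ...) {
  cat(sprintf("<intensity_set> %d reads x %d cycles\n",
              length(x$intensities), nrow(x$intensities[[1]])))
  invisible(x)
}

#' Bustard-style baseline base calling
#'
#' Reproduces the classical matrix-inversion pipeline: (1) crosstalk is
#' estimated from the first two cycles ([init_crosstalk()]) and inverted onto
#' the observations; (2) the tile-average total signal per cycle renormalizes
#' the per-cycle scale (droop correction); (3) a strand-length profile is
#' fitted from the leakage pattern of the first 12 cycles and its
#' pseudo-inverse applied (phasing correction; the fitting rule is a
#' least-squares stand-in for an unpublished procedure); (4) each cycle's
#' base is the argmax channel. Qualities are flat (this caller produces no
#' posteriors).
#'
#' @param x An `intensity_set`, `sim_tile`, or list of intensity matrices.
#' @return A calls tibble of class `softcall_calls` (see [call_tile()]);
#'   `qual` is `NA` for this decoder.
#' @export
bustard_call <- function(x) {
  xs <- as_intensity_set(x)
  reads <- xs$intensities
  if (length(reads) < 10) stop("need at least 10 reads to estimate crosstalk")
  N <- nrow(reads[[1]])
  K <- init_crosstalk(reads)
  Kinv <- solve(K)
  X <- lapply(reads, function(Y) Y %*% t(Kinv))
  ## droop renormalization: tile-average total signal per cycle
  tot <- Reduce(`+`, lapply(X, function(Z) pmax(rowSums(Z), 0)))
  scale <- ifelse(tot > 0, tot[1] / tot, 1)
  X <- lapply(X, function(Z) Z * scale)
  ## phasing correction from the first 12 cycles' leakage pattern
  p_hat <- estimate_phasing_rates(X, n_cycles = min(12L, N))
  Emat <- phasing_profile(transition_matrix(p_hat, N), N)
  S_hat <- tryCatch({
    Epinv <- solve(crossprod(Emat), t(Emat))   # pseudo-inverse (E'E)^-1 E'
    lapply(X, function(Z) Epinv %*% Z)
  }, error = function(e) {
    warning("singular phasing profile; skipping phasing correction")
    X
  })
  calls <- lapply(S_hat, function(Z) max.col(Z, ties.method = "first"))
  build_calls(calls, qual = NULL, meta = xs$meta, decoder = "bustard")
}

## estimate (p_ii, p_cf) from lead/lag leakage growth over early cycles:
## the signal fraction on the next (previous) base's channel grows roughly
## linearly in the cycle index with slope p_cf (p_ii); fit both by least
## squares through the origin on per-cycle median fractions.
estimate_phasing_rates <- function(X, n_cycles = 12L) {
  calls <- lapply(X, function(Z) max.col(Z[seq_len(n_cycles), , drop = FALSE],
                                         ties.method = "first"))
  lead_fr <- matrix(NA_real_, length(X), n_cycles - 1L)
  lag_fr <- matrix(NA_real_, length(X), n_cycles - 1L)
  for (r in seq_along(X)) {
    Z <- X[[r]]; cl <- calls[[r]]
    for (i in seq_len(n_cycles - 1L)) {
      own <- Z[i, cl[i]]
      nxt <- cl[i + 1L]
      if (nxt != cl[i] && own > 0) {
        lead_fr[r, i] <- max(Z[i, nxt], 0) / (max(Z[i, nxt], 0) + own)
      }
      if (i > 1 && cl[i - 1L] != cl[i] && own > 0) {
        prv <- cl[i - 1L]
        lag_fr[r, i] <- max(Z[i, prv], 0) / (max(Z[i, prv], 0) + own)
      }
    }
  }
  med_lead <- apply(lead_fr, 2, stats::median, na.rm = TRUE)
  med_lag <- apply(lag_fr, 2, stats::median, na.rm = TRUE)
  fit_slope <- function(y) {
    i <- seq_along(y)
    ok <- is.finite(y)
    if (sum(ok) < 2) return(0)
    max(sum(i[ok] * y[ok]) / sum(i[ok]^2), 0)
  }
  ## baseline channel bleed (crosstalk residue) inflates both fractions at
  ## every cycle equally; the slope isolates the phasing-driven growth
  p_cf <- min(fit_slope(med_lead), 0.2)
  p_ii <- min(fit_slope(med_lag), 0.2)
  phasing_params(p_ii, p_cf)
}

build_calls <- function(bases_list, qual, meta, decoder) {
  N <- length(bases_list[[1]])
  ids <- read_ids(meta)
  out <- tibble::tibble(
    read = rep(ids, each = N),
    cycle = rep(seq_len(N), times = length(bases_list)),
    base = BASES[unlist(bases_list)],
    qual = if (is.null(qual)) NA_real_ else
      pmin(pmax(unlist(qual), 1e-12), 1))  # guard numerical 1 +/- eps
  out$phred <- if (is.null(qual)) NA_integer_ else posterior_to_phred(out$qual)
  attr(out, "decoder") <- decoder
  class(out) <- c("softcall_calls", class(out))
  out
}

#' Call one read with the windowed trellis model
#'
#' Calls a read window by window: for window `l` the per-read scale is the
#' positive root of the scale quadratic ([estimate_lambda()]) assembled from
#' the previous window's calls and parameters (window 1 bootstraps from the
#' supplied baseline calls); emissions are built over the window plus 5
#' padding cycles (truncated at the read end) and decoded by forward-backward
#' or SOVA; the argmax posterior per cycle is the call and the posterior
#' itself the quality.
#'
#' @param Y `N x 4` intensity matrix (already on the fit's intensity scale).
#' @param fit A `softcall_fit` from [train_basecaller()].
#' @param boot_bases Integer base indices (length `>=` first window end) used
#'   to bootstrap the window-1 scale; typically Bustard calls.
#' @param decoder `"fb"` or `"sova"`.
#' @param priors Optional `(N + 1) x 4` base-prior matrix.
#' @return List: `bases` (integer indices), `qual` (posterior of the called
#'   base per cycle), `lambda` (per-window scale estimates).
#' @export
call_read <- function(Y, fit, boot_bases, decoder = c("fb", "sova"),
                      priors = NULL) {
  decoder <- match.arg(decoder)
  N <- nrow(Y)
  sched <- fit$schedule
  calls <- integer(N)
  qual <- numeric(N)
  lam_by_win <- numeric(nrow(sched))
  dprod_all <- cumprod(1 - fit$dbar)      # D_i for i = 1..N (dbar[1] == 0)
  prev_bases <- boot_bases
  for (l in seq_len(nrow(sched))) {
    th <- fit$params[[l]]
    st <- sched$start[l]; en <- sched$end[l]
    lam_win <- if (l == 1L) {
      estimate_lambda(Y, prev_bases, fit$params[[1]], cycles = st:en,
                      dprod = dprod_all[st:en])
    } else {
      ps <- sched$start[l - 1L]; pe <- sched$end[l - 1L]
      estimate_lambda(Y, calls, fit$params[[l - 1L]], cycles = ps:pe,
                      dprod = dprod_all[ps:pe])
    }
    lam_by_win[l] <- lam_win
    span <- st:min(en + fit$pad, N)
    em <- emission_matrix(Y, span, lam_win, th$K, th$Sigma, th$alpha,
                          th$beta, dprod_all[span])
    pr <- if (is.null(priors)) NULL else
      trellis_priors(length(span), priors[span[1]:(span[length(span)] + 1L), ,
                                          drop = FALSE])
    dec <- if (decoder == "fb") forward_backward(em, pr) else sova(em, pr)
    keep <- seq_len(en - st + 1L)
    bp <- dec$base_post[keep, , drop = FALSE]
    calls[st:en] <- max.col(bp, ties.method = "first")
    qual[st:en] <- bp[cbind(seq_len(nrow(bp)), calls[st:en])]
  }
  list(bases = calls, qual = qual, lambda = lam_by_win)
}

#' Call every read of a tile
#'
#' Runs the full model-based pipeline over a tile: Bustard baseline calls
#' (for window-1 scale bootstrap), then per-read windowed decoding with the
#' fitted parameters.
#'
#' @param x An `intensity_set`, `sim_tile`, or list of intensity matrices.
#' @param fit A `softcall_fit` from [train_basecaller()].
#' @param decoder `"fb"` (forward-backward posteriors), `"sova"`, or
#'   `"bustard"` (baseline only).
#' @return Tibble of class `softcall_calls` with one row per (read, cycle):
#'   columns `read`, `cycle`, `base`, `qual` (posterior of the call), `phred`.
#' @export
call_tile <- function(x, fit = NULL, decoder = c("fb", "sova", "bustard")) {
  decoder <- match.arg(decoder)
  xs <- as_intensity_set(x)
  if (decoder == "bustard") return(bustard_call(xs))
  if (is.null(fit)) stop("model-based decoding requires a fit; see train_basecaller()")
  boot <- bustard_call(xs)
  N <- nrow(xs$intensities[[1]])
  boot_idx <- split(match(boot$base, BASES), rep(seq_along(xs$intensities), each = N))
  bases_list <- vector("list", length(xs$intensities))
  qual_list <- vector("list", length(xs$intensities))
  for (r in seq_along(xs$intensities)) {
    res <- call_read(xs$intensities[[r]] / fit$scale, fit, boot_idx[[r]], decoder)
    bases_list[[r]] <- res$bases
    qual_list[[r]] <- res$qual
  }
  build_calls(bases_list, qual_list, xs$meta, decoder)
}

#' Map a posterior probability to a Phred score
#'
#' `Q = round(-10 log10(max(1 - p, 1e-4)))`, capped to `[0, 40]`; a posterior
#' of exactly 1 therefore maps to the cap.
#'
#' @param p Posterior probabilities in `(0, 1]` (vectorized).
#' @return Integer Phred scores.
#' @export
#' @examples
#' posterior_to_phred(c(0.9, 1, 0.25))  # 10 40 1
posterior_to_phred <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("posterior must be in (0, 1]")
  q <- as.integer(round(-10 * log10(pmax(1 - p, 1e-4))))
  pmin(pmax(q, 0L), 40L)
}

#' Write calls to a FASTQ file
#'
#' Standard 4-line records, Phred+33 qualities, read ids `lane_tile_x_y`.
#' Bustard calls (no posteriors) are written with a flat quality of 2.
#'
#' @param calls A `softcall_calls` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(calls, path) {
  byread <- split(calls, factor(calls$read, levels = unique(calls$read)))
  seqs <- vapply(byread, function(d) paste(d$base[order(d$cycle)], collapse = ""),
                 character(1))
  quals <- vapply(byread, function(d) {
    q <- d$phred[order(d$cycle)]
    q[is.na(q)] <- 2L
    intToUtf8(q + 33L)
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(byread)
  qsd <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
  ## Biostrings warns about dropping (empty) metadata columns; that is noise
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(qsd, path))
  invisible(path)
}

#' Read a FASTQ file of calls
#'
#' @param path FASTQ path (Phred+33).
#' @return Tibble with columns `read`, `cycle`, `base`, `phred`.
#' @export
read_fastq <- function(path) {
  ## Biostrings warns about dropping (empty) metadata columns; that is noise
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  seqs <- as.character(qs)
  quals <- suppressWarnings(as.character(Biostrings::quality(qs)))
  purrr::map2_dfr(seq_along(seqs), names(qs), function(i, id) {
    b <- strsplit(seqs[i], "")[[1]]
    q <- utf8ToInt(quals[i]) - 33L
    tibble::tibble(read = id, cycle = seq_along(b), base = b, phred = q)
  })
}
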