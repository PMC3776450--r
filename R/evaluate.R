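## Scoring calls against a reference or simulation truth: exhaustive
## Hamming-distance alignment with a 30% retention rule, per-cycle and
## overall error rates, and quality-score discrimination ability.

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## mismatch counts of `read` against every window of `ref` (integer vectors)
hamming_profile <- function(readI, refI) {
  L <- length(readI); G <- length(refI)
  n_off <- G - L + 1L
  if (n_off < 1) return(integer(0))
  mm <- rep(L, n_off)
  base_off <- 0:(n_off - 1L)
  match_sum <- integer(n_off)
  for (j in seq_len(L)) {
    match_sum <- match_sum + (refI[base_off + j] == readI[j])
  }
  L - match_sum
}

#' Exhaustive Hamming alignment of a read to a reference
#'
#' Minimizes the mismatch count over every offset of the reference and both
#' strands (the reverse strand compares the reverse complement of the read).
#' A read is retained when its best mismatch fraction is below 30%. Ties are
#' broken toward the forward strand, then the smallest offset.
#'
#' @param read Called sequence (character, A/C/G/T).
#' @param reference Reference sequence (character).
#' @param circular Treat the reference as circular (extends it by
#'   `nchar(read) - 1` leading bases so wrap-around offsets are scored).
#' @return One-row tibble: `offset` (1-based reference start), `strand`
#'   (`"+"` or `"-"`), `mismatches`, `retained`.
#' @export
align_hamming <- function(read, reference, circular = FALSE) {
  if (!nzchar(read) || !nzchar(reference)) stop("empty read or reference")
  L <- nchar(read)
  ref_ext <- if (circular) paste0(reference, substr(reference, 1L, L - 1L)) else reference
  if (L > nchar(ref_ext)) stop("read longer than (extended) reference")
  refI <- dna_to_idx(ref_ext)
  fwd <- hamming_profile(dna_to_idx(read), refI)
  rev <- hamming_profile(dna_to_idx(revcomp(read)), refI)
  best_f <- min(fwd); best_r <- min(rev)
  if (best_f <= best_r) {
    off <- which.min(fwd); strand <- "+"; mm <- best_f
  } else {
    off <- which.min(rev); strand <- "-"; mm <- best_r
  }
  tibble::tibble(offset = as.integer(off), strand = strand,
                 mismatches = as.integer(mm),
                 retained = mm / L < 0.30)
}

#' Error rates of a call set
#'
#' Compares calls with either the known simulation truth or an alignment to
#' a reference, over retained reads only (mismatch fraction below 30%).
#'
#' @param calls A `softcall_calls` tibble (or any tibble with `read`,
#'   `cycle`, `base`).
#' @param truth Named character vector of true templates (names = read ids),
#'   or a tibble with columns `read` and `template` (e.g. `sim_tile$truth`).
#'   Mutually exclusive with `reference`.
#' @param reference Reference sequence for alignment-based scoring.
#' @param circular Passed to [align_hamming()] in alignment mode.
#' @return List of class `error_report`: `by_cycle` tibble
#'   (`cycle`, `errors`, `bases`, `rate`), `overall`, `n_bases`,
#'   `n_reads`, `n_retained`, and `per_read` tibble with per-read error
#'   counts and retention flags.
#' @export
error_rates <- function(calls, truth = NULL, reference = NULL, circular = FALSE) {
  if (is.null(truth) == is.null(reference))
    stop("supply exactly one of truth or reference")
  byread <- split(calls, factor(calls$read, levels = unique(calls$read)))
  seqs <- vapply(byread, function(d) paste(d$base[order(d$cycle)], collapse = ""),
                 character(1))
  if (!is.null(truth)) {
    if (is.data.frame(truth)) truth <- stats::setNames(truth$template, truth$read)
    tpl <- truth[names(seqs)]
    if (anyNA(tpl)) stop("truth missing for some reads")
  } else {
    al <- lapply(seqs, align_hamming, reference = reference, circular = circular)
    tpl <- vapply(seq_along(seqs), function(i) {
      a <- al[[i]]
      L <- nchar(seqs[i])
      ref_ext <- if (circular) paste0(reference, substr(reference, 1L, L - 1L)) else reference
      seg <- substr(ref_ext, a$offset, a$offset + L - 1L)
      if (a$strand == "-") revcomp(seg) else seg
    }, character(1))
  }
  N <- nchar(seqs[[1]])
  err_mat <- t(vapply(seq_along(seqs), function(i) {
    unname(strsplit(seqs[i], "")[[1]] != strsplit(tpl[[i]], "")[[1]])
  }, logical(N)))
  dimnames(err_mat) <- NULL
  per_read <- tibble::tibble(read = names(seqs),
                             errors = rowSums(err_mat),
                             retained = rowSums(err_mat) / N < 0.30)
  keep <- per_read$retained
  if (!any(keep)) stop("no reads retained at the 30% error threshold")
  by_cycle <- tibble::tibble(
    cycle = seq_len(N),
    errors = unname(colSums(err_mat[keep, , drop = FALSE])),
    bases = sum(keep))
  by_cycle$rate <- by_cycle$errors / by_cycle$bases
  res <- list(by_cycle = by_cycle,
              overall = unname(sum(by_cycle$errors) / (sum(keep) * N)),
              n_bases = sum(keep) * N,
              n_reads = length(seqs),
              n_retained = sum(keep),
              per_read = per_read,
              err_mat = err_mat[keep, , drop = FALSE],
              retained_reads = names(seqs)[keep])
  class(res) <- "error_report"
  res
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %d/%d reads retained, %d bases, overall error %.4f\n",
              x$n_retained, x$n_reads, x$n_bases, x$overall))
  invisible(x)
}

#' Discrimination ability of quality scores
#'
#' Sorts bases by quality in descending order (stable, so ties keep their
#' original order) and returns the largest prefix length whose cumulative
#' error rate does not exceed the threshold.
#'
#' @param qualities Numeric quality scores (higher = more confident).
#' @param correct Logical; whether each base call was correct.
#' @param threshold Error-rate threshold in (0, 1).
#' @return Integer count of bases callable at the threshold.
#' @export
discrimination_ability <- function(qualities, correct, threshold) {
  stopifnot(length(qualities) == length(correct),
            threshold > 0, threshold < 1)
  ord <- order(-qualities)           # stable: original order breaks ties
  cum_err <- cumsum(!correct[ord]) / seq_along(ord)
  ok <- which(cum_err <= threshold)
  if (length(ok) == 0) 0L else max(ok)
}

#' Quality calibration table
#'
#' Bins bases by predicted error probability (1 - posterior) and tabulates
#' the empirical error rate per bin; a calibrated caller yields a monotone
#' relationship.
#'
#' @param qual Posterior of the called base per position.
#' @param correct Logical correctness per position.
#' @param n_bins Number of quantile bins.
#' @return Tibble: `bin`, `predicted_error`, `empirical_error`, `n`.
#' @export
quality_calibration <- function(qual, correct, n_bins = 5) {
  pred <- 1 - qual
  br <- unique(stats::quantile(pred, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(pred, breaks = br, include.lowest = TRUE)
  tibble::tibble(pred = pred, correct = correct, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(predicted_error = mean(.data$pred),
                     empirical_error = mean(!.data$correct),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$predicted_error)
}

#' Reference-supervised per-position base priors
#'
#' Aligns baseline calls to a reference ([align_hamming()]) and derives, for
#' each retained read, per-position prior probabilities: a call agreeing
#' with the reference gets a point mass; on a mismatch the mass is split
#' between the reference base (`trust`) and the called base (`1 - trust`).
#' The position one past the read end (needed by the trellis lookahead)
#' takes the reference base. Unmapped reads get uniform priors with a
#' warning. State priors follow by the product rule inside the decoder.
#'
#' @param calls A `softcall_calls` tibble of baseline calls.
#' @param reference Reference sequence (character).
#' @param circular Treat the reference as circular.
#' @param trust Prior mass on the reference base at a mismatch (default 0.5).
#' @return Named list (by read id) of `(N + 1) x 4` prior matrices.
#' @export
supervised_priors <- function(calls, reference, circular = FALSE, trust = 0.5) {
  stopifnot(trust >= 0, trust <= 1)
  byread <- split(calls, factor(calls$read, levels = unique(calls$read)))
  n_unmapped <- 0L
  out <- lapply(byread, function(d) {
    d <- d[order(d$cycle), ]
    seq <- paste(d$base, collapse = "")
    N <- nchar(seq)
    P <- matrix(0.25, N + 1L, 4L)
    al <- align_hamming(seq, reference, circular)
    if (!al$retained) { n_unmapped <<- n_unmapped + 1L; return(P) }
    ref_ext <- if (circular) paste0(reference, substr(reference, 1L, N)) else reference
    refI <- dna_to_idx(ref_ext)
    ## reference base implied at each read position (NA when off the end)
    segI <- rep(NA_integer_, N + 1L)
    for (i in seq_len(N + 1L)) {
      pos <- if (al$strand == "+") al$offset + i - 1L else al$offset + N - i
      if (pos >= 1L && pos <= length(refI)) {
        segI[i] <- if (al$strand == "+") refI[pos] else 5L - refI[pos]
      }
    }
    callI <- dna_to_idx(seq)
    for (i in seq_len(N)) {
      if (is.na(segI[i])) next
      P[i, ] <- 0
      if (segI[i] == callI[i]) {
        P[i, callI[i]] <- 1
      } else {
        P[i, segI[i]] <- P[i, segI[i]] + trust
        P[i, callI[i]] <- P[i, callI[i]] + (1 - trust)
      }
    }
    if (!is.na(segI[N + 1L])) {
      P[N + 1L, ] <- 0
      P[N + 1L, segI[N + 1L]] <- 1
    }
    P
  })
  if (n_unmapped > 0)
    warning(n_unmapped, " read(s) not retained by the aligner; using uniform priors")
  out
}
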