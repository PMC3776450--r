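## broom-style accessors and ggplot2 displays for fits, call sets and
## error reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted base-calling model
#'
#' @param x A `softcall_fit`.
#' @param ... Unused.
#' @return Tibble with one row per window: `window`, `start`, `end`,
#'   `alpha`, `beta`, `droop_mean` (mean droop factor over the window's
#'   cycles), and `k_offdiag` (mean absolute off-diagonal of the
#'   column-normalized crosstalk estimate).
#' @method tidy softcall_fit
#' @export
tidy.softcall_fit <- function(x, ...) {
  sched <- x$schedule
  tibble::tibble(
    window = sched$window,
    start = sched$start,
    end = sched$end,
    alpha = vapply(x$params, `[[`, numeric(1), "alpha"),
    beta = vapply(x$params, `[[`, numeric(1), "beta"),
    droop_mean = vapply(seq_len(nrow(sched)), function(l)
      mean(x$dbar[max(sched$start[l], 2L):sched$end[l]]), numeric(1)),
    k_offdiag = vapply(x$params, function(p) {
      Kn <- normalize_crosstalk(p$K)
      mean(abs(Kn[row(Kn) != col(Kn)]))
    }, numeric(1)))
}

#' Model-level summary of a fit
#'
#' @param x A `softcall_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_windows`, `n_cycles`, `n_train`, `scale`,
#'   `objective` (final EM objective), `lambda_median`.
#' @method glance softcall_fit
#' @export
glance.softcall_fit <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$schedule),
    n_cycles = x$cycles,
    n_train = length(x$lambda_hat),
    scale = x$scale,
    objective = x$trace$objective[nrow(x$trace)],
    lambda_median = stats::median(x$lambda_hat))
}

#' Tidy an error report
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @return The per-cycle tibble (`cycle`, `errors`, `bases`, `rate`).
#' @method tidy error_report
#' @export
tidy.error_report <- function(x, ...) x$by_cycle

#' Summary row of an error report
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @return One-row tibble: `overall`, `n_bases`, `n_reads`, `n_retained`.
#' @method glance error_report
#' @export
glance.error_report <- function(x, ...) {
  tibble::tibble(overall = x$overall, n_bases = x$n_bases,
                 n_reads = x$n_reads, n_retained = x$n_retained)
}

#' Plot per-cycle error rates
#'
#' @param object An `error_report` (or a named list of them, one line each).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object, ...) {
  df <- tidy.error_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "cycle", y = "error rate") +
    ggplot2::theme_minimal()
}

#' Compare per-cycle error rates of several call sets
#'
#' @param reports Named list of `error_report` objects.
#' @return A ggplot object with one line per report.
#' @export
plot_error_by_cycle <- function(reports) {
  stopifnot(is.list(reports), !is.null(names(reports)))
  df <- purrr::imap_dfr(reports, function(r, nm)
    dplyr::mutate(tidy.error_report(r), decoder = nm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$rate,
                                   colour = .data$decoder)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "error rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the EM objective trace of a fit
#'
#' @param object A `softcall_fit`.
#' @param ... Unused.
#' @return A ggplot object (objective by EM iteration, faceted by window).
#' @method autoplot softcall_fit
#' @export
autoplot.softcall_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~window, scales = "free_y") +
    ggplot2::labs(x = "EM iteration", y = "objective") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
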