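## Flat key-value serialization of a fitted parameter set, for reuse and
## inspection. One `key value` pair per line; matrices are comma-separated
## in column-major order.

fmt_vec <- function(x) paste(format(x, digits = 17, scientific = TRUE,
                                    trim = TRUE), collapse = ",")
parse_vec <- function(s) as.numeric(strsplit(s, ",")[[1]])

#' Write fitted parameters to a text file
#'
#' @param fit A `softcall_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_params()]
#' @export
write_params <- function(fit, path) {
  stopifnot(inherits(fit, "softcall_fit"))
  ln <- c(
    paste("cycles", fit$cycles),
    paste("W", fit$W),
    paste("pad", fit$pad),
    paste("decoder", fit$decoder),
    paste("scale", fmt_vec(fit$scale)),
    paste("dbar", fmt_vec(fit$dbar)),
    paste("n_windows", nrow(fit$schedule)))
  for (l in seq_len(nrow(fit$schedule))) {
    p <- fit$params[[l]]
    pre <- sprintf("window.%d.", l)
    ln <- c(ln,
            paste0(pre, "start ", fit$schedule$start[l]),
            paste0(pre, "end ", fit$schedule$end[l]),
            paste0(pre, "opt_end ", fit$schedule$opt_end[l]),
            paste0(pre, "alpha ", fmt_vec(p$alpha)),
            paste0(pre, "beta ", fmt_vec(p$beta)),
            paste0(pre, "K ", fmt_vec(as.numeric(p$K))),
            paste0(pre, "Sigma ", fmt_vec(as.numeric(p$Sigma))))
  }
  ln <- c(ln,
          paste("lambda_ids", paste(names(fit$lambda_hat), collapse = ",")),
          paste("lambda_hat", fmt_vec(unname(fit$lambda_hat))))
  writeLines(ln, path)
  invisible(path)
}

#' Read fitted parameters from a text file
#'
#' @param path Path written by [write_params()].
#' @return A `softcall_fit` (without the EM trace).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ln <- readLines(path)
  kv <- regmatches(ln, regexpr(" ", ln), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  get <- function(k) vals[match(k, keys)]
  nw <- as.integer(get("n_windows"))
  params <- vector("list", nw)
  sched <- tibble::tibble(window = seq_len(nw),
                          start = integer(nw), end = integer(nw),
                          opt_end = integer(nw))
  for (l in seq_len(nw)) {
    pre <- sprintf("window.%d.", l)
    sched$start[l] <- as.integer(get(paste0(pre, "start")))
    sched$end[l] <- as.integer(get(paste0(pre, "end")))
    sched$opt_end[l] <- as.integer(get(paste0(pre, "opt_end")))
    params[[l]] <- list(
      K = matrix(parse_vec(get(paste0(pre, "K"))), 4, 4),
      Sigma = matrix(parse_vec(get(paste0(pre, "Sigma"))), 4, 4),
      alpha = parse_vec(get(paste0(pre, "alpha"))),
      beta = parse_vec(get(paste0(pre, "beta"))))
  }
  lam <- parse_vec(get("lambda_hat"))
  names(lam) <- strsplit(get("lambda_ids"), ",")[[1]]
  fit <- list(schedule = sched, params = params,
              dbar = parse_vec(get("dbar")),
              lambda_hat = lam,
              scale = parse_vec(get("scale")),
              trace = tibble::tibble(window = integer(0), iteration = integer(0),
                                     objective = numeric(0)),
              W = as.integer(get("W")), pad = as.integer(get("pad")),
              decoder = get("decoder"), cycles = as.integer(get("cycles")),
              train_ids = names(lam))
  class(fit) <- "softcall_fit"
  fit
}
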