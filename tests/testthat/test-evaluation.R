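test_that("hamming alignment finds planted segments on both strands", {
  set.seed(61)
  ref <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  seg <- substr(ref, 1234, 1269)
  al <- align_hamming(seg, ref)
  expect_equal(al$offset, 1234L)
  expect_equal(al$strand, "+")
  expect_equal(al$mismatches, 0L)
  expect_true(al$retained)
  al_rc <- align_hamming(softcall:::revcomp(seg), ref)
  expect_equal(al_rc$strand, "-")
  expect_equal(al_rc$offset, 1234L)
  expect_equal(al_rc$mismatches, 0L)
  expect_error(align_hamming("", ref), "empty")
})

test_that("hamming alignment equals an exhaustive-offset oracle", {
  set.seed(62)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  refI <- softcall:::dna_to_idx(ref)
  for (t in 1:10) {
    read <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    al <- align_hamming(read, ref)
    ## oracle: plain double loop over offsets and strands
    best <- Inf
    for (strand in c("+", "-")) {
      rI <- softcall:::dna_to_idx(if (strand == "+") read else softcall:::revcomp(read))
      for (o in 1:(300 - 30 + 1)) {
        mm <- sum(refI[o:(o + 29)] != rI)
        if (mm < best) best <- mm
      }
    }
    expect_equal(al$mismatches, best)
    expect_equal(al$retained, best / 30 < 0.30)
  }
})

test_that("circular references capture wrap-around reads", {
  ref <- "ACGTACGTAACCGGTTACGT"
  wrap <- paste0(substr(ref, 16, 20), substr(ref, 1, 5))
  al_lin <- align_hamming(wrap, ref, circular = FALSE)
  al_circ <- align_hamming(wrap, ref, circular = TRUE)
  expect_gt(al_lin$mismatches, 0)
  expect_equal(al_circ$mismatches, 0L)
  expect_equal(al_circ$offset, 16L)
})

test_that("error rates count mismatches over retained reads only", {
  calls <- tibble::tibble(read = rep(c("r1", "r2"), each = 10),
                          cycle = rep(1:10, 2),
                          base = c(rep("A", 10), rep("A", 10)))
  truth <- c(r1 = paste(rep("A", 10), collapse = ""),
             r2 = paste(c(rep("A", 9), "C"), collapse = ""))
  er <- error_rates(calls, truth = truth)
  expect_equal(er$overall, 0.05)
  expect_equal(er$by_cycle$rate, c(rep(0, 9), 0.5))
  expect_equal(er$n_bases, 20)
  ## a read over the 30% threshold is dropped
  truth_bad <- truth
  truth_bad["r2"] <- paste(rep("G", 10), collapse = "")
  er2 <- error_rates(calls, truth = truth_bad)
  expect_equal(er2$n_retained, 1)
  expect_equal(er2$overall, 0)
  expect_error(error_rates(calls, truth = truth, reference = "ACGT"), "exactly one")
})

test_that("simulation-mode and alignment-mode rates agree on planted templates", {
  cfg <- sim_config(reads = 40, cycles = 18, seed = 63)
  tile <- simulate_tile(cfg)
  calls <- call_tile(tile, sim_params_fit(cfg), "fb")
  er_truth <- error_rates(calls, truth = tile$truth)
  ## plant every template in one reference with junk separators
  set.seed(64)
  sep <- function() paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                          collapse = "")
  ref <- paste(vapply(tile$truth$template, function(t) paste0(t, sep()),
                      character(1)), collapse = "")
  er_ref <- error_rates(calls, reference = ref)
  expect_equal(er_ref$overall, er_truth$overall, tolerance = 1e-12)
})

test_that("discrimination ability matches a brute-force prefix scan", {
  ## crafted 10-base example
  qual <- c(0.99, 0.98, 0.97, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3)
  correct <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  for (thr in c(0.01, 0.1, 0.2, 0.25, 0.4)) {
    got <- discrimination_ability(qual, correct, thr)
    ## oracle: scan every prefix of the sorted order
    ord <- order(-qual)
    best <- 0
    for (n in seq_along(ord)) {
      if (mean(!correct[ord][1:n]) <= thr) best <- n
    }
    expect_equal(got, best)
  }
  ## all correct: every base callable
  expect_equal(discrimination_ability(runif(50), rep(TRUE, 50), 0.01), 50L)
  ## uninformative qualities: prefix set by the overall error rate
  expect_equal(discrimination_ability(rep(0.5, 4), c(TRUE, TRUE, TRUE, FALSE), 0.25),
               4L)
  expect_equal(discrimination_ability(rep(0.5, 4), c(FALSE, TRUE, TRUE, TRUE), 0.2),
               0L)
  ## monotone in the threshold
  set.seed(65)
  q <- runif(200); cor_flags <- runif(200) > 0.1
  d <- vapply(seq(0.02, 0.3, by = 0.02), function(thr)
    discrimination_ability(q, cor_flags, thr), integer(1))
  expect_true(all(diff(d) >= 0))
})

test_that("better-calibrated qualities never discriminate worse", {
  set.seed(66)
  correct <- c(rep(TRUE, 90), rep(FALSE, 10))[sample(100)]
  ## calibrated: errors get low quality; uninformative: random qualities
  q_cal <- ifelse(correct, runif(100, 0.6, 1), runif(100, 0, 0.4))
  q_flat <- runif(100)
  for (thr in c(0.02, 0.05, 0.1, 0.2)) {
    expect_gte(discrimination_ability(q_cal, correct, thr),
               discrimination_ability(q_flat, correct, thr))
  }
})

test_that("tidy, glance and plot accessors expose fit and report summaries", {
  cfg <- sim_config(reads = 60, cycles = 12, seed = 67)
  tile <- simulate_tile(cfg)
  fit <- train_basecaller(tile, train_reads = 40, seed = 5)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(fit$schedule))
  expect_true(all(c("alpha", "beta", "droop_mean") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_train, 40)
  er <- error_rates(call_tile(tile, fit, "fb"), truth = tile$truth)
  expect_equal(nrow(tidy(er)), 12)
  expect_s3_class(autoplot(er), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_error_by_cycle(list(fb = er)), "ggplot")
})
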