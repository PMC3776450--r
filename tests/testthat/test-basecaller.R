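test_that("intensity files round-trip and report malformed rows", {
  prefix <- tempfile()
  tile <- simulate_tile(sim_config(reads = 20, cycles = 7, seed = 41),
                        out_prefix = prefix)
  xs <- read_intensities(tile$int_path)
  expect_length(xs$intensities, 20)
  expect_equal(nrow(xs$intensities[[1]]), 7)
  expect_equal(xs$meta$x, 1:20)
  ## corrupt one value
  ln <- readLines(tile$int_path)
  bad <- strsplit(ln[18], "\t")[[1]]
  bad[10] <- "not_a_number"
  ln[18] <- paste(bad, collapse = "\t")
  bf <- tempfile(); writeLines(ln, bf)
  expect_error(read_intensities(bf), "parse error")
  expect_error(read_intensities(tempfile()), "not found")
})

test_that("bustard calls a clean tile perfectly, with and without droop", {
  tile <- simulate_tile(clean_config(reads = 40, cycles = 18, seed = 42,
                                     K = default_crosstalk()))
  er <- error_rates(bustard_call(tile), truth = tile$truth)
  expect_equal(er$overall, 0)
  ## droop only: renormalization restores a flat signal
  tiled <- simulate_tile(clean_config(reads = 40, cycles = 18, seed = 43,
                                      d = 0.08, K = default_crosstalk()))
  erd <- error_rates(bustard_call(tiled), truth = tiled$truth)
  expect_equal(erd$overall, 0)
  expect_error(bustard_call(tile$intensities[1:5]), "at least 10")
})

test_that("model-based calls beat the baseline under phasing and noise", {
  cfg <- sim_config(reads = 150, cycles = 24, seed = 44)
  tile <- simulate_tile(cfg)
  fit <- sim_params_fit(cfg)
  er_fb <- error_rates(call_tile(tile, fit, "fb"), truth = tile$truth)
  er_bu <- error_rates(bustard_call(tile), truth = tile$truth)
  expect_lt(er_fb$overall, er_bu$overall)
})

test_that("windowed calling with true parameters is exact on short fixtures", {
  ## single-window reads decoded via the full pipeline equal the MAP-marginal
  ## calls of the exhaustive oracle
  set.seed(45)
  cfg <- sim_config(reads = 12, cycles = 6, p = phasing_params(0, 0.015),
                    seed = 46)
  tile <- simulate_tile(cfg)
  fit <- sim_params_fit(cfg, W = 6, pad = 0)
  calls <- call_tile(tile, fit, "fb")
  th <- fit$params[[1]]
  boot_tbl <- bustard_call(tile)
  for (k in 1:12) {
    Y <- tile$intensities[[k]] / fit$scale
    boot <- match(boot_tbl$base[boot_tbl$read == read_ids_for(tile)[k]],
                  base_letters())
    lam <- estimate_lambda(Y, boot, th, 1:6, cumprod(1 - fit$dbar)[1:6])
    em <- softcall:::emission_matrix(Y, 1:6, lam, th$K, th$Sigma, th$alpha,
                                     th$beta, cumprod(1 - fit$dbar)[1:6])
    oracle <- brute_force_trellis(em)
    got <- calls$base[calls$read == read_ids_for(tile)[k]]
    expect_equal(match(got, base_letters()),
                 unname(apply(oracle$post[1:6, ], 1, which.max)))
  }
})

test_that("posteriors are valid probabilities and phred mapping is exact", {
  cfg <- sim_config(reads = 30, cycles = 12, seed = 47)
  tile <- simulate_tile(cfg)
  calls <- call_tile(tile, sim_params_fit(cfg), "fb")
  expect_true(all(calls$qual > 0 & calls$qual <= 1))
  expect_true(all(calls$phred >= 0 & calls$phred <= 40))
  expect_equal(posterior_to_phred(c(0.9, 1, 0.25)), c(10L, 40L, 1L))
  expect_equal(posterior_to_phred(0.999), 30L)
  expect_error(posterior_to_phred(1.5), "posterior")
  expect_error(posterior_to_phred(0), "posterior")
})

test_that("fastq output round-trips sequences and qualities exactly", {
  cfg <- sim_config(reads = 25, cycles = 9, seed = 48)
  tile <- simulate_tile(cfg)
  calls <- call_tile(tile, sim_params_fit(cfg), "sova")
  fq <- tempfile(fileext = ".fastq")
  write_fastq(calls, fq)
  expect_length(readLines(fq), 100)
  back <- read_fastq(fq)
  expect_equal(back$base, calls$base)
  expect_equal(back$phred, calls$phred)
  expect_equal(back$read, calls$read)
  ## per-record sequence and quality lengths agree
  ln <- readLines(fq)
  expect_equal(nchar(ln[seq(2, 100, 4)]), nchar(ln[seq(4, 100, 4)]))
})

test_that("fb and sova agree on essentially all calls at realistic noise", {
  cfg <- sim_config(reads = 100, cycles = 24, seed = 49)
  tile <- simulate_tile(cfg)
  fit <- sim_params_fit(cfg)
  fb <- call_tile(tile, fit, "fb")
  sv <- call_tile(tile, fit, "sova")
  expect_gt(mean(fb$base == sv$base), 0.99)
})

test_that("the command-line interface runs every subcommand", {
  prefix <- tempfile()
  expect_equal(cli_main(c("simulate", "--reads", "30", "--cycles", "8",
                          "--seed", "3", "--out-prefix", prefix)), 0L)
  int_file <- paste0(prefix, "_int.txt")
  expect_true(file.exists(int_file))
  fq <- tempfile(fileext = ".fastq")
  expect_equal(cli_main(c("call", "--int-file", int_file, "--decoder",
                          "bustard", "--out", fq)), 0L)
  rep_file <- tempfile(fileext = ".tsv")
  expect_equal(cli_main(c("evaluate", "--fastq", fq, "--truth",
                          paste0(prefix, "_truth.fa"),
                          "--report", rep_file)), 0L)
  expect_true(file.exists(rep_file))
  ## error contracts
  expect_equal(cli_main(c("call", "--int-file", tempfile(), "--out", fq)), 1L)
  expect_equal(cli_main("frobnicate"), 2L)
  expect_equal(cli_main(character(0)), 2L)
})
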