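test_that("condition summaries compute mean and sample SD deterministically", {
  tbl <- results_table(
    condition = c("a", "a", "a", "b", "b", "c"),
    replicate = c("1", "2", "3", "1", "2", "1"),
    metric = "m", value = c(5, 5, 5, 4, 6, 7), units = "au")
  s <- summarize_results(tbl)
  expect_equal(s$condition, c("a", "b", "c")) # lexicographic
  expect_equal(s$mean, c(5, 5, 7))
  expect_equal(s$sd, c(0, sqrt(2), 0))
  expect_equal(s$sd_undefined, c(FALSE, FALSE, TRUE))
  expect_error(summarize_results(tbl, metric = "nope"), "unknown metric")

  # large-sample agreement with an independent two-pass computation
  withr::with_seed(81, v <- stats::rnorm(1000, 3, 7))
  big <- results_table("x", as.character(seq_along(v)), "m", v, "au")
  sb <- summarize_results(big)
  two_pass_mean <- sum(v) / length(v)
  two_pass_sd <- sqrt(sum((v - two_pass_mean)^2) / (length(v) - 1))
  expect_equal(sb$mean, two_pass_mean, tolerance = 1e-12)
  expect_equal(sb$sd, two_pass_sd, tolerance = 1e-12)
})

elong_config <- function(n_per_cond = 2L) {
  list(
    pixel_size_um = 0.5,
    stages = list("elongation"),
    params = list(elongation = list(seg_threshold = 70)),
    conditions = list(
      list(name = "spindle", images = lapply(seq_len(n_per_cond), function(s)
        list(id = sprintf("f%d", s),
             synthetic = list(type = "cell_body", cell_morphology = "spindle", seed = s)))),
      list(name = "round", images = lapply(seq_len(n_per_cond), function(s)
        list(id = sprintf("f%d", s),
             synthetic = list(type = "cell_body", cell_morphology = "round", seed = s + 900L))))))
}

test_that("an empty pipeline config yields an empty table with a warning", {
  out <- withr::local_tempdir()
  expect_warning(tbl <- run_pipeline(list(conditions = list()), out_dir = out),
                 "no images")
  expect_equal(nrow(tbl), 0L)
  expect_true(file.exists(file.path(out, "results.csv")))
})

test_that("the pipeline reproduces the spindle-over-round ordering", {
  out <- withr::local_tempdir()
  tbl <- run_pipeline(elong_config(), out_dir = out)
  s <- summarize_results(tbl, metric = "elongation_index")
  expect_gt(s$mean[s$condition == "spindle"], s$mean[s$condition == "round"])
  # every numeric row carries a unit from the fixed vocabulary
  expect_true(all(tbl$units %in% RESULT_UNITS))
})

test_that("identical configs produce byte-identical outputs", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- elong_config(1L)
  run_pipeline(cfg, out_dir = out1)
  run_pipeline(cfg, out_dir = out2)
  for (f in c("results.csv", "pipeline.log")) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
})

test_that("missing channels for a requested stage name the stage", {
  cfg <- list(stages = list("clusters"),
              params = list(clusters = list(btx_threshold = 50)),
              conditions = list(list(name = "c", images = list(
                list(id = "i1", synthetic = list(type = "nuclei", n_nuclei = 5L))))))
  expect_error(run_pipeline(cfg, out_dir = withr::local_tempdir()),
               "stage 'clusters' needs channel 'btx'")
})

test_that("a marker-plus-elongation run uses classified counts downstream", {
  cfg <- list(
    pixel_size_um = 0.5,
    stages = list("nuclei", "markers"),
    params = list(nuclei = list(detect_threshold = 10),
                  markers = list(rule = "point_max", threshold = 90)),
    conditions = list(list(name = "c", images = list(
      list(id = "i1", synthetic = list(type = "nuclei", n_nuclei = 50L, seed = 82L))))))
  tbl <- run_pipeline(cfg, out_dir = withr::local_tempdir())
  expect_equal(tbl$value[tbl$metric == "n_nuclei"], 50)
  expect_equal(tbl$value[tbl$metric == "fraction_positive"], 0.6)
})
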