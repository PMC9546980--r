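fake_result <- function(seed, fg) {
  structure(
    list(
      seed = seed, best_epoch = 1L,
      cells = data.frame(
        cell = "overlap_50", iou_fg = fg, iou_bg = 0.99,
        iou_overall = (fg + 0.99) / 2
      )
    ),
    class = "run_result"
  )
}

test_that("summaries reproduce hand-computed statistics", {
  res <- structure(
    list(fake_result(1, 0.87), fake_result(2, 0.88), fake_result(3, 0.89)),
    class = "run_results"
  )
  s <- summarize_runs(res)
  expect_equal(s$mean, 0.88)
  expect_equal(s$sd, 0.01) # sample sd of {0.87, 0.88, 0.89}
  expect_equal(s$max, 0.89)
  expect_equal(s$n, 3L)
})

test_that("a single run yields mean = max and undefined sd", {
  s <- summarize_runs(structure(list(fake_result(1, 0.8)), class = "run_results"))
  expect_equal(s$mean, s$max)
  expect_true(is.na(s$sd))
})

test_that("identical runs have zero spread and failures are kept in n", {
  res <- structure(
    list(
      fake_result(1, 0.85), fake_result(2, 0.85),
      structure(list(seed = 3, error = "boom"), class = "run_error")
    ),
    class = "run_results"
  )
  s <- summarize_runs(res)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 2L)
  expect_equal(attr(s, "n_failed"), 1L)
})

test_that("summary statistics agree with an independent oracle on random values", {
  set.seed(22)
  vals <- runif(7, 0.5, 0.95)
  res <- structure(
    lapply(seq_along(vals), function(i) fake_result(i, vals[i])),
    class = "run_results"
  )
  s <- summarize_runs(res)
  # oracle: direct formulas
  expect_equal(s$mean, sum(vals) / length(vals))
  expect_equal(s$sd, sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)))
  expect_equal(s$max, sort(vals, decreasing = TRUE)[1])
  expect_true(s$mean >= min(vals) && s$mean <= max(vals)) # convex hull
})

test_that("emitters produce the table in both formats", {
  res <- structure(
    list(fake_result(1, 0.87), fake_result(2, 0.89)),
    class = "run_results"
  )
  s <- summarize_runs(res)
  md <- format_stability_md(s)
  expect_true(any(grepl("0.880±0.014", md)))
  expect_true(any(grepl("0.890", md)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_stability_csv(s, f)
  back <- read.csv(f)
  expect_equal(back$mean, 0.88)
})

test_that("profiles are complete and internally consistent", {
  for (nm in c("desk", "paper")) {
    p <- pipeline_profile(nm)
    expect_s3_class(p$train, "train_config")
    expect_s3_class(p$sampling, "sample_config")
    expect_true(all(vapply(p$cells, function(cl) inherits(cl$policy, "recon_policy"), TRUE)))
    expect_true(all(vapply(
      p$cells,
      function(cl) identical(as.integer(cl$policy$patch_shape), p$patch_shape), TRUE
    )))
  }
  expect_equal(pipeline_profile("paper")$n_runs, 10L)
  expect_equal(pipeline_profile("paper")$train$max_epochs, 360L)
  expect_equal(pipeline_profile("paper")$train$patience, 100L)
  expect_equal(pipeline_profile("paper")$train$learning_rate, 0.002)
  expect_equal(pipeline_profile("paper")$train$momentum, 0.99)
  expect_equal(pipeline_profile("paper")$train$batch_size, 6L)
})
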