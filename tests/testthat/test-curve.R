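test_that("fold plans are balanced, deterministic partitions", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 37, seed = 51))
  for (k in c(2, 5, 10)) {
    plan <- make_folds(gen$corpus, k = k, seed = 3)
    sizes <- table(plan$assignment$fold)
    expect_equal(length(sizes), k)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sort(plan$assignment$unit_id),
                 sort(paste0(gen$corpus$sentences$record_id, "#",
                             gen$corpus$sentences$index)))
    plan2 <- make_folds(gen$corpus, k = k, seed = 3)
    expect_identical(plan$assignment, plan2$assignment)
  }
  plan_r <- make_folds(gen$corpus, k = 5, unit = "record", seed = 3)
  expect_setequal(plan_r$assignment$unit_id,
                  unique(gen$corpus$sentences$record_id))
  tiny <- ann_corpus(gen$corpus$sentences[1:3, ])
  expect_error(make_folds(tiny, k = 10), "k = 10")
})

test_that("step sizes are evenly spaced, strictly increasing, ending at the total", {
  s <- step_sizes(12004, 10)
  expect_length(s, 10)
  expect_equal(s[1], 1200)
  expect_equal(s[10], 12004)
  expect_true(all(diff(s) > 0))
  expect_equal(step_sizes(10, 2), c(5L, 10L))
  for (n in c(57, 200, 999)) {
    ss <- step_sizes(n, 7)
    expect_true(all(diff(ss) > 0))
    expect_equal(ss[7], n)
  }
  expect_error(step_sizes(5, 6), "n_total")
})

test_that("a memorizing trainer yields F1 = 1 at every size", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 60, seed = 52))
  plan <- make_folds(gen$corpus, k = 2, seed = 4)
  n_train <- min(table(plan$assignment$fold))
  curve <- run_curve(gen$corpus, memorizing_trainer(), plan,
                     step_sizes(n_train, 2))
  expect_true(all(curve$points$f1 == 1))
  expect_equal(nrow(curve$folds), 2 * 2 * 2)  # sizes x folds x modes
  expect_error(run_curve(gen$corpus, memorizing_trainer(), plan, 10 * n_train),
               "exceeds")
})

test_that("degraded-tagger curves rise with training size and are reproducible", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 500, char_noise_rate = 0,
                                          seed = 53))
  plan <- make_folds(gen$corpus, k = 3, seed = 5)
  sizes <- c(150, 500, 1100)
  curve <- run_curve(gen$corpus, degraded_trainer(a = 0.4, b = 0.08), plan, sizes)
  exact <- curve$points[curve$points$mode == "exact", ]
  expect_true(all(diff(exact$f1[order(exact$train_size)]) > -0.02))
  expect_equal(exact$f1, 0.4 * exact$train_size^0.08, tolerance = 0.02)
  curve2 <- run_curve(gen$corpus, degraded_trainer(a = 0.4, b = 0.08), plan, sizes)
  expect_identical(curve$points, curve2$points)
})

test_that("power-law fitting recovers exact relationships", {
  x <- c(1200, 2400, 4800, 9600)
  fit <- fit_power(x, 0.5 * x^0.1)
  expect_equal(fit$a, 0.5, tolerance = 1e-10)
  expect_equal(fit$b, 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  two <- fit_power(c(10, 100), c(0.3, 0.6))
  expect_equal(two$r_squared, 1)
  expect_equal(predict_f1(two, 10), 0.3, tolerance = 1e-12)
  expect_error(fit_power(c(-1, 2), c(1, 2)), "positive")
})

test_that("power-law fit is scale-covariant and noise-robust", {
  x <- c(500, 1000, 2000, 4000, 8000)
  y <- 0.42 * x^0.07
  f1 <- fit_power(x, y)
  f2 <- fit_power(10 * x, y)
  expect_equal(f2$b, f1$b, tolerance = 1e-10)
  expect_equal(f2$a, f1$a * 10^(-f1$b), tolerance = 1e-10)
  # noisy recovery within 3 standard errors at a fixed seed
  withr::with_seed(54, {
    xs <- round(exp(seq(log(300), log(20000), length.out = 12)))
    ys <- 0.40 * xs^0.08 * exp(rnorm(12, sd = 0.01))
  })
  fit <- fit_power(xs, ys)
  se_b <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$b - 0.08), 3 * se_b)
})

test_that("prediction and inversion are mutually inverse", {
  fit <- list(a = 0.40, b = 0.08)
  expect_equal(round_half_up(predict_f1(fit, 25251), 2), 0.90)
  for (x in c(100, 5000, 25251)) {
    expect_equal(required_size(fit, predict_f1(fit, x)) / x, 1,
                 tolerance = 1e-9)
  }
  expect_equal(required_size(fit, 0.90), (0.90 / 0.40)^(1 / 0.08))
  expect_error(required_size(list(a = 1, b = 0), 2), "flat")
})

test_that("curve objects tidy, glance and autoplot", {
  gen <- generate_corpus(default_lexicon(),
                         generator_config(n_records = 40, seed = 55))
  plan <- make_folds(gen$corpus, k = 2, seed = 6)
  curve <- run_curve(gen$corpus, memorizing_trainer(), plan, c(30, 60))
  expect_s3_class(tidy(curve), "tbl_df")
  expect_equal(glance(curve)$f1_last, 1)
  p <- autoplot(curve, fit = fit_power(c(30, 60), c(0.5, 0.6)))
  expect_s3_class(p, "ggplot")
})
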