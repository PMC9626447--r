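# statistical_cell: prototype profiles, synthetic trace generator, trace
# statistics and classification.

test_that("prototype profiles encode the phenotype statistics", {
  pr <- make_prototype(ec_phenotype_stats("REC"))
  expect_equal(unique(pr$lengths), 50.1)
  expect_equal(pr$times[2] - pr$times[1], 120)

  pt <- make_prototype(ec_phenotype_stats("TEC"), duration = 24 * 3600)
  expect_setequal(unique(pt$lengths), c(13.1, 64.1))
  expect_equal(pt$lengths[1], 13.1)           # starts tumbling (rounded)
  # first low span has length T_P, first high span T_I
  r <- rle(pt$lengths < 20)
  expect_equal(r$lengths[1] * 120, 4440, tolerance = 120)
  expect_equal(r$lengths[2] * 120, 9180, tolerance = 120)
})

test_that("measure_trace recovers square-wave timing to within one frame", {
  pt <- make_prototype(ec_phenotype_stats("TEC"), duration = 24 * 3600)
  st <- measure_trace(pt)
  expect_equal(st$L_min, 13.1)
  expect_equal(st$L_max, 64.1)
  expect_equal(st$T_P_mean, 4440, tolerance = 120)
  expect_equal(st$T_I_mean, 9180, tolerance = 120)
  expect_equal(st$n_tumbles, ceiling(24 * 3600 / (4440 + 9180)))
})

test_that("synthetic traces are reproducible and carry realistic statistics", {
  s <- ec_phenotype_stats("TEC")
  t1 <- synth_trace(s, seed = 11)
  t2 <- synth_trace(s, seed = 11)
  t3 <- synth_trace(s, seed = 12)
  expect_identical(t1$lengths, t2$lengths)
  expect_false(identical(t1$lengths, t3$lengths))

  # jitter = 0 gives a strictly periodic wave; timing recovered within a frame
  st0 <- measure_trace(synth_trace(s, seed = 3, jitter = 0))
  expect_equal(st0$T_P_mean, s$T_P, tolerance = 240)
  expect_equal(st0$T_I_mean, s$T_I, tolerance = 240)
  expect_gte(st0$n_tumbles, 2)

  # REC/UEC traces stay inside the observed length range
  for (lbl in c("REC", "UEC")) {
    ss <- ec_phenotype_stats(lbl)
    tr <- synth_trace(ss, seed = 5)
    expect_true(all(tr$lengths >= ss$L_min & tr$lengths <= ss$L_max))
    expect_equal(mean(tr$lengths), ss$L_mean, tolerance = 0.1 * ss$L_mean)
  }
})

test_that("beta_hat estimates the noise amplitude at fine frames", {
  # the lag-1 quadratic-variation estimator is consistent when the frame is
  # short against the reversion time; use 1-s frames over 24 h
  s <- ec_phenotype_stats("REC")
  tr <- synth_trace(s, frame = 1, seed = 99)
  st <- measure_trace(tr)
  expect_equal(st$beta_hat, s$beta, tolerance = 0.05 * s$beta)
})

test_that("classification is consistent with the generator", {
  labels <- rep(c("REC", "UEC", "TEC"), length.out = 201)
  got <- vapply(seq_along(labels), function(i)
    classify_trace(synth_trace(ec_phenotype_stats(labels[i]),
                               duration = 12 * 3600, seed = 1000 + i)),
    character(1))
  expect_gte(mean(got == labels), 0.95)
})

test_that("traces and their statistics round-trip through files", {
  tr <- synth_trace(ec_phenotype_stats("TEC"), duration = 4 * 3600, seed = 8)
  path <- file.path(tempdir(), "trace.csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$lengths, tr$lengths, tolerance = 1e-9)
  st <- measure_trace(back)
  jpath <- file.path(tempdir(), "stats.json")
  write_trace_stats(st, jpath)
  js <- jsonlite::read_json(jpath)
  expect_equal(js$L_mean, st$L_mean, tolerance = 1e-9)
  expect_equal(js$n_tumbles, st$n_tumbles)
  unlink(c(path, jpath))
  expect_error(measure_trace(list(times = numeric(), lengths = numeric())),
               "trace")
})
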