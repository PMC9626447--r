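# simulator: agreement of the reference R stepper with the compiled loop,
# fixed points, reproducibility, stochastic moments, serialization.

test_that("the R and compiled steppers agree step for step", {
  p <- p_TEC
  init <- ec_default_init(p)
  n <- 500
  traj <- ec_simulate(p, init = init,
                      config = ec_sim_config(dt = 1e-3, T = n * 1e-3,
                                             record_every = 1))
  st <- init
  for (i in seq_len(n)) st <- imex_step(st, p, dt = 1e-3)
  expect_equal(traj$a_mM[n + 1], st$a, tolerance = 1e-12)
  expect_equal(traj$L_um[n + 1], st$L, tolerance = 1e-12)
  expect_equal(traj$c_mM[n + 1], st$c, tolerance = 1e-12)
  expect_equal(traj$branch[n + 1], st$branch)
})

test_that("equilibrium initial states are fixed points of the deterministic map", {
  # REC starts at its joint (a, L) equilibrium; a and L must stay put while
  # ATP recharges toward its crest
  traj <- ec_simulate(p_REC, config = ec_sim_config(dt = 1e-2, hours = 2))
  expect_equal(max(abs(traj$L_um - 50.1)), 0, tolerance = 1e-6)
  expect_equal(max(abs(traj$a_mM - a_max(p_REC))), 0, tolerance = 1e-9)
})

test_that("stochastic runs are reproducible from the seed", {
  cfg <- function(seed) ec_sim_config(dt = 1e-2, T = 600, stochastic = TRUE,
                                      seed = seed)
  t1 <- ec_simulate(p_REC, config = cfg(42))
  t2 <- ec_simulate(p_REC, config = cfg(42))
  t3 <- ec_simulate(p_REC, config = cfg(43))
  expect_identical(t1$L_um, t2$L_um)
  expect_false(identical(t1$L_um, t3$L_um))
  # deterministic mode ignores the stream entirely
  d1 <- ec_simulate(p_REC, config = ec_sim_config(dt = 1e-2, T = 600))
  d2 <- ec_simulate(p_REC, config = ec_sim_config(dt = 1e-2, T = 600))
  expect_identical(d1$L_um, d2$L_um)
})

test_that("stochastic length moments match the OU closed form", {
  # raise the friction so the reversion rate is slow (alpha ~ 0.05 /s) and
  # the implicit-scheme variance bias (~ alpha dt / 2) is negligible; F-actin
  # stays at a_max throughout, so the length equation is exactly OU
  p <- update_params(p_REC, phi = 10)
  alpha <- contractility(a_max(p), p) / p$phi
  mu <- p$v_p / contractility(a_max(p), p)
  init <- ec_default_init(p)
  init$L <- 40
  cfg <- ec_sim_config(dt = 1e-2, T = 60, record_every = 6000,
                       stochastic = TRUE)
  set.seed(1203)
  n <- 1500
  L_end <- vapply(seq_len(n), function(i)
    tail(ec_simulate(p, init = init, config = cfg)$L_um, 1), numeric(1))
  om <- ou_moments(60, init$L, alpha, mu, p$beta)
  # 4-SE bounds at this reduced path count to keep the sampling-noise
  # false-alarm rate negligible; the acceptance suite runs the 3-SE version
  # over 5000 paths
  expect_lt(abs(mean(L_end) - om$mean), 4 * sd(L_end) / sqrt(n))
  expect_lt(abs(var(L_end) - om$variance),
            4 * var(L_end) * sqrt(2 / (n - 1)))
})

test_that("configuration and initial states are validated", {
  expect_error(ec_sim_config(dt = 0), "dt must be > 0")
  expect_error(ec_sim_config(dt = 1, T = 0.5), "T must be >= dt")
  expect_error(ec_sim_config(record_every = 0), "record_every")
  expect_error(ec_simulate(p_REC, init = list(a = 0.1, L = -5, c = 5),
                           config = cfg_12h),
               "initial state")
  expect_error(ec_simulate(p_REC, init = list(a = 0.1), config = cfg_12h),
               "must provide")
})

test_that("trajectories round-trip through CSV with their sidecar", {
  traj <- ec_simulate(p_TEC, config = ec_sim_config(dt = 1e-2, T = 600))
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(traj, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_trajectory(path)
  expect_s3_class(back, "ec_traj")
  expect_equal(back$L_um, traj$L_um, tolerance = 1e-9)
  expect_equal(back$branch, traj$branch)
  p_back <- attr(back, "params")
  expect_equal(coef(p_back), coef(p_TEC), tolerance = 1e-9)
  expect_equal(attr(back, "config")$dt, 1e-2)
  unlink(c(path, paste0(path, ".meta.json")))
})

test_that("ou_moments validates its reversion rate", {
  expect_error(ou_moments(1, 10, alpha = 0, mu = 50, beta = 1), "alpha")
  om <- ou_moments(c(0, 1e9), 10, alpha = 0.1, mu = 50, beta = 2)
  expect_equal(om$mean[1], 10)
  expect_equal(om$mean[2], 50)
  expect_equal(om$variance[2], 2^2 / (2 * 0.1))
})
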