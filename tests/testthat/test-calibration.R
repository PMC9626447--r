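# calibration: objective self-consistency and exactness, PSO mechanics on
# analytic functions, and the fitting front end.

make_rec_problem <- function(hours = 2, shift = 0, ...) {
  cfg <- ec_sim_config(dt = 1e-2, hours = hours)
  traj <- ec_simulate(p_REC, config = cfg)
  grid <- seq(0, hours * 3600, by = 120)
  L <- approx(traj$t_s, traj$L_um, xout = grid, rule = 2)$y + shift
  ec_calib_problem(free = c("c_eq", "M2"),
                   bounds = ec_calib_bounds(),
                   template = p_REC,
                   target = list(times = grid, lengths = L),
                   sim_config = cfg, ...)
}

test_that("the objective vanishes at the generating parameters", {
  prob <- make_rec_problem()
  J0 <- objective(c(c_eq = p_REC$c_eq, M2 = p_REC$M2), prob)
  expect_lt(J0, 1e-8)
})

test_that("the objective measures a constant offset exactly", {
  delta <- 0.7
  prob <- make_rec_problem(shift = delta)
  J <- objective(c(c_eq = p_REC$c_eq, M2 = p_REC$M2), prob)
  n <- length(prob$target$times)
  expect_equal(J, delta * sqrt(n * 120), tolerance = 1e-6)
})

test_that("problem construction and objective inputs are validated", {
  expect_error(make_rec_problem(objective = "nonsense"), "arg")
  prob <- make_rec_problem()
  expect_error(objective(c(c_eq = 0.5, M2 = 6), prob), "out of bounds")
  expect_error(ec_calib_problem(free = "k", bounds = list(k = c(0, 1)),
                                template = p_REC,
                                target = list(times = 0:1, lengths = c(1, 1))),
               "subset")
  expect_error(ec_calib_problem(free = "M2", bounds = list(M2 = c(2, 1)),
                                template = p_REC,
                                target = list(times = 0:1, lengths = c(1, 1))),
               "invalid bounds")
})

test_that("PSO minimizes a smooth bowl and its history is nonincreasing", {
  prob <- list(free = "c_eq", bounds = list(c_eq = c(1.5, 5.5)),
               log_scale = character())
  fn <- function(theta, prob) (theta[["c_eq"]] - 3)^2
  cfg <- ec_pso_config(swarm_size = 15, iterations = 30, seed = 1)
  res <- pso_minimize(prob, cfg, fn = fn)
  expect_lt(abs(res$theta_best[["c_eq"]] - 3), 1e-2)
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$evaluations, 15 * 31)
})

test_that("PSO searches log-scaled parameters on the natural scale", {
  prob <- list(free = "lam", bounds = list(lam = c(1e-6, 1e-2)),
               log_scale = "lam")
  fn <- function(theta, prob) (log10(theta[["lam"]]) + 4)^2
  res <- pso_minimize(prob, ec_pso_config(swarm_size = 12, iterations = 30,
                                          seed = 2), fn = fn)
  expect_equal(res$theta_best[["lam"]], 1e-4, tolerance = 0.05)
})

test_that("PSO honors degenerate bounds", {
  prob <- list(free = "c_eq", bounds = list(c_eq = c(2, 2)),
               log_scale = character())
  fn <- function(theta, prob) theta[["c_eq"]]^2
  res <- pso_minimize(prob, ec_pso_config(swarm_size = 5, iterations = 3,
                                          seed = 3), fn = fn)
  expect_equal(res$theta_best[["c_eq"]], 2)
})

test_that("ec_calibrate returns a usable fit object", {
  # tiny budget: this checks the plumbing and the S3 surface, not optimality
  fit <- ec_calibrate("REC", pso = ec_pso_config(swarm_size = 6,
                                                 iterations = 6, seed = 4),
                      duration = 2 * 3600)
  expect_s3_class(fit, "ec_fit")
  expect_true(is.finite(fit$J))
  expect_named(coef(fit), c("M1", "M2", "M3", "c_eq"))
  expect_length(fitted(fit), length(fit$problem$target$times))
  expect_length(residuals(fit), length(fit$problem$target$times))
  expect_output(print(fit), "objective J")
  # free parameters landed inside their bounds
  for (nm in names(coef(fit))) {
    b <- fit$problem$bounds[[nm]]
    expect_gte(coef(fit)[[nm]], b[1])
    expect_lte(coef(fit)[[nm]], b[2])
  }
})
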