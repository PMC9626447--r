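# model_core: kernels, equilibria, constraint-based derivation, parameter
# validation and serialization.

test_that("phenotype statistics are validated", {
  expect_s3_class(ec_phenotype_stats("TEC"), "ec_stats")
  expect_equal(ec_phenotype_stats("TEC")$T_P, 4440)
  expect_equal(ec_phenotype_stats("REC")$L_mean, 50.1)
  expect_error(validate_ec_stats(list(label = "XEC", L_max = 1, L_min = 0,
                                      beta = 1)),
               "unknown phenotype")
  expect_error(validate_ec_stats(list(label = "REC", L_max = 10, L_min = 20,
                                      beta = 1)),
               "L_min < L_max")
  bad <- ec_phenotype_stats("TEC"); bad$T_P <- -1
  expect_error(validate_ec_stats(bad), "positive T_P")
})

test_that("kernel functions match their closed forms", {
  # switch rate: k1 at zero ATP, k2 at and above the homeostatic level,
  # nonincreasing in between
  expect_equal(actin_switch_rate(0, p_TEC), p_TEC$k1)
  expect_equal(actin_switch_rate(c(10, 12), p_TEC), rep(p_TEC$k2, 2))
  cs <- seq(0, 12, by = 0.05)
  expect_true(all(diff(actin_switch_rate(cs, p_TEC)) <= 1e-9))
  expect_equal(actin_switch_rate(2.26, p_TEC), 1000.921255, tolerance = 1e-6)
  expect_error(actin_switch_rate(-1, p_TEC), ">= 0")

  # contractility: maximal at a = 2 a_sat, and sigma(a_min) = v_p / L_min by
  # construction of psi
  a <- seq(1e-3, p_TEC$a_h, length.out = 400)
  expect_equal(a[which.max(contractility(a, p_TEC))], 2 * p_TEC$a_sat,
               tolerance = 1e-2)
  expect_equal(contractility(a_min(p_TEC), p_TEC), p_TEC$v_p / p_TEC$L_min,
               tolerance = 1e-12)

  # release fraction: zero at L_min, in [0, 1], nondecreasing, clamped below
  Ls <- seq(5, 200, by = 1)
  R <- release_fraction(Ls, p_TEC)
  expect_equal(release_fraction(p_TEC$L_min, p_TEC), 0)
  expect_true(all(R >= 0 & R <= 1))
  expect_true(all(diff(R) >= 0))
  expect_equal(release_fraction(1, p_TEC), 0)  # clamped, not negative

  # hysteresis: f1 closed below c_eq and saturated at c_h; f2 closed at c_L
  # and saturated at c_eq; f2 >= f1 everywhere
  expect_equal(hysteresis_value(p_TEC$c_eq, "rising", p_TEC), 0)
  expect_equal(hysteresis_value(10, "rising", p_TEC), 1)
  expect_equal(hysteresis_value(1, "falling", p_TEC), 0)
  expect_equal(hysteresis_value(p_TEC$c_eq, "falling", p_TEC), 1)
  cs <- seq(0, 10, by = 0.01)
  expect_true(all(hysteresis_value(cs, "falling", p_TEC) >=
                    hysteresis_value(cs, "rising", p_TEC)))
  expect_equal(hysteresis_value(9.99, "rising", p_REC), 0.041115,
               tolerance = 1e-4)
})

test_that("equilibrium relations invert each other", {
  expect_equal(equilibrium_actin(p_TEC$k1, p_TEC), a_min(p_TEC))
  expect_equal(equilibrium_actin(p_TEC$k2, p_TEC), a_max(p_TEC))
  # the derived a_max pins the equilibrium length at the reference length
  expect_equal(equilibrium_length(a_max(p_TEC), p_TEC), p_TEC$L_max,
               tolerance = 1e-9)
  expect_equal(equilibrium_length(a_max(p_REC), p_REC), 50.1,
               tolerance = 1e-9)
  expect_equal(equilibrium_length(a_max(p_UEC), p_UEC), 185.5,
               tolerance = 1e-9)
  # minimum length is attained exactly at a_min
  expect_equal(equilibrium_length(a_min(p_TEC), p_TEC), p_TEC$L_min,
               tolerance = 1e-9)
  expect_error(equilibrium_length(0, p_TEC), "> 0")
})

test_that("derivation satisfies its defining constraints", {
  for (p in list(p_REC, p_UEC, p_TEC)) {
    # a_max is the root of sigma(a) = v_p / L_ref on the decreasing branch
    expect_gt(a_max(p), 2 * p$a_sat)
    # S_max balances production against full-stretch release
    expect_equal(p$S_max * release_fraction(p$L_max, p),
                 p$lam * (p$c_h - p$c_L), tolerance = 1e-12)
    # a_sat sits at half the minimum F-actin level
    expect_equal(p$a_sat, a_min(p) / 2)
  }
  expect_error(solve_a_max(psi = 100, a_sat = 0.025, v_p = 25, L_ref = 1,
                           a_h = 0.2),
               "no root")
})

test_that("parameter validation rejects inconsistent sets", {
  expect_error(update_params(p_TEC, k1 = 1), "k1 > k2")
  expect_error(update_params(p_TEC, c_eq = 11), "c_L < c_eq < c_h")
  expect_error(update_params(p_TEC, psi = -1), "positive")
  expect_error(update_params(p_TEC, nonsense = 1), "unknown parameter")
  expect_error(update_params(p_TEC, L_min = 100), "L_min < L_max")
  # rederive_S_max keeps the release balance intact after a lam change
  p2 <- update_params(p_TEC, lam = 2e-3, rederive_S_max = TRUE)
  expect_equal(p2$S_max * release_fraction(p2$L_max, p2),
               p2$lam * (p2$c_h - p2$c_L), tolerance = 1e-12)
})

test_that("parameter sets round-trip through YAML and JSON", {
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("params.", ext))
    write_ec_params(list(REC = p_REC, TEC = p_TEC), path)
    back <- read_ec_params(path)
    expect_named(back, c("REC", "TEC"))
    expect_equal(coef(back$TEC), coef(p_TEC), tolerance = 1e-9)
    expect_equal(back$REC$phenotype, "REC")
    unlink(path)
  }
  # single object simplifies back to a bare ec_params
  path <- file.path(tempdir(), "one.yml")
  write_ec_params(p_UEC, path)
  one <- read_ec_params(path)
  expect_s3_class(one, "ec_params")
  expect_equal(coef(one), coef(p_UEC), tolerance = 1e-9)
  unlink(path)
  expect_error(write_ec_params(p_REC, "x.txt"), "extension")
})
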