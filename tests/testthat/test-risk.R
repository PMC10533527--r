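collider <- build_preset_network("collider_test")

test_that("relative risk reads off the collider CPT", {
  rr <- relative_risk(collider,
                      risk_scenario("C", "true", c(A = "true", B = "true")))
  expect_equal(rr, 9, tolerance = 1e-12)
})

test_that("a single risk variable gives the direct CPT ratio", {
  st <- c("false", "true")
  net <- bn_network(list(A = st, B = st), parents = list(A = "B"),
                    cpts = list(B = c(0.5, 0.5),
                                A = c(0.7, 0.3, 0.4, 0.6)))
  rr <- relative_risk(net, risk_scenario("A", "true", c(B = "true")))
  expect_equal(rr, 0.6 / 0.3, tolerance = 1e-12)
})

test_that("a d-separated outcome has relative risk exactly 1", {
  net <- build_preset_network("svr_core")
  rr <- relative_risk(net, risk_scenario("MDI_low", "true", c(SEX = "true")))
  expect_equal(rr, 1, tolerance = 1e-12)
  ind <- build_preset_network("independent_test")
  expect_equal(relative_risk(ind, risk_scenario("C", "true", c(A = "true"))),
               1, tolerance = 1e-12)
})

test_that("swapping flagged and complement states inverts the ratio", {
  net <- build_preset_network("svr_core")
  sc <- risk_scenario("MDI_low", "true", c(dGV = "true", SYNDR = "true"))
  sc_swapped <- risk_scenario("MDI_low", "true",
                              c(dGV = "false", SYNDR = "false"))
  rr <- relative_risk(net, sc)
  rr_swapped <- relative_risk(net, sc_swapped)
  expect_equal(rr_swapped, 1 / rr, tolerance = 1e-12)
})

test_that("relative risk agrees with the brute-force arms", {
  for (seed in c(2, 9, 23)) {
    net <- random_network(6, seed = 3000 + seed)
    vars <- bn_nodes(net)
    sc <- risk_scenario(vars[1], "true",
                        stats::setNames(c("true", "true"), vars[2:3]))
    num <- brute_force_query(net, vars[1],
                             evidence(stats::setNames(c("true", "true"),
                                                      vars[2:3])))
    den <- brute_force_query(net, vars[1],
                             evidence(stats::setNames(c("false", "false"),
                                                      vars[2:3])))
    oracle <- num$distribution[["true"]] / den$distribution[["true"]]
    expect_equal(relative_risk(net, sc), oracle, tolerance = 1e-12)
  }
})

test_that("an interacting outcome is synergistic, not multiplicative", {
  rr_joint <- relative_risk(collider,
                            risk_scenario("C", "true",
                                          c(A = "true", B = "true")))
  rr_a <- relative_risk(collider, risk_scenario("C", "true", c(A = "true")))
  rr_b <- relative_risk(collider, risk_scenario("C", "true", c(B = "true")))
  expect_gt(abs(rr_joint - rr_a * rr_b), 0.1)
})

test_that("scenario validation catches malformed queries", {
  expect_error(risk_scenario("C", "true", c("true")),
               class = "svbn_validation_error")
  expect_error(risk_scenario("C", "true", c(C = "true")),
               class = "svbn_validation_error")
  expect_error(relative_risk(collider,
                             risk_scenario("C", "true", c(Z = "true"))),
               class = "svbn_validation_error")
})

svr_cohort_500 <- function(seed = 11) {
  as_discrete_cohort(sample_discrete_cohort(
    synthetic_spec(build_preset_network("svr_core"), 500, seed = seed)))
}

test_that("bootstrap estimates are reproducible bit-for-bit from the seed", {
  dc <- svr_cohort_500()
  sc <- risk_scenario("MDI_low", "true", c(dGV = "true"))
  e1 <- bootstrap_ci(dc, sc, n_boot = 25, seed = 99)
  e2 <- bootstrap_ci(dc, sc, n_boot = 25, seed = 99)
  expect_identical(e1$rr, e2$rr)
  expect_identical(e1$boot_rr, e2$boot_rr)
  expect_identical(c(e1$ci_lo, e1$ci_hi), c(e2$ci_lo, e2$ci_hi))
  expect_true(e1$ci_lo <= e1$ci_hi)
  expect_true(e1$rr > 0 && e1$ci_lo > 0)
  expect_lt(e1$n_failed, e1$n_boot)
})

test_that("extending n_boot preserves the earlier replicate stream", {
  dc <- svr_cohort_500()
  sc <- risk_scenario("MDI_low", "true", c(dGV = "true"))
  short <- bootstrap_ci(dc, sc, n_boot = 10, seed = 7)
  long <- bootstrap_ci(dc, sc, n_boot = 20, seed = 7)
  expect_identical(short$boot_rr, long$boot_rr[1:10])
})

test_that("identical rows make every resample, hence the interval, degenerate", {
  dc <- make_binary_cohort(B = rep(TRUE, 12), A = rep(TRUE, 12))
  sc <- risk_scenario("A", "true", c(B = "true"))
  est <- bootstrap_ci(dc, sc, n_boot = 20, seed = 3)
  expect_equal(est$ci_lo, est$rr, tolerance = 1e-12)
  expect_equal(est$ci_hi, est$rr, tolerance = 1e-12)
  expect_identical(est$n_failed, 0L)
})

test_that("the battery preserves order and shares the replicate stream", {
  dc <- svr_cohort_500()
  scs <- list(
    risk_scenario("MDI_low", "true", c(dGV = "true")),
    risk_scenario("MDI_low", "true", c(PDI_low = "low")),  # bad state: error
    risk_scenario("MDI_low", "true", c(dGV = "true")))
  ests <- scenario_battery(dc, scs, n_boot = 15, seed = 21)
  expect_length(ests, 3L)
  expect_s3_class(ests[[1]], "risk_estimate")
  expect_s3_class(ests[[2]], "risk_error")
  expect_identical(ests[[2]]$index, 2L)
  expect_s3_class(ests[[3]], "risk_estimate")
  # duplicates under the shared stream are identical
  expect_identical(ests[[1]]$rr, ests[[3]]$rr)
  expect_identical(ests[[1]]$boot_rr, ests[[3]]$boot_rr)
})

test_that("a battery expresses single factors and their combination", {
  dc <- svr_cohort_500(seed = 4)
  scs <- list(
    risk_scenario("MDI_low", "true", c(dGV = "true")),
    risk_scenario("MDI_low", "true", c(PDI_low = "true")),
    risk_scenario("MDI_low", "true", c(dGV = "true", PDI_low = "true")))
  ests <- scenario_battery(dc, scs, n_boot = 10, seed = 5)
  expect_true(all(vapply(ests, inherits, logical(1), "risk_estimate")))
  ft <- forest_table(ests)
  expect_identical(nrow(ft), 3L)
  expect_true(all(ft$rr > 0))
})

test_that("bootstrap inputs are validated", {
  dc <- svr_cohort_500()
  sc <- risk_scenario("MDI_low", "true", c(dGV = "true"))
  expect_error(bootstrap_ci(dc, sc, n_boot = 0, seed = 1),
               class = "svbn_validation_error")
  expect_error(scenario_battery(dc, list(), n_boot = 5, seed = 1),
               class = "svbn_validation_error")
  expect_error(scenario_battery(dc, list(sc), n_boot = 5),
               class = "svbn_validation_error")
})
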