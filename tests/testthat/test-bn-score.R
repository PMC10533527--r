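# Closed-form multinomial oracle for a parentless binary family.
root_bic_oracle <- function(flags) {
  n <- length(flags)
  k <- sum(flags)
  ll <- 0
  if (k > 0) ll <- ll + k * log(k / n)
  if (k < n) ll <- ll + (n - k) * log((n - k) / n)
  c(loglik = ll, bic = ll - 0.5 * log(n))
}

test_that("family BIC matches the closed-form multinomial MLE", {
  dc <- make_binary_cohort(X = c(rep(TRUE, 6), rep(FALSE, 4)))
  fs <- family_score_bic("X", character(), dc)
  oracle <- root_bic_oracle(c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(fs$loglik, unname(oracle["loglik"]), tolerance = 1e-12)
  expect_equal(fs$bic, unname(oracle["bic"]), tolerance = 1e-12)
  expect_equal(fs$loglik, 6 * log(0.6) + 4 * log(0.4))
  expect_identical(fs$n_params, 1L)
  expect_identical(fs$n_obs, 10L)
})

test_that("a constant child has zero log-likelihood", {
  dc <- make_binary_cohort(X = rep(TRUE, 16))
  fs <- family_score_bic("X", character(), dc)
  expect_equal(fs$loglik, 0)
  expect_equal(fs$bic, -0.5 * log(16))
})

test_that("a deterministic copy scores above the parentless family", {
  x <- rep(c(TRUE, FALSE), each = 4)
  dc <- make_binary_cohort(P = x, C = x)
  with_parent <- family_score_bic("C", "P", dc)
  without <- family_score_bic("C", character(), dc)
  expect_equal(with_parent$loglik, 0)
  expect_equal(with_parent$bic, -0.5 * log(8) * 2, tolerance = 1e-12)
  expect_equal(without$bic, unname(root_bic_oracle(x)["bic"]), tolerance = 1e-12)
  expect_gt(with_parent$bic, without$bic)
})

test_that("family scoring validates its inputs", {
  dc <- make_binary_cohort(X = c(TRUE, FALSE), Y = c(TRUE, TRUE))
  expect_error(family_score_bic("X", "X", dc), class = "svbn_validation_error")
  expect_error(family_score_bic("Z", character(), dc),
               class = "svbn_validation_error")
})

test_that("network_score decomposes exactly over families", {
  set.seed(77)
  dc <- random_binary_cohort(120, 4, seed = 77)
  vars <- names(cohort_states(dc))
  s <- dag_structure(cohort_states(dc),
                     parents = list(B = "A", C = c("A", "B"), D = "C"))
  total <- network_score(s, dc)
  by_hand <- sum(vapply(vars, function(v) {
    family_score_bic(v, s$parents[[v]], dc)$bic
  }, numeric(1)))
  expect_equal(total, by_hand, tolerance = 1e-12)
})

test_that("cyclic structures are rejected", {
  dc <- make_binary_cohort(A = c(TRUE, FALSE), B = c(TRUE, TRUE))
  s <- dag_structure(cohort_states(dc), parents = list(A = "B", B = "A"))
  expect_error(network_score(s, dc), class = "svbn_cycle_error")
})

test_that("opposite orientations of one edge tie in BIC", {
  set.seed(41)
  x <- stats::runif(200) < 0.5
  y <- ifelse(stats::runif(200) < 0.8, x, !x)
  dc <- make_binary_cohort(A = x, B = y)
  states <- cohort_states(dc)
  ab <- network_score(dag_structure(states, list(B = "A")), dc)
  ba <- network_score(dag_structure(states, list(A = "B")), dc)
  expect_equal(ab, ba, tolerance = 1e-12)
})

test_that("a single variable yields the empty DAG", {
  dc <- make_binary_cohort(X = c(TRUE, FALSE, TRUE))
  s <- exact_structure_search(dc)
  expect_identical(sum(lengths(s$parents)), 0L)
})

test_that("independent variables learn an empty DAG, matching enumeration", {
  set.seed(5)
  dc <- random_binary_cohort(500, 2, seed = 5)
  s <- exact_structure_search(dc)
  expect_identical(sum(lengths(s$parents)), 0L)
  oracle <- brute_force_best_score(dc)
  expect_equal(attr(s, "score"), oracle$best, tolerance = 1e-10)
})

test_that("the DAG enumeration oracle has the known counts", {
  expect_equal(brute_force_best_score(
    make_binary_cohort(A = c(TRUE, FALSE), B = c(TRUE, TRUE),
                       C = c(FALSE, TRUE)))$n_dags, 25L)
})

test_that("exact search attains the enumeration maximum on 4 variables", {
  n_dags <- NULL
  for (seed in 1:6) {
    dc <- random_binary_cohort(150, 4, seed = 900 + seed)
    s <- exact_structure_search(dc, max_parents = 3L)
    oracle <- brute_force_best_score(dc)
    n_dags <- oracle$n_dags
    expect_equal(attr(s, "score"), oracle$best, tolerance = 1e-9)
    expect_equal(network_score(s, dc), attr(s, "score"), tolerance = 1e-9)
  }
  expect_equal(n_dags, 543L)
})

test_that("the search respects a max_parents cap", {
  dc <- as_discrete_cohort(sample_discrete_cohort(
    synthetic_spec(build_preset_network("svr_core"), 800, seed = 31)))
  s1 <- exact_structure_search(dc, max_parents = 1L)
  expect_true(all(lengths(s1$parents) <= 1L))
  capped <- brute_force_best_score(
    as_discrete_cohort(sample_discrete_cohort(
      synthetic_spec(build_preset_network("chain_test"), 300, seed = 8))),
    max_parents = 1L)
  s2 <- exact_structure_search(as_discrete_cohort(sample_discrete_cohort(
    synthetic_spec(build_preset_network("chain_test"), 300, seed = 8))),
    max_parents = 1L)
  expect_equal(attr(s2, "score"), capped$best, tolerance = 1e-9)
})

test_that("row order does not affect scores or the learned structure", {
  spec <- synthetic_spec(build_preset_network("svr_core"), 400, seed = 19)
  dc <- as_discrete_cohort(sample_discrete_cohort(spec))
  set.seed(1)
  perm <- sample(nrow(dc))
  dcp <- dc[perm, , drop = FALSE]
  attributes(dcp)[c("states", "rules", "flags")] <-
    attributes(dc)[c("states", "rules", "flags")]
  class(dcp) <- class(dc)
  s1 <- exact_structure_search(dc)
  s2 <- exact_structure_search(dcp)
  expect_identical(s1$parents, s2$parents)
  expect_equal(attr(s1, "score"), attr(s2, "score"), tolerance = 1e-12)
})

test_that("search guards reject oversized problems and bad caps", {
  dc <- make_binary_cohort(A = c(TRUE, FALSE))
  expect_error(exact_structure_search(dc, max_parents = -1L),
               class = "svbn_validation_error")
  spec <- synthetic_spec(build_preset_network("svr_core"), 50, seed = 2)
  dc6 <- as_discrete_cohort(sample_discrete_cohort(spec))
  expect_error(exact_structure_search(dc6, max_nodes = 3L),
               class = "svbn_validation_error")
})

test_that("fit_parameters matches the posterior-mean closed form", {
  dc <- make_binary_cohort(X = c(rep(TRUE, 6), rep(FALSE, 4)))
  s <- dag_structure(cohort_states(dc))
  net1 <- fit_parameters(s, dc, pseudocount = 1)
  expect_equal(unname(net1$cpts$X["true"]), 7 / 12, tolerance = 1e-12)

  dc2 <- make_binary_cohort(X = c(rep(TRUE, 5), rep(FALSE, 5)))
  net0 <- fit_parameters(dag_structure(cohort_states(dc2)), dc2,
                         pseudocount = 0)
  expect_equal(unname(net0$cpts$X["true"]), 0.5)
})

test_that("unseen parent configurations: uniform with prior, error without", {
  # parent always TRUE, so the parent = false configuration is unseen
  dc <- make_binary_cohort(P = rep(TRUE, 10),
                           C = c(rep(TRUE, 7), rep(FALSE, 3)))
  s <- dag_structure(cohort_states(dc), parents = list(C = "P"))
  net <- fit_parameters(s, dc, pseudocount = 1)
  expect_equal(unname(net$cpts$C[, "false"]), c(0.5, 0.5))
  expect_equal(unname(net$cpts$C["true", "true"]), 8 / 12, tolerance = 1e-12)
  expect_error(fit_parameters(s, dc, pseudocount = 0),
               class = "svbn_fit_error")
})

test_that("fitted CPTs recover a known network's parameters at scale", {
  truth <- build_preset_network("svr_core")
  spec <- synthetic_spec(truth, 20000, seed = 424)
  dc <- as_discrete_cohort(sample_discrete_cohort(spec))
  fitted <- fit_parameters(truth$structure, dc, pseudocount = 1)
  worst <- 0
  for (v in bn_nodes(truth)) {
    tab_t <- truth$cpts[[v]]
    tab_f <- fitted$cpts[[v]]
    p <- bn_parents(truth)[[v]]
    cfg_prob <- if (length(p)) {
      # probability of each parent configuration under the truth net
      probs <- vapply(seq_len(prod(dim(tab_t)[-1])), function(j) {
        idx <- arrayInd(j, dim(tab_t)[-1])
        ev <- stats::setNames(vapply(seq_along(p), function(i) {
          bn_states(truth)[[p[i]]][idx[i]]
        }, character(1)), p)
        joint_of_evidence(truth, ev)
      }, numeric(1))
      probs
    } else 1
    exp_row <- 20000 * cfg_prob
    exp_cell <- sweep(matrix(tab_t, nrow = dim(tab_t)[1L]), 2L, exp_row, `*`)
    check <- exp_cell >= 100
    err <- abs(matrix(tab_f, nrow = dim(tab_t)[1L]) -
               matrix(tab_t, nrow = dim(tab_t)[1L]))
    if (any(check)) worst <- max(worst, max(err[check]))
  }
  expect_lt(worst, 0.02)
})
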