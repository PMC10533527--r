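#' Learning configuration
#'
#' Bundles the structure/parameter learning settings used wherever a network
#' is (re)learned: the per-node parent cap for the exact search and the
#' Dirichlet pseudocount for parameter fitting.
#'
#' @param max_parents per-node parent cap (default 3).
#' @param pseudocount nonnegative prior weight (default 1, the posterior
#'   mean under a uniform prior; 0 gives pure MLE).
#' @return a `learner_config` object.
#' @export
learner_config <- function(max_parents = 3L, pseudocount = 1) {
  stopifnot(max_parents >= 0L, pseudocount >= 0)
  structure(list(max_parents = as.integer(max_parents),
                 pseudocount = as.numeric(pseudocount)),
            class = "learner_config")
}

#' Learn a network (structure plus parameters) from a discrete cohort
#'
#' Convenience wrapper: [exact_structure_search()] followed by
#' [fit_parameters()].
#'
#' @param cohort a complete [discrete_cohort()].
#' @param learner a [learner_config()].
#' @return a [bn_network()].
#' @export
learn_network <- function(cohort, learner = learner_config()) {
  s <- exact_structure_search(cohort, max_parents = learner$max_parents)
  fit_parameters(s, cohort, pseudocount = learner$pseudocount)
}

#' Risk scenarios
#'
#' A scenario is the (A; B, C, ...) pattern of the relative-risk query: an
#' outcome node with its adverse (or favorable) state, plus one or more risk
#' variables each with its flagged state.
#'
#' @param outcome outcome node name (A).
#' @param outcome_state the outcome state of interest.
#' @param risk named character vector: risk variable -> flagged state, e.g.
#'   `c(dGV = "true", VENT = "prolonged")`.
#' @param label optional human-readable label (defaults to a compact form).
#' @return a `risk_scenario` object.
#' @export
risk_scenario <- function(outcome, outcome_state = "true", risk,
                          label = NULL) {
  if (length(risk) < 1L || is.null(names(risk)) || any(!nzchar(names(risk)))) {
    abort("at least one named risk variable is required",
          class = "svbn_validation_error")
  }
  if (outcome %in% names(risk)) {
    abort("outcome '", outcome, "' cannot also be a risk variable",
          class = "svbn_validation_error")
  }
  if (is.null(label)) {
    label <- paste0(outcome, "=", outcome_state, " | ",
                    paste0(names(risk), "=", risk, collapse = ","))
  }
  structure(list(outcome = outcome, outcome_state = as.character(outcome_state),
                 risk = vapply(risk, as.character, character(1)),
                 label = label),
            class = "risk_scenario")
}

#' @export
print.risk_scenario <- function(x, ...) {
  cat("<risk_scenario> ", x$label, "\n", sep = "")
  invisible(x)
}

# The complement of a state in a binary node's state set.
other_state <- function(net, v, state) {
  st <- bn_states(net)[[v]]
  if (length(st) != 2L) {
    abort("risk variable '", v, "' is not binary; cannot form the ",
          "all-complement arm", class = "svbn_validation_error")
  }
  setdiff(st, state)
}

check_scenario <- function(net, scenario) {
  stopifnot(inherits(scenario, "risk_scenario"))
  nodes <- bn_nodes(net)
  for (v in c(scenario$outcome, names(scenario$risk))) {
    if (!v %in% nodes) {
      abort("scenario names unknown node '", v, "'",
            class = "svbn_validation_error")
    }
  }
  if (!scenario$outcome_state %in% bn_states(net)[[scenario$outcome]]) {
    abort("outcome state '", scenario$outcome_state, "' not in state set",
          class = "svbn_validation_error")
  }
  for (v in names(scenario$risk)) {
    if (!scenario$risk[[v]] %in% bn_states(net)[[v]]) {
      abort("state '", scenario$risk[[v]], "' not in state set of '", v, "'",
            class = "svbn_validation_error")
    }
  }
}

#' Relative-risk ratio from a fitted network
#'
#' The conditional-probability ratio
#' `P(A = a | all risk variables flagged) / P(A = a | all risk variables at
#' their complements)`, with every unlisted variable marginalized. Both arms
#' are exact [query()] results; a zero denominator or inconsistent evidence
#' in either arm is an error naming the arm.
#'
#' @param net a [bn_network()].
#' @param scenario a [risk_scenario()].
#' @return the positive relative-risk ratio (fold change, unitless).
#' @export
relative_risk <- function(net, scenario) {
  check_scenario(net, scenario)
  arm <- function(states, which_arm) {
    res <- tryCatch(
      query(net, scenario$outcome, evidence(states)),
      svbn_inconsistent_evidence = function(e) {
        abort("inconsistent evidence in the ", which_arm, " arm of ",
              scenario$label, class = "svbn_rr_error")
      })
    unname(res$distribution[[scenario$outcome_state]])
  }
  flagged <- scenario$risk
  complement <- vapply(names(scenario$risk), function(v) {
    other_state(net, v, scenario$risk[[v]])
  }, character(1))
  num <- arm(flagged, "flagged")
  den <- arm(complement, "complement")
  if (den == 0) {
    abort("relative risk undefined: complement arm has probability 0",
          class = "svbn_rr_error")
  }
  num / den
}

# Shared bootstrap machinery: resampled row indices depend only on
# (seed, replicate), so every scenario sees the same replicate stream.
bootstrap_indices <- function(n, seed, b) {
  set.seed(derive_seed(seed, b))
  sample.int(n, n, replace = TRUE)
}

resample_cohort <- function(cohort, idx) {
  out <- cohort[idx, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("states", "rules", "flags")] <-
    attributes(cohort)[c("states", "rules", "flags")]
  class(out) <- class(cohort)
  out
}

#' Bootstrap percentile confidence interval for a relative risk
#'
#' The point estimate comes from the network learned on the full cohort.
#' Each bootstrap replicate resamples rows with replacement to the original
#' N, relearns structure AND parameters, and recomputes the relative risk;
#' replicates with an undefined ratio are discarded and counted. The
#' interval is the 5th/95th percentile of the surviving replicate ratios
#' (a 90% percentile interval, reported as the 5 and 95% confidence bounds).
#' Fully reproducible from `seed`; extending `n_boot` under the same seed
#' leaves earlier replicates unchanged.
#'
#' @param cohort a complete [discrete_cohort()].
#' @param scenario a [risk_scenario()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed (recorded in the result).
#' @param learner a [learner_config()].
#' @return a `risk_estimate`: `scenario`, `rr`, `ci_lo`, `ci_hi`, `n_boot`,
#'   `n_failed`, `seed`, and the replicate ratios in `boot_rr`.
#' @export
bootstrap_ci <- function(cohort, scenario, n_boot = 1000L, seed,
                         learner = learner_config()) {
  if (n_boot < 1L) abort("n_boot must be >= 1", class = "svbn_validation_error")
  ests <- scenario_battery(cohort, list(scenario), n_boot = n_boot,
                           seed = seed, learner = learner)
  ests[[1L]]
}

boot_quantiles <- function(x) {
  stats::quantile(x, probs = c(0.05, 0.95), names = FALSE, type = 7)
}

#' Battery of risk scenarios with a shared bootstrap stream
#'
#' Evaluates every scenario against the same full-data network and the same
#' bootstrap replicate networks (identical resampled row indices across
#' scenarios), so the estimates are directly comparable — the structure used
#' to report synergy between single risk factors and their combination.
#' Scenarios that fail individually are returned as error records (with the
#' scenario index) without stopping the battery.
#'
#' @inheritParams bootstrap_ci
#' @param scenarios nonempty list of [risk_scenario()]s.
#' @return list of `risk_estimate` objects (or `risk_error` records), in
#'   input order.
#' @export
scenario_battery <- function(cohort, scenarios, n_boot = 1000L, seed,
                             learner = learner_config()) {
  if (!length(scenarios)) abort("no scenarios", class = "svbn_validation_error")
  if (missing(seed) || is.null(seed)) {
    abort("seed is required for the bootstrap", class = "svbn_validation_error")
  }
  if (n_boot < 1L) abort("n_boot must be >= 1", class = "svbn_validation_error")
  k <- length(scenarios)
  full_net <- learn_network(cohort, learner)
  point <- vector("list", k)
  for (i in seq_len(k)) {
    point[[i]] <- tryCatch(relative_risk(full_net, scenarios[[i]]),
                           svbn_error = function(e) e)
  }
  boot <- matrix(NA_real_, nrow = n_boot, ncol = k)
  n <- nrow(cohort)
  for (b in seq_len(n_boot)) {
    idx <- bootstrap_indices(n, seed, b)
    rep_net <- learn_network(resample_cohort(cohort, idx), learner)
    for (i in seq_len(k)) {
      if (inherits(point[[i]], "condition")) next
      boot[b, i] <- tryCatch(relative_risk(rep_net, scenarios[[i]]),
                             svbn_error = function(e) NA_real_)
    }
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    if (inherits(point[[i]], "condition")) {
      out[[i]] <- structure(list(scenario = scenarios[[i]], index = i,
                                 message = conditionMessage(point[[i]])),
                            class = "risk_error")
      next
    }
    ok <- boot[, i][!is.na(boot[, i])]
    if (!length(ok)) {
      out[[i]] <- structure(list(scenario = scenarios[[i]], index = i,
                                 message = "all bootstrap replicates failed"),
                            class = "risk_error")
      next
    }
    ci <- boot_quantiles(ok)
    out[[i]] <- structure(list(scenario = scenarios[[i]],
                               rr = point[[i]],
                               ci_lo = ci[1L], ci_hi = ci[2L],
                               n_boot = as.integer(n_boot),
                               n_failed = as.integer(n_boot - length(ok)),
                               seed = seed, boot_rr = boot[, i]),
                          class = "risk_estimate")
  }
  out
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("<risk_estimate> %s\n  RR %.3f [%.3f, %.3f] (5-95%% bootstrap, %d reps, %d failed)\n",
              x$scenario$label, x$rr, x$ci_lo, x$ci_hi, x$n_boot, x$n_failed))
  invisible(x)
}

#' Forest-plot table from a scenario battery
#'
#' Flattens a list of risk estimates into a plot-ready data.frame (one row
#' per scenario: label, rr, ci_lo, ci_hi, n_boot, n_failed); failed
#' scenarios appear with `NA` estimates.
#'
#' @param estimates list returned by [scenario_battery()].
#' @return a data.frame.
#' @export
forest_table <- function(estimates) {
  rows <- lapply(estimates, function(e) {
    if (inherits(e, "risk_error")) {
      data.frame(label = e$scenario$label, rr = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, n_boot = NA_integer_,
                 n_failed = NA_integer_, error = e$message,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = e$scenario$label, rr = e$rr, ci_lo = e$ci_lo,
                 ci_hi = e$ci_hi, n_boot = e$n_boot, n_failed = e$n_failed,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
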