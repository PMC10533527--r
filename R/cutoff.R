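#' Area under the ROC curve
#'
#' The probability that a uniformly random positive's score exceeds a random
#' negative's, with ties counted 1/2 (the Mann-Whitney identity:
#' `AUC = U / (n1 * n2)`); invariant under strictly increasing transforms of
#' the scores. Computed via \pkg{pROC}.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector of the same length; both classes
#'   must be present.
#' @return the AUC, a fraction in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length",
          class = "svbn_validation_error")
  }
  if (anyNA(scores) || anyNA(labels)) {
    abort("missing values in scores or labels", class = "svbn_validation_error")
  }
  if (length(unique(labels)) < 2L) {
    abort("AUC undefined: labels contain a single class",
          class = "svbn_single_class_error")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Per-subject conditional probability of an outcome state
#'
#' For each subject, the exact posterior probability that `target` takes its
#' flagged state given the subject's observed states on every other cohort
#' column — the score the cutoff grid search feeds into the ROC. Identical
#' covariate rows receive identical scores (queries are collapsed over
#' unique patterns).
#'
#' @param net a [bn_network()] whose nodes cover the cohort columns.
#' @param cohort a [discrete_cohort()].
#' @param target node / column name to score.
#' @param flag_state the target state scored; defaults to the cohort's
#'   recorded flagged state for `target`.
#' @return numeric vector of probabilities, one per cohort row.
#' @export
score_subjects <- function(net, cohort, target, flag_state = NULL) {
  states <- cohort_states(cohort)
  if (!target %in% names(states)) {
    abort("target '", target, "' not in cohort", class = "svbn_validation_error")
  }
  if (is.null(flag_state)) {
    flag_state <- cohort_flags(cohort)[[target]] %||% "true"
  }
  covars <- setdiff(names(states), target)
  miss <- setdiff(c(target, covars), bn_nodes(net))
  if (length(miss)) {
    abort("cohort column(s) missing from the network: ",
          paste(miss, collapse = ", "), class = "svbn_validation_error")
  }
  net_states <- bn_states(net)
  for (v in covars) {
    bad <- setdiff(unique(as.character(cohort[[v]])), net_states[[v]])
    if (length(bad)) {
      subj <- cohort$subject_id[match(bad[1L], as.character(cohort[[v]]))]
      abort("state '", bad[1L], "' of variable '", v, "' (subject ", subj,
            ") not in the network's state set", class = "svbn_validation_error")
    }
  }
  if (!length(covars)) {
    res <- query(net, target)
    return(rep(unname(res$distribution[[flag_state]]), nrow(cohort)))
  }
  pattern <- do.call(paste, c(lapply(covars, function(v) {
    as.character(cohort[[v]])
  }), sep = "\x01"))
  uniq <- !duplicated(pattern)
  u_rows <- which(uniq)
  u_scores <- vapply(u_rows, function(i) {
    ev <- evidence(stats::setNames(
      vapply(covars, function(v) as.character(cohort[[v]][i]), character(1)),
      covars))
    unname(query(net, target, ev)$distribution[[flag_state]])
  }, numeric(1))
  u_scores[match(pattern, pattern[u_rows])]
}

#' Select an outcome cutoff by ROC-AUC grid search
#'
#' For each candidate cutoff the continuous target is dichotomized, the
#' network is relearned (structure and parameters) on the resulting discrete
#' cohort, every subject is scored by [score_subjects()], and the AUC of the
#' scores against the induced labels is computed. The returned optimum is
#' the AUC argmax; ties are broken toward the more balanced class split,
#' then toward the smaller cutoff. Candidates inducing an empty class, or a
#' class smaller than `min_class_size`, are skipped with a reason.
#'
#' Scoring reuses the data the network was fit on (no cross-validation), so
#' the AUCs are optimistic in the usual in-sample sense.
#'
#' @param table a [cohort_table()] whose non-target analysis columns are all
#'   binary and complete.
#' @param target continuous column to dichotomize.
#' @param grid numeric vector of candidate cutoffs; `NULL` (default) uses
#'   integer steps over the observed target range.
#' @param direction comparator (`"le"`, `"lt"`, `"gt"`) defining the flagged
#'   class, as in [threshold_rule()].
#' @param learner a [learner_config()] used at every candidate.
#' @param min_class_size minimum subjects per induced class (default 5).
#' @param exclude columns to leave out of the analysis (e.g. a generator's
#'   latent-class column).
#' @param flag_label,complement_label labels for the induced states.
#' @return a `cutoff_search_result`: `target`, `grid`, `auc_by_cutoff`,
#'   `optimal_cutoff`, `optimal_auc`, `skipped` (data.frame), `direction`,
#'   `rule` (the optimal [threshold_rule()]).
#' @export
optimize_cutoff <- function(table, target, grid = NULL,
                            direction = c("le", "lt", "gt"),
                            learner = learner_config(),
                            min_class_size = 5L,
                            exclude = character(),
                            flag_label = "flagged",
                            complement_label = "not_flagged") {
  direction <- match.arg(direction)
  kinds <- cohort_kinds(table)
  if (is.null(kinds[[target]]) || kinds[[target]] != "continuous") {
    abort("target '", target, "' must be a continuous column",
          class = "svbn_validation_error")
  }
  vals <- table[[target]]
  if (anyNA(vals)) {
    abort("missing cells in target; apply filter_complete_cases() first",
          class = "svbn_validation_error")
  }
  if (is.null(grid)) grid <- seq(ceiling(min(vals)), floor(max(vals)), by = 1)
  if (!length(grid) || any(!is.finite(grid))) {
    abort("grid must be nonempty and finite", class = "svbn_validation_error")
  }
  if (min_class_size < 1L) min_class_size <- 1L
  covars <- setdiff(names(kinds)[kinds == "binary"], exclude)
  if (!length(covars)) {
    abort("no binary covariates available", class = "svbn_validation_error")
  }
  n <- nrow(table)
  auc_by_cutoff <- stats::setNames(rep(NA_real_, length(grid)),
                                   format(grid, trim = TRUE))
  balance <- rep(NA_real_, length(grid))
  skipped <- data.frame(cutoff = numeric(), reason = character(),
                        stringsAsFactors = FALSE)
  for (j in seq_along(grid)) {
    cand <- grid[j]
    rule <- threshold_rule(target, cand, direction, flag_label,
                           complement_label)
    flag <- apply_rule_values(rule, vals)
    n_flag <- sum(flag)
    if (n_flag == 0L || n_flag == n) {
      skipped <- rbind(skipped, data.frame(cutoff = cand,
                                           reason = "degenerate class"))
      next
    }
    if (min(n_flag, n - n_flag) < min_class_size) {
      skipped <- rbind(skipped,
                       data.frame(cutoff = cand,
                                  reason = "class below min_class_size"))
      next
    }
    dc <- apply_thresholds(table, list(rule), keep = c(target, covars))
    net <- learn_network(dc, learner)
    scores <- score_subjects(net, dc, target, flag_state = flag_label)
    auc_by_cutoff[j] <- roc_auc(scores, flag)
    balance[j] <- abs(n_flag - n / 2)
  }
  evaluated <- which(!is.na(auc_by_cutoff))
  if (!length(evaluated)) {
    abort("every candidate cutoff was skipped", class = "svbn_validation_error")
  }
  best_auc <- max(auc_by_cutoff[evaluated])
  cand_best <- evaluated[auc_by_cutoff[evaluated] == best_auc]
  cand_best <- cand_best[balance[cand_best] == min(balance[cand_best])]
  j_best <- cand_best[which.min(grid[cand_best])]
  structure(list(target = target, grid = grid,
                 auc_by_cutoff = auc_by_cutoff,
                 optimal_cutoff = grid[j_best],
                 optimal_auc = unname(auc_by_cutoff[j_best]),
                 skipped = skipped, direction = direction,
                 rule = threshold_rule(target, grid[j_best], direction,
                                       flag_label, complement_label)),
            class = "cutoff_search_result")
}

#' @export
print.cutoff_search_result <- function(x, ...) {
  cat(sprintf("<cutoff_search_result> %s: optimal cutoff %g (AUC %.3f); %d/%d candidates evaluated, %d skipped\n",
              x$target, x$optimal_cutoff, x$optimal_auc,
              sum(!is.na(x$auc_by_cutoff)), length(x$grid), nrow(x$skipped)))
  invisible(x)
}
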