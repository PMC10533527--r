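#' Threshold rules for dichotomization
#'
#' A threshold rule turns a continuous variable into a binary one: values
#' satisfying `value <cmp> cutoff` receive `flag_label`, the rest
#' `complement_label`. Comparator semantics are literal: `"le"` flags
#' `value <= cutoff`, `"lt"` flags `value < cutoff`, `"gt"` flags
#' `value > cutoff`.
#'
#' @param variable continuous column name.
#' @param cutoff finite numeric cutoff, in the variable's units.
#' @param direction one of `"le"`, `"lt"`, `"gt"`.
#' @param flag_label,complement_label distinct state labels.
#' @return a `threshold_rule` object.
#' @seealso [adverse_threshold_rules()], [favorable_threshold_rules()],
#'   [clinical_threshold_rules()]
#' @export
threshold_rule <- function(variable, cutoff, direction = c("le", "lt", "gt"),
                           flag_label = "flagged",
                           complement_label = "not_flagged") {
  direction <- match.arg(direction)
  if (!is.finite(cutoff)) abort("cutoff must be finite", class = "svbn_validation_error")
  if (identical(flag_label, complement_label)) {
    abort("flag and complement labels must differ", class = "svbn_validation_error")
  }
  structure(list(variable = variable, cutoff = as.numeric(cutoff),
                 direction = direction, flag_label = flag_label,
                 complement_label = complement_label),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cmp <- c(le = "<=", lt = "<", gt = ">")[[x$direction]]
  cat(sprintf("<threshold_rule> %s %s %g -> '%s' (else '%s')\n",
              x$variable, cmp, x$cutoff, x$flag_label, x$complement_label))
  invisible(x)
}

apply_rule_values <- function(rule, values) {
  switch(rule$direction,
         le = values <= rule$cutoff,
         lt = values < rule$cutoff,
         gt = values > rule$cutoff)
}

#' Published outcome and clinical cutoffs
#'
#' `adverse_threshold_rules()` flags adverse outcomes: MDI <= 70 and
#' PDI <= 70 (two SD below the Bayley-II population mean) and length-for-age
#' z-score <= -1.6. `favorable_threshold_rules()` flags favorable outcomes:
#' MDI > 100, PDI > 100, LAZ > 0. `clinical_threshold_rules()` carries the
#' previously published clinical/demographic cutoffs: birthweight < 2500 g
#' (low), post-Stage-I mechanical ventilation > 7 days (prolonged),
#' gestational age < 37 weeks (preterm), and US-census socioeconomic score
#' < -0.3 (low). Adverse-mode and favorable-mode discretizations are separate
#' runs producing separate discrete cohorts; no three-state encoding is used.
#'
#' @param mdi,pdi,laz column names of the outcome variables.
#' @return list of [threshold_rule()] objects.
#' @export
adverse_threshold_rules <- function(mdi = "MDI", pdi = "PDI", laz = "LAZ") {
  list(threshold_rule(mdi, 70, "le", "low", "not_low"),
       threshold_rule(pdi, 70, "le", "low", "not_low"),
       threshold_rule(laz, -1.6, "le", "low", "not_low"))
}

#' @rdname adverse_threshold_rules
#' @export
favorable_threshold_rules <- function(mdi = "MDI", pdi = "PDI", laz = "LAZ") {
  list(threshold_rule(mdi, 100, "gt", "normal", "not_normal"),
       threshold_rule(pdi, 100, "gt", "normal", "not_normal"),
       threshold_rule(laz, 0, "gt", "normal", "not_normal"))
}

#' @rdname adverse_threshold_rules
#' @param bwt,vent,ga,ses column names of the clinical variables.
#' @export
clinical_threshold_rules <- function(bwt = "BWT", vent = "VENT", ga = "GA",
                                     ses = "SES") {
  list(threshold_rule(bwt, 2500, "lt", "low", "not_low"),
       threshold_rule(vent, 7, "gt", "prolonged", "not_prolonged"),
       threshold_rule(ga, 37, "lt", "preterm", "term"),
       threshold_rule(ses, -0.3, "lt", "low", "not_low"))
}

#' Discrete cohorts
#'
#' A discrete cohort is a complete (no missing cells) subject-by-variable
#' table whose columns are categorical with explicit finite state sets —
#' binary in all presets. It records, as provenance, the threshold rules
#' applied and the flagged state of each thresholded column.
#'
#' @param data data.frame of factor columns (plus `subject_id`).
#' @param states named list: column -> character vector of states.
#' @param rules list of the [threshold_rule()]s applied (provenance).
#' @param flags named character vector: column -> flagged state, where known.
#' @return an object of class `discrete_cohort`.
#' @export
discrete_cohort <- function(data, states, rules = list(), flags = character()) {
  stopifnot(is.data.frame(data), "subject_id" %in% names(data))
  vars <- names(states)
  if (!all(vars %in% names(data))) {
    abort("state set declared for absent column", class = "svbn_schema_error")
  }
  out <- data.frame(subject_id = as.character(data$subject_id),
                    stringsAsFactors = FALSE)
  for (v in vars) {
    col <- as.character(data[[v]])
    if (anyNA(col) || anyNA(data[[v]])) {
      abort("missing cells in column '", v,
            "'; apply filter_complete_cases() first",
            class = "svbn_validation_error")
    }
    bad <- setdiff(unique(col), states[[v]])
    if (length(bad)) {
      abort("value(s) outside declared state set in '", v, "': ",
            paste(bad, collapse = ", "), class = "svbn_validation_error")
    }
    out[[v]] <- factor(col, levels = states[[v]])
  }
  structure(out, states = states, rules = rules, flags = flags,
            class = c("discrete_cohort", "data.frame"))
}

#' @export
print.discrete_cohort <- function(x, ...) {
  cat(sprintf("<discrete_cohort> %d subjects, %d variables\n",
              nrow(x), length(attr(x, "states"))))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' State sets of a discrete cohort
#' @param cohort a `discrete_cohort`.
#' @return named list of character state vectors.
#' @export
cohort_states <- function(cohort) attr(cohort, "states")

#' Flagged states recorded for a discrete cohort
#' @param cohort a `discrete_cohort`.
#' @return named character vector (column -> flagged state).
#' @export
cohort_flags <- function(cohort) attr(cohort, "flags")

#' Dichotomize continuous cohort variables at fixed thresholds
#'
#' Applies one [threshold_rule()] per continuous variable and passes binary
#' columns through unchanged (states `"false"`/`"true"`, `"true"` flagged).
#' All named variables must be complete; filter with
#' [filter_complete_cases()] first. A rule naming a binary or absent column
#' is an error — rules are never silently re-applied to an already binary
#' column.
#'
#' @param table a `cohort_table`.
#' @param rules list of [threshold_rule()]s, at most one per variable.
#' @param keep optional character vector restricting which columns enter the
#'   discrete cohort; defaults to the rule variables plus all binary columns.
#' @return a [discrete_cohort()] whose provenance records `rules`.
#' @export
apply_thresholds <- function(table, rules, keep = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (inherits(rules, "threshold_rule")) rules <- list(rules)
  kinds <- cohort_kinds(table)
  rule_vars <- vapply(rules, `[[`, character(1), "variable")
  if (anyDuplicated(rule_vars)) {
    abort("more than one rule for variable '",
          rule_vars[duplicated(rule_vars)][1L], "'",
          class = "svbn_validation_error")
  }
  for (rv in rule_vars) {
    if (!rv %in% names(kinds)) {
      abort("rule on absent column '", rv, "'", class = "svbn_validation_error")
    }
    if (kinds[[rv]] != "continuous") {
      abort("rule on binary column '", rv, "'; already dichotomized",
            class = "svbn_validation_error")
    }
  }
  if (is.null(keep)) keep <- c(rule_vars, names(kinds)[kinds == "binary"])
  keep <- unique(keep)

  data <- data.frame(subject_id = table$subject_id, stringsAsFactors = FALSE)
  states <- list()
  flags <- character()
  for (v in keep) {
    if (v %in% rule_vars) {
      rule <- rules[[match(v, rule_vars)]]
      vals <- table[[v]]
      if (anyNA(vals)) {
        abort("missing cells in column '", v,
              "'; apply filter_complete_cases() first",
              class = "svbn_validation_error")
      }
      hit <- apply_rule_values(rule, vals)
      data[[v]] <- ifelse(hit, rule$flag_label, rule$complement_label)
      states[[v]] <- c(rule$complement_label, rule$flag_label)
      flags[[v]] <- rule$flag_label
    } else {
      vals <- table[[v]]
      if (anyNA(vals)) {
        abort("missing cells in column '", v,
              "'; apply filter_complete_cases() first",
              class = "svbn_validation_error")
      }
      data[[v]] <- ifelse(vals, "true", "false")
      states[[v]] <- c("false", "true")
      flags[[v]] <- "true"
    }
  }
  discrete_cohort(data, states = states, rules = rules, flags = flags)
}

#' Convert an all-binary cohort table to a discrete cohort
#'
#' Used when every analysis variable is already binary (e.g. sampled from a
#' ground-truth network); binary columns map to states `"false"`/`"true"`
#' with `"true"` flagged.
#'
#' @param table a `cohort_table` whose selected columns are all binary.
#' @param variables columns to include; default all binary columns.
#' @return a [discrete_cohort()].
#' @export
as_discrete_cohort <- function(table, variables = NULL) {
  kinds <- cohort_kinds(table)
  if (is.null(variables)) variables <- names(kinds)[kinds == "binary"]
  nonbin <- variables[kinds[variables] != "binary"]
  if (length(nonbin)) {
    abort("non-binary column(s): ", paste(nonbin, collapse = ", "),
          class = "svbn_validation_error")
  }
  apply_thresholds(table, rules = list(), keep = variables)
}

#' Write / read a discrete cohort as TSV plus a provenance sidecar
#'
#' The TSV holds the cells; `<path>.json` records the state sets, flagged
#' states, and the threshold rules applied, so a round trip reproduces the
#' cohort bit-exactly.
#'
#' @param cohort a `discrete_cohort`.
#' @param path output TSV path.
#' @return `write_discrete_cohort` returns `path` invisibly;
#'   `read_discrete_cohort` returns the reconstructed `discrete_cohort`.
#' @export
write_discrete_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "discrete_cohort"))
  df <- as.data.frame(cohort)
  df[] <- lapply(df, as.character)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    states = cohort_states(cohort),
    flags = as.list(cohort_flags(cohort)),
    rules = lapply(attr(cohort, "rules"), unclass)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_discrete_cohort
#' @export
read_discrete_cohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, stringsAsFactors = FALSE)
  sc <- jsonlite::read_json(paste0(path, ".json"))
  states <- lapply(sc$states, function(s) unlist(s, use.names = FALSE))
  flags <- unlist(sc$flags)
  rules <- lapply(sc$rules, function(r) {
    threshold_rule(r$variable, r$cutoff, r$direction, r$flag_label,
                   r$complement_label)
  })
  discrete_cohort(df, states = states, rules = rules,
                  flags = if (is.null(flags)) character() else flags)
}
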