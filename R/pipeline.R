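# Reproducible pipeline: simulate/read -> discretize -> learn -> risk /
# cutoff search / group comparisons, with a manifest of every artifact.

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

config_from_yaml <- function(path) yaml::read_yaml(path)

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- config_from_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML path",
                              class = "svbn_config_error")
  if (is.null(config$out_dir)) {
    abort("config field 'out_dir' is required", class = "svbn_config_error")
  }
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (!has_sim && !has_input) {
    abort("config needs either 'simulate' or 'input'",
          class = "svbn_config_error")
  }
  n_boot <- config$n_boot %||% 0L
  if ((has_sim || n_boot > 0L) && is.null(config$seed)) {
    abort("config field 'seed' is required for stochastic stages",
          class = "svbn_config_error")
  }
  config$n_boot <- n_boot
  config$learner <- learner_config(
    max_parents = config$learner$max_parents %||% 3L,
    pseudocount = config$learner$pseudocount %||% 1)
  config
}

parse_scenarios <- function(scenarios) {
  lapply(scenarios, function(s) {
    risk_scenario(outcome = s$outcome,
                  outcome_state = s$outcome_state %||% "true",
                  risk = unlist(s$risk),
                  label = s$label %||% NULL)
  })
}

parse_rules <- function(rules) {
  lapply(rules, function(r) {
    threshold_rule(r$variable, r$cutoff, r$direction,
                   r$flag_label %||% "flagged",
                   r$complement_label %||% "not_flagged")
  })
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (synthetic simulation from a
#' preset truth network, or reading a TSV/CSV), complete-case filtering and
#' discretization, exact structure learning plus parameter fitting, then any
#' requested cutoff search, risk-scenario battery, and group comparisons.
#' Every artifact is written under `out_dir` and listed, with an MD5
#' checksum, in `manifest.json` alongside the config hash and package
#' version. Identical config and seed produce byte-identical outputs; a
#' stage failure aborts with the stage name after writing an
#' incomplete-status manifest.
#'
#' Config fields (list or YAML path): `out_dir`; `simulate` (`preset`, `n`)
#' or `input` (`path`, `schema`); `seed` (required for any stochastic
#' stage); `thresholds` (list of rule specs); `complete_cases` (variables);
#' `learner` (`max_parents`, `pseudocount`); `cutoff_search` (`target`,
#' `direction`, optional `grid`, `min_class_size`, `exclude`); `scenarios`
#' (each: `outcome`, `outcome_state`, `risk` map, optional `label`);
#' `n_boot`; `comparisons` (each: `by`, `value`).
#'
#' @param config list or YAML file path.
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  manifest_path <- file.path(out_dir, "manifest.json")
  stage <- "init"
  write_manifest <- function(status) {
    files <- file.path(out_dir, artifacts)
    manifest <- list(
      status = status,
      package_version = as.character(utils::packageVersion("svbn")),
      config_hash = config_hash(config),
      seed = config$seed,
      artifacts = lapply(seq_along(artifacts), function(i) {
        list(file = artifacts[i], md5 = unname(tools::md5sum(files[i])))
      }))
    write_json_artifact(manifest, manifest_path)
    manifest
  }
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      write_manifest("incomplete")
      abort("pipeline stage '", name, "' failed: ", conditionMessage(e),
            class = "svbn_pipeline_error")
    })
  }

  table <- run_stage("acquire", {
    if (!is.null(config$simulate)) {
      truth <- build_preset_network(config$simulate$preset)
      spec <- synthetic_spec(truth, n_subjects = config$simulate$n,
                             seed = config$seed)
      tbl <- sample_discrete_cohort(spec)
      write_bn_json(truth, file.path(out_dir, "truth_network.json"))
      artifacts <- c(artifacts, "truth_network.json")
      tbl
    } else {
      schema <- unlist(config$input$schema)
      read_cohort(config$input$path, schema = schema,
                  sep = config$input$sep %||% NULL)
    }
  })

  dc <- run_stage("discretize", {
    kinds <- cohort_kinds(table)
    vars <- config$complete_cases %||% names(kinds)
    tbl <- filter_complete_cases(table, vars)
    rules <- parse_rules(config$thresholds %||% list())
    dcoh <- if (length(rules)) apply_thresholds(tbl, rules)
            else as_discrete_cohort(tbl)
    write_discrete_cohort(dcoh, file.path(out_dir, "cohort.tsv"))
    artifacts <- c(artifacts, "cohort.tsv", "cohort.tsv.json")
    dcoh
  })

  net <- run_stage("learn", {
    nt <- learn_network(dc, config$learner)
    write_bn_json(nt, file.path(out_dir, "network.json"))
    artifacts <- c(artifacts, "network.json")
    nt
  })

  if (!is.null(config$cutoff_search)) {
    run_stage("cutoff_search", {
      cs <- config$cutoff_search
      res <- optimize_cutoff(table, target = cs$target,
                             grid = cs$grid %||% NULL,
                             direction = cs$direction %||% "le",
                             learner = config$learner,
                             min_class_size = cs$min_class_size %||% 5L,
                             exclude = cs$exclude %||% character())
      out <- list(target = res$target, grid = res$grid,
                  auc_by_cutoff = as.list(res$auc_by_cutoff),
                  optimal_cutoff = res$optimal_cutoff,
                  optimal_auc = res$optimal_auc,
                  skipped = res$skipped)
      write_json_artifact(out, file.path(out_dir, "cutoff_search.json"))
      artifacts <- c(artifacts, "cutoff_search.json")
    })
  }

  if (length(config$scenarios %||% list())) {
    run_stage("risk", {
      scenarios <- parse_scenarios(config$scenarios)
      ests <- scenario_battery(dc, scenarios, n_boot = config$n_boot,
                               seed = config$seed, learner = config$learner)
      ft <- forest_table(ests)
      out <- lapply(ests, function(e) {
        if (inherits(e, "risk_error")) {
          list(label = e$scenario$label, error = e$message, index = e$index)
        } else {
          list(label = e$scenario$label, rr = e$rr, ci_lo = e$ci_lo,
               ci_hi = e$ci_hi, n_boot = e$n_boot, n_failed = e$n_failed,
               seed = e$seed)
        }
      })
      write_json_artifact(out, file.path(out_dir, "risk.json"))
      utils::write.table(ft, file.path(out_dir, "forest.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, "risk.json", "forest.tsv")
    })
  }

  if (length(config$comparisons %||% list())) {
    run_stage("group_stats", {
      res <- lapply(config$comparisons, function(cmp) {
        gc <- compare_groups(table, by = cmp$by, value = cmp$value)
        list(by = cmp$by, value = cmp$value, u_statistic = gc$u_statistic,
             n1 = gc$n1, n2 = gc$n2, p_value = gc$p_value,
             method = gc$method)
      })
      p <- vapply(res, `[[`, numeric(1), "p_value")
      adj <- bonferroni_adjust(p)
      for (i in seq_along(res)) res[[i]]$p_adjusted <- adj[i]
      write_json_artifact(res, file.path(out_dir, "group_comparisons.json"))
      artifacts <- c(artifacts, "group_comparisons.json")
    })
  }

  manifest <- write_manifest("complete")
  invisible(manifest)
}
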