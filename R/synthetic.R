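# Synthetic cohorts with known ground truth. The preset networks below are
# fixed constants of the package: the dGV and SYNDR prevalences (0.44 and
# 0.14) match the reported cohort, the remaining CPTs are chosen once to
# give clearly detectable dependencies and a supra-multiplicative outcome
# interaction. Every number is printed in the function documentation and the
# methods vignette so downstream results are reproducible.

# rbind(1 - p, p) flattened: child states c("false","true"), configurations
# in column-major order over the (name-sorted) parents.
bin_cpt <- function(p_true) as.numeric(rbind(1 - p_true, p_true))

svr_core_def <- function() {
  st <- c("false", "true")
  list(
    states = list(dGV = st, SYNDR = st, SEX = st, PDI_low = st,
                  MDI_low = st, LAZ_low = st),
    parents = list(PDI_low = c("SYNDR", "dGV"),
                   MDI_low = c("PDI_low", "dGV"),
                   LAZ_low = "SYNDR"),
    cpts = list(
      dGV = bin_cpt(0.44),
      SYNDR = bin_cpt(0.14),
      SEX = bin_cpt(0.45),                     # true = female
      # configs over (SYNDR, dGV): ff, tf, ft, tt
      PDI_low = bin_cpt(c(0.05, 0.35, 0.30, 0.60)),
      # configs over (PDI_low, dGV): ff, tf, ft, tt — supra-multiplicative
      MDI_low = bin_cpt(c(0.02, 0.30, 0.10, 0.85)),
      LAZ_low = bin_cpt(c(0.12, 0.35))
    ))
}

svr_clinical_def <- function() {
  core <- svr_core_def()
  st <- c("false", "true")
  states <- c(core$states,
              list(PRETERM = st, BWT_low = st, VENT_prolonged = st,
                   SES_low = st))
  parents <- core$parents
  parents$BWT_low <- "PRETERM"
  parents$VENT_prolonged <- "BWT_low"
  parents$MDI_low <- c("PDI_low", "VENT_prolonged", "dGV")
  parents$LAZ_low <- c("PRETERM", "SYNDR")
  cpts <- core$cpts
  cpts$PRETERM <- bin_cpt(0.20)
  cpts$BWT_low <- bin_cpt(c(0.08, 0.55))
  cpts$VENT_prolonged <- bin_cpt(c(0.22, 0.50))
  cpts$SES_low <- bin_cpt(0.35)
  # configs over (PDI_low, VENT_prolonged, dGV), PDI_low fastest
  cpts$MDI_low <- bin_cpt(c(0.02, 0.35, 0.10, 0.70,
                            0.06, 0.65, 0.22, 0.90))
  # configs over (PRETERM, SYNDR)
  cpts$LAZ_low <- bin_cpt(c(0.10, 0.28, 0.30, 0.55))
  list(states = states, parents = parents, cpts = cpts)
}

#' Preset ground-truth networks
#'
#' Fixed networks used across the test suite and the synthetic generator.
#' All nodes are binary with states `"false"`/`"true"` (for `SEX`, `"true"`
#' denotes female).
#'
#' * `svr_core` — nodes `dGV`, `SYNDR`, `SEX`, `MDI_low`, `PDI_low`,
#'   `LAZ_low`. Marginals P(dGV) = 0.44 and P(SYNDR) = 0.14 match the
#'   reported cohort prevalences. CPTs (probability of `"true"`):
#'   `PDI_low | SYNDR, dGV` = 0.05 / 0.35 (SYNDR) / 0.30 (dGV) / 0.60 (both);
#'   `MDI_low | PDI_low, dGV` = 0.02 / 0.30 (PDI) / 0.10 (dGV) / 0.85 (both,
#'   a supra-multiplicative interaction); `LAZ_low | SYNDR` = 0.12 / 0.35;
#'   P(SEX = true) = 0.45, isolated (d-separated from every outcome).
#' * `svr_clinical` — `svr_core` plus `PRETERM` (0.20),
#'   `BWT_low | PRETERM` = 0.08 / 0.55, `VENT_prolonged | BWT_low` =
#'   0.22 / 0.50, `SES_low` (0.35, isolated);
#'   `MDI_low | PDI_low, VENT_prolonged, dGV` = 0.02 / 0.35 / 0.10 / 0.70 /
#'   0.06 / 0.65 / 0.22 / 0.90 (configurations with `PDI_low` varying
#'   fastest, then `VENT_prolonged`, then `dGV`);
#'   `LAZ_low | PRETERM, SYNDR` = 0.10 / 0.28 / 0.30 / 0.55.
#' * `chain_test` — `A -> B -> C`, P(A) = 0.5, P(B|A) = 0.9 / 0.1,
#'   P(C|B) = 0.9 / 0.1.
#' * `collider_test` — `A -> C <- B`, P(A) = P(B) = 0.5,
#'   P(C = true | A, B) = 0.9 if A = B = true else 0.1.
#' * `independent_test` — three independent nodes with P(true) 0.3, 0.5, 0.7.
#'
#' @param preset one of `"svr_core"`, `"svr_clinical"`, `"chain_test"`,
#'   `"collider_test"`, `"independent_test"`.
#' @return a [bn_network()].
#' @export
build_preset_network <- function(preset) {
  st <- c("false", "true")
  def <- switch(preset,
    svr_core = svr_core_def(),
    svr_clinical = svr_clinical_def(),
    chain_test = list(
      states = list(A = st, B = st, C = st),
      parents = list(B = "A", C = "B"),
      cpts = list(A = bin_cpt(0.5), B = bin_cpt(c(0.1, 0.9)),
                  C = bin_cpt(c(0.1, 0.9)))),
    collider_test = list(
      states = list(A = st, B = st, C = st),
      parents = list(C = c("A", "B")),
      cpts = list(A = bin_cpt(0.5), B = bin_cpt(0.5),
                  C = bin_cpt(c(0.1, 0.1, 0.1, 0.9)))),
    independent_test = list(
      states = list(A = st, B = st, C = st),
      parents = list(),
      cpts = list(A = bin_cpt(0.3), B = bin_cpt(0.5), C = bin_cpt(0.7))),
    abort("unknown preset '", preset, "'; available: svr_core, ",
          "svr_clinical, chain_test, collider_test, independent_test",
          class = "svbn_validation_error"))
  bn_network(def$states, def$parents, def$cpts)
}

#' Default Gaussian emission for continuous outcome scores
#'
#' Latent-state mixture used by [sample_continuous_scores()]: subjects whose
#' latent `MDI_low` state is `"true"` emit N(60, 7^2) developmental-index
#' points, the rest N(100, 10^2) — unimodal per class, centered on the
#' Bayley population mean for the unaffected class.
#'
#' @param target latent node the emission attaches to.
#' @param mean_flagged,sd_flagged,mean_complement,sd_complement mixture
#'   parameters in the outcome's units.
#' @return named list suitable for the `continuous_emission` field of
#'   [synthetic_spec()].
#' @export
default_emission <- function(target = "MDI_low", mean_flagged = 60,
                             sd_flagged = 7, mean_complement = 100,
                             sd_complement = 10) {
  out <- list(list(means = c(true = mean_flagged, false = mean_complement),
                   sds = c(true = sd_flagged, false = sd_complement)))
  names(out) <- target
  out
}

#' Synthetic cohort specification
#'
#' Ground-truth network plus sampling parameters: cohort size, seed,
#' optional per-column missingness, and optional per-variable Gaussian
#' emissions for continuous scores.
#'
#' @param truth a [bn_network()] ground truth.
#' @param n_subjects positive integer.
#' @param seed integer RNG seed.
#' @param missing_rate fraction in \[0, 1) applied per designated column.
#' @param missing_vars columns receiving missingness.
#' @param continuous_emission named list (see [default_emission()]).
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(truth, n_subjects, seed, missing_rate = 0,
                           missing_vars = character(),
                           continuous_emission = NULL) {
  stopifnot(inherits(truth, "bn_network"), n_subjects >= 1,
            missing_rate >= 0, missing_rate < 1)
  bad <- setdiff(missing_vars, bn_nodes(truth))
  if (length(bad)) {
    abort("missing_vars not in truth network: ", paste(bad, collapse = ", "),
          class = "svbn_validation_error")
  }
  for (v in names(continuous_emission)) {
    em <- continuous_emission[[v]]
    if (any(em$sds <= 0)) {
      abort("emission standard deviations must be positive",
            class = "svbn_validation_error")
    }
  }
  structure(list(truth = truth, n_subjects = as.integer(n_subjects),
                 seed = seed, missing_rate = missing_rate,
                 missing_vars = missing_vars,
                 continuous_emission = continuous_emission),
            class = "synthetic_spec")
}

# Ancestral sampling of node states (integer codes) from a network.
sample_codes <- function(net, n) {
  states <- bn_states(net)
  ord <- topological_order(bn_parents(net))
  codes <- matrix(0L, nrow = n, ncol = length(ord),
                  dimnames = list(NULL, ord))
  for (v in ord) {
    p <- bn_parents(net)[[v]]
    nc <- length(states[[v]])
    tab <- net$cpts[[v]]
    if (length(p)) {
      cfg <- codes[, p[1L]]
      mult <- length(states[[p[1L]]])
      for (q in p[-1L]) {
        cfg <- cfg + (codes[, q] - 1L) * mult
        mult <- mult * length(states[[q]])
      }
      probmat <- matrix(as.numeric(tab), nrow = nc)
    } else {
      cfg <- rep(1L, n)
      probmat <- matrix(as.numeric(tab), nrow = nc)
    }
    cpm <- apply(probmat, 2L, cumsum)
    u <- stats::runif(n)
    st <- rep(1L, n)
    if (nc > 1L) {
      for (s in seq_len(nc - 1L)) {
        st <- st + as.integer(u > cpm[s, cfg])
      }
    }
    codes[, v] <- st
  }
  codes[, bn_nodes(net), drop = FALSE]
}

#' Sample a discrete cohort from a ground-truth network
#'
#' Ancestral sampling of `n_subjects` rows; missingness is then injected
#' independently per designated column at `missing_rate`. Identical seeds
#' give bit-identical tables. All preset nodes are binary, so the result is
#' a [cohort_table()] of logical columns (state `"true"` maps to `TRUE`).
#'
#' @param spec a [synthetic_spec()].
#' @return a `cohort_table` with subject ids `S1..Sn`.
#' @export
sample_discrete_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  net <- spec$truth
  n <- spec$n_subjects
  set.seed(derive_seed(spec$seed, 1L))
  codes <- sample_codes(net, n)
  states <- bn_states(net)
  df <- data.frame(subject_id = paste0("S", seq_len(n)),
                   stringsAsFactors = FALSE)
  kinds <- character()
  for (v in bn_nodes(net)) {
    if (!identical(states[[v]], c("false", "true"))) {
      abort("non-binary (or non false/true) node '", v,
            "' cannot map to a cohort table", class = "svbn_validation_error")
    }
    df[[v]] <- codes[, v] == 2L
    kinds[[v]] <- "binary"
  }
  if (spec$missing_rate > 0 && length(spec$missing_vars)) {
    for (v in spec$missing_vars) {
      df[[v]][stats::runif(n) < spec$missing_rate] <- NA
    }
  }
  cohort_table(df, kinds = kinds)
}

#' Sample continuous outcome scores around a latent class
#'
#' Draws the full discrete cohort from the truth network, then replaces the
#' target column by a continuous score emitted from the Gaussian component
#' of the subject's latent state (standard deviations floored at 1e-6). The
#' latent state is retained as binary column `latent_<target>` for recovery
#' testing; the continuous column is named after the target with a trailing
#' `_low` stripped (`MDI_low` emits column `MDI`).
#'
#' @param spec a [synthetic_spec()] with a `continuous_emission` entry for
#'   `target`.
#' @param target latent node to emit from.
#' @return a `cohort_table` with the continuous score column, the latent
#'   column, and all other network columns.
#' @export
sample_continuous_scores <- function(spec, target) {
  stopifnot(inherits(spec, "synthetic_spec"))
  em <- spec$continuous_emission[[target]]
  if (is.null(em)) {
    abort("no continuous emission defined for '", target, "'",
          class = "svbn_validation_error")
  }
  tbl <- sample_discrete_cohort(spec)
  latent <- tbl[[target]]
  state <- ifelse(latent, "true", "false")
  sds <- pmax(em$sds, 1e-6)
  score <- stats::rnorm(nrow(tbl), mean = em$means[state], sd = sds[state])
  score_col <- sub("_low$", "", target)
  if (identical(score_col, target)) score_col <- paste0(target, "_score")
  df <- as.data.frame(tbl)
  df[[target]] <- NULL
  df[[score_col]] <- score
  df[[paste0("latent_", target)]] <- latent
  kinds <- cohort_kinds(tbl)
  kinds <- kinds[setdiff(names(kinds), target)]
  kinds[[score_col]] <- "continuous"
  kinds[[paste0("latent_", target)]] <- "binary"
  cohort_table(df, kinds = kinds)
}
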