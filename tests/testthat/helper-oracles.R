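# Shared fixtures and independent oracles, all built in code.

# A tiny discrete cohort from logical columns.
make_binary_cohort <- function(...) {
  cols <- list(...)
  df <- data.frame(subject_id = paste0("S", seq_len(length(cols[[1]]))),
                   stringsAsFactors = FALSE)
  kinds <- character()
  for (v in names(cols)) {
    df[[v]] <- cols[[v]]
    kinds[[v]] <- "binary"
  }
  as_discrete_cohort(cohort_table(df, kinds))
}

# Cheap acyclicity check on a parents list (index-free DFS).
is_acyclic <- function(parents) {
  nodes <- names(parents)
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  ok <- TRUE
  visit <- function(v) {
    if (!ok) return()
    if (color[[v]] == 1L) { ok <<- FALSE; return() }
    if (color[[v]] == 2L) return()
    color[[v]] <<- 1L
    for (p in parents[[v]]) visit(p)
    color[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  ok
}

# Enumerate every DAG over `vars` with at most max_parents parents per node.
# Returns a list of parents-lists. 25 DAGs for 3 nodes, 543 for 4.
enumerate_dags <- function(vars, max_parents = length(vars) - 1L) {
  subsets_of <- function(others) {
    out <- list(character())
    for (sz in seq_len(min(max_parents, length(others)))) {
      cmb <- utils::combn(others, sz, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  per_node <- lapply(vars, function(v) subsets_of(setdiff(vars, v)))
  names(per_node) <- vars
  dags <- list()
  assign_next <- function(i, parents) {
    if (i > length(vars)) {
      if (is_acyclic(parents)) dags[[length(dags) + 1L]] <<- parents
      return()
    }
    v <- vars[i]
    for (ps in per_node[[v]]) {
      parents[[v]] <- ps
      assign_next(i + 1L, parents)
    }
  }
  empty <- stats::setNames(lapply(vars, function(v) character()), vars)
  assign_next(1L, empty)
  dags
}

# Brute-force maximum network score over every DAG (with a family cache).
brute_force_best_score <- function(cohort, max_parents = NULL) {
  vars <- names(cohort_states(cohort))
  if (is.null(max_parents)) max_parents <- length(vars) - 1L
  cache <- new.env(parent = emptyenv())
  fam <- function(v, ps) {
    key <- paste(v, paste(sort(ps), collapse = ","), sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- family_score_bic(v, ps, cohort)$bic
    }
    cache[[key]]
  }
  dags <- enumerate_dags(vars, max_parents)
  best <- -Inf
  for (parents in dags) {
    s <- sum(vapply(vars, function(v) fam(v, parents[[v]]), numeric(1)))
    if (s > best) best <- s
  }
  list(best = best, n_dags = length(dags))
}

# Random discrete cohort of binary columns (independent coin flips with
# random biases), for score-oracle comparisons.
random_binary_cohort <- function(n_rows, n_vars, seed) {
  set.seed(seed)
  biases <- stats::runif(n_vars, 0.2, 0.8)
  cols <- lapply(biases, function(b) stats::runif(n_rows) < b)
  names(cols) <- LETTERS[seq_len(n_vars)]
  do.call(make_binary_cohort, cols)
}

# Random binary network: random order, random sparse parent sets, CPT rows
# bounded away from 0/1 so all evidence has positive probability.
random_network <- function(n_nodes, seed, max_parents = 3L) {
  set.seed(seed)
  vars <- LETTERS[seq_len(n_nodes)]
  ord <- sample(vars)
  parents <- list()
  states <- stats::setNames(rep(list(c("false", "true")), n_nodes), vars)
  cpts <- list()
  for (i in seq_along(ord)) {
    v <- ord[i]
    pool <- ord[seq_len(i - 1L)]
    np <- if (length(pool)) sample(0:min(max_parents, length(pool)), 1L) else 0L
    p <- sort(if (np > 0L) sample(pool, np) else character())
    parents[[v]] <- p
    ncfg <- prod(vapply(states[p], length, integer(1)), 1)
    pt <- stats::runif(ncfg, 0.05, 0.95)
    cpts[[v]] <- as.numeric(rbind(1 - pt, pt))
  }
  bn_network(states, parents, cpts)
}

# Probability of a partial assignment under a network (via the enumeration
# oracle's evidence_probability).
joint_of_evidence <- function(net, ev) {
  tgt <- setdiff(bn_nodes(net), names(ev))[1L]
  brute_force_query(net, tgt, evidence(ev))$evidence_probability
}

# Random evidence over a random subset of nodes (never the target).
random_evidence <- function(net, target, seed) {
  set.seed(seed)
  pool <- setdiff(bn_nodes(net), target)
  k <- sample(0:length(pool), 1L)
  if (k == 0L) return(evidence())
  vs <- sample(pool, k)
  evidence(stats::setNames(
    vapply(vs, function(v) sample(bn_states(net)[[v]], 1L), character(1)), vs))
}
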