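# Exact inference on discrete networks: variable elimination with a
# min-fill elimination order, plus a full-joint enumeration oracle.

# A factor is list(vars = character, table = array over those vars).
factor_from_cpt <- function(net, v) {
  p <- bn_parents(net)[[v]]
  list(vars = c(v, p), table = net$cpts[[v]])
}

align_factor_table <- function(tab, fvars, vars, dims) {
  if (!length(vars)) return(array(as.numeric(tab), dim = 1L))
  extra <- setdiff(vars, fvars)
  t1 <- array(as.numeric(tab), dim = c(dims[fvars], dims[extra]))
  aperm(t1, match(vars, c(fvars, extra)))
}

factor_product <- function(f1, f2, dims) {
  vars <- union(f1$vars, f2$vars)
  a <- align_factor_table(f1$table, f1$vars, vars, dims)
  b <- align_factor_table(f2$table, f2$vars, vars, dims)
  list(vars = vars, table = a * b)
}

factor_sum_out <- function(f, v, dims) {
  idx <- match(v, f$vars)
  if (is.na(idx)) return(f)
  if (length(f$vars) == 1L) {
    return(list(vars = character(), table = array(sum(f$table), dim = 1L)))
  }
  keep <- setdiff(seq_along(f$vars), idx)
  tab <- aperm(array(as.numeric(f$table), dim = dims[f$vars]), c(idx, keep))
  out <- colSums(array(tab, dim = c(dims[[v]], prod(dims[f$vars][keep]))))
  list(vars = f$vars[keep], table = array(out, dim = dims[f$vars][keep]))
}

factor_reduce <- function(f, v, state_idx, dims) {
  idx <- match(v, f$vars)
  if (is.na(idx)) return(f)
  tab <- array(as.numeric(f$table), dim = dims[f$vars])
  args <- rep(list(quote(expr = )), length(f$vars))
  args[[idx]] <- state_idx
  newtab <- do.call(`[`, c(list(tab), args, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), idx)
  if (!length(keep)) {
    return(list(vars = character(), table = array(as.numeric(newtab), dim = 1L)))
  }
  list(vars = f$vars[keep],
       table = array(as.numeric(newtab), dim = dims[f$vars][keep]))
}

# Min-fill elimination order over the interaction graph of the factor
# scopes; deterministic tie-break by node name.
min_fill_order <- function(scopes, elim_vars) {
  if (!length(elim_vars)) return(character())
  vars <- csort(unique(unlist(scopes)))
  adj <- matrix(FALSE, length(vars), length(vars),
                dimnames = list(vars, vars))
  for (sc in scopes) {
    for (a in sc) for (b in sc) if (a != b) adj[a, b] <- TRUE
  }
  order_out <- character()
  remaining <- csort(elim_vars)
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- names(which(adj[v, ]))
      if (length(nb) < 2L) return(0L)
      prs <- utils::combn(nb, 2L)
      sum(vapply(seq_len(ncol(prs)), function(j) {
        !adj[prs[1L, j], prs[2L, j]]
      }, logical(1)))
    }, integer(1))
    v <- remaining[which.min(fill)]  # which.min takes the first = lex smallest
    nb <- names(which(adj[v, ]))
    for (a in nb) for (b in nb) if (a != b) adj[a, b] <- TRUE
    adj[v, ] <- FALSE
    adj[, v] <- FALSE
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
  }
  order_out
}

#' Evidence for a network query
#'
#' @param ... named observed states, e.g. `evidence(dGV = "true")`, or a
#'   single named character vector / list.
#' @return a named character vector of class `bn_evidence`.
#' @export
evidence <- function(...) {
  args <- list(...)
  if (length(args) == 0L) return(structure(character(), class = "bn_evidence"))
  if (length(args) == 1L && is.null(names(args))) {
    x <- args[[1L]]
    if (inherits(x, "bn_evidence")) return(x)
    args <- as.list(x)
    if (length(args) == 0L) {
      return(structure(character(), class = "bn_evidence"))
    }
  }
  ev <- vapply(args, as.character, character(1))
  if (length(ev) && (is.null(names(ev)) || any(!nzchar(names(ev))))) {
    abort("evidence must be named", class = "svbn_validation_error")
  }
  if (anyDuplicated(names(ev))) {
    abort("duplicate evidence variable", class = "svbn_validation_error")
  }
  structure(ev, class = "bn_evidence")
}

check_evidence <- function(net, ev) {
  states <- bn_states(net)
  for (v in names(ev)) {
    if (!v %in% bn_nodes(net)) {
      abort("evidence on unknown node '", v, "'", class = "svbn_validation_error")
    }
    if (!ev[[v]] %in% states[[v]]) {
      abort("state '", ev[[v]], "' not in state set of '", v, "'",
            class = "svbn_validation_error")
    }
  }
}

#' Joint probability of a full assignment
#'
#' The factorized joint: the product over nodes of the CPT entry for the
#' node's state given its parents' states.
#'
#' @param net a [bn_network()].
#' @param assignment named states covering every node (an [evidence()] or
#'   named character vector).
#' @return a probability.
#' @export
joint_probability <- function(net, assignment) {
  ev <- evidence(assignment)
  check_evidence(net, ev)
  miss <- setdiff(bn_nodes(net), names(ev))
  if (length(miss)) {
    abort("assignment incomplete; missing: ", paste(miss, collapse = ", "),
          class = "svbn_validation_error")
  }
  states <- bn_states(net)
  prob <- 1
  for (v in bn_nodes(net)) {
    p <- bn_parents(net)[[v]]
    idx <- c(match(ev[[v]], states[[v]]),
             vapply(p, function(q) match(ev[[q]], states[[q]]), integer(1)))
    prob <- prob * net$cpts[[v]][matrix(idx, nrow = 1L)]
  }
  unname(prob)
}

finish_query <- function(target, states, unnorm) {
  z <- sum(unnorm)
  if (!is.finite(z) || z <= 0) {
    abort("evidence has probability 0 under the network",
          class = "svbn_inconsistent_evidence")
  }
  structure(list(target = target,
                 distribution = stats::setNames(as.numeric(unnorm) / z, states),
                 evidence_probability = z),
            class = "bn_query_result")
}

#' @export
print.bn_query_result <- function(x, ...) {
  cat(sprintf("<query> P(%s | evidence), P(evidence) = %.6g\n",
              x$target, x$evidence_probability))
  print(round(x$distribution, 6))
  invisible(x)
}

#' Exact conditional-probability query
#'
#' Computes the posterior `P(target | evidence)` exactly by variable
#' elimination (min-fill order, deterministic tie-break by node name),
#' together with the probability of the evidence itself. Evidence with
#' probability 0 under the network is an error rather than a silent `NaN`.
#'
#' @param net a [bn_network()].
#' @param target node name, not among the evidence.
#' @param ev an [evidence()] object (possibly empty).
#' @return a `bn_query_result`: `target`, `distribution` (named, sums to 1),
#'   `evidence_probability`.
#' @export
query <- function(net, target, ev = evidence()) {
  ev <- evidence(ev)
  check_evidence(net, ev)
  if (!target %in% bn_nodes(net)) {
    abort("unknown target '", target, "'", class = "svbn_validation_error")
  }
  if (target %in% names(ev)) {
    abort("target '", target, "' appears in the evidence",
          class = "svbn_validation_error")
  }
  states <- bn_states(net)
  dims <- vapply(states, length, integer(1))
  factors <- lapply(bn_nodes(net), function(v) factor_from_cpt(net, v))
  for (v in names(ev)) {
    si <- match(ev[[v]], states[[v]])
    factors <- lapply(factors, factor_reduce, v = v, state_idx = si,
                      dims = dims)
  }
  elim <- setdiff(bn_nodes(net), c(target, names(ev)))
  ord <- min_fill_order(lapply(factors, `[[`, "vars"), elim)
  for (v in ord) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    fs <- factors[involved]
    prod_f <- Reduce(function(a, b) factor_product(a, b, dims), fs)
    factors <- c(factors[!involved],
                 list(factor_sum_out(prod_f, v, dims)))
  }
  final <- Reduce(function(a, b) factor_product(a, b, dims), factors)
  # remaining scope is target only (constants have empty scope)
  tab <- if (length(final$vars)) {
    align_factor_table(final$table, final$vars, target, dims)
  } else {
    rep(as.numeric(final$table), dims[[target]])
  }
  finish_query(target, states[[target]], tab)
}

#' Brute-force query by full-joint enumeration
#'
#' The testing oracle: enumerates every full assignment (guarded at 2^20
#' configurations), sums the factorized joint over assignments consistent
#' with the evidence, and normalizes. Definitionally correct; used to
#' validate [query()].
#'
#' @inheritParams query
#' @return a `bn_query_result`.
#' @export
brute_force_query <- function(net, target, ev = evidence()) {
  ev <- evidence(ev)
  check_evidence(net, ev)
  if (!target %in% bn_nodes(net)) {
    abort("unknown target '", target, "'", class = "svbn_validation_error")
  }
  if (target %in% names(ev)) {
    abort("target '", target, "' appears in the evidence",
          class = "svbn_validation_error")
  }
  states <- bn_states(net)
  if (prod(vapply(states, length, integer(1))) > 2^20) {
    abort("state space exceeds enumeration guard (2^20)",
          class = "svbn_validation_error")
  }
  grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(ev)) keep <- keep & grid[[v]] == ev[[v]]
  grid <- grid[keep, , drop = FALSE]
  joint <- rep(1, nrow(grid))
  for (v in bn_nodes(net)) {
    p <- bn_parents(net)[[v]]
    idx <- cbind(match(grid[[v]], states[[v]]))
    for (q in p) idx <- cbind(idx, match(grid[[q]], states[[q]]))
    joint <- joint * net$cpts[[v]][idx]
  }
  unnorm <- vapply(states[[target]], function(s) {
    sum(joint[grid[[target]] == s])
  }, numeric(1))
  finish_query(target, states[[target]], unnorm)
}
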