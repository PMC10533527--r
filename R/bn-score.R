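# Decomposable BIC scoring and exact optimal structure search.
#
# Convention (natural log, larger is better):
#   bic(family) = loglik - 0.5 * ln(N) * n_params
#   n_params    = (|states(child)| - 1) * prod(|states(parent)|)
# The optimal DAG under a max-parents cap is found by dynamic programming
# over variable subsets: best parent set per (node, candidate set), best
# sink per subset, then order reconstruction.

# Integer coding of a discrete cohort: D[i, j] in 1..ns[j].
cohort_codes <- function(cohort) {
  stopifnot(inherits(cohort, "discrete_cohort"))
  states <- cohort_states(cohort)
  vars <- names(states)
  if (nrow(cohort) == 0L) abort("empty cohort", class = "svbn_validation_error")
  D <- matrix(0L, nrow = nrow(cohort), ncol = length(vars),
              dimnames = list(NULL, vars))
  for (j in seq_along(vars)) D[, j] <- as.integer(cohort[[vars[j]]])
  list(D = D, ns = vapply(states, length, integer(1)), vars = vars,
       states = states)
}

# Counts of (child state, parent configuration): nc x nconfig matrix,
# first parent (in the given order) varying fastest down the configs.
fam_counts <- function(D, ns, child, parents) {
  nc <- ns[[child]]
  if (length(parents)) {
    cfg <- D[, parents[1L]]
    mult <- ns[[parents[1L]]]
    for (p in parents[-1L]) {
      cfg <- cfg + (D[, p] - 1L) * mult
      mult <- mult * ns[[p]]
    }
    matrix(tabulate(D[, child] + (cfg - 1L) * nc, nbins = nc * mult), nrow = nc)
  } else {
    matrix(tabulate(D[, child], nbins = nc), nrow = nc)
  }
}

bic_from_counts <- function(M, nc, n_params, N) {
  M <- matrix(M, nrow = nc)
  tot <- colSums(M)
  nz <- M > 0L
  ll <- sum(M[nz] * log(M[nz] / rep(tot, each = nc)[nz]))
  c(loglik = ll, n_params = n_params, bic = ll - 0.5 * log(N) * n_params)
}

fam_bic_int <- function(D, ns, child, parents) {
  M <- fam_counts(D, ns, child, parents)
  bic_from_counts(M, ns[[child]], (ns[[child]] - 1L) * prod(ns[parents]),
                  nrow(D))
}

# Family scorer factory: when the full joint contingency table is small it
# is tabulated once and every family's counts come from marginalizing it,
# turning per-family cost from O(N) into O(#cells).
make_family_scorer <- function(D, ns, vars) {
  N <- nrow(D)
  if (prod(ns) <= 65536) {
    lin <- D[, 1L]
    mult <- ns[[1L]]
    if (length(vars) > 1L) {
      for (j in 2:length(vars)) {
        lin <- lin + (D[, j] - 1L) * mult
        mult <- mult * ns[[j]]
      }
    }
    J <- array(tabulate(lin, nbins = prod(ns)), dim = ns)
    nd <- length(vars)
    function(child, parents) {
      idx <- match(c(child, parents), vars)
      M <- if (length(idx) == nd) {
        aperm(J, idx)
      } else {
        other <- setdiff(seq_len(nd), idx)
        colSums(aperm(J, c(other, idx)), dims = length(other))
      }
      bic_from_counts(M, ns[[child]],
                      (ns[[child]] - 1L) * prod(ns[parents]), N)
    }
  } else {
    function(child, parents) fam_bic_int(D, ns, child, parents)
  }
}

#' BIC score of one node family
#'
#' The maximized multinomial log-likelihood of `child` given each parent
#' configuration (with the 0*log 0 = 0 convention), penalized by
#' `0.5 * ln(N)` per free parameter, where the free-parameter count is
#' `(|states(child)| - 1) * prod(|states(parent)|)`.
#'
#' @param child node name.
#' @param parents character vector of parent names (may be empty).
#' @param cohort a complete [discrete_cohort()].
#' @return a `family_score` object with fields `child`, `parents`, `loglik`,
#'   `n_params`, `n_obs`, `bic`.
#' @examples
#' # 6 of 10 rows flagged, no parents: loglik = 6 log .6 + 4 log .4
#' @export
family_score_bic <- function(child, parents, cohort) {
  cc <- cohort_codes(cohort)
  if (child %in% parents) {
    abort("child '", child, "' cannot be its own parent",
          class = "svbn_validation_error")
  }
  miss <- setdiff(c(child, parents), cc$vars)
  if (length(miss)) {
    abort("unknown column(s): ", paste(miss, collapse = ", "),
          class = "svbn_validation_error")
  }
  s <- fam_bic_int(cc$D, cc$ns, child, parents)
  structure(list(child = child, parents = csort(parents),
                 loglik = unname(s[["loglik"]]),
                 n_params = as.integer(s[["n_params"]]),
                 n_obs = nrow(cc$D), bic = unname(s[["bic"]])),
            class = "family_score")
}

#' @export
print.family_score <- function(x, ...) {
  cat(sprintf("<family_score> %s | {%s}: loglik %.4f, %d params, N %d, bic %.4f\n",
              x$child, paste(x$parents, collapse = ", "), x$loglik,
              x$n_params, x$n_obs, x$bic))
  invisible(x)
}

#' Total BIC score of a DAG on a cohort
#'
#' The decomposable network score: the sum over nodes of
#' [family_score_bic()] of each node given its parents. Errors on cyclic
#' structures.
#'
#' @param structure a [dag_structure()] over the cohort's columns.
#' @param cohort a complete [discrete_cohort()].
#' @return a single numeric score (larger is better).
#' @export
network_score <- function(structure, cohort) {
  stopifnot(inherits(structure, "dag_structure"))
  topological_order(structure$parents)
  cc <- cohort_codes(cohort)
  if (!setequal(structure$nodes, cc$vars)) {
    abort("structure nodes do not match cohort columns",
          class = "svbn_validation_error")
  }
  sum(vapply(structure$nodes, function(v) {
    fam_bic_int(cc$D, cc$ns, v, structure$parents[[v]])[["bic"]]
  }, numeric(1)))
}

# TRUE if parent set A is preferred to B on a score tie: fewer parents,
# then the lexicographically smaller sorted name set. Sets are compared as
# sorted integer ranks under C collation, so the result is locale-free.
prefer_parent_ranks <- function(ra, rb) {
  if (length(ra) != length(rb)) return(length(ra) < length(rb))
  d <- ra - rb
  i <- which(d != 0L)
  length(i) > 0L && d[i[1L]] < 0L
}

#' Exact BIC-optimal structure search
#'
#' Finds a DAG maximizing [network_score()] subject to a maximum-parents cap
#' by exact dynamic programming over variable subsets (best parent set per
#' node and candidate set, best sink per subset, order reconstruction). The
#' returned score is the maximum over all DAGs respecting the cap; ties are
#' broken deterministically (per family: fewer parents, then the
#' lexicographically smallest parent-name set; per subset: lexicographically
#' smallest sink).
#'
#' @param cohort a complete [discrete_cohort()].
#' @param max_parents per-node parent cap (default 3).
#' @param max_nodes guard on the number of variables (default 18): the DP
#'   visits every variable subset, so wider problems must be reduced to a
#'   variable subset first.
#' @return the optimal [dag_structure()], with attribute `score`.
#' @export
exact_structure_search <- function(cohort, max_parents = 3L, max_nodes = 18L) {
  if (max_parents < 0L) abort("max_parents must be >= 0",
                              class = "svbn_validation_error")
  cc <- cohort_codes(cohort)
  n <- length(cc$vars)
  if (n > max_nodes) {
    abort(n, " variables exceed the exact-search guard (", max_nodes,
          "); select a subset of variables", class = "svbn_validation_error")
  }
  if (n == 1L) {
    out <- dag_structure(cc$states)
    attr(out, "score") <- fam_bic_int(cc$D, cc$ns, cc$vars[1L], character())[["bic"]]
    return(out)
  }
  k <- min(max_parents, n - 1L)
  half <- bitwShiftL(1L, n - 1L)          # size of each node's others-space
  others_idx <- lapply(seq_len(n), function(v) setdiff(seq_len(n), v))
  scorer <- make_family_scorer(cc$D, cc$ns, cc$vars)
  bit_lists <- lapply(0:(half - 1L), bits_of, nmax = n - 1L)
  rankv <- match(cc$vars, csort(cc$vars))   # C-collation rank of each node
  bitm <- bitwShiftL(1L, seq_len(n) - 1L)

  # --- best parent set per (node, candidate set) -------------------------
  bps_score <- vector("list", n)
  bps_choice <- vector("list", n)
  for (v in seq_len(n)) {
    sc <- rep(-Inf, half)
    ch <- integer(half)
    oth <- others_idx[[v]]
    # local scores for all parent sets of size <= k
    for (sz in 0:k) {
      combos <- if (sz == 0L) list(integer()) else
        utils::combn(n - 1L, sz, simplify = FALSE)
      for (cb in combos) {
        m <- mask_of(cb)
        sc[m + 1L] <- scorer(cc$vars[v], cc$vars[oth[cb]])[["bic"]]
        ch[m + 1L] <- m
      }
    }
    # best over subsets of each candidate set
    oranks <- rankv[oth]
    if (half > 1L) {
      for (m in 1:(half - 1L)) {
        for (b in bit_lists[[m + 1L]]) {
          pm <- m - bitm[b]
          if (sc[pm + 1L] > sc[m + 1L] ||
              (sc[pm + 1L] == sc[m + 1L] && ch[pm + 1L] != ch[m + 1L] &&
               prefer_parent_ranks(
                 sort.int(oranks[bit_lists[[ch[pm + 1L] + 1L]]]),
                 sort.int(oranks[bit_lists[[ch[m + 1L] + 1L]]])))) {
            sc[m + 1L] <- sc[pm + 1L]
            ch[m + 1L] <- ch[pm + 1L]
          }
        }
      }
    }
    bps_score[[v]] <- sc
    bps_choice[[v]] <- ch
  }

  # --- best sink per subset ---------------------------------------------
  halfbit <- bitwShiftL(1L, seq_len(n - 1L) - 1L)
  project <- function(mask, v) {
    # compress a full-space mask (v excluded) into v's others-space
    oth <- others_idx[[v]]
    sum(halfbit[bitwAnd(mask, bitm[oth]) != 0L])
  }
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(-Inf, full + 1L)
  best[1L] <- 0
  sink <- integer(full + 1L)
  full_bits <- lapply(0:full, bits_of, nmax = n)
  for (m in 1:full) {
    bb <- full_bits[[m + 1L]]
    for (s in bb) {
      rest <- m - bitm[s]
      cand <- best[rest + 1L] + bps_score[[s]][project(rest, s) + 1L]
      if (cand > best[m + 1L] ||
          (cand == best[m + 1L] && sink[m + 1L] != 0L &&
           rankv[s] < rankv[sink[m + 1L]])) {
        best[m + 1L] <- cand
        sink[m + 1L] <- s
      }
    }
  }

  # --- reconstruct -------------------------------------------------------
  parents <- stats::setNames(vector("list", n), cc$vars)
  m <- full
  while (m > 0L) {
    s <- sink[m + 1L]
    rest <- m - bitm[s]
    pm <- bps_choice[[s]][project(rest, s) + 1L]
    parents[[cc$vars[s]]] <- cc$vars[others_idx[[s]][bits_of(pm, n - 1L)]]
    m <- rest
  }
  out <- dag_structure(cc$states, parents)
  attr(out, "score") <- best[full + 1L]
  out
}

#' Maximum-likelihood / posterior-mean parameter fitting
#'
#' Each CPT entry is `(count + pseudocount) / (config_total +
#' pseudocount * |states|)`: pure MLE at `pseudocount = 0`, the posterior
#' mean under a uniform Dirichlet prior otherwise. With `pseudocount = 0` an
#' unseen parent configuration leaves a row undefined and is an error; with
#' a positive pseudocount it yields the uniform distribution.
#'
#' @param structure a [dag_structure()] over the cohort's columns.
#' @param cohort a complete [discrete_cohort()].
#' @param pseudocount nonnegative prior weight (default 1).
#' @return a [bn_network()].
#' @export
fit_parameters <- function(structure, cohort, pseudocount = 1) {
  stopifnot(inherits(structure, "dag_structure"), pseudocount >= 0)
  topological_order(structure$parents)
  cc <- cohort_codes(cohort)
  if (!setequal(structure$nodes, cc$vars)) {
    abort("structure nodes do not match cohort columns",
          class = "svbn_validation_error")
  }
  cpts <- list()
  for (v in structure$nodes) {
    p <- structure$parents[[v]]
    M <- fam_counts(cc$D, cc$ns, v, p)
    tot <- colSums(M)
    if (pseudocount == 0 && any(tot == 0L)) {
      abort("unseen parent configuration for node '", v,
            "' with pseudocount 0", class = "svbn_fit_error")
    }
    nc <- nrow(M)
    probs <- (M + pseudocount) / rep(tot + pseudocount * nc, each = nc)
    dims <- c(nc, cc$ns[p])
    cpts[[v]] <- array(as.numeric(probs), dim = dims)
  }
  bn_network(cc$states[structure$nodes], structure$parents, cpts,
             pseudocount = pseudocount)
}

#' Markov equivalence of two DAGs
#'
#' Two DAGs are Markov equivalent iff they share the same skeleton and the
#' same v-structures (colliders whose parents are non-adjacent); equivalent
#' DAGs are indistinguishable by likelihood-based scores such as BIC.
#'
#' @param s1,s2 [dag_structure()] objects over the same nodes.
#' @return logical.
#' @export
markov_equivalent <- function(s1, s2) {
  stopifnot(setequal(s1$nodes, s2$nodes))
  skel <- function(s) {
    e <- dag_edges(s)
    if (!nrow(e)) return(character())
    csort(apply(e, 1L, function(r) paste(csort(r), collapse = "~")))
  }
  vstruct <- function(s) {
    e <- dag_edges(s)
    und <- if (nrow(e)) {
      apply(e, 1L, function(r) paste(csort(r), collapse = "~"))
    } else character()
    out <- character()
    for (v in s$nodes) {
      p <- s$parents[[v]]
      if (length(p) >= 2L) {
        prs <- utils::combn(csort(p), 2L)
        for (j in seq_len(ncol(prs))) {
          ab <- csort(prs[, j])
          if (!(paste(ab, collapse = "~") %in% und)) {
            out <- c(out, paste(ab[1L], v, ab[2L], sep = ">"))
          }
        }
      }
    }
    csort(out)
  }
  identical(skel(s1), skel(s2)) && identical(vstruct(s1), vstruct(s2))
}
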