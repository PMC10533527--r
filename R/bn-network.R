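#' DAG structures
#'
#' A `dag_structure` is an ordered node list with finite state sets plus a
#' parent-set map. Acyclicity is enforced wherever a structure is scored,
#' fitted, or searched; parent sets are stored sorted by name.
#'
#' @param states named list: node -> character vector of states (length >= 2).
#' @param parents named list: node -> character vector of parent names;
#'   absent entries mean no parents.
#' @return an object of class `dag_structure` with elements `nodes`, `states`
#'   and `parents`.
#' @export
dag_structure <- function(states, parents = list()) {
  nodes <- names(states)
  stopifnot(!is.null(nodes), !anyDuplicated(nodes))
  par <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) par[[v]] <- character()
  for (v in names(parents)) {
    if (!v %in% nodes) abort("parents declared for unknown node '", v, "'",
                             class = "svbn_validation_error")
    p <- as.character(parents[[v]])
    bad <- setdiff(p, nodes)
    if (length(bad)) abort("unknown parent(s) of '", v, "': ",
                           paste(bad, collapse = ", "),
                           class = "svbn_validation_error")
    if (v %in% p) abort("node '", v, "' cannot be its own parent",
                        class = "svbn_validation_error")
    par[[v]] <- csort(p)
  }
  structure(list(nodes = nodes, states = states, parents = par),
            class = "dag_structure")
}

#' @export
print.dag_structure <- function(x, ...) {
  cat(sprintf("<dag_structure> %d nodes, %d edges\n", length(x$nodes),
              sum(lengths(x$parents))))
  for (v in x$nodes) {
    if (length(x$parents[[v]])) {
      cat("  ", v, " <- ", paste(x$parents[[v]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Edges of a DAG structure
#' @param structure a `dag_structure`.
#' @return two-column character matrix (`from`, `to`), sorted.
#' @export
dag_edges <- function(structure) {
  e <- do.call(rbind, lapply(structure$nodes, function(v) {
    p <- structure$parents[[v]]
    if (length(p)) cbind(from = p, to = v) else NULL
  }))
  if (is.null(e)) e <- matrix(character(), ncol = 2,
                              dimnames = list(NULL, c("from", "to")))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Kahn topological sort; errors on cycles.
topological_order <- function(parents) {
  nodes <- names(parents)
  indeg <- vapply(parents, length, integer(1))
  order <- character()
  avail <- csort(nodes[indeg == 0L])
  remaining <- parents
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    remaining[[v]] <- NULL
    for (w in names(remaining)) {
      if (v %in% remaining[[w]]) {
        remaining[[w]] <- setdiff(remaining[[w]], v)
        if (!length(remaining[[w]])) avail <- csort(c(avail, w))
      }
    }
  }
  if (length(order) != length(nodes)) {
    abort("structure contains a cycle", class = "svbn_cycle_error")
  }
  order
}

#' Discrete Bayesian networks
#'
#' A fitted network: a [dag_structure()] plus one conditional probability
#' table per node. Each CPT is a numeric array whose first dimension runs
#' over the node's states and whose remaining dimensions run over the states
#' of its parents (sorted by name); every conditional distribution sums to 1
#' within 1e-12.
#'
#' @param states named list: node -> state set.
#' @param parents named list: node -> parent names.
#' @param cpts named list: node -> CPT array (a plain vector for a root
#'   node), with `dimnames` matching the state sets.
#' @param pseudocount the Dirichlet prior weight used in fitting, if any.
#' @return an object of class `bn_network`.
#' @export
bn_network <- function(states, parents, cpts, pseudocount = NA_real_) {
  structure_ <- dag_structure(states, parents)
  topological_order(structure_$parents)
  nodes <- structure_$nodes
  cpts_out <- list()
  for (v in nodes) {
    if (is.null(cpts[[v]])) abort("missing CPT for node '", v, "'",
                                  class = "svbn_validation_error")
    p <- structure_$parents[[v]]
    dims <- c(length(states[[v]]), vapply(states[p], length, integer(1)))
    tab <- array(as.numeric(cpts[[v]]), dim = dims,
                 dimnames = c(stats::setNames(list(states[[v]]), v),
                              stats::setNames(states[p], p)))
    if (length(tab) != prod(dims)) {
      abort("CPT for '", v, "' has wrong size", class = "svbn_validation_error")
    }
    if (any(tab < -1e-12) || any(tab > 1 + 1e-12)) {
      abort("CPT entries for '", v, "' outside [0,1]",
            class = "svbn_validation_error")
    }
    sums <- if (length(dims) == 1L) sum(tab) else
      apply(tab, seq_along(dims)[-1L], sum)
    if (any(abs(sums - 1) > 1e-12)) {
      abort("CPT rows for '", v, "' do not sum to 1",
            class = "svbn_validation_error")
    }
    cpts_out[[v]] <- tab
  }
  structure(list(structure = structure_, cpts = cpts_out,
                 pseudocount = pseudocount),
            class = "bn_network")
}

#' @export
print.bn_network <- function(x, ...) {
  cat(sprintf("<bn_network> %d nodes, %d edges (pseudocount %s)\n",
              length(x$structure$nodes), sum(lengths(x$structure$parents)),
              format(x$pseudocount)))
  print(x$structure)
  invisible(x)
}

#' Nodes / states / parents of a network
#' @param net a `bn_network`.
#' @return `bn_nodes`: character vector; `bn_states`: named list;
#'   `bn_parents`: named list.
#' @export
bn_nodes <- function(net) net$structure$nodes

#' @rdname bn_nodes
#' @export
bn_states <- function(net) net$structure$states

#' @rdname bn_nodes
#' @export
bn_parents <- function(net) net$structure$parents

# Parent-state configurations in lexicographic order (parents sorted by
# name, last parent varying fastest) — the documented serialization order.
lex_config_grid <- function(states, parents) {
  if (!length(parents)) return(data.frame())
  g <- expand.grid(rev(states[parents]), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(parents)), drop = FALSE]
  names(g) <- parents
  g
}

#' Serialize / deserialize a network as JSON
#'
#' Nodes are written with their ordered state lists, sorted parent lists and
#' CPT rows in lexicographic parent-configuration order (parents sorted by
#' name, last parent varying fastest). Writing, reading, and re-writing the
#' file reproduces it byte-identically.
#'
#' @param net a `bn_network`.
#' @param path output / input path.
#' @return `write_bn_json` returns `path` invisibly; `read_bn_json` a
#'   `bn_network`.
#' @export
write_bn_json <- function(net, path) {
  nodes <- lapply(bn_nodes(net), function(v) {
    p <- bn_parents(net)[[v]]
    tab <- net$cpts[[v]]
    if (length(p)) {
      # permute so parent dims run last-fastest, then split into rows
      perm <- c(length(dim(tab)):2L, 1L)
      flat <- aperm(tab, perm)
      nst <- length(bn_states(net)[[v]])
      rows <- matrix(as.numeric(flat), ncol = nst)
      cpt <- lapply(seq_len(nrow(rows)), function(i) as.numeric(rows[i, ]))
    } else {
      cpt <- list(as.numeric(tab))
    }
    list(name = v, states = as.list(bn_states(net)[[v]]),
         parents = as.list(p), cpt = cpt)
  })
  obj <- list(nodes = nodes, pseudocount = net$pseudocount)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path)
  states <- list()
  parents <- list()
  cpts <- list()
  for (nd in obj$nodes) {
    v <- nd$name
    states[[v]] <- unlist(nd$states, use.names = FALSE)
    parents[[v]] <- unlist(nd$parents, use.names = FALSE) %||% character()
  }
  for (nd in obj$nodes) {
    v <- nd$name
    p <- parents[[v]]
    rows <- do.call(rbind, lapply(nd$cpt, function(r) unlist(r, use.names = FALSE)))
    if (length(p)) {
      dims_rev <- rev(vapply(states[p], length, integer(1)))
      # rows are in last-parent-fastest order; rebuild and invert the aperm
      flat <- array(as.numeric(rows), dim = c(dims_rev, length(states[[v]])))
      perm <- c(length(dim(flat)), (length(dim(flat)) - 1L):1L)
      cpts[[v]] <- aperm(flat, perm)
    } else {
      cpts[[v]] <- as.numeric(rows[1L, ])
    }
  }
  pc <- obj$pseudocount
  bn_network(states, parents, cpts,
             pseudocount = if (is.null(pc)) NA_real_ else as.numeric(pc))
}
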