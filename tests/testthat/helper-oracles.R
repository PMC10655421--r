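# Independent oracles and shared toy fixtures. The oracles deliberately
# use the dumbest correct algorithm (repeated sweeps, per-node BFS,
# exhaustive subset search) and never call the package's internals.

# safe scalar sampling (sample() misbehaves on length-1 numeric vectors)
pick <- function(v) v[sample.int(length(v), 1L)]

# --- toy networks used across files ------------------------------------

toy_s1 <- function() {
  metabolic_network("S1", list(
    reaction("R1", c("A", "B"), "C"),
    reaction("R2", "C", "D")
  ))
}

toy_s2 <- function() {
  metabolic_network("S2", list(
    reaction("R3", "D", "E"),
    reaction("R4", c("E", "A"), "F")
  ))
}

toy_s3 <- function() {
  metabolic_network("S3", c(unname(toy_s1()$reactions),
                            unname(toy_s2()$reactions)))
}

# --- naive repeated-sweep expansion oracle -----------------------------

naive_scope <- function(networks, seeds) {
  if (inherits(networks, "metabolic_network")) networks <- list(networks)
  rules <- list()
  for (net in networks) {
    for (r in net$reactions) {
      rules[[length(rules) + 1L]] <- list(r$reactants, r$products)
      if (r$reversible) {
        rules[[length(rules) + 1L]] <- list(r$products, r$reactants)
      }
    }
  }
  scope <- unique(as.character(seeds))
  repeat {
    before <- length(scope)
    for (r in rules) {
      if (all(r[[1L]] %in% scope)) scope <- union(scope, r[[2L]])
    }
    if (length(scope) == before) break
  }
  sort(scope)
}

# --- random instances ---------------------------------------------------

random_network <- function(species_id, n_reactions = 10L,
                           n_compounds = 15L, p_reversible = 0.2) {
  comps <- sprintf("c%02d", seq_len(n_compounds))
  rxs <- lapply(seq_len(n_reactions), function(j) {
    reactants <- sample(comps, sample(1:3, 1))
    products <- sample(comps, sample(1:3, 1))
    reaction(sprintf("r%02d", j), reactants, products,
             reversible = stats::runif(1) < p_reversible)
  })
  metabolic_network(species_id, rxs)
}

# --- brute-force seed characterization ---------------------------------

# A compound is a seed-component member iff every node that reaches it is
# also reachable from it (per-node BFS reachability, reflexive).
brute_seed_compounds <- function(graph) {
  nodes <- graph$nodes
  adj <- lapply(stats::setNames(nodes, nodes), function(n)
    unique(graph$edges[graph$edges[, "from"] == n, "to"]))
  reach <- lapply(stats::setNames(nodes, nodes), function(start) {
    seen <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                     seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  })
  is_seed <- vapply(nodes, function(cmp) {
    reaching <- nodes[vapply(nodes, function(u) cmp %in% reach[[u]],
                             logical(1))]
    all(reaching %in% reach[[cmp]])
  }, logical(1))
  sort(nodes[is_seed])
}

# --- exhaustive minimal-community search -------------------------------

exhaustive_mincom <- function(instance) {
  members <- instance$members
  ids <- names(members)
  host <- instance$host
  targets <- instance$targets$compounds
  seeds <- instance$seeds
  scope_of <- function(sel) {
    nets <- members[sel]
    if (!is.null(host)) nets <- c(nets, list(host))
    if (length(nets) == 0L) return(sort(unique(seeds)))
    naive_scope(nets, seeds)
  }
  producible <- intersect(targets, scope_of(ids))
  n <- length(ids)
  best <- NULL
  best_k <- Inf
  for (mask in 0:(2^n - 1L)) {
    sel <- ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(sel) > best_k) next
    if (all(producible %in% scope_of(sel))) {
      if (length(sel) < best_k) {
        best_k <- length(sel)
        best <- list()
      }
      best[[length(best) + 1L]] <- sort(sel)
    }
  }
  list(optimum_size = best_k, optima = best[order(vapply(
    best, paste, character(1), collapse = "|"))],
    producible = sort(producible))
}

sorted_solution_key <- function(solutions) {
  sort(vapply(solutions, function(s) paste(sort(s), collapse = "|"),
              character(1)))
}
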