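# Compile networks to irreversible firing rules. A reversible reaction
# becomes two one-way rules, which makes the fixed point manifestly
# order-independent.
compile_rules <- function(networks) {
  rules <- list()
  k <- 0L
  for (net in networks) {
    for (r in net$reactions) {
      k <- k + 1L
      rules[[k]] <- list(reactants = r$reactants, products = r$products)
      if (r$reversible) {
        k <- k + 1L
        rules[[k]] <- list(reactants = r$products, products = r$reactants)
      }
    }
  }
  rules
}

# Least fixed point of the expansion operator: starting from the seeds, a
# rule fires (contributes its products) once all of its reactants are in
# the current set. Worklist over compounds with per-rule unmet-reactant
# counters; linear in total rule arity.
scope_closure <- function(rules, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(rules) == 0L) return(sort(seeds))
  comps <- unique(c(seeds,
                    unlist(lapply(rules, function(r)
                      c(r$reactants, r$products)), use.names = FALSE)))
  n <- length(comps)
  nr <- length(rules)
  unmet <- integer(nr)
  need <- vector("list", n)
  prods <- vector("list", nr)
  for (j in seq_len(nr)) {
    rs <- match(rules[[j]]$reactants, comps)
    unmet[j] <- length(rs)
    for (ci in rs) need[[ci]] <- c(need[[ci]], j)
    prods[[j]] <- match(rules[[j]]$products, comps)
  }
  in_scope <- logical(n)
  queue <- integer(n)
  seed_idx <- match(seeds, comps)
  in_scope[seed_idx] <- TRUE
  queue[seq_along(seed_idx)] <- seed_idx
  tail <- length(seed_idx)
  head <- 1L
  while (head <= tail) {
    ci <- queue[head]
    head <- head + 1L
    for (j in need[[ci]]) {
      unmet[j] <- unmet[j] - 1L
      if (unmet[j] == 0L) {
        for (p in prods[[j]]) {
          if (!in_scope[p]) {
            in_scope[p] <- TRUE
            tail <- tail + 1L
            queue[tail] <- p
          }
        }
      }
    }
  }
  sort(comps[in_scope])
}

new_scope_result <- function(owner, seeds, full_scope) {
  seeds <- sort(unique(as.character(seeds)))
  structure(
    list(owner = owner, seeds = seeds, full_scope = full_scope,
         producible = setdiff(full_scope, seeds)),
    class = "scope_result"
  )
}

#' @export
print.scope_result <- function(x, ...) {
  cat("<scope_result> ", x$owner, ": full scope ", length(x$full_scope),
      " compounds (", length(x$producible),
      " producible beyond the seeds)\n", sep = "")
  invisible(x)
}

#' Individual metabolic potential (scope) of one network
#'
#' Computes the network-expansion scope of a single species: the least
#' fixed point reached by starting from the seed medium and repeatedly
#' firing every reaction whose reactants are all already reachable.
#' Reversible reactions may fire in either direction. The result does not
#' depend on the order in which reactions are considered.
#'
#' @param network A [metabolic_network()].
#' @param seeds Character vector of seed-medium compound ids. Seeds absent
#'   from the network's compound set still count as available substrates
#'   (the medium is external to any genome).
#'
#' @return A `"scope_result"` with `full_scope` (seeds included) and
#'   `producible` (`full_scope` minus seeds, the "newly producible"
#'   compounds).
#'
#' @examples
#' s1 <- metabolic_network("S1", list(
#'   reaction("R1", c("A", "B"), "C"),
#'   reaction("R2", "C", "D")
#' ))
#' compute_scope(s1, c("A", "B"))$producible  # "C" "D"
#' @export
compute_scope <- function(network, seeds) {
  stopifnot(inherits(network, "metabolic_network"))
  new_scope_result(network$species_id, seeds,
                   scope_closure(compile_rules(list(network)), seeds))
}

#' Community metabolic potential (mixed-bag scope)
#'
#' Computes the collective scope of a community under the mixed-bag
#' (meta-organism) assumption: all members' reactions — plus the host's,
#' when one is given — are pooled into a single network before expansion.
#'
#' @param members List of [metabolic_network()] objects (at least one).
#' @param seeds Character vector of seed-medium compound ids.
#' @param host Optional host [metabolic_network()] whose reactions join
#'   the pool.
#'
#' @return A `"scope_result"`; `owner` is `"community"` or
#'   `"community+host"`.
#' @export
community_scope <- function(members, seeds, host = NULL) {
  if (inherits(members, "metabolic_network")) members <- list(members)
  stopifnot(length(members) >= 1L)
  nets <- members
  owner <- "community"
  if (!is.null(host)) {
    nets <- c(nets, list(host))
    owner <- "community+host"
  }
  new_scope_result(owner, seeds, scope_closure(compile_rules(nets), seeds))
}

#' Cooperation added value of a community
#'
#' The compounds producible by the community's mixed bag but by no member
#' alone — the gain attributable to metabolic cooperation.
#'
#' @inheritParams community_scope
#' @return Sorted character vector of compound ids, disjoint from every
#'   individual producible set.
#' @export
added_value <- function(members, seeds) {
  if (inherits(members, "metabolic_network")) members <- list(members)
  stopifnot(length(members) >= 1L)
  indiv <- unlist(lapply(members, function(m)
    compute_scope(m, seeds)$producible), use.names = FALSE)
  setdiff(community_scope(members, seeds)$producible, indiv)
}

#' Summary statistics over individual scopes
#'
#' Per-species full-scope sizes with their minimum, maximum and arithmetic
#' mean, plus the core (intersection of all full scopes — the metabolites
#' every member can access) and the union scope.
#'
#' @inheritParams community_scope
#' @return A `"scope_statistics"` list with `sizes` (named by species),
#'   `min`, `max`, `mean`, `core` and `union_scope`.
#' @export
scope_statistics <- function(members, seeds) {
  if (inherits(members, "metabolic_network")) members <- list(members)
  stopifnot(length(members) >= 1L)
  scopes <- lapply(members, function(m) compute_scope(m, seeds)$full_scope)
  names(scopes) <- vapply(members, `[[`, character(1), "species_id")
  sizes <- vapply(scopes, length, integer(1))
  structure(
    list(sizes = sizes,
         min = min(sizes), max = max(sizes), mean = mean(sizes),
         core = sort(Reduce(intersect, scopes)),
         union_scope = sort(Reduce(union, scopes))),
    class = "scope_statistics"
  )
}

#' @export
print.scope_statistics <- function(x, ...) {
  cat("<scope_statistics> ", length(x$sizes), " species; scope sizes ",
      x$min, "-", x$max, " (mean ", format(x$mean), "); core ",
      length(x$core), ", union ", length(x$union_scope), " compounds\n",
      sep = "")
  invisible(x)
}
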