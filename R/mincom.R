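new_mincom_result <- function(optimum_size, one_solution, all_solutions,
                              truncated, unproducible, producible,
                              host_included) {
  all_solutions <- lapply(all_solutions, function(s) sort(s))
  essential <- NULL
  alternative <- NULL
  if (!truncated && length(all_solutions) > 0L) {
    essential <- sort(Reduce(intersect, all_solutions))
    alternative <- sort(setdiff(Reduce(union, all_solutions), essential))
  }
  structure(
    list(optimum_size = optimum_size,
         one_solution = sort(one_solution),
         all_solutions = all_solutions,
         truncated = truncated,
         essential = essential,
         alternative = alternative,
         unproducible_targets = sort(unproducible),
         producible_targets = sort(producible),
         host_included = host_included),
    class = "mincom_result"
  )
}

#' @export
print.mincom_result <- function(x, ...) {
  cat("<mincom_result> optimum size ", x$optimum_size, "; ",
      length(x$all_solutions), " optimal communit",
      if (length(x$all_solutions) == 1L) "y" else "ies",
      if (x$truncated) " (truncated)" else "", "\n", sep = "")
  if (!is.null(x$essential)) {
    cat("  essential: ",
        if (length(x$essential)) paste(x$essential, collapse = ", ")
        else "(none)", "\n", sep = "")
    cat("  alternative: ",
        if (length(x$alternative)) paste(x$alternative, collapse = ", ")
        else "(none)", "\n", sep = "")
  }
  if (length(x$unproducible_targets)) {
    cat("  unproducible targets: ",
        paste(x$unproducible_targets, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Core search. Species are explored in lexicographic id order; solutions
# at the optimum depth are collected in that order, so output is
# deterministic. Species none of whose reactions can fire even in the
# full mixed-bag scope (plus host) are provably unable to contribute to
# any community and are excluded from the search up front.
mincom_search <- function(instance, enumerate, cap) {
  stopifnot(inherits(instance, "community_instance"))
  members <- instance$members
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  targets <- instance$targets$compounds
  if (length(targets) == 0L) stop("targets must be non-empty", call. = FALSE)
  seeds <- instance$seeds
  host_rules <- if (!is.null(instance$host)) {
    compile_rules(list(instance$host))
  } else {
    list()
  }
  member_rules <- lapply(members, function(m) compile_rules(list(m)))
  ids <- names(members)

  scope_of <- function(which_members) {
    scope_closure(c(do.call(c, c(member_rules[which_members],
                                 list(list()))),
                    host_rules), seeds)
  }
  full_scope <- scope_of(ids)
  producible <- intersect(targets, full_scope)
  unproducible <- setdiff(targets, full_scope)
  if (length(unproducible)) {
    warning("target(s) unproducible even by the full community",
            if (!is.null(instance$host)) " with host" else "", ": ",
            paste(sort(unproducible), collapse = ", "), call. = FALSE)
  }
  covers <- function(which_members) {
    all(producible %in% scope_of(which_members))
  }
  if (length(producible) == 0L) {
    return(new_mincom_result(0L, character(0), list(character(0)),
                             FALSE, unproducible, producible,
                             !is.null(instance$host)))
  }
  # Drop species that cannot fire any reaction in the full scope.
  relevant <- ids[vapply(ids, function(id) {
    any(vapply(member_rules[[id]], function(r)
      all(r$reactants %in% full_scope), logical(1)))
  }, logical(1))]
  if (covers(character(0))) {
    # Seeds plus host reactions alone already cover every target.
    return(new_mincom_result(0L, character(0), list(character(0)),
                             FALSE, unproducible, producible,
                             !is.null(instance$host)))
  }
  # Greedy upper bound on the optimum cardinality.
  chosen <- character(0)
  pool <- relevant
  while (!covers(chosen) && length(pool)) {
    gains <- vapply(pool, function(id)
      length(intersect(producible, scope_of(c(chosen, id)))), integer(1))
    best <- pool[which.max(gains)]
    chosen <- c(chosen, best)
    pool <- setdiff(pool, best)
  }
  upper <- length(chosen)

  n <- length(relevant)
  solutions <- list()
  truncated <- FALSE
  for (k in seq_len(upper)) {
    idx_sets <- utils::combn(n, k, simplify = FALSE)
    for (sel in idx_sets) {
      subset_ids <- relevant[sel]
      if (covers(subset_ids)) {
        solutions[[length(solutions) + 1L]] <- subset_ids
        if (!enumerate) break
        if (length(solutions) >= cap) {
          truncated <- TRUE
          break
        }
      }
    }
    if (length(solutions)) break
  }
  if (length(solutions) == 0L) {
    stop("internal error: no covering community found despite feasible ",
         "full community", call. = FALSE)
  }
  if (!enumerate && length(solutions) == 1L) {
    # A single solve does not establish uniqueness; mark as truncated so
    # essential/alternative classification is refused.
    truncated <- TRUE
  }
  new_mincom_result(length(solutions[[1L]]), solutions[[1L]], solutions,
                    truncated, unproducible, producible,
                    !is.null(instance$host))
}

#' Solve for one minimal community
#'
#' Finds a minimum-cardinality subset of the instance's members whose
#' mixed-bag expansion from the seed medium (with the host's reactions
#' included when a host is present) produces every producible target
#' compound. Targets that even the full community cannot produce are
#' reported in `unproducible_targets` and excluded from the covering
#' requirement, with a warning.
#'
#' The host supports coverage but is never a selectable member and never
#' counts toward the community size. The search is an iterative deepening
#' over community cardinality bounded by a greedy cover, with species
#' explored in lexicographic id order, so the returned solution is
#' deterministic.
#'
#' @param instance A [community_instance()] with non-empty targets.
#' @return A `"mincom_result"` with `optimum_size`, `one_solution`,
#'   `all_solutions` (here the single reported solution, flagged
#'   `truncated` because uniqueness was not established),
#'   `unproducible_targets` and `producible_targets`.
#' @seealso [enumerate_minimal_communities()] for all optima and
#'   essential/alternative symbiont classification.
#' @export
solve_minimal_community <- function(instance) {
  mincom_search(instance, enumerate = FALSE, cap = 1L)
}

#' Enumerate all minimal communities
#'
#' Enumerates every minimum-cardinality community (up to `cap`) and
#' classifies species as essential symbionts (present in every optimum)
#' or alternative symbionts (present in at least one but not all optima).
#'
#' @inheritParams solve_minimal_community
#' @param cap Maximum number of optima to collect; if reached the result
#'   is flagged `truncated` and essential/alternative are not derived.
#' @return A `"mincom_result"`; `all_solutions` is sorted
#'   lexicographically, `essential` and `alternative` are `NULL` when
#'   truncated.
#' @export
enumerate_minimal_communities <- function(instance, cap = 1000L) {
  stopifnot(is.numeric(cap), length(cap) == 1L, cap >= 1)
  mincom_search(instance, enumerate = TRUE, cap = as.integer(cap))
}

#' Classify essential and alternative symbionts
#'
#' Essential symbionts are present in all minimal communities; alternative
#' symbionts occur in at least one but not all. Classification from a
#' truncated enumeration would be unsound and is refused.
#'
#' @param result A `"mincom_result"` from
#'   [enumerate_minimal_communities()] with `truncated = FALSE`.
#' @return A list with components `essential` and `alternative` (sorted
#'   character vectors).
#' @export
classify_symbionts <- function(result) {
  stopifnot(inherits(result, "mincom_result"))
  if (length(result$all_solutions) == 0L) {
    stop("no solutions to classify", call. = FALSE)
  }
  if (isTRUE(result$truncated)) {
    stop("enumeration was truncated; essential/alternative ",
         "classification would be unsound", call. = FALSE)
  }
  essential <- sort(Reduce(intersect, result$all_solutions))
  list(essential = essential,
       alternative = sort(setdiff(Reduce(union, result$all_solutions),
                                  essential)))
}
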