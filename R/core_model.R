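#' Construct a qualitative reaction
#'
#' A reaction in a qualitative genome-scale metabolic network (GSMN) is a
#' directed transformation of a non-empty set of reactant compounds into a
#' non-empty set of product compounds. Stoichiometric coefficients are
#' deliberately not represented: producibility is modelled by network
#' expansion, which is purely qualitative.
#'
#' @param id Unique reaction identifier (non-empty string).
#' @param reactants Character vector of reactant compound ids (non-empty).
#' @param products Character vector of product compound ids (non-empty).
#' @param reversible Logical; if `TRUE` the reaction may also fire in the
#'   product-to-reactant direction.
#'
#' @return An object of class `"sc_reaction"`.
#'
#' @details A compound may appear both as reactant and product of the same
#'   reaction; this is allowed and preserved.
#'
#' @examples
#' reaction("R1", c("A", "B"), "C")
#' @export
reaction <- function(id, reactants, products, reversible = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction id must be a single non-empty string", call. = FALSE)
  }
  reactants <- unique(as.character(reactants))
  products <- unique(as.character(products))
  if (length(reactants) == 0L || any(!nzchar(reactants))) {
    stop("reaction '", id, "' must have a non-empty reactant list",
         call. = FALSE)
  }
  if (length(products) == 0L || any(!nzchar(products))) {
    stop("reaction '", id, "' must have a non-empty product list",
         call. = FALSE)
  }
  structure(
    list(id = id,
         reactants = sort(reactants),
         products = sort(products),
         reversible = isTRUE(reversible)),
    class = "sc_reaction"
  )
}

#' Construct a qualitative metabolic network
#'
#' Bundles a species identifier with its reaction set. The compound set of
#' the network is always derived as the union of all reactant and product
#' ids, never stored independently, so it cannot drift out of sync.
#'
#' @param species_id Unique species (genome) identifier.
#' @param reactions A list of [reaction()] objects (possibly empty) or of
#'   plain lists with fields `id`, `reactants`, `products`, `reversible`.
#'
#' @return An object of class `"metabolic_network"` with elements
#'   `species_id`, `reactions` (named by reaction id) and `compounds`
#'   (sorted character vector).
#'
#' @examples
#' net <- metabolic_network("S1", list(
#'   reaction("R1", c("A", "B"), "C"),
#'   reaction("R2", "C", "D")
#' ))
#' net$compounds
#' @export
metabolic_network <- function(species_id, reactions = list()) {
  if (!is.character(species_id) || length(species_id) != 1L ||
      !nzchar(species_id)) {
    stop("species_id must be a single non-empty string", call. = FALSE)
  }
  reactions <- lapply(reactions, function(r) {
    if (inherits(r, "sc_reaction")) r
    else reaction(r$id, r$reactants, r$products, isTRUE(r$reversible))
  })
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids in network '", species_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(reactions) <- ids
  reactions <- reactions[order(ids)]
  compounds <- sort(unique(unlist(
    lapply(reactions, function(r) c(r$reactants, r$products)),
    use.names = FALSE
  )))
  if (is.null(compounds)) compounds <- character(0)
  structure(
    list(species_id = species_id, reactions = reactions,
         compounds = compounds),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_rev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat("<metabolic_network> ", x$species_id, ": ",
      length(x$reactions), " reactions (", n_rev, " reversible), ",
      length(x$compounds), " compounds\n", sep = "")
  invisible(x)
}

#' Construct a target-compound set
#'
#' The target set lists the compounds a designed community is required to
#' produce (e.g. amino acids, vitamins, phytohormones and other compounds
#' relevant to plant interactions), optionally labelled with a compound
#' category.
#'
#' @param compounds Character vector of target compound ids.
#' @param categories Optional named character vector mapping compound id to
#'   a category label; every named id must be in `compounds`.
#'
#' @return An object of class `"target_set"`.
#' @export
target_set <- function(compounds, categories = NULL) {
  compounds <- sort(unique(as.character(compounds)))
  if (!is.null(categories)) {
    categories <- unlist(categories)
    if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
      stop("categories must be a named vector (compound id -> label)",
           call. = FALSE)
    }
    bad <- setdiff(names(categories), compounds)
    if (length(bad)) {
      stop("categorized ids not in target compounds: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    categories <- categories[order(names(categories))]
  }
  structure(list(compounds = compounds, categories = categories),
            class = "target_set")
}

#' Construct a community instance
#'
#' A community instance is the full input of a design run: the member
#' networks, the seed growth medium (compounds assumed freely available
#' from the environment, e.g. a root exudate-mimicking medium), the target
#' compounds, and optionally a host metabolic network whose reactions can
#' support the community but which is never itself selectable.
#'
#' @param members List of [metabolic_network()] objects with unique
#'   `species_id`s.
#' @param seeds Character vector of seed-medium compound ids (non-empty).
#' @param targets A [target_set()] or character vector of target ids.
#' @param host Optional [metabolic_network()]; its `species_id` must
#'   differ from every member's.
#'
#' @return An object of class `"community_instance"`.
#' @export
community_instance <- function(members, seeds, targets, host = NULL) {
  if (!is.list(members) ||
      !all(vapply(members, inherits, logical(1), "metabolic_network"))) {
    stop("members must be a list of metabolic_network objects",
         call. = FALSE)
  }
  ids <- vapply(members, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) {
    stop("duplicate species_id among members: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  members <- members[order(ids)]
  names(members) <- sort(ids)
  seeds <- sort(unique(as.character(seeds)))
  if (length(seeds) == 0L) {
    stop("seed medium must be non-empty", call. = FALSE)
  }
  if (is.character(targets)) targets <- target_set(targets)
  if (!inherits(targets, "target_set")) {
    stop("targets must be a target_set or character vector", call. = FALSE)
  }
  if (!is.null(host)) {
    if (!inherits(host, "metabolic_network")) {
      stop("host must be a metabolic_network", call. = FALSE)
    }
    if (host$species_id %in% names(members)) {
      stop("host species_id clashes with a member id: ", host$species_id,
           call. = FALSE)
    }
  }
  known <- unique(c(seeds,
                    unlist(lapply(members, `[[`, "compounds"),
                           use.names = FALSE),
                    if (!is.null(host)) host$compounds))
  orphan <- setdiff(targets$compounds, known)
  if (length(orphan)) {
    warning("target compound(s) absent from every network and the seeds ",
            "(may be unproducible): ", paste(orphan, collapse = ", "),
            call. = FALSE)
  }
  structure(
    list(members = members, seeds = seeds, targets = targets, host = host),
    class = "community_instance"
  )
}

#' @export
print.community_instance <- function(x, ...) {
  cat("<community_instance> ", length(x$members), " members, ",
      length(x$seeds), " seed compounds, ",
      length(x$targets$compounds), " targets",
      if (!is.null(x$host)) paste0(", host ", x$host$species_id) else "",
      "\n", sep = "")
  invisible(x)
}

#' Summarize a metabolic network
#'
#' @param network A [metabolic_network()].
#' @return A one-row data frame with `species_id`, `n_compounds`,
#'   `n_reactions` and `n_reversible`.
#' @examples
#' net <- metabolic_network("S1", list(reaction("R1", "A", "B")))
#' summarize_network(net)
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  data.frame(
    species_id = network$species_id,
    n_compounds = length(network$compounds),
    n_reactions = length(network$reactions),
    n_reversible = sum(vapply(network$reactions, `[[`, logical(1),
                              "reversible")),
    stringsAsFactors = FALSE
  )
}
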