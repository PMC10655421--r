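#' Build the directed compound graph of a network
#'
#' The substrate-to-product graph underlying reverse-ecology analysis:
#' every reaction contributes an edge from each of its reactants to each
#' of its products; reversible reactions also contribute the mirrored
#' edges. Optionally a list of compounds (e.g. currency metabolites) is
#' excluded together with all incident edges; by default nothing is
#' excluded.
#'
#' @param network A [metabolic_network()].
#' @param exclude Optional character vector of compound ids to remove.
#' @return A `"compound_graph"` with `nodes` (character) and `edges`
#'   (two-column character matrix, from/to).
#' @export
build_compound_graph <- function(network, exclude = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  from <- character(0)
  to <- character(0)
  for (r in network$reactions) {
    pairs <- expand.grid(r$reactants, r$products,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    from <- c(from, pairs[[1L]])
    to <- c(to, pairs[[2L]])
    if (r$reversible) {
      from <- c(from, pairs[[2L]])
      to <- c(to, pairs[[1L]])
    }
  }
  nodes <- network$compounds
  if (!is.null(exclude)) {
    exclude <- as.character(exclude)
    nodes <- setdiff(nodes, exclude)
    keep <- !(from %in% exclude) & !(to %in% exclude)
    from <- from[keep]
    to <- to[keep]
  }
  edges <- unique(cbind(from = from, to = to))
  structure(
    list(owner = network$species_id, nodes = nodes, edges = edges),
    class = "compound_graph"
  )
}

#' Detect the reverse-ecology seed set of a compound graph
#'
#' The seed set of a species is the set of compounds it must acquire
#' exogenously: the members of the source strongly-connected components
#' (SCCs) of its substrate-to-product graph, i.e. the components of the
#' condensation with no incoming edge from outside. Each seed compound is
#' weighted by a confidence of 1 / (size of its source component), so the
#' confidences within one component sum to 1 (any member of the component
#' could equivalently be the exogenously acquired one). An isolated
#' compound is its own source component with confidence 1.
#'
#' @param graph A `"compound_graph"` from [build_compound_graph()].
#' @param max_component_size Optional cap on the size of source
#'   components admitted as seeds (sensitivity analysis); default keeps
#'   every source component regardless of size.
#' @return A `"seed_set"` with `owner`, `entries` (named numeric vector,
#'   compound id to confidence) and `components` (list of character
#'   vectors, one per source component). An empty graph yields an empty
#'   seed set.
#' @export
compute_seed_set <- function(graph, max_component_size = Inf) {
  stopifnot(inherits(graph, "compound_graph"))
  if (length(graph$nodes) == 0L) {
    return(structure(list(owner = graph$owner,
                          entries = stats::setNames(numeric(0),
                                                    character(0)),
                          components = list()),
                     class = "seed_set"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges[, "from"], to = graph$edges[, "to"],
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = graph$nodes)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  el <- igraph::as_edgelist(g, names = TRUE)
  cross <- memb[el[, 1L]] != memb[el[, 2L]]
  has_incoming <- unique(memb[el[cross, 2L]])
  source_comps <- setdiff(seq_len(comp$no), has_incoming)
  components <- lapply(source_comps, function(ci)
    sort(names(memb)[memb == ci]))
  components <- components[vapply(components, length, integer(1)) <=
                             max_component_size]
  components <- components[order(vapply(components, `[`, character(1), 1L))]
  entries <- unlist(lapply(components, function(cc)
    stats::setNames(rep(1 / length(cc), length(cc)), cc)))
  if (is.null(entries)) entries <- stats::setNames(numeric(0), character(0))
  entries <- entries[order(names(entries))]
  structure(list(owner = graph$owner, entries = entries,
                 components = components),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", x$owner, ": ", length(x$entries),
      " seed compounds in ", length(x$components),
      " source components\n", sep = "")
  invisible(x)
}

#' Convenience: seed set straight from a network
#'
#' @inheritParams build_compound_graph
#' @inheritParams compute_seed_set
#' @return A `"seed_set"`.
#' @export
network_seed_set <- function(network, exclude = NULL,
                             max_component_size = Inf) {
  compute_seed_set(build_compound_graph(network, exclude),
                   max_component_size = max_component_size)
}

seed_weight <- function(seed_set, which, weighted) {
  if (weighted) sum(seed_set$entries[which]) else length(which)
}

seed_total <- function(seed_set, weighted) {
  if (weighted) sum(seed_set$entries) else length(seed_set$entries)
}

check_focal <- function(focal) {
  stopifnot(inherits(focal, "seed_set"))
  if (length(focal$entries) == 0L) {
    stop("focal seed set is empty; the index is undefined", call. = FALSE)
  }
}

#' Metabolic competition index of an ordered species pair
#'
#' The fraction of the focal species' seed set that is also in the
#' partner's seed set — overlapping exogenous requirements indicate
#' competition for the same resources. Confidence-weighted on the focal
#' side by default. Ranges from 0 (no competition) to 1 (complete
#' overlap); not symmetric in general. Values exceeding a threshold
#' (0.6 by convention) flag potential competitors.
#'
#' @param focal,partner `"seed_set"` objects.
#' @param weighted If `TRUE` (default) qualifying seeds are weighted by
#'   their confidences; if `FALSE`, the plain fraction of seed compounds.
#' @return A value in \[0, 1\].
#' @export
competition_index <- function(focal, partner, weighted = TRUE) {
  check_focal(focal)
  overlap <- intersect(names(focal$entries), names(partner$entries))
  seed_weight(focal, overlap, weighted) / seed_total(focal, weighted)
}

#' Metabolic complementarity index of an ordered pair
#'
#' The fraction of the focal species' seed set that the partner's network
#' contains outside the partner's own seed set — compounds the partner
#' can synthesize (rather than also requiring) and could therefore supply
#' to the focal species.
#'
#' @param focal A `"seed_set"`.
#' @param partner_network The partner's [metabolic_network()].
#' @param partner_seeds The partner's `"seed_set"`; computed from
#'   `partner_network` when omitted.
#' @inheritParams competition_index
#' @return A value in \[0, 1\].
#' @export
complementarity_index <- function(focal, partner_network,
                                  partner_seeds = NULL, weighted = TRUE) {
  check_focal(focal)
  stopifnot(inherits(partner_network, "metabolic_network"))
  if (is.null(partner_seeds)) {
    partner_seeds <- network_seed_set(partner_network)
  }
  qualifying <- setdiff(
    intersect(names(focal$entries), partner_network$compounds),
    names(partner_seeds$entries))
  seed_weight(focal, qualifying, weighted) / seed_total(focal, weighted)
}

#' Biosynthetic support score (BSS)
#'
#' The fraction of a consumer's seed set present anywhere in a
#' supporter's compound set (the supporter's own seeds included): the
#' capacity of the supporter's metabolism to sustain the consumer's
#' exogenous requirements.
#'
#' @param consumer A `"seed_set"`.
#' @param supporter_network The supporter's [metabolic_network()].
#' @inheritParams competition_index
#' @return A value in \[0, 1\].
#' @export
biosynthetic_support_score <- function(consumer, supporter_network,
                                       weighted = TRUE) {
  check_focal(consumer)
  stopifnot(inherits(supporter_network, "metabolic_network"))
  supported <- intersect(names(consumer$entries),
                         supporter_network$compounds)
  seed_weight(consumer, supported, weighted) /
    seed_total(consumer, weighted)
}

#' Pairwise interaction matrix over a set of networks
#'
#' Computes the chosen reverse-ecology metric for every ordered pair of
#' species (rows: focal/consumer, columns: partner/supporter), including
#' the self-pair diagonal. `"mci"` (metabolic complementarity index) is
#' the complementarity formula exposed under the host-microbe pairing
#' name; the two entry points share one implementation by design.
#'
#' @param networks List of at least two [metabolic_network()] objects.
#' @param metric One of `"competition"`, `"complementarity"`, `"bss"`,
#'   `"mci"`.
#' @param exclude Optional compound exclusion list passed to the graph
#'   construction.
#' @inheritParams competition_index
#' @return A numeric matrix with species ids as dimnames.
#' @export
pairwise_matrix <- function(networks,
                            metric = c("competition", "complementarity",
                                       "bss", "mci"),
                            exclude = NULL, weighted = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is.list(networks), length(networks) >= 2L)
  ids <- vapply(networks, `[[`, character(1), "species_id")
  stopifnot(!anyDuplicated(ids))
  names(networks) <- ids
  ids <- sort(ids)
  networks <- networks[ids]
  seed_sets <- lapply(networks, network_seed_set, exclude = exclude)
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(focal = ids, partner = ids))
  for (i in ids) {
    for (j in ids) {
      m[i, j] <- switch(
        metric,
        competition = competition_index(seed_sets[[i]], seed_sets[[j]],
                                        weighted = weighted),
        complementarity = ,
        mci = complementarity_index(seed_sets[[i]], networks[[j]],
                                    seed_sets[[j]], weighted = weighted),
        bss = biosynthetic_support_score(seed_sets[[i]], networks[[j]],
                                         weighted = weighted))
    }
  }
  m
}
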