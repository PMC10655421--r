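# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic-instance generator
#'
#' Describes a community with planted ground truth: a hub of essential
#' species jointly carrying linear target pathways, inert decoy species,
#' optionally a pair of competitor species (identical copies of one hub
#' member, forcing identical reverse-ecology seed sets and competition
#' index 1.0 — and therefore interchangeable optima, recorded via the
#' ambiguity flag), and optionally a host network carrying one pathway
#' segment so that a smaller community suffices when the host is present.
#'
#' @param n_species Total number of member species.
#' @param n_targets Number of target compounds, one linear pathway each.
#' @param chain_length Reactions per target pathway; must be at least
#'   `ceiling(n_hub / n_targets)` so every hub member can own a segment.
#' @param n_hub Size of the planted minimal community.
#' @param n_decoys Minimum number of inert decoy species; any species
#'   slots not taken by hub or competitor-pair members are filled with
#'   further decoys.
#' @param plant_competitor_pair Plant two copies of one hub member?
#' @param plant_host_support Plant a host carrying one pathway segment?
#' @param n_seeds_per_chain Seed-medium compounds consumed by the first
#'   reaction of each pathway.
#' @param n_clutter Dead-end clutter reactions per hub species (products
#'   are fresh compounds, so minimality and seed sets are unaffected).
#' @param rng_seed Integer seed; generation is a pure function of the
#'   config.
#' @return A `"generator_config"` list.
#' @export
generator_config <- function(n_species = 10L, n_targets = 2L,
                             chain_length = 4L, n_hub = 4L,
                             n_decoys = 2L,
                             plant_competitor_pair = FALSE,
                             plant_host_support = FALSE,
                             n_seeds_per_chain = 2L, n_clutter = 2L,
                             rng_seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_targets = as.integer(n_targets),
              chain_length = as.integer(chain_length),
              n_hub = as.integer(n_hub),
              n_decoys = as.integer(n_decoys),
              plant_competitor_pair = isTRUE(plant_competitor_pair),
              plant_host_support = isTRUE(plant_host_support),
              n_seeds_per_chain = as.integer(n_seeds_per_chain),
              n_clutter = as.integer(n_clutter),
              rng_seed = as.integer(rng_seed))
  pair_slots <- if (cfg$plant_competitor_pair) 2L else 0L
  if (cfg$n_species < 1L || cfg$n_targets < 1L || cfg$n_hub < 1L ||
      cfg$chain_length < 1L || cfg$n_decoys < 0L ||
      cfg$n_seeds_per_chain < 1L || cfg$n_clutter < 0L) {
    stop("generator_config: counts must be positive (decoys/clutter ",
         "non-negative)", call. = FALSE)
  }
  if (cfg$n_hub > cfg$n_species - cfg$n_decoys - pair_slots) {
    stop("generator_config: need n_hub <= n_species - n_decoys - ",
         pair_slots, call. = FALSE)
  }
  if (cfg$chain_length < ceiling(cfg$n_hub / cfg$n_targets)) {
    stop("generator_config: chain_length too short to give every hub ",
         "member a pathway segment (need >= ",
         ceiling(cfg$n_hub / cfg$n_targets), ")", call. = FALSE)
  }
  if (cfg$plant_host_support && cfg$n_hub < 2L) {
    stop("generator_config: host support needs n_hub >= 2", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a community instance with planted ground truth
#'
#' For each target, a linear pathway is built from fresh seed compounds
#' through `chain_length` reactions to the target compound; the pathway's
#' reactions are partitioned into contiguous segments distributed over
#' the planted hub species so that every hub member is the sole carrier
#' of at least one segment (hence indispensable) and no other species
#' carries any pathway reaction. Decoys receive reactions whose reactants
#' are producible by nothing and absent from the seeds, so they are
#' provably inert. See [generator_config()] for the optional competitor
#' pair and host plants. All randomness (segment partitioning, role
#' placement, clutter) is driven solely by the config's `rng_seed`.
#'
#' @param config A [generator_config()].
#' @return A `"synthetic_instance"` with `instance` (a
#'   [community_instance()]) and `truth`: `planted_hub`,
#'   `planted_minimum_size`, `planted_optima` (for the instance as
#'   generated, host included when planted), `planted_essential`,
#'   `planted_competitor_pairs`, `planted_complementary_pairs`,
#'   `duplicated_hub_member`, `host_relieved_member` and `ambiguity`
#'   (TRUE when the optima are non-unique by construction).
#' @export
generate_instance <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_rng_seed(config$rng_seed, generate_instance_impl(config))
}

generate_instance_impl <- function(cfg) {
  hub_ids <- sprintf("hub%02d", seq_len(cfg$n_hub))
  pair_ids <- if (cfg$plant_competitor_pair) c("dup01", "dup02")
              else character(0)
  n_decoys <- cfg$n_species - cfg$n_hub - length(pair_ids)
  decoy_ids <- if (n_decoys > 0L) sprintf("decoy%02d", seq_len(n_decoys))
               else character(0)

  # Assign hub members to chains round-robin, then split each chain into
  # contiguous segments, one per assigned member, at random cut points.
  chain_of <- ((seq_len(cfg$n_hub) - 1L) %% cfg$n_targets) + 1L
  reactions_of <- stats::setNames(
    replicate(cfg$n_hub, list(), simplify = FALSE), hub_ids)
  seeds <- character(0)
  targets <- character(0)
  complementary <- list()
  segment_owner <- list()  # per chain: owner of each reaction position

  for (t in seq_len(cfg$n_targets)) {
    chain_members <- hub_ids[chain_of == t]
    if (length(chain_members) == 0L) {
      # more chains than hub members: hand the spare chain to one member
      chain_members <- hub_ids[((t - 1L) %% cfg$n_hub) + 1L]
    }
    chain_members <- sample(chain_members)  # segment order varies
    k <- length(chain_members)
    chain_seeds <- sprintf("t%d_seed%d", t, seq_len(cfg$n_seeds_per_chain))
    seeds <- c(seeds, chain_seeds)
    target_id <- sprintf("t%d_target", t)
    targets <- c(targets, target_id)
    comps <- c(sprintf("t%d_c%d", t, seq_len(cfg$chain_length - 1L)),
               target_id)
    # cut chain_length reactions into k contiguous non-empty segments
    cuts <- if (k > 1L) {
      sort(sample(seq_len(cfg$chain_length - 1L), k - 1L))
    } else {
      integer(0)
    }
    bounds <- c(0L, cuts, cfg$chain_length)
    owners <- character(cfg$chain_length)
    for (s in seq_len(k)) {
      owners[(bounds[s] + 1L):bounds[s + 1L]] <- chain_members[s]
    }
    segment_owner[[t]] <- owners
    for (j in seq_len(cfg$chain_length)) {
      reactants <- if (j == 1L) chain_seeds else comps[j - 1L]
      rx <- reaction(sprintf("t%d_r%d", t, j), reactants, comps[j])
      own <- owners[j]
      reactions_of[[own]] <- c(reactions_of[[own]], list(rx))
    }
    for (j in seq_len(cfg$chain_length - 1L)) {
      if (owners[j] != owners[j + 1L]) {
        complementary[[length(complementary) + 1L]] <-
          c(focal = owners[j + 1L], partner = owners[j])
      }
    }
  }

  # Clutter: from a member's own pathway products to fresh dead ends.
  if (cfg$n_clutter > 0L) {
    for (id in hub_ids) {
      own_products <- unique(unlist(lapply(reactions_of[[id]],
                                           `[[`, "products")))
      for (j in seq_len(cfg$n_clutter)) {
        src <- sample(own_products, 1L)
        reactions_of[[id]] <- c(reactions_of[[id]], list(
          reaction(sprintf("clut_%s_%d", id, j), src,
                   sprintf("clut_%s_p%d", id, j))))
      }
    }
  }

  members <- lapply(hub_ids, function(id)
    metabolic_network(id, reactions_of[[id]]))
  names(members) <- hub_ids

  dup_of <- NULL
  if (cfg$plant_competitor_pair) {
    dup_of <- sample(hub_ids, 1L)
    for (pid in pair_ids) {
      members[[pid]] <- metabolic_network(pid, reactions_of[[dup_of]])
    }
  }

  for (d in seq_along(decoy_ids)) {
    id <- decoy_ids[d]
    rxs <- lapply(seq_len(2L), function(j)
      reaction(sprintf("decoy_%s_r%d", id, j),
               sprintf("inert_%s_in", id),
               sprintf("inert_%s_p%d", id, j)))
    members[[id]] <- metabolic_network(id, rxs)
  }

  host <- NULL
  relieved <- NULL
  if (cfg$plant_host_support) {
    candidates <- setdiff(hub_ids, dup_of)
    relieved <- sample(candidates, 1L)
    host_rxs <- Filter(function(r) !grepl("^clut_", r$id),
                       reactions_of[[relieved]])
    host <- metabolic_network("host_plant",
                              lapply(host_rxs, function(r)
                                reaction(paste0("host_", r$id),
                                         r$reactants, r$products,
                                         r$reversible)))
  }

  category_pool <- c("amino acid", "organic acid", "aromatic compound",
                     "vitamin", "phytohormone", "nucleotide component",
                     "cofactor", "inorganic ion", "other")
  categories <- stats::setNames(
    category_pool[((seq_along(targets) - 1L) %% length(category_pool)) + 1L],
    targets)

  instance <- community_instance(unname(members), seeds,
                                 target_set(targets, categories),
                                 host = host)

  base <- hub_ids
  if (!is.null(relieved)) base <- setdiff(base, relieved)
  if (!is.null(dup_of) && dup_of %in% base) {
    optima <- lapply(c(dup_of, pair_ids), function(x)
      sort(c(setdiff(base, dup_of), x)))
  } else {
    optima <- list(sort(base))
  }
  competitor_pairs <- NULL
  if (!is.null(dup_of)) {
    trio <- c(dup_of, pair_ids)
    idx <- expand.grid(a = trio, b = trio, stringsAsFactors = FALSE)
    idx <- idx[idx$a != idx$b, , drop = FALSE]
    competitor_pairs <- data.frame(focal = idx$a, partner = idx$b,
                                   expected_competition = 1,
                                   stringsAsFactors = FALSE,
                                   row.names = NULL)
  }
  truth <- list(
    planted_hub = sort(hub_ids),
    planted_minimum_size = length(base),
    planted_optima = optima,
    planted_essential = sort(Reduce(intersect, optima)),
    planted_competitor_pairs = competitor_pairs,
    planted_complementary_pairs = unique(do.call(
      rbind, c(lapply(complementary, function(p)
        data.frame(focal = p[["focal"]], partner = p[["partner"]],
                   stringsAsFactors = FALSE)), list(NULL)))),
    duplicated_hub_member = dup_of,
    host_relieved_member = relieved,
    ambiguity = length(optima) > 1L
  )
  structure(list(instance = instance, truth = truth, config = cfg),
            class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat("<synthetic_instance> ", length(x$instance$members), " species, ",
      length(x$instance$targets$compounds), " targets; planted optimum ",
      "size ", x$truth$planted_minimum_size,
      if (x$truth$ambiguity) " (ambiguous optima)" else "", "\n",
      sep = "")
  invisible(x)
}

#' Generate random gene annotations for a synthetic instance
#'
#' Samples gene presence independently per (genome, gene) at the given
#' probability over the catalog's symbols; one genome (the
#' lexicographically first) is additionally forced to carry the
#' catalog's first category in full, so a complete trait set always
#' occurs.
#'
#' @param instance A `"synthetic_instance"`, [community_instance()] or
#'   character vector of genome ids.
#' @param catalog A `"pgpt_catalog"`.
#' @param per_category_presence Presence probability in \[0, 1\].
#' @param rng_seed Integer seed.
#' @return A named list mapping genome id to gene symbols, usable with
#'   [screen_genomes()].
#' @export
generate_annotations <- function(instance, catalog = load_catalog(),
                                 per_category_presence = 0.5,
                                 rng_seed = 1L) {
  stopifnot(per_category_presence >= 0, per_category_presence <= 1)
  ids <- if (inherits(instance, "synthetic_instance")) {
    names(instance$instance$members)
  } else if (inherits(instance, "community_instance")) {
    names(instance$members)
  } else {
    as.character(instance)
  }
  ids <- sort(ids)
  genes <- unlist(catalog$categories, use.names = FALSE)
  with_rng_seed(rng_seed, {
    ann <- lapply(ids, function(g) {
      genes[stats::runif(length(genes)) < per_category_presence]
    })
    names(ann) <- ids
    ann[[ids[1L]]] <- sort(unique(c(ann[[ids[1L]]],
                                    catalog$categories[[1L]])))
    ann
  })
}
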