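competition_matrix_of <- function(networks, weighted = TRUE) {
  ids <- sort(vapply(networks, `[[`, character(1), "species_id"))
  if (length(ids) < 2L) {
    return(matrix(1, length(ids), length(ids),
                  dimnames = list(focal = ids, partner = ids)))
  }
  pairwise_matrix(networks, "competition", weighted = weighted)
}

#' Iteratively exclude over-competitive species
#'
#' Recomputes the full pairwise competition matrix on the current member
#' set and, while any off-diagonal entry exceeds the threshold, removes
#' one species per round: the species involved in the greatest number of
#' violating pairs; ties broken by greater mean off-diagonal competition,
#' then by lexicographically last id. Each removal is recorded with the
#' largest violating index value that triggered it. The procedure is
#' deterministic.
#'
#' @param members List of [metabolic_network()] objects (at least one).
#' @param threshold Competition index above which (strictly) a pair is a
#'   violation; default 0.6.
#' @inheritParams competition_index
#' @return A `"prune_result"` with `kept` (sorted species ids),
#'   `excluded` (data frame with `species_id`, `reason`, `index_value`,
#'   in removal order), `matrix_before` and `matrix_after`.
#' @export
prune_competitors <- function(members, threshold = 0.6, weighted = TRUE) {
  stopifnot(is.list(members), length(members) >= 1L,
            is.numeric(threshold), threshold >= 0, threshold <= 1)
  ids <- unname(vapply(members, `[[`, character(1), "species_id"))
  names(members) <- ids
  current <- sort(ids)
  matrix_before <- competition_matrix_of(members[current],
                                         weighted = weighted)
  excluded <- data.frame(species_id = character(0),
                         reason = character(0),
                         index_value = numeric(0),
                         stringsAsFactors = FALSE)
  repeat {
    if (length(current) < 2L) break
    m <- competition_matrix_of(members[current], weighted = weighted)
    off <- m
    diag(off) <- NA_real_
    viol <- which(off > threshold, arr.ind = TRUE)
    if (nrow(viol) == 0L) break
    counts <- stats::setNames(integer(length(current)), current)
    for (r in seq_len(nrow(viol))) {
      i <- current[viol[r, 1L]]
      j <- current[viol[r, 2L]]
      counts[i] <- counts[i] + 1L
      counts[j] <- counts[j] + 1L
    }
    cand <- names(counts)[counts == max(counts)]
    if (length(cand) > 1L) {
      mean_comp <- vapply(cand, function(id) {
        mean(c(off[id, ], off[, id]), na.rm = TRUE)
      }, numeric(1))
      cand <- cand[mean_comp == max(mean_comp)]
    }
    victim <- cand[order(cand)][length(cand)]  # lexicographically last
    trig <- max(c(off[victim, ], off[, victim]), na.rm = TRUE)
    excluded <- rbind(excluded, data.frame(
      species_id = victim,
      reason = sprintf("competition index %.6g exceeds threshold %.6g",
                       trig, threshold),
      index_value = trig, stringsAsFactors = FALSE))
    current <- setdiff(current, victim)
  }
  if (length(current) == 0L) {
    stop("competitor pruning removed every member; exclusion trail: ",
         paste(excluded$species_id, collapse = " -> "), call. = FALSE)
  }
  matrix_after <- competition_matrix_of(members[current],
                                        weighted = weighted)
  structure(
    list(kept = current, excluded = excluded, threshold = threshold,
         matrix_before = matrix_before, matrix_after = matrix_after),
    class = "prune_result"
  )
}

#' @export
print.prune_result <- function(x, ...) {
  cat("<prune_result> kept ", length(x$kept), " species, excluded ",
      nrow(x$excluded), " at threshold ", x$threshold, "\n", sep = "")
  if (nrow(x$excluded)) {
    for (r in seq_len(nrow(x$excluded))) {
      cat("  - ", x$excluded$species_id[r], ": ", x$excluded$reason[r],
          "\n", sep = "")
    }
  }
  invisible(x)
}

annotate_categories <- function(compounds, targets) {
  cats <- rep(NA_character_, length(compounds))
  if (!is.null(targets) && !is.null(targets$categories)) {
    hit <- match(compounds, names(targets$categories))
    cats[!is.na(hit)] <- unname(targets$categories[hit[!is.na(hit)]])
  }
  data.frame(compound = compounds, category = cats,
             stringsAsFactors = FALSE)
}

#' Host-microbe metabolic support summary
#'
#' For every ordered (consumer, supporter) pair across the community
#' members and the hosts — in both directions — computes the biosynthetic
#' support score (BSS) and the metabolic complementarity index (MCI). A
#' pair (A, B) means A is metabolically supported or complemented by B.
#' The concrete seed compounds counted by the BSS are aggregated per
#' direction and annotated with target categories when available.
#'
#' @param members List of community [metabolic_network()] objects.
#' @param hosts List of host [metabolic_network()] objects.
#' @param targets Optional [target_set()] supplying category labels.
#' @inheritParams competition_index
#' @return A `"host_support"` list with `pairs` (data frame: `consumer`,
#'   `supporter`, `direction`, `bss`, `mci`) and `supported_compounds`
#'   (data frames `host_to_community` and `community_to_host`).
#' @export
host_support_summary <- function(members, hosts, targets = NULL,
                                 weighted = TRUE) {
  stopifnot(is.list(members), length(members) >= 1L,
            is.list(hosts), length(hosts) >= 1L)
  member_ids <- vapply(members, `[[`, character(1), "species_id")
  host_ids <- vapply(hosts, `[[`, character(1), "species_id")
  names(members) <- member_ids
  names(hosts) <- host_ids
  member_seeds <- lapply(members, network_seed_set)
  host_seeds <- lapply(hosts, network_seed_set)

  rows <- list()
  supported <- list(host_to_community = character(0),
                    community_to_host = character(0))
  for (h in sort(host_ids)) {
    for (m in sort(member_ids)) {
      # member supported by host
      bss_mh <- biosynthetic_support_score(member_seeds[[m]], hosts[[h]],
                                           weighted = weighted)
      mci_mh <- complementarity_index(member_seeds[[m]], hosts[[h]],
                                      host_seeds[[h]], weighted = weighted)
      # host supported by member
      bss_hm <- biosynthetic_support_score(host_seeds[[h]], members[[m]],
                                           weighted = weighted)
      mci_hm <- complementarity_index(host_seeds[[h]], members[[m]],
                                      member_seeds[[m]],
                                      weighted = weighted)
      rows[[length(rows) + 1L]] <- data.frame(
        consumer = c(m, h), supporter = c(h, m),
        direction = c("host_to_community", "community_to_host"),
        bss = c(bss_mh, bss_hm), mci = c(mci_mh, mci_hm),
        stringsAsFactors = FALSE)
      supported$host_to_community <- union(
        supported$host_to_community,
        intersect(names(member_seeds[[m]]$entries),
                  hosts[[h]]$compounds))
      supported$community_to_host <- union(
        supported$community_to_host,
        intersect(names(host_seeds[[h]]$entries),
                  members[[m]]$compounds))
    }
  }
  structure(
    list(pairs = do.call(rbind, rows),
         supported_compounds = list(
           host_to_community = annotate_categories(
             sort(supported$host_to_community), targets),
           community_to_host = annotate_categories(
             sort(supported$community_to_host), targets))),
    class = "host_support"
  )
}

#' Design a synthetic community end to end
#'
#' Runs the full selection pipeline: enumerate all minimal communities
#' for the instance without a host and once per supplied host, classify
#' essential symbionts per run, pool the per-run essential sets (a
#' species is retained when it is essential — present in all optima — in
#' at least one run), iteratively exclude over-competitive species at the
#' competition threshold, and attach PGPT profiles and host-support
#' summaries for the final members.
#'
#' @param instance A [community_instance()]; its own `host` slot, if set,
#'   is treated as one of `hosts`.
#' @param annotations Optional named list (genome id to gene symbols) for
#'   PGPT screening of the final members.
#' @param hosts Optional list of host [metabolic_network()] objects.
#' @param threshold Competition-index exclusion threshold (default 0.6,
#'   strict inequality).
#' @param cap Enumeration cap per run; a truncated enumeration aborts the
#'   design (essentiality from a truncated run would be unsound).
#' @param catalog PGPT catalog for screening.
#' @inheritParams competition_index
#' @return A `"syncom_report"` with `initial_members`,
#'   `essential_symbionts`, `per_run` (per-run optimum sizes, optima and
#'   essential/alternative breakdown), `excluded`, `final_members`,
#'   `competition_matrix_before`/`_after`, `host_support`,
#'   `pgpt_summary` and `supported_compounds`.
#' @export
design_syncom <- function(instance, annotations = NULL, hosts = NULL,
                          threshold = 0.6, cap = 1000L,
                          catalog = load_catalog(), weighted = TRUE) {
  stopifnot(inherits(instance, "community_instance"))
  if (is.null(hosts)) hosts <- list()
  if (inherits(hosts, "metabolic_network")) hosts <- list(hosts)
  if (!is.null(instance$host)) {
    host_ids_given <- vapply(hosts, `[[`, character(1), "species_id")
    if (!(instance$host$species_id %in% host_ids_given)) {
      hosts <- c(hosts, list(instance$host))
    }
  }
  members <- instance$members
  initial_members <- names(members)

  run_instance <- function(host) {
    community_instance(unname(members), instance$seeds, instance$targets,
                       host = host)
  }
  run_hosts <- c(list(none = NULL),
                 stats::setNames(hosts, vapply(hosts, `[[`, character(1),
                                               "species_id")))
  per_run <- lapply(names(run_hosts), function(label) {
    res <- withCallingHandlers(
      enumerate_minimal_communities(run_instance(run_hosts[[label]]),
                                    cap = cap),
      warning = function(w) {
        warning("mincom stage [run ", label, "]: ", conditionMessage(w),
                call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (isTRUE(res$truncated)) {
      stop("mincom stage [run ", label, "]: enumeration truncated at cap ",
           cap, "; essentiality would be unsound", call. = FALSE)
    }
    list(run = label, optimum_size = res$optimum_size,
         n_optima = length(res$all_solutions),
         all_solutions = res$all_solutions,
         essential = res$essential, alternative = res$alternative,
         unproducible_targets = res$unproducible_targets)
  })
  names(per_run) <- names(run_hosts)

  essential <- sort(unique(unlist(lapply(per_run, `[[`, "essential"),
                                  use.names = FALSE)))
  if (length(essential) == 0L) {
    warning("selection stage: no species is essential in any run; ",
            "the selection is empty", call. = FALSE)
    prune <- NULL
    final <- character(0)
  } else {
    prune <- prune_competitors(members[essential], threshold = threshold,
                               weighted = weighted)
    final <- prune$kept
  }

  pgpt <- NULL
  if (!is.null(annotations) && length(final)) {
    ann <- annotations[intersect(names(annotations), final)]
    if (length(ann)) pgpt <- screen_genomes(ann, catalog = catalog)
  }
  support <- NULL
  if (length(hosts) && length(final)) {
    support <- host_support_summary(members[final], hosts,
                                    targets = instance$targets,
                                    weighted = weighted)
  }
  structure(
    list(initial_members = initial_members,
         essential_symbionts = essential,
         per_run = per_run,
         excluded = if (is.null(prune)) NULL else prune$excluded,
         final_members = final,
         threshold = threshold,
         competition_matrix_before = if (is.null(prune)) NULL else
           prune$matrix_before,
         competition_matrix_after = if (is.null(prune)) NULL else
           prune$matrix_after,
         host_support = if (is.null(support)) NULL else support$pairs,
         supported_compounds = if (is.null(support)) NULL else
           support$supported_compounds,
         pgpt_summary = pgpt),
    class = "syncom_report"
  )
}

#' @export
print.syncom_report <- function(x, ...) {
  cat("<syncom_report>\n")
  cat("  initial members:    ", length(x$initial_members), "\n", sep = "")
  cat("  essential symbionts:",
      if (length(x$essential_symbionts))
        paste("", paste(x$essential_symbionts, collapse = ", "))
      else " (none)", "\n", sep = "")
  if (!is.null(x$excluded) && nrow(x$excluded)) {
    cat("  excluded: ", paste(x$excluded$species_id, collapse = ", "),
        "\n", sep = "")
  }
  cat("  final SynCom:       ",
      if (length(x$final_members))
        paste(x$final_members, collapse = ", ")
      else "(empty)", "\n", sep = "")
  invisible(x)
}

#' Write a SynCom design report to JSON
#'
#' Serialization is fully deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report A `"syncom_report"` from [design_syncom()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_syncom_report <- function(report, path) {
  stopifnot(inherits(report, "syncom_report"))
  matrix_to_list <- function(m) {
    if (is.null(m)) return(NULL)
    list(species = rownames(m),
         values = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
  }
  pgpt_to_list <- function(profiles) {
    if (is.null(profiles)) return(NULL)
    lapply(unname(profiles), function(p) {
      list(genome_id = p$genome_id,
           categories = lapply(p$categories, function(cc) {
             list(present = as.list(cc$present),
                  n_genes = cc$n_genes,
                  completeness = cc$completeness,
                  complete = cc$complete)
           }))
    })
  }
  obj <- list(
    initial_members = as.list(report$initial_members),
    essential_symbionts = as.list(report$essential_symbionts),
    per_run = lapply(unname(report$per_run), function(r) {
      list(run = r$run, optimum_size = r$optimum_size,
           n_optima = r$n_optima,
           all_solutions = lapply(r$all_solutions, as.list),
           essential = as.list(r$essential),
           alternative = as.list(r$alternative),
           unproducible_targets = as.list(r$unproducible_targets))
    }),
    excluded = report$excluded,
    final_members = as.list(report$final_members),
    threshold = report$threshold,
    competition_matrix_before =
      matrix_to_list(report$competition_matrix_before),
    competition_matrix_after =
      matrix_to_list(report$competition_matrix_after),
    host_support = report$host_support,
    supported_compounds = report$supported_compounds,
    pgpt_summary = pgpt_to_list(report$pgpt_summary)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
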