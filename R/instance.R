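network_from_list <- function(x, field = "species") {
  if (is.null(x$id) || !nzchar(x$id)) {
    stop("instance field '", field, "': missing species id", call. = FALSE)
  }
  if (is.null(x$reactions)) {
    stop("instance field '", field, "' (", x$id, "): missing 'reactions'",
         call. = FALSE)
  }
  reactions <- lapply(x$reactions, function(r) {
    if (is.null(r$id)) {
      stop("instance field '", field, "' (", x$id,
           "): reaction without an id", call. = FALSE)
    }
    reaction(r$id, unlist(r$reactants), unlist(r$products),
             isTRUE(r$reversible))
  })
  metabolic_network(x$id, reactions)
}

parse_target_field <- function(targets) {
  if (is.null(targets) || length(targets) == 0L) {
    stop("instance field 'targets': must list at least one compound",
         call. = FALSE)
  }
  if (is.character(targets)) return(target_set(targets))
  ids <- vapply(targets, function(t) {
    if (is.character(t) && length(t) == 1L) t
    else if (!is.null(t$id)) as.character(t$id)
    else stop("instance field 'targets': entry without an id",
              call. = FALSE)
  }, character(1))
  cats <- unlist(lapply(targets, function(t) {
    if (is.list(t) && !is.null(t$category)) {
      stats::setNames(as.character(t$category), t$id)
    }
  }))
  target_set(ids, cats)
}

#' Load a community instance
#'
#' Reads a full design input from either a JSON instance file or a
#' directory of SBML networks plus a `config.yaml`/`config.json` file
#' naming the seeds, targets and (optionally) the host file.
#'
#' The JSON schema is
#' `{"species": [{"id", "reactions": [{"id", "reactants", "products",
#' "reversible"}]}], "seeds": [id], "targets": [{"id", "category"}],
#' "host": {like one species, optional}}`; target entries may also be bare
#' id strings. For a directory, every `*.sbml`/`*.xml` file except the one
#' named by the config's `host:` field becomes a member network.
#'
#' @param path Path to a JSON instance file or an instance directory.
#' @return A validated [community_instance()].
#'
#' @details Target compounds appearing in no network and not in the seeds
#'   raise a warning (they may be unproducible), not an error; duplicate
#'   species ids and schema violations are errors naming the field.
#' @export
load_instance <- function(path) {
  if (dir.exists(path)) return(load_instance_dir(path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("species", "seeds", "targets")) {
    if (is.null(obj[[field]])) {
      stop("instance file '", path, "': missing field '", field, "'",
           call. = FALSE)
    }
  }
  members <- lapply(obj$species, network_from_list)
  host <- if (!is.null(obj$host)) network_from_list(obj$host, "host")
  community_instance(
    members = members,
    seeds = unlist(obj$seeds),
    targets = parse_target_field(obj$targets),
    host = host
  )
}

load_instance_dir <- function(path) {
  cfg_path <- c(file.path(path, "config.yaml"),
                file.path(path, "config.yml"),
                file.path(path, "config.json"))
  cfg_path <- cfg_path[file.exists(cfg_path)][1]
  if (is.na(cfg_path)) {
    stop("instance directory '", path,
         "' has no config.yaml/config.yml/config.json", call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", cfg_path)) {
    jsonlite::read_json(cfg_path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(cfg_path)
  }
  if (is.null(cfg$seeds)) {
    stop("instance config '", cfg_path, "': missing field 'seeds'",
         call. = FALSE)
  }
  if (is.null(cfg$targets)) {
    stop("instance config '", cfg_path, "': missing field 'targets'",
         call. = FALSE)
  }
  sbml_files <- sort(list.files(path, pattern = "\\.(sbml|xml)$",
                                full.names = TRUE, ignore.case = TRUE))
  host <- NULL
  if (!is.null(cfg$host)) {
    host_path <- file.path(path, cfg$host)
    if (!file.exists(host_path)) {
      stop("instance config '", cfg_path, "': host file not found: ",
           cfg$host, call. = FALSE)
    }
    host <- parse_sbml_network(host_path)
    sbml_files <- setdiff(sbml_files, normalizePath(host_path,
                                                    mustWork = FALSE))
    sbml_files <- sbml_files[basename(sbml_files) != cfg$host]
  }
  if (length(sbml_files) == 0L) {
    stop("instance directory '", path, "' contains no member SBML files",
         call. = FALSE)
  }
  community_instance(
    members = lapply(sbml_files, parse_sbml_network),
    seeds = unlist(cfg$seeds),
    targets = parse_target_field(cfg$targets),
    host = host
  )
}

network_to_list <- function(network) {
  list(
    id = network$species_id,
    reactions = lapply(unname(network$reactions), function(r) {
      list(id = r$id, reactants = as.list(r$reactants),
           products = as.list(r$products), reversible = r$reversible)
    })
  )
}

#' Write a community instance to a JSON file
#'
#' Inverse of [load_instance()] for the JSON format; element ordering is
#' deterministic so two writes of the same instance are byte-identical.
#'
#' @param instance A [community_instance()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path) {
  stopifnot(inherits(instance, "community_instance"))
  targets <- lapply(instance$targets$compounds, function(id) {
    cat <- instance$targets$categories[id]
    if (length(cat) == 1L && !is.na(cat)) list(id = id, category = unname(cat))
    else list(id = id)
  })
  obj <- list(
    species = lapply(unname(instance$members), network_to_list),
    seeds = as.list(instance$seeds),
    targets = targets
  )
  if (!is.null(instance$host)) obj$host <- network_to_list(instance$host)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
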