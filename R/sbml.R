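#' Read a metabolic network from an SBML file
#'
#' Reads the subset of SBML Level 3 core used by qualitative GSMNs: the
#' species list and the reaction list with reactant/product species
#' references and the `reversible` attribute. Kinetic laws, annotations,
#' units and compartments (beyond any compartment suffix already embedded
#' in the species id) are ignored. Compound ids are taken verbatim from
#' the SBML species ids.
#'
#' @param path Path to an SBML file.
#' @param species_id Optional species identifier for the returned network;
#'   defaults to the SBML model id, falling back to the file base name.
#'
#' @return A [metabolic_network()].
#'
#' @details A missing `reversible` attribute is interpreted as
#'   irreversible. A reaction with an empty reactant or product list is a
#'   validation error naming the reaction id.
#' @export
parse_sbml_network <- function(path, species_id = NULL) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("failed to parse SBML '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) {
    stop("no <model> element in SBML file '", path, "'", call. = FALSE)
  }
  if (is.null(species_id)) {
    species_id <- xml2::xml_attr(model, "id")
    if (is.na(species_id) || !nzchar(species_id)) {
      species_id <- sub("\\.(sbml|xml)$", "", basename(path),
                        ignore.case = TRUE)
    }
  }
  rxn_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rxn_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    reactants <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfReactants/speciesReference"),
      "species")
    products <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfProducts/speciesReference"),
      "species")
    if (length(reactants) == 0L) {
      stop("reaction '", rid, "' in '", path, "' has no reactants",
           call. = FALSE)
    }
    if (length(products) == 0L) {
      stop("reaction '", rid, "' in '", path, "' has no products",
           call. = FALSE)
    }
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    reaction(rid, reactants, products, rev)
  })
  metabolic_network(species_id, reactions)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a metabolic network to an SBML file
#'
#' Emits SBML Level 3 core with a single default compartment. Species and
#' reactions are written in sorted id order so that two writes of the same
#' network are byte-identical.
#'
#' @param network A [metabolic_network()] with at least one reaction.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_network <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  if (length(network$reactions) == 0L) {
    stop("refusing to write a network with no reactions: ",
         network$species_id, call. = FALSE)
  }
  esc <- xml_escape
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
           " level=\"3\" version=\"1\">"),
    paste0("  <model id=\"", esc(network$species_id), "\">"),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"c\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    paste0("      <species id=\"", esc(network$compounds),
           "\" compartment=\"c\" hasOnlySubstanceUnits=\"false\"",
           " boundaryCondition=\"false\" constant=\"false\"/>"),
    "    </listOfSpecies>",
    "    <listOfReactions>"
  )
  for (r in network$reactions) {
    lines <- c(
      lines,
      paste0("      <reaction id=\"", esc(r$id), "\" reversible=\"",
             if (r$reversible) "true" else "false", "\" fast=\"false\">"),
      "        <listOfReactants>",
      paste0("          <speciesReference species=\"", esc(r$reactants),
             "\" constant=\"true\"/>"),
      "        </listOfReactants>",
      "        <listOfProducts>",
      paste0("          <speciesReference species=\"", esc(r$products),
             "\" constant=\"true\"/>"),
      "        </listOfProducts>",
      "      </reaction>"
    )
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
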