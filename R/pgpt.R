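# Default PGPT gene catalog: the eight trait categories with their gene
# symbols, transcribed verbatim (duplicate prints collapsed, first
# occurrence kept). The published count of 86 genes does not reconcile
# exactly with the enumerated symbols (93 printed, 91 unique, including
# the unusual entries "node", "nod" and the "_like" variants); fidelity
# is preferred over cleanup and the discrepancy is kept in the metadata.
pgpt_default_categories <- list(
  "nitrogen fixation" = c(
    "nifA", "nifB", "nifD", "nifE", "nifF", "nifH", "nifHD1", "nifHD2",
    "nifJ", "nifK", "nifM", "nifN", "nifQ", "nifS", "nifT", "nifU",
    "nifV", "nifW", "nifX", "nifZ"),
  "exopolysaccharide production" = c(
    "epsE", "epsD", "epsF", "epsH", "epsI", "epsJ", "epsL", "epsM",
    "epsN", "epsO"),
  "root colonization by nodulation" = c(
    "nodA", "nodB", "nodC", "node", "nodF", "nodI", "nodJ", "nodU",
    "nod", "nodT", "nolM", "noeA", "noeB", "noeC", "noeD", "noeE",
    "nodN", "nodN_like", "nodO", "nodP", "nodS", "nodS_like", "nodY",
    "nodZ", "nodV", "nodV_like", "nodW", "nodX"),
  "oxidative stress ROS scavenging" = c("sodN", "sodC", "sod3"),
  "iron acquisition" = c("lipA", "lipB", "lipL", "lipL2", "lipM", "lplA"),
  "salinity stress potassium transport" = c(
    "kdpA", "kdpB", "kdpC", "kdpD", "kdpE", "kdpF"),
  "plant embryogenesis spermidine" = c(
    "puuA", "puuB", "puuC", "puuD", "puuE", "pup"),
  "IAA-related tryptophan metabolism" = c(
    "trpA", "trpB", "trpC", "trpCF", "trpD", "trpE", "trpEG", "trpG",
    "trpDG", "trpF", "trpS", "trpR")
)

new_pgpt_catalog <- function(categories, metadata = list()) {
  categories <- lapply(categories, function(g) {
    g <- as.character(g)
    g[!duplicated(tolower(g))]
  })
  all_genes <- unlist(categories, use.names = FALSE)
  dup <- unique(all_genes[duplicated(tolower(all_genes))])
  if (length(dup)) {
    stop("gene symbol(s) present in more than one category: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(categories = categories, metadata = metadata),
            class = "pgpt_catalog")
}

#' Load a PGPT gene catalog
#'
#' With no path, returns the packaged catalog of plant growth-promoting
#' trait (PGPT) genes: eight categories (nitrogen fixation,
#' exopolysaccharide production, root colonization by nodulation,
#' oxidative stress/ROS scavenging, iron acquisition, salinity
#' stress-potassium transport, plant embryogenesis-spermidine and
#' IAA-related tryptophan metabolism). A custom catalog is a JSON object
#' mapping category name to a gene-symbol array.
#'
#' Symbols are deduplicated case-insensitively within a category on load;
#' a symbol occurring in two categories is an error.
#'
#' @param path Optional path to a JSON catalog.
#' @return A `"pgpt_catalog"` with `categories` (named list of character
#'   vectors) and `metadata`.
#' @examples
#' cat <- load_catalog()
#' lengths(cat$categories)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    return(new_pgpt_catalog(
      pgpt_default_categories,
      metadata = list(
        source = "packaged default",
        n_symbols_printed = 93L,
        n_symbols_unique = length(unique(tolower(
          unlist(pgpt_default_categories, use.names = FALSE)))),
        stated_count = 86L,
        note = paste("the published gene count (86) does not reconcile",
                     "with the enumerated symbols; every distinct",
                     "printed symbol is kept"))))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$categories)) obj <- obj$categories
  if (is.null(names(obj)) || any(!nzchar(names(obj)))) {
    stop("catalog JSON must map category names to gene arrays",
         call. = FALSE)
  }
  new_pgpt_catalog(as.list(obj), metadata = list(source = path))
}

#' @export
print.pgpt_catalog <- function(x, ...) {
  cat("<pgpt_catalog> ", length(x$categories), " categories, ",
      length(unlist(x$categories, use.names = FALSE)), " gene symbols\n",
      sep = "")
  for (nm in names(x$categories)) {
    cat("  ", nm, ": ", length(x$categories[[nm]]), " genes\n", sep = "")
  }
  invisible(x)
}

#' Read a genome annotation table
#'
#' Reads a two-column TSV (genome_id, gene_symbol; one row per
#' assignment, no header by default) into the named-list annotation
#' structure used by [screen_genomes()].
#'
#' @param path Path to the TSV file.
#' @param header Whether the file carries a header line.
#' @return A named list mapping genome id to a character vector of gene
#'   symbols.
#' @export
read_annotations <- function(path, header = FALSE) {
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE,
                           col.names = if (!header)
                             c("genome_id", "gene_symbol") else NULL)
  names(tab)[1:2] <- c("genome_id", "gene_symbol")
  split(trimws(tab$gene_symbol), tab$genome_id)
}

#' Screen genomes against a PGPT catalog
#'
#' Marks, per genome and category, which catalog genes are present in the
#' genome's annotation (exact symbol matching, case-insensitive, after
#' trimming whitespace) and reports per-category completeness: the
#' fraction of the category's genes found, with a `complete` flag when
#' the fraction is exactly 1.
#'
#' @param annotations Named list mapping genome id to a character vector
#'   of annotated gene symbols (see [read_annotations()]).
#' @param catalog A `"pgpt_catalog"`; the packaged default when omitted.
#' @return A list of `"pgpt_profile"` objects ordered by genome id; each
#'   has `genome_id` and `categories`, a named list with `present`,
#'   `completeness` and `complete` per category.
#' @export
screen_genomes <- function(annotations, catalog = load_catalog()) {
  stopifnot(inherits(catalog, "pgpt_catalog"))
  if (length(annotations) == 0L) return(list())
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("annotations must be a named list (genome id -> gene symbols)",
         call. = FALSE)
  }
  if (anyDuplicated(names(annotations))) {
    stop("duplicate genome ids in annotations", call. = FALSE)
  }
  genomes <- sort(names(annotations))
  profiles <- lapply(genomes, function(gid) {
    have <- unique(tolower(trimws(as.character(annotations[[gid]]))))
    cats <- lapply(catalog$categories, function(genes) {
      present <- genes[tolower(genes) %in% have]
      completeness <- length(present) / length(genes)
      list(present = present, n_genes = length(genes),
           completeness = completeness, complete = completeness == 1)
    })
    structure(list(genome_id = gid, categories = cats),
              class = "pgpt_profile")
  })
  names(profiles) <- genomes
  profiles
}

#' @export
print.pgpt_profile <- function(x, ...) {
  cat("<pgpt_profile> ", x$genome_id, "\n", sep = "")
  for (nm in names(x$categories)) {
    cc <- x$categories[[nm]]
    cat(sprintf("  %-36s %d/%d (%.2f)%s\n", nm, length(cc$present),
                cc$n_genes, cc$completeness,
                if (cc$complete) " complete" else ""))
  }
  invisible(x)
}

#' Completeness table for screened genomes
#'
#' @param profiles List of `"pgpt_profile"` objects from
#'   [screen_genomes()].
#' @return A data frame with one row per (genome, category) and columns
#'   `genome_id`, `category`, `n_present`, `n_genes`, `completeness`,
#'   `complete`.
#' @export
pgpt_completeness <- function(profiles) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(names(p$categories), function(nm) {
      cc <- p$categories[[nm]]
      data.frame(genome_id = p$genome_id, category = nm,
                 n_present = length(cc$present),
                 n_genes = cc$n_genes,
                 completeness = cc$completeness,
                 complete = cc$complete,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Gene presence/absence matrix
#'
#' @param profiles List of `"pgpt_profile"` objects.
#' @param catalog The `"pgpt_catalog"` the profiles were screened
#'   against; fixes the gene (column) order.
#' @return A 0/1 integer matrix, genomes (sorted by id) by genes (catalog
#'   order).
#' @export
presence_matrix <- function(profiles, catalog = load_catalog()) {
  stopifnot(inherits(catalog, "pgpt_catalog"))
  genes <- unlist(catalog$categories, use.names = FALSE)
  genomes <- sort(vapply(profiles, `[[`, character(1), "genome_id"))
  m <- matrix(0L, length(genomes), length(genes),
              dimnames = list(genome = genomes, gene = genes))
  for (p in profiles) {
    present <- unlist(lapply(p$categories, `[[`, "present"),
                      use.names = FALSE)
    m[p$genome_id, match(present, genes)] <- 1L
  }
  m
}
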