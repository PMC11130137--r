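#' Catalog of symbiont functional groups
#'
#' The 16 functional groups of arthropod symbionts recorded in red wood ant
#' nests: 9 obligate myrmecophile groups (found only with ants) and 7
#' facultative groups (soil generalists that opportunistically use the nest).
#' Feeding ecology is encoded in the id suffix: \code{_P} predator, \code{_S}
#' scavenger, \code{_SP} scavenger-predator, \code{_D} detritivore, \code{_B}
#' brood predator.
#'
#' @return A data.frame with columns \code{id} (ASCII slug), \code{label}
#'   (display name with subscript notation), \code{association}
#'   (\code{"obligate"} or \code{"facultative"}) and \code{trophic_role}.
#' @examples
#' fg <- functional_groups()
#' table(fg$association)
#' @export
functional_groups <- function() {
  data.frame(
    id = c(
      "spider_P", "rove_beetle_P", "rove_beetle_SP1", "rove_beetle_SP2",
      "rove_beetle_S", "beetle_D", "beetle_B", "springtail_D", "isopod_D",
      "fac_armoured_D", "fac_pred_P1", "fac_pred_P2", "fac_prey_D",
      "fac_rove_beetle_S", "fac_mite_D", "fac_mite_P"
    ),
    label = c(
      "spider_P", "rove beetle_P", "rove beetle_SP1", "rove beetle_SP2",
      "rove beetle_S", "beetle_D", "beetle_B", "springtail_D", "isopod_D",
      "fac armoured_D", "fac pred_P1", "fac pred_P2", "fac prey_D",
      "fac rove beetle_S", "fac mite_D", "fac mite_P"
    ),
    association = c(rep("obligate", 9), rep("facultative", 7)),
    trophic_role = c(
      "predator", "predator", "scavenger_predator", "scavenger_predator",
      "scavenger", "detritivore", "brood_predator", "detritivore",
      "detritivore", "detritivore", "predator", "predator", "detritivore",
      "scavenger", "detritivore", "predator"
    ),
    stringsAsFactors = FALSE
  )
}

#' Basal resource identifiers
#'
#' The two aggregate basal resources of the nest food web: ant brood (eggs,
#' larvae, pupae) and nest food (ant corpses, organic nest material, fungi,
#' spores). They are food-web nodes but are never sampled as community
#' members.
#'
#' @return Character vector of the two basal node ids.
#' @export
basal_resources <- function() c("ant_brood", "nest_food")

#' Construct a general trophic adjacency from an edge list
#'
#' Trophic structure is stored as explicit (consumer, resource) edge records;
#' matrix views are derived on demand via [adjacency_matrix()], never stored,
#' so no row/column orientation convention can silently flip.
#'
#' @param edges data.frame with character columns \code{consumer} and
#'   \code{resource}, one row per trophic link.
#' @param nodes ordered character vector of all node ids (groups then basal
#'   resources). Defaults to the 16-group catalog plus the two basal nodes.
#' @return An object of class \code{"general_adjacency"} with elements
#'   \code{nodes} and \code{edges}.
#' @export
general_adjacency <- function(edges,
                              nodes = c(functional_groups()$id, basal_resources())) {
  stopifnot(is.data.frame(edges), all(c("consumer", "resource") %in% names(edges)))
  edges <- data.frame(consumer = as.character(edges$consumer),
                      resource = as.character(edges$resource),
                      stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(edges$consumer, edges$resource)), nodes)
  if (length(unknown))
    stop("adjacency references unknown node id(s): ", paste(unknown, collapse = ", "))
  if (any(edges$consumer %in% basal_resources()))
    stop("basal resources cannot be consumers")
  if (any(edges$consumer == edges$resource))
    stop("self-links are not allowed")
  if (anyDuplicated(paste(edges$consumer, edges$resource)))
    stop("duplicate edges in adjacency")
  structure(list(nodes = nodes, edges = edges), class = "general_adjacency")
}

#' @export
print.general_adjacency <- function(x, ...) {
  cat("General trophic adjacency:", length(x$nodes), "nodes,",
      nrow(x$edges), "links\n")
  invisible(x)
}

#' Read a general adjacency from a consumer,resource CSV edge list
#'
#' @param path CSV file with header \code{consumer,resource}.
#' @param nodes node universe, as in [general_adjacency()].
#' @return A \code{"general_adjacency"} object.
#' @export
read_adjacency <- function(path, nodes = c(functional_groups()$id, basal_resources())) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  general_adjacency(edges, nodes = nodes)
}

#' The packaged general adjacency of the nest food web
#'
#' Returns the 18-node trophic adjacency over the 16 functional groups and
#' the two basal resources. The packaged edge list is a synthetic
#' reconstruction assembled from the groups' published trophic roles and
#' diets (predators take springtails, other soft-bodied prey and mites;
#' scavengers and detritivores feed on nest food; the brood predator takes
#' ant brood and, through its case-building larvae, organic nest material;
#' the large scavenger-predator takes ant brood, nest food and small
#' arthropod prey); it stands in for the field-calibrated diet table and is
#' shipped as \code{extdata/general_adjacency_synthetic.csv}.
#'
#' @return A \code{"general_adjacency"} object with 18 nodes.
#' @examples
#' adj <- default_general_adjacency()
#' length(adj$nodes)
#' @export
default_general_adjacency <- function() {
  path <- system.file("extdata", "general_adjacency_synthetic.csv",
                      package = "nestwebs", mustWork = TRUE)
  read_adjacency(path)
}

#' Derive a binary adjacency matrix view
#'
#' @param adj a \code{"general_adjacency"}.
#' @param orientation \code{"consumer_by_resource"} (rows are consumers) or
#'   \code{"resource_by_consumer"} (rows are resources).
#' @return Binary integer matrix with dimnames = node ids.
#' @export
adjacency_matrix <- function(adj, orientation = c("consumer_by_resource",
                                                  "resource_by_consumer")) {
  orientation <- match.arg(orientation)
  n <- length(adj$nodes)
  m <- matrix(0L, n, n, dimnames = list(adj$nodes, adj$nodes))
  ci <- match(adj$edges$consumer, adj$nodes)
  ri <- match(adj$edges$resource, adj$nodes)
  if (orientation == "consumer_by_resource") m[cbind(ci, ri)] <- 1L
  else m[cbind(ri, ci)] <- 1L
  m
}

#' Diet of one node
#'
#' @param adj a \code{"general_adjacency"}.
#' @param id consumer node id.
#' @return Character vector of resource ids the node consumes (empty for
#'   basal resources).
#' @export
diet_of <- function(adj, id) {
  stopifnot(id %in% adj$nodes)
  adj$edges$resource[adj$edges$consumer == id]
}

#' Read a nest-by-group abundance table
#'
#' Expects a delimited text file whose first column is \code{nest_id} and
#' whose remaining columns are functional-group ids holding nonnegative
#' integer counts. Missing cells and unknown group columns are errors, never
#' silently imputed: a silent zero would corrupt the downstream rarity
#' quantiles.
#'
#' @param path CSV/TSV file (delimiter sniffed from the header line).
#' @param groups allowed group ids; defaults to the 16-group catalog.
#' @return Named list of abundance vectors (one per nest, named by group id).
#' @export
read_abundance_table <- function(path, groups = functional_groups()$id) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("no data rows in abundance table: ", path)
  if (names(tab)[1] != "nest_id") stop("first column must be 'nest_id'")
  gcols <- names(tab)[-1]
  unknown <- setdiff(gcols, groups)
  if (length(unknown))
    stop("unknown group column(s): ", paste(unknown, collapse = ", "))
  out <- vector("list", nrow(tab))
  names(out) <- tab$nest_id
  for (i in seq_len(nrow(tab))) {
    raw <- unlist(tab[i, -1, drop = FALSE])
    for (j in seq_along(raw)) {
      v <- raw[[j]]
      if (is.na(v) || !nzchar(v))
        stop("missing count at nest '", tab$nest_id[i], "', group '", gcols[j], "'")
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num) || num < 0 || num != round(num))
        stop("invalid count '", v, "' at nest '", tab$nest_id[i],
             "', group '", gcols[j], "' (need nonnegative integer)")
    }
    counts <- as.integer(round(as.numeric(raw)))
    names(counts) <- gcols
    out[[i]] <- counts
  }
  out
}

#' Read nest metadata
#'
#' @param path CSV/TSV with columns \code{nest_id, age_class, connectivity,
#'   moisture, pH, canopy_openness, x, y}.
#' @return data.frame of nest covariates.
#' @export
read_nest_metadata <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("nest_id", "age_class", "connectivity", "moisture", "pH",
            "canopy_openness", "x", "y")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(md$age_class), c("new", "old"))
  if (length(bad)) stop("age_class must be 'new' or 'old', found: ",
                        paste(bad, collapse = ", "))
  md
}

#' Assemble a study dataset
#'
#' Bundles the functional-group catalog, the general adjacency, and per-nest
#' communities (covariates + abundance vector) into one object used by all
#' downstream stages.
#'
#' @param metadata data.frame as returned by [read_nest_metadata()].
#' @param abundance named list of abundance vectors as returned by
#'   [read_abundance_table()], or a nest-by-group matrix.
#' @param adjacency a \code{"general_adjacency"}; default the packaged one.
#' @param catalog functional-group catalog data.frame.
#' @return An object of class \code{"study_dataset"} with elements
#'   \code{catalog}, \code{adjacency}, \code{metadata}, and \code{abundance}
#'   (nest-by-group integer matrix with nest ids as rownames).
#' @export
study_dataset <- function(metadata, abundance,
                          adjacency = default_general_adjacency(),
                          catalog = functional_groups()) {
  if (is.list(abundance) && !is.data.frame(abundance) && !is.matrix(abundance)) {
    groups <- names(abundance[[1]])
    ab <- do.call(rbind, lapply(abundance, function(v) as.integer(v[groups])))
    dimnames(ab) <- list(names(abundance), groups)
  } else {
    ab <- as.matrix(abundance)
    storage.mode(ab) <- "integer"
  }
  ds <- structure(list(catalog = catalog, adjacency = adjacency,
                       metadata = metadata, abundance = ab),
                  class = "study_dataset")
  ds
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Study dataset:", nrow(x$abundance), "nests x",
      ncol(x$abundance), "functional groups\n")
  cat("  age classes:", paste(sprintf("%s=%d", names(table(x$metadata$age_class)),
                                      table(x$metadata$age_class)), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a study dataset
#'
#' Checks every structural invariant of the data model and returns findings
#' rather than raising: an empty character vector means the dataset is valid.
#'
#' @param ds a \code{"study_dataset"}.
#' @return Character vector of human-readable findings (empty if valid).
#' @examples
#' ds <- generate_dataset(preset_paperlike(seed = 1))
#' validate_dataset(ds)  # character(0)
#' @export
validate_dataset <- function(ds) {
  f <- character(0)
  say <- function(...) f <<- c(f, paste0(...))
  cat_ids <- ds$catalog$id
  if (anyDuplicated(cat_ids)) say("duplicate group ids in catalog")
  if (!all(ds$catalog$association %in% c("obligate", "facultative")))
    say("invalid association value in catalog")
  nodes <- ds$adjacency$nodes
  if (!all(cat_ids %in% nodes)) say("catalog group(s) missing from adjacency nodes")
  if (!all(basal_resources() %in% nodes)) say("basal resources missing from adjacency")
  for (g in setdiff(nodes, basal_resources()))
    if (length(diet_of(ds$adjacency, g)) == 0L)
      say("group '", g, "' has an empty diet")
  ids <- ds$metadata$nest_id
  if (anyDuplicated(ids))
    say("duplicate nest_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!setequal(ids, rownames(ds$abundance)) ||
      nrow(ds$metadata) != nrow(ds$abundance))
    say("metadata nest ids do not match abundance rows")
  unknown <- setdiff(colnames(ds$abundance), cat_ids)
  if (length(unknown))
    say("abundance references unknown group id(s): ",
        paste(unknown, collapse = ", "))
  if (any(is.na(ds$abundance)) || any(ds$abundance < 0))
    say("abundance contains missing or negative counts")
  if (!all(ds$metadata$age_class %in% c("new", "old")))
    say("age_class outside {new, old}")
  f
}

#' Write a study dataset to a three-file bundle with a JSON manifest
#'
#' Writes \code{abundance.csv}, \code{metadata.csv},
#' \code{adjacency.csv} plus a \code{manifest.json} naming them.
#'
#' @param ds a \code{"study_dataset"}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_bundle <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ab <- data.frame(nest_id = rownames(ds$abundance), ds$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(ab, file.path(dir, "abundance.csv"), row.names = FALSE)
  utils::write.csv(ds$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(ds$adjacency$edges, file.path(dir, "adjacency.csv"),
                   row.names = FALSE)
  manifest <- list(abundance = "abundance.csv", metadata = "metadata.csv",
                   adjacency = "adjacency.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a study dataset bundle written by [write_bundle()]
#'
#' @param manifest path to the bundle's \code{manifest.json}.
#' @return A \code{"study_dataset"}.
#' @export
read_bundle <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  ab <- read_abundance_table(file.path(dir, m$abundance))
  md <- read_nest_metadata(file.path(dir, m$metadata))
  adj <- read_adjacency(file.path(dir, m$adjacency))
  study_dataset(md, ab, adjacency = adj)
}
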