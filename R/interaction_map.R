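#' Build an interaction map from raw edge records
#'
#' An interaction map is a simple undirected graph over gene identifiers in
#' which each retained pair carries the set of source datasets supporting it
#' (the evidence count) and, optionally, a confidence score. Duplicate
#' (pair, dataset) records are collapsed, self-loops are dropped with a
#' warning, and identifiers are canonicalized by trimming and case-folding.
#'
#' @param edge_records A data frame whose first three columns are interpreted
#'   as protein A, protein B and source dataset id; an optional fourth
#'   (or a column named `confidence`) holds a confidence score in \[0, 1\].
#'   Alternatively a file path accepted by [read_edge_list()].
#' @param isolated_nodes Optional character vector of gene identifiers to
#'   register as nodes even when they touch no edge.
#'
#' @return An object of class `interaction_map`: a list with elements
#'   `edges` (data frame with columns `a`, `b`, `datasets`, `n_datasets`,
#'   `confidence`) and `nodes` (character vector).
#' @export
#' @examples
#' edges <- data.frame(a = c("A", "B", "A"), b = c("B", "A", "B"),
#'                     dataset = c("y2h1", "y2h2", "y2h1"))
#' m <- load_interaction_map(edges)
#' m$edges$n_datasets  # 2: the pair A-B is supported by two datasets
load_interaction_map <- function(edge_records, isolated_nodes = character()) {
  if (is.character(edge_records) && length(edge_records) == 1L) {
    edge_records <- read_edge_list(edge_records)
  }
  stopifnot(is.data.frame(edge_records))
  if (nrow(edge_records) == 0L) {
    return(new_interaction_map(empty_edges(), canonicalize_ids(isolated_nodes)))
  }
  if (ncol(edge_records) < 3L) {
    stop("edge records need at least 3 columns (protein A, protein B, dataset id)")
  }
  a <- canonicalize_ids(edge_records[[1L]])
  b <- canonicalize_ids(edge_records[[2L]])
  ds <- trimws(as.character(edge_records[[3L]]))
  conf <- if ("confidence" %in% names(edge_records)) {
    suppressWarnings(as.numeric(edge_records[["confidence"]]))
  } else if (ncol(edge_records) >= 4L) {
    suppressWarnings(as.numeric(edge_records[[4L]]))
  } else {
    rep(NA_real_, length(a))
  }

  bad <- which(is.na(a) | is.na(b) | a == "" | b == "" | is.na(ds) | ds == "")
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge record at row %d: empty or missing identifier",
                 bad[1L]))
  }

  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge record(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]; ds <- ds[!loops]; conf <- conf[!loops]
  }
  if (length(a) == 0L) {
    return(new_interaction_map(empty_edges(), canonicalize_ids(isolated_nodes)))
  }

  key <- pair_key(a, b)
  # collapse duplicate (pair, dataset) records, then count distinct datasets
  pd <- !duplicated(paste(key, ds, sep = "\n"))
  key <- key[pd]; a <- a[pd]; b <- b[pd]; ds <- ds[pd]; conf <- conf[pd]

  ord <- order(key, ds)
  key <- key[ord]; ds <- ds[ord]; conf <- conf[ord]
  first <- !duplicated(key)
  ends <- do.call(rbind, strsplit(key[first], "\r", fixed = TRUE))
  edges <- data.frame(
    a = ends[, 1L],
    b = ends[, 2L],
    datasets = vapply(split(ds, key), paste, "", collapse = ","),
    n_datasets = as.integer(lengths(split(ds, key))),
    confidence = vapply(split(conf, key),
                        function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
                        0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  nodes <- sort(unique(c(edges$a, edges$b, canonicalize_ids(isolated_nodes))))
  new_interaction_map(edges, nodes)
}

empty_edges <- function() {
  data.frame(a = character(), b = character(), datasets = character(),
             n_datasets = integer(), confidence = numeric(),
             stringsAsFactors = FALSE)
}

new_interaction_map <- function(edges, nodes) {
  nodes <- sort(unique(nodes))
  structure(list(edges = edges, nodes = nodes), class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("<interaction_map> %d nodes, %d edges (%d multi-study)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$n_datasets >= 2L)))
  invisible(x)
}

#' Read an interaction edge list from disk
#'
#' Accepts either a tab-separated file with header
#' `protein_a  protein_b  dataset_id  confidence` (confidence optional) or a
#' 3-column SIF file (`A  interacts  B`), in which case the dataset id
#' defaults to `"unknown"`.
#'
#' @param path Path to the edge-list file.
#' @return A data frame suitable for [load_interaction_map()].
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t")[[1L]]
  if (length(fields) >= 2L && tolower(fields[1L]) == "protein_a") {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(df)[1:3] <- c("protein_a", "protein_b", "dataset_id")
    return(df)
  }
  sif <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(sif) == 3L && !any(grepl("^[0-9.]+$", sif[[3L]]))) {
    # SIF: A <relation> B
    return(data.frame(protein_a = sif[[1L]], protein_b = sif[[3L]],
                      dataset_id = "unknown", stringsAsFactors = FALSE))
  }
  names(sif)[1:min(4L, ncol(sif))] <-
    c("protein_a", "protein_b", "dataset_id", "confidence")[1:min(4L, ncol(sif))]
  sif
}

#' Write an interaction map as a tab-separated edge list
#'
#' Emits one row per (pair, dataset) record with header
#' `protein_a  protein_b  dataset_id  confidence`, the dialect
#' [read_edge_list()] accepts, so maps round-trip through disk.
#'
#' @param map An `interaction_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(map, path) {
  ds <- strsplit(map$edges$datasets, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(map$edges)), lengths(ds))
  records <- data.frame(protein_a = map$edges$a[idx],
                        protein_b = map$edges$b[idx],
                        dataset_id = unlist(ds),
                        confidence = map$edges$confidence[idx],
                        stringsAsFactors = FALSE)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene list (one identifier per line, `#` comments allowed)
#'
#' @param path Path to the file.
#' @return Character vector of canonicalized gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  canonicalize_ids(x[x != ""])
}

#' Declare the bait set of a virtual interaction screen
#'
#' Baits are the seed genes used to query the interaction data (for example,
#' hits of earlier screens plus genes annotated to the process of interest).
#' `rescue_baits` are baits whose interaction partners are always retained by
#' [apply_hub_filter()], regardless of the hub rule — used in the original
#' screen for the central cell cycle kinases Cdk1 and Cdk2.
#'
#' @param genes Character vector of bait gene identifiers.
#' @param rescue_baits Subset of `genes` exempt from hub-based removal.
#' @return An object of class `bait_set`.
#' @export
bait_set <- function(genes, rescue_baits = character()) {
  genes <- unique(canonicalize_ids(genes))
  rescue_baits <- unique(canonicalize_ids(rescue_baits))
  if (!all(rescue_baits %in% genes)) {
    stop("rescue_baits must be a subset of the bait genes")
  }
  structure(list(genes = genes, rescue_baits = rescue_baits),
            class = "bait_set")
}

as_bait_set <- function(x) {
  if (inherits(x, "bait_set")) x else bait_set(x)
}

#' Filtering parameters for the bait neighborhood
#'
#' @param max_bait_degree Baits with strictly more than this many distinct
#'   partners in the neighborhood are treated as hubs and have their partner
#'   edges removed (default 30, the original screen's threshold).
#' @param multi_study_min Minimum number of distinct source datasets for a
#'   removed edge to be added back (default 2: "more than one independent
#'   study").
#' @param min_confidence Optional confidence threshold for
#'   [filter_by_confidence()]; kept here so one config object can describe a
#'   full filtering run.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_bait_degree = 30L, multi_study_min = 2L,
                          min_confidence = NULL) {
  max_bait_degree <- as.integer(max_bait_degree)
  multi_study_min <- as.integer(multi_study_min)
  stopifnot(max_bait_degree >= 0L, multi_study_min >= 2L)
  if (!is.null(min_confidence) &&
      (min_confidence < 0 || min_confidence > 1)) {
    stop("min_confidence must lie in [0, 1]")
  }
  structure(list(max_bait_degree = max_bait_degree,
                 multi_study_min = multi_study_min,
                 min_confidence = min_confidence),
            class = "filter_config")
}

#' Number of distinct interaction partners per node
#'
#' @param map An `interaction_map`.
#' @param nodes Nodes to report (default all nodes of the map; absent nodes
#'   get degree 0).
#' @return Named integer vector of degrees.
#' @export
map_degree <- function(map, nodes = map$nodes) {
  nodes <- canonicalize_ids(nodes)
  tab <- table(c(map$edges$a, map$edges$b))
  deg <- as.integer(tab[nodes])
  deg[is.na(deg)] <- 0L
  names(deg) <- nodes
  deg
}

# Convert to an igraph object (isolated nodes preserved).
as_igraph <- function(map) {
  igraph::graph_from_data_frame(map$edges[, c("a", "b")], directed = FALSE,
                                vertices = data.frame(name = map$nodes))
}
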