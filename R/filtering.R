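#' Extract the bait-centric neighborhood of an interaction map
#'
#' Returns the submap containing exactly the edges with at least one bait
#' endpoint. Baits absent from the map are kept as isolated nodes, so the
#' bait roster is never silently shrunk.
#'
#' @param map An `interaction_map`.
#' @param baits A [bait_set()] or character vector of bait identifiers.
#' @return An `interaction_map` whose non-bait nodes are the candidate
#'   interactors (see [interactors()]).
#' @export
extract_bait_neighborhood <- function(map, baits) {
  baits <- as_bait_set(baits)
  keep <- map$edges$a %in% baits$genes | map$edges$b %in% baits$genes
  edges <- map$edges[keep, , drop = FALSE]
  row.names(edges) <- NULL
  new_interaction_map(edges, c(edges$a, edges$b, baits$genes))
}

#' Candidate interactors of a bait neighborhood
#'
#' @param neighborhood An `interaction_map` produced by
#'   [extract_bait_neighborhood()] (possibly after filtering).
#' @param baits The bait set used to build it.
#' @return Character vector of non-bait genes touching at least one edge.
#' @export
interactors <- function(neighborhood, baits) {
  baits <- as_bait_set(baits)
  setdiff(unique(c(neighborhood$edges$a, neighborhood$edges$b)), baits$genes)
}

#' Remove partners of promiscuous (hub) baits, with rescue rules
#'
#' Baits with strictly more than `config$max_bait_degree` distinct partners in
#' the neighborhood are treated as likely "sticky" proteins and their partner
#' edges are removed. Two rescue rules then add removed edges back:
#' edges supported by at least `config$multi_study_min` distinct source
#' datasets, and all edges touching a rescue bait (partners of designated
#' central regulators are retained unconditionally).
#'
#' Removal operates on edges, not nodes: an edge is removed only when every
#' bait endpoint it has is a hub, so a partner shared with a non-hub bait
#' keeps that connection. Bait degrees are counted in the neighborhood as
#' supplied, before any removal.
#'
#' @param neighborhood Bait neighborhood from [extract_bait_neighborhood()].
#' @param baits A [bait_set()] (its `rescue_baits` drive rule 3).
#' @param config A [filter_config()].
#' @return The filtered `interaction_map`; its edge set is always a subset of
#'   the input's. Node set is preserved (roles are decided downstream).
#' @export
apply_hub_filter <- function(neighborhood, baits, config = filter_config()) {
  baits <- as_bait_set(baits)
  edges <- neighborhood$edges
  if (nrow(edges) == 0L) {
    return(neighborhood)
  }
  deg <- map_degree(neighborhood, baits$genes)
  hubs <- names(deg)[deg > config$max_bait_degree]

  a_bait <- edges$a %in% baits$genes
  b_bait <- edges$b %in% baits$genes
  a_hub <- edges$a %in% hubs
  b_hub <- edges$b %in% hubs
  # removed iff every bait endpoint is a hub (and there is >= 1 bait endpoint)
  removed <- (a_bait | b_bait) &
    (!a_bait | a_hub) & (!b_bait | b_hub)
  rescued <- removed &
    (edges$n_datasets >= config$multi_study_min |
       edges$a %in% baits$rescue_baits | edges$b %in% baits$rescue_baits)
  keep <- !removed | rescued
  out <- edges[keep, , drop = FALSE]
  row.names(out) <- NULL
  new_interaction_map(out, neighborhood$nodes)
}

#' Keep only edges above a confidence threshold
#'
#' Edges with a confidence score strictly greater than `min_confidence` are
#' retained; edges lacking a score are dropped (their count is reported via
#' a message).
#'
#' @param map An `interaction_map`.
#' @param min_confidence Threshold in \[0, 1\] (the original analysis used
#'   0.5).
#' @return The filtered `interaction_map` (node set preserved).
#' @export
filter_by_confidence <- function(map, min_confidence = 0.5) {
  if (!is.numeric(min_confidence) || length(min_confidence) != 1L ||
      is.na(min_confidence) || min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must be a single value in [0, 1]")
  }
  edges <- map$edges
  unscored <- is.na(edges$confidence)
  if (any(unscored)) {
    message(sprintf("dropping %d edge(s) without a confidence score",
                    sum(unscored)))
  }
  keep <- !unscored & edges$confidence > min_confidence
  out <- edges[keep, , drop = FALSE]
  row.names(out) <- NULL
  new_interaction_map(out, map$nodes)
}

#' Partition genes into bait / interactor / non-interactor / unclassified
#'
#' Roles follow the virtual-screen definitions: a bait is any gene of the
#' bait set (bait status overrides everything); an interactor is a non-bait
#' gene with at least one edge in the filtered bait neighborhood; a
#' non-interactor candidate is a gene of the full map that is neither a bait
#' nor adjacent (in the full map) to any bait or interactor; everything else
#' is unclassified.
#'
#' @param full_map The complete `interaction_map` that was queried.
#' @param baits A [bait_set()] or character vector.
#' @param filtered_neighborhood The filtered bait neighborhood.
#' @return A data frame with columns `gene` and `role` (factor with levels
#'   `bait`, `interactor`, `non_interactor`, `unclassified`). Every node of
#'   `full_map` (plus any bait absent from it) receives exactly one role.
#' @export
assign_roles <- function(full_map, baits, filtered_neighborhood) {
  baits <- as_bait_set(baits)
  genes <- sort(unique(c(full_map$nodes, baits$genes)))
  inter <- interactors(filtered_neighborhood, baits)

  adj_a <- split(full_map$edges$b, full_map$edges$a)
  adj_b <- split(full_map$edges$a, full_map$edges$b)
  neighbors_of <- function(set) {
    unique(c(unlist(adj_a[intersect(names(adj_a), set)], use.names = FALSE),
             unlist(adj_b[intersect(names(adj_b), set)], use.names = FALSE)))
  }
  near_bait <- neighbors_of(baits$genes)
  near_inter <- neighbors_of(inter)

  role <- rep("unclassified", length(genes))
  names(role) <- genes
  candidates <- setdiff(full_map$nodes, c(baits$genes, near_bait, near_inter))
  role[candidates] <- "non_interactor"
  role[intersect(genes, inter)] <- "interactor"
  role[intersect(genes, baits$genes)] <- "bait"

  data.frame(gene = genes,
             role = factor(unname(role),
                           levels = c("bait", "interactor", "non_interactor",
                                      "unclassified")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample a random comparison set of non-interactors
#'
#' Uniform sample without replacement from the non-interactor candidates
#' (the original screen drew 550 such genes).
#'
#' @param candidates Character vector of candidate genes.
#' @param n Number of genes to draw.
#' @param seed Optional integer seed; identical seeds give identical sets.
#' @return Character vector of length `n`.
#' @export
sample_non_interactors <- function(candidates, n, seed = NULL) {
  candidates <- sort(unique(canonicalize_ids(candidates)))
  if (n > length(candidates)) {
    stop(sprintf("cannot sample %d non-interactors from %d candidates",
                 n, length(candidates)))
  }
  with_seed(seed, sort(sample(candidates, n)))
}
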