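# Brute-force oracles, independent of the package's implementation paths.

# phase-percentage columns of a well table
PHASE_PARAMS <- c("pct_g1", "pct_g2m", "pct_gt_g2m", "pct_subg1")
HIT_COLS <- c("hit_g1", "hit_g2m", "hit_gt_g2m", "hit_subg1")

# Build an interaction map directly from a data frame of edges
# (columns a, b, optionally dataset and confidence; one row per record).
make_map <- function(a, b, dataset = "ds1", confidence = NA_real_,
                     isolated = character()) {
  load_interaction_map(
    data.frame(protein_a = a, protein_b = b, dataset_id = dataset,
               confidence = confidence, stringsAsFactors = FALSE),
    isolated_nodes = isolated)
}

# Random simple graph as raw edge records; multi-dataset support and
# confidence scores included so filter rules are exercised.
random_edge_records <- function(n_nodes, p_edge = 0.15, n_datasets = 3) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      dataset_id = character(), confidence = numeric()))
  }
  n_support <- 1L + (runif(nrow(pairs)) < 0.3)
  idx <- rep(seq_len(nrow(pairs)), n_support)
  ds <- unlist(lapply(n_support, function(k) sample(n_datasets, k)))
  data.frame(protein_a = pairs[idx, 1L], protein_b = pairs[idx, 2L],
             dataset_id = paste0("ds", ds),
             confidence = round(runif(length(idx)), 2),
             stringsAsFactors = FALSE)
}

# Hub filter by explicit removal and add-back lists, one bait at a time.
brute_hub_filter <- function(neighborhood, baits, config) {
  baits <- if (inherits(baits, "bait_set")) baits else bait_set(baits)
  edges <- neighborhood$edges
  partner_of <- function(bait) {
    unique(c(edges$b[edges$a == bait], edges$a[edges$b == bait]))
  }
  hub <- vapply(baits$genes, function(bt) {
    length(partner_of(bt)) > config$max_bait_degree
  }, TRUE)
  names(hub) <- baits$genes

  removed <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ends <- c(edges$a[i], edges$b[i])
    bait_ends <- ends[ends %in% baits$genes]
    if (length(bait_ends) == 0L) next
    if (all(hub[bait_ends])) removed[i] <- TRUE
  }
  added_back <- logical(nrow(edges))
  for (i in which(removed)) {
    if (edges$n_datasets[i] >= config$multi_study_min) added_back[i] <- TRUE
    if (edges$a[i] %in% baits$rescue_baits ||
        edges$b[i] %in% baits$rescue_baits) added_back[i] <- TRUE
  }
  edges[!removed | added_back, , drop = FALSE]
}

# Connected-component sizes by hand-rolled breadth-first search.
brute_component_sizes <- function(nodes, edge_a, edge_b) {
  lab <- setNames(rep(NA_integer_, length(nodes)), nodes)
  comp <- 0L
  for (start in nodes) {
    if (!is.na(lab[start])) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- c(edge_b[edge_a == v], edge_a[edge_b == v])
      nb <- nb[nb %in% nodes]
      new <- nb[is.na(lab[nb])]
      lab[new] <- comp
      queue <- c(queue, new)
    }
  }
  as.integer(table(lab))
}

brute_lcc <- function(map, group = NULL) {
  nodes <- map$nodes
  a <- map$edges$a; b <- map$edges$b
  if (!is.null(group)) {
    nodes <- intersect(nodes, group)
    keep <- a %in% group & b %in% group
    a <- a[keep]; b <- b[keep]
  }
  if (length(nodes) == 0L) return(0L)
  max(brute_component_sizes(nodes, a, b))
}

# Within-group edge count by double loop over all unordered pairs.
brute_within_edges <- function(map, group) {
  key <- paste(pmin(map$edges$a, map$edges$b), pmax(map$edges$a, map$edges$b))
  group <- sort(unique(group))
  count <- 0L
  for (i in seq_along(group)) {
    for (j in seq_len(i - 1L)) {
      if (paste(group[j], group[i]) %in% key) count <- count + 1L
    }
  }
  count
}

# Minimal valid well table for normalization tests: `values` is a list of
# per-plate non-control value vectors (recycled across the four parameters),
# `controls` a list of per-plate control value vectors.
toy_wells <- function(values, controls = NULL, replicate_id = "r1") {
  rows <- list()
  for (p in seq_along(values)) {
    v <- values[[p]]
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = sprintf("P%d", p),
      well_id = sprintf("s%02d", seq_along(v)),
      replicate_id = replicate_id, target = sprintf("gene_p%d_%02d", p, seq_along(v)),
      is_control = FALSE,
      pct_g1 = v, pct_g2m = v, pct_gt_g2m = v, pct_subg1 = v,
      stringsAsFactors = FALSE)
    if (!is.null(controls)) {
      cv <- controls[[p]]
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = sprintf("P%d", p),
        well_id = sprintf("c%02d", seq_along(cv)),
        replicate_id = replicate_id, target = "gfp", is_control = TRUE,
        pct_g1 = cv, pct_g2m = cv, pct_gt_g2m = cv, pct_subg1 = cv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# 99% binomial interval around a true proportion.
binom99 <- function(p, n) {
  hw <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - hw, p + hw)
}
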