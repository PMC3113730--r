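#' Configuration for synthetic interaction networks
#'
#' Describes a degree-heterogeneous protein-interaction network with hub
#' nodes and a planted, densely interconnected module — the structural
#' features the connectivity statistics and the hub filter are designed
#' around.
#'
#' @param n_nodes Number of proteins.
#' @param mean_degree Target mean degree of the heavy-tailed background.
#' @param degree_exponent Power-law exponent of the degree fitness.
#' @param n_hubs Number of nodes guaranteed to exceed `hub_degree_floor`
#'   partners (candidate "sticky" proteins).
#' @param hub_degree_floor Hubs are topped up to strictly more than this many
#'   partners (default 30, matching the hub-filter threshold).
#' @param module_size Size of the planted module.
#' @param p_within Edge probability inside the planted module.
#' @param n_datasets Number of source-dataset labels.
#' @param p_multi_dataset Probability that an edge is supported by a second,
#'   distinct dataset (multi-study evidence).
#' @param seed Optional integer seed.
#' @return Object of class `network_sim_config`.
#' @export
network_sim_config <- function(n_nodes = 1000L, mean_degree = 6,
                               degree_exponent = 2.3,
                               n_hubs = 10L, hub_degree_floor = 30L,
                               module_size = 40L, p_within = 0.25,
                               n_datasets = 7L, p_multi_dataset = 0.15,
                               seed = NULL) {
  stopifnot(n_nodes >= 2L, mean_degree > 0, module_size <= n_nodes,
            p_within >= 0, p_within <= 1,
            p_multi_dataset >= 0, p_multi_dataset <= 1,
            n_datasets >= 1L, n_hubs >= 0L,
            n_hubs + module_size <= n_nodes,
            n_datasets >= 2L || p_multi_dataset == 0)
  structure(as.list(environment()), class = "network_sim_config")
}

#' Generate a synthetic interaction network with known ground truth
#'
#' Builds a heavy-tailed background graph, tops up `n_hubs` nodes past the
#' hub-degree floor, plants a module whose within-module edge probability is
#' `p_within`, and labels every pair with 1-2 source datasets plus a
#' confidence score in (0, 1). Identical seeds give identical edge lists.
#'
#' @param config A [network_sim_config()].
#' @return List with `map` (an `interaction_map`) and `truth` (list with
#'   `module`, `hubs`, `config`).
#' @export
generate_network <- function(config = network_sim_config()) {
  stopifnot(inherits(config, "network_sim_config"))
  ids <- sprintf("g%05d", seq_len(config$n_nodes))
  with_seed(config$seed, {
    n_edges <- round(config$n_nodes * config$mean_degree / 2)
    g <- igraph::sample_fitness_pl(config$n_nodes, n_edges,
                                   exponent.out = config$degree_exponent)
    el <- igraph::as_edgelist(g, names = FALSE)

    # guarantee hub nodes: top up the highest-degree background nodes
    deg <- tabulate(c(el[, 1L], el[, 2L]), nbins = config$n_nodes)
    hubs <- order(deg, decreasing = TRUE)[seq_len(config$n_hubs)]
    pairkeys <- pair_key(el[, 1L], el[, 2L])
    extra <- list()
    for (h in hubs) {
      need <- config$hub_degree_floor + 1L - deg[h]
      while (need > 0L) {
        cand <- sample(setdiff(seq_len(config$n_nodes), h), need)
        k <- pair_key(rep(h, length(cand)), cand)
        fresh <- !(k %in% pairkeys) & !duplicated(k)
        if (any(fresh)) {
          extra[[length(extra) + 1L]] <- cbind(rep(h, sum(fresh)), cand[fresh])
          pairkeys <- c(pairkeys, k[fresh])
          deg[h] <- deg[h] + sum(fresh)
          deg[cand[fresh]] <- deg[cand[fresh]] + 1L
          need <- need - sum(fresh)
        }
      }
    }

    # plant the module on non-hub nodes
    module <- sample(setdiff(seq_len(config$n_nodes), hubs), config$module_size)
    pairs <- utils::combn(sort(module), 2L)
    pick <- stats::runif(ncol(pairs)) < config$p_within
    k <- pair_key(pairs[1L, pick], pairs[2L, pick])
    fresh <- !(k %in% pairkeys)
    planted <- cbind(pairs[1L, pick][fresh], pairs[2L, pick][fresh])

    el <- rbind(el, do.call(rbind, extra), planted)
    m <- nrow(el)
    ds1 <- sample(config$n_datasets, m, replace = TRUE)
    second <- stats::runif(m) < config$p_multi_dataset
    ds2 <- (ds1 + sample(config$n_datasets - 1L, m, replace = TRUE) - 1L) %%
      config$n_datasets + 1L
    conf <- round(stats::runif(m), 3)

    records <- data.frame(
      protein_a = ids[el[, 1L]], protein_b = ids[el[, 2L]],
      dataset_id = paste0("ds", ds1), confidence = conf,
      stringsAsFactors = FALSE)
    if (any(second)) {
      records <- rbind(records, data.frame(
        protein_a = ids[el[second, 1L]], protein_b = ids[el[second, 2L]],
        dataset_id = paste0("ds", ds2[second]), confidence = conf[second],
        stringsAsFactors = FALSE))
    }
    map <- load_interaction_map(records, isolated_nodes = ids)
    list(map = map,
         truth = list(module = ids[sort(module)], hubs = ids[sort(hubs)],
                      config = config))
  })
}
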