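# Cell cycle phase parameters as stored in well tables, and their
# phenotype-class labels.
PHASE_PARAMS <- c("pct_g1", "pct_g2m", "pct_gt_g2m", "pct_subg1")
PHASE_LABELS <- c(pct_g1 = "G1", pct_g2m = "G2/M", pct_gt_g2m = ">G2/M",
                  pct_subg1 = "subG1")

#' Phase phenotype class labels
#'
#' @return Character vector of the four phenotype classes in well-table
#'   column order: `G1`, `G2/M`, `>G2/M`, `subG1`.
#' @export
phase_classes <- function() unname(PHASE_LABELS)

check_wells <- function(wells) {
  need <- c("plate_id", "well_id", "replicate_id", "target", "is_control",
            PHASE_PARAMS)
  missing <- setdiff(need, names(wells))
  if (length(missing) > 0L) {
    stop("well table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(duplicated(wells[, c("plate_id", "well_id", "replicate_id")]))) {
    stop("(plate_id, well_id, replicate_id) must be unique")
  }
  invisible(wells)
}

plate_key <- function(wells) paste(wells$plate_id, wells$replicate_id, sep = "\r")

#' Read a plate-format screen table
#'
#' CSV with header `plate_id,well_id,replicate_id,target,is_control,
#' pct_g1,pct_g2m,pct_gt_g2m,pct_subg1`. `is_control` marks wells treated
#' with the control (e.g. GFP) dsRNA.
#'
#' @param path Path to the CSV file.
#' @return A validated well table (data frame).
#' @export
read_plate_table <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  wells$is_control <- as.logical(wells$is_control)
  check_wells(wells)
}

#' Compute global/plate normalization factors
#'
#' For each measured parameter a global average `g` is computed over all
#' non-control wells of all (physical) plates, and a plate average `p` over
#' each plate's non-control wells; the per-plate factor is `g / p`. Each
#' replicate plate is treated as its own physical plate. Control wells are
#' excluded from both averages so extreme controls cannot distort the
#' factors.
#'
#' @param wells Well table (see [read_plate_table()]).
#' @return Object of class `normalization_factors`: `global_mean` (named
#'   numeric), `plate_mean` and `factor` (data frames keyed by plate_id and
#'   replicate_id).
#' @export
compute_normalization_factors <- function(wells) {
  check_wells(wells)
  samp <- wells[!wells$is_control, , drop = FALSE]
  plates <- unique(wells[, c("plate_id", "replicate_id")])
  key_all <- paste(plates$plate_id, plates$replicate_id, sep = "\r")
  key_smp <- plate_key(samp)
  absent <- setdiff(key_all, key_smp)
  if (length(absent) > 0L) {
    stop("plate with no non-control wells: ",
         gsub("\r", "/", absent[1L], fixed = TRUE))
  }
  g <- colMeans(samp[, PHASE_PARAMS, drop = FALSE])
  pm <- do.call(rbind, lapply(split(samp, key_smp), function(d) {
    colMeans(d[, PHASE_PARAMS, drop = FALSE])
  }))
  if (any(pm == 0)) {
    bad <- which(pm == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("plate mean is zero for plate %s, parameter %s",
                 gsub("\r", "/", rownames(pm)[bad[1L]], fixed = TRUE),
                 PHASE_PARAMS[bad[2L]]))
  }
  fac <- sweep(pm, 2L, g, FUN = function(p, g) g / p)
  ids <- do.call(rbind, strsplit(rownames(pm), "\r", fixed = TRUE))
  mk <- function(m) data.frame(plate_id = ids[, 1L], replicate_id = ids[, 2L],
                               m, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(global_mean = g, plate_mean = mk(pm), factor = mk(fac)),
            class = "normalization_factors")
}

#' Apply g/p normalization to a well table
#'
#' Every well (controls included) is scaled by its plate's per-parameter
#' factor, so each plate's non-control mean equals the global mean after
#' normalization.
#'
#' @param wells Well table.
#' @param factors A `normalization_factors` object; computed from `wells`
#'   when omitted.
#' @return The well table with normalized phase percentages.
#' @export
normalize_wells <- function(wells, factors = compute_normalization_factors(wells)) {
  check_wells(wells)
  fk <- paste(factors$factor$plate_id, factors$factor$replicate_id, sep = "\r")
  m <- match(plate_key(wells), fk)
  if (anyNA(m)) {
    miss <- unique(plate_key(wells)[is.na(m)])[1L]
    stop("no normalization factor for plate ",
         gsub("\r", "/", miss, fixed = TRUE))
  }
  fmat <- as.matrix(factors$factor[m, PHASE_PARAMS, drop = FALSE])
  wells[, PHASE_PARAMS] <- wells[, PHASE_PARAMS, drop = FALSE] * fmat
  wells
}

#' Average normalized replicate values per dsRNA
#'
#' @param wells Normalized well table.
#' @return Data frame with one row per non-control target: the arithmetic
#'   mean of its replicate values per parameter, the replicate count, and an
#'   `incomplete` flag for targets measured on fewer replicates than the
#'   screen's maximum.
#' @export
average_replicates <- function(wells) {
  check_wells(wells)
  samp <- wells[!wells$is_control, , drop = FALSE]
  if (nrow(samp) == 0L) stop("no non-control wells to average")
  sp <- split(samp, samp$target)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(target = d$target[1L],
               t(colMeans(d[, PHASE_PARAMS, drop = FALSE])),
               n_replicates = nrow(d),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out$incomplete <- out$n_replicates < max(out$n_replicates)
  out
}

#' Control-well statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) per parameter over
#' all normalized control wells, pooled across plates.
#'
#' @param wells Normalized well table (its control wells are used), or a
#'   table containing only control wells.
#' @return Object of class `control_stats` with named numeric vectors `mean`
#'   and `sd` and the control-well count `n`.
#' @export
control_statistics <- function(wells) {
  check_wells(wells)
  ctrl <- wells[wells$is_control, , drop = FALSE]
  if (nrow(ctrl) < 2L) {
    stop("need at least 2 control wells to estimate control statistics")
  }
  structure(list(
    mean = colMeans(ctrl[, PHASE_PARAMS, drop = FALSE]),
    sd = apply(ctrl[, PHASE_PARAMS, drop = FALSE], 2L, stats::sd),
    n = nrow(ctrl)
  ), class = "control_stats")
}

#' Score dsRNAs in control-SD units and call hits
#'
#' For each parameter, the deviation `z = (value - mean) / sd` from the
#' control mean is computed in control-SD units. A dsRNA is a hit when the
#' percentage of cells in any phase is strictly more than `k` control SDs
#' above the control mean (one-sided: only increases are called, decreases
#' never flag).
#'
#' @param dsrna_means Per-dsRNA averaged vectors from [average_replicates()].
#' @param stats A `control_stats` object.
#' @param k Threshold in control-SD units (default 3).
#' @return Data frame per target: `z_g1`, `z_g2m`, `z_gt_g2m`, `z_subg1`,
#'   per-parameter hit flags, overall `hit`, and `phenotypes`
#'   (comma-separated flagged classes, `""` for non-hits).
#' @export
score_and_call <- function(dsrna_means, stats, k = 3) {
  if (any(stats$sd <= 0)) {
    stop("control SD is zero for at least one parameter; ",
         "add control wells (or control-well noise) before calling hits")
  }
  vals <- as.matrix(dsrna_means[, PHASE_PARAMS, drop = FALSE])
  z <- sweep(sweep(vals, 2L, stats$mean), 2L, stats$sd, "/")
  hitmat <- z > k
  zcols <- sub("^pct", "z", PHASE_PARAMS)
  hcols <- sub("^pct", "hit", PHASE_PARAMS)
  out <- data.frame(target = dsrna_means$target, stringsAsFactors = FALSE)
  out[zcols] <- as.data.frame(z)
  out[hcols] <- as.data.frame(hitmat)
  out$hit <- rowSums(hitmat) > 0L
  out$phenotypes <- apply(hitmat, 1L, function(h) {
    paste(PHASE_LABELS[PHASE_PARAMS[h]], collapse = ",")
  })
  row.names(out) <- NULL
  out
}

phenotype_set <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, ",", fixed = TRUE)[[1L]]
}

#' Aggregate amplicon-level calls to genes
#'
#' Several dsRNA amplicons can target one gene. A gene is a hit when any of
#' its amplicons is a hit; its phenotype set is the union of amplicon
#' phenotypes and the strongest (maximum) deviation per parameter is kept.
#'
#' @param calls Amplicon-level calls from [score_and_call()].
#' @param mapping Data frame with columns `amplicon` and `gene`; every
#'   amplicon must map to exactly one gene. Amplicons without a mapping are
#'   dropped with a warning.
#' @return Gene-level call table (same shape as `calls`, keyed by `gene`).
#' @export
aggregate_genes <- function(calls, mapping) {
  stopifnot(all(c("amplicon", "gene") %in% names(mapping)))
  if (any(duplicated(mapping$amplicon))) {
    stop("every amplicon must map to exactly one gene")
  }
  m <- match(calls$target, mapping$amplicon)
  if (anyNA(m)) {
    warning(sprintf("excluding %d amplicon(s) with no gene mapping", sum(is.na(m))))
    calls <- calls[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  calls$gene <- mapping$gene[m]
  zcols <- sub("^pct", "z", PHASE_PARAMS)
  hcols <- sub("^pct", "hit", PHASE_PARAMS)
  sp <- split(calls, calls$gene)
  out <- do.call(rbind, lapply(sp, function(d) {
    res <- data.frame(gene = d$gene[1L], stringsAsFactors = FALSE)
    res[zcols] <- lapply(d[zcols], max)
    res[hcols] <- lapply(d[hcols], any)
    res$hit <- any(d$hit)
    res$phenotypes <- paste(
      unname(PHASE_LABELS[PHASE_PARAMS[unlist(res[hcols], use.names = FALSE)]]),
      collapse = ",")
    res
  }))
  row.names(out) <- NULL
  out
}

#' Hit rate per gene class
#'
#' The hit rate of a class is the percentage of tested genes of that class
#' that scored as hits (e.g., baits vs interactors vs non-interactors).
#'
#' @param gene_calls Gene-level calls (columns `gene`, `hit`).
#' @param roles Data frame with columns `gene` and `role`
#'   (see [assign_roles()]); every screened gene must have a role.
#' @return Data frame per class: `role`, `n_tested`, `n_hits`, `hit_rate`
#'   (percent, unrounded; `NA` for classes with zero tested genes).
#' @export
hit_rate_by_class <- function(gene_calls, roles) {
  m <- match(gene_calls$gene, roles$gene)
  if (anyNA(m)) {
    stop(sprintf("%d screened gene(s) have no role assignment", sum(is.na(m))))
  }
  cls <- factor(roles$role[m], levels = levels(factor(roles$role)))
  tested <- table(cls)
  hits <- table(cls[gene_calls$hit])
  data.frame(role = names(tested),
             n_tested = as.integer(tested),
             n_hits = as.integer(hits),
             hit_rate = ifelse(tested > 0, 100 * as.integer(hits) / as.integer(tested),
                               NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full screen-analysis pipeline on a well table
#'
#' Convenience wrapper: g/p normalization, replicate averaging, control
#' statistics, scoring and hit calling (and optional gene aggregation).
#'
#' @param wells Raw well table.
#' @param k Hit threshold in control-SD units.
#' @param mapping Optional amplicon-to-gene mapping for [aggregate_genes()];
#'   when omitted, targets are treated as genes (one amplicon each).
#' @return List with `normalized`, `factors`, `control_stats`, `calls`
#'   (amplicon level) and `gene_calls`.
#' @export
analyze_screen <- function(wells, k = 3, mapping = NULL) {
  factors <- compute_normalization_factors(wells)
  normalized <- normalize_wells(wells, factors)
  stats <- control_statistics(normalized)
  means <- average_replicates(normalized)
  calls <- score_and_call(means, stats, k = k)
  if (is.null(mapping)) {
    mapping <- data.frame(amplicon = calls$target, gene = calls$target,
                          stringsAsFactors = FALSE)
  }
  gene_calls <- aggregate_genes(calls, mapping)
  list(normalized = normalized, factors = factors, control_stats = stats,
       calls = calls, gene_calls = gene_calls)
}
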