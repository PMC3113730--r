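#' Bundle one screen's universe and hits
#'
#' @param screen_id Label for the screen.
#' @param universe Character vector of all genes screened.
#' @param hits Either a character vector of hit genes or a gene-level call
#'   table (columns `gene`, `hit`, `phenotypes`) from [analyze_screen()].
#' @return Object of class `screen_result`.
#' @export
screen_result <- function(screen_id, universe, hits) {
  universe <- unique(canonicalize_ids(universe))
  if (is.data.frame(hits)) {
    hits <- canonicalize_ids(hits$gene[hits$hit])
  } else {
    hits <- unique(canonicalize_ids(hits))
  }
  if (!all(hits %in% universe)) {
    stop("hits must be a subset of the screened universe")
  }
  structure(list(screen_id = screen_id, universe = universe, hits = hits),
            class = "screen_result")
}

#' Overlap between two screens on their common gene universe
#'
#' Comparisons are restricted to genes screened in both studies before any
#' counting, so differing library coverage cannot masquerade as discordance.
#'
#' @param a,b `screen_result` objects.
#' @return List: `common_universe_size`, per-screen hit counts within the
#'   common universe, `n_overlap`, unique-hit counts, and the percentage of
#'   each screen's (common-universe) hits recovered by the other.
#' @export
compare_screens <- function(a, b) {
  u <- intersect(a$universe, b$universe)
  if (length(u) == 0L) stop("the two screens share no screened genes")
  ha <- intersect(a$hits, u)
  hb <- intersect(b$hits, u)
  ov <- intersect(ha, hb)
  list(screen_a = a$screen_id, screen_b = b$screen_id,
       common_universe_size = length(u),
       n_hits_a = length(ha), n_hits_b = length(hb),
       n_overlap = length(ov),
       n_unique_a = length(setdiff(ha, hb)),
       n_unique_b = length(setdiff(hb, ha)),
       pct_a_recovered_in_b = if (length(ha) > 0) 100 * length(ov) / length(ha) else NA_real_,
       pct_b_recovered_in_a = if (length(hb) > 0) 100 * length(ov) / length(hb) else NA_real_)
}

#' Second-dsRNA validation of primary hits
#'
#' A primary hit is validated when an independent dsRNA targeting the same
#' gene is itself a hit with a matching phenotype. Under the default
#' `"shared-class"` rule the phenotypes match when the two calls share at
#' least one phenotype class (G1, G2/M, >G2/M, subG1); `"exact-set"` demands
#' identical class sets.
#'
#' @param primary Gene-level call table of the primary screen.
#' @param validation Gene-level call table of the validation screen; only
#'   genes present here count as tested.
#' @param match_rule `"shared-class"` (default) or `"exact-set"`.
#' @param strata Optional data frame `gene`, `stratum` labelling each tested
#'   gene (e.g. prior-screen status); carried onto the records.
#' @return Data frame per tested gene: `gene`, `primary_phenotypes`,
#'   `validation_phenotypes`, `validation_hit`, `validated`, and `stratum`
#'   when supplied. Genes tested in validation but never hit in the primary
#'   screen are excluded with a warning.
#' @export
validate_hits <- function(primary, validation,
                          match_rule = c("shared-class", "exact-set"),
                          strata = NULL) {
  match_rule <- match.arg(match_rule)
  m <- match(validation$gene, primary$gene)
  primary_hit <- !is.na(m) & primary$hit[m]
  if (any(!primary_hit)) {
    warning(sprintf("excluding %d validation record(s) for genes not hit in the primary screen",
                    sum(!primary_hit)))
  }
  validation <- validation[primary_hit, , drop = FALSE]
  m <- m[primary_hit]
  recs <- data.frame(gene = validation$gene,
                     primary_phenotypes = primary$phenotypes[m],
                     validation_phenotypes = validation$phenotypes,
                     validation_hit = validation$hit,
                     stringsAsFactors = FALSE, row.names = NULL)
  recs$validated <- mapply(function(vh, pp, vp) {
    if (!vh) return(FALSE)
    ps <- phenotype_set(pp); vs <- phenotype_set(vp)
    if (match_rule == "shared-class") length(intersect(ps, vs)) > 0L
    else setequal(ps, vs)
  }, recs$validation_hit, recs$primary_phenotypes, recs$validation_phenotypes)
  if (!is.null(strata)) {
    recs$stratum <- strata$stratum[match(recs$gene, strata$gene)]
  }
  recs
}

#' Validation rate, optionally stratified
#'
#' @param records Validation records from [validate_hits()].
#' @param stratifier Optional column name in `records` (default `"stratum"`
#'   when present) or a data frame `gene`, `stratum`.
#' @return Data frame per stratum (single row `"all"` when unstratified):
#'   `stratum`, `n_tested`, `n_validated`, `validation_rate` (percent).
#' @export
stratified_validation_rate <- function(records, stratifier = NULL) {
  if (is.data.frame(stratifier)) {
    records$stratum <- stratifier$stratum[match(records$gene, stratifier$gene)]
    stratifier <- "stratum"
  }
  if (is.null(stratifier)) {
    stratifier <- if ("stratum" %in% names(records)) "stratum" else NULL
  }
  strat <- if (is.null(stratifier)) rep("all", nrow(records))
           else as.character(records[[stratifier]])
  sp <- split(records$validated, strat)
  data.frame(stratum = names(sp),
             n_tested = lengths(sp),
             n_validated = vapply(sp, sum, 0L),
             validation_rate = 100 * vapply(sp, mean, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the high-confidence regulator set
#'
#' The union of (a) genes validated with a second dsRNA and (b) genes hit in
#' both the current and a previous screen, regardless of validation.
#'
#' @param validated Character vector of validated genes (must be current
#'   hits).
#' @param current_hits Character vector of current-screen hit genes.
#' @param prior_hits Character vector of hit genes from previous screens.
#' @return Data frame `gene`, `provenance` in
#'   `{validated, dual_screen, both}`.
#' @export
assemble_high_confidence <- function(validated, current_hits, prior_hits) {
  validated <- unique(canonicalize_ids(validated))
  current_hits <- unique(canonicalize_ids(current_hits))
  prior_hits <- unique(canonicalize_ids(prior_hits))
  if (!all(validated %in% current_hits)) {
    stop("validated genes must be a subset of the current screen's hits")
  }
  dual <- intersect(current_hits, prior_hits)
  genes <- sort(union(validated, dual))
  provenance <- ifelse(genes %in% validated & genes %in% dual, "both",
                       ifelse(genes %in% validated, "validated", "dual_screen"))
  data.frame(gene = genes, provenance = provenance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Identify novel regulators among validated hits
#'
#' Novel regulators are validated genes that were neither hits in previous
#' screens nor already annotated to the process of interest.
#'
#' @param validated Character vector of validated genes, or a data frame with
#'   columns `gene` and `phenotypes`.
#' @param prior_hits Character vector of previous-screen hit genes.
#' @param annotated Character vector of genes already annotated to the
#'   process (e.g. a GO biological-process gene list).
#' @return Data frame `gene` (the novel genes) plus `phenotypes` when
#'   supplied; the per-phenotype-class tally is attached as attribute
#'   `"class_counts"`.
#' @export
classify_novel_regulators <- function(validated, prior_hits, annotated) {
  phen <- NULL
  if (is.data.frame(validated)) {
    phen <- validated
    phen$gene <- canonicalize_ids(phen$gene)
    genes <- unique(phen$gene)
  } else {
    genes <- unique(canonicalize_ids(validated))
  }
  prior_hits <- canonicalize_ids(prior_hits)
  annotated <- canonicalize_ids(annotated)
  novel <- sort(setdiff(genes, union(prior_hits, annotated)))
  out <- data.frame(gene = novel, stringsAsFactors = FALSE)
  counts <- NULL
  if (!is.null(phen)) {
    out$phenotypes <- phen$phenotypes[match(novel, phen$gene)]
    counts <- table(unlist(lapply(out$phenotypes, phenotype_set)))
  }
  attr(out, "class_counts") <- counts
  out
}
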