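#' Configuration for synthetic RNAi screens
#'
#' Emulates the statistical structure of a plate-based flow-cytometry RNAi
#' screen: duplicate 96-well plates with 1-3 control wells each,
#' multiplicative per-plate batch effects on the gate readings, Gaussian
#' well noise, true regulators that shift one phase parameter, off-target
#' false positives, and knockdown-failure false negatives.
#'
#' Per gene class, `class_hit_prob` is the marginal probability that a dsRNA
#' of that class displays a phenotype, and `off_target_hit_fraction` is the
#' fraction of displayed phenotypes caused by off-target effects rather than
#' the intended gene. Internally the generator derives, per class, the
#' true-regulator probability `r = H * (1 - ofrac) / (1 - f)` and the
#' per-dsRNA off-target probability `o = H * ofrac / (1 - r)` so that both
#' configured quantities are realized in expectation (`H` = class hit
#' probability, `f` = knockdown failure rate). Off-target and
#' knockdown-failure events are drawn independently per dsRNA, which is
#' exactly the assumption behind second-dsRNA validation.
#'
#' @param roster Data frame with columns `gene` and `role` (role values must
#'   have entries in `class_hit_prob`).
#' @param class_hit_prob Named marginal phenotype probabilities per role;
#'   defaults mirror the observed class hit rates of the original screen
#'   (baits 0.26, interactors 0.118, non-interactors 0.045).
#' @param off_target_hit_fraction Fraction of phenotype-displaying dsRNAs
#'   that are off-target (default 0.4, the level reported for long-dsRNA
#'   screens).
#' @param knockdown_failure_rate Probability that a true regulator's dsRNA
#'   produces no effect (default 0; raise it to emulate false negatives).
#' @param effect_size Phenotype shift in control-SD units (default 6, a
#'   clearly separated phenotype).
#' @param baseline Baseline 5-part phase composition (percent) over G1, S,
#'   G2/M, >G2/M and subG1; must sum to 100. S is never reported — the four
#'   emitted gates therefore sum to less than 100.
#' @param noise_sd Gaussian well noise SD in percentage points.
#' @param plate_effect_sdlog SD (log scale) of the multiplicative per-plate,
#'   per-parameter batch effect.
#' @param controls_per_plate Candidate control-well counts; each plate draws
#'   one (default 1:3).
#' @param n_replicates Number of duplicate plates per layout (default 2).
#' @param plate_size Wells per plate (default 96).
#' @param seed Optional integer seed.
#' @return Object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(roster,
                              class_hit_prob = c(bait = 0.26,
                                                 interactor = 0.118,
                                                 non_interactor = 0.045),
                              off_target_hit_fraction = 0.4,
                              knockdown_failure_rate = 0,
                              effect_size = 6,
                              baseline = c(g1 = 48, s = 20, g2m = 22,
                                           gt_g2m = 5, subg1 = 5),
                              noise_sd = 2,
                              plate_effect_sdlog = 0.05,
                              controls_per_plate = 1:3,
                              n_replicates = 2L,
                              plate_size = 96L,
                              seed = NULL) {
  stopifnot(is.data.frame(roster), all(c("gene", "role") %in% names(roster)),
            nrow(roster) > 0L,
            all(class_hit_prob >= 0), all(class_hit_prob <= 1),
            off_target_hit_fraction >= 0, off_target_hit_fraction <= 1,
            knockdown_failure_rate >= 0, knockdown_failure_rate < 1,
            effect_size >= 0, noise_sd >= 0, plate_effect_sdlog >= 0,
            all(controls_per_plate >= 1),
            all(controls_per_plate < plate_size),
            n_replicates >= 1L,
            length(baseline) == 5L, all(baseline >= 0),
            abs(sum(baseline) - 100) < 1e-8)
  roster$gene <- canonicalize_ids(roster$gene)
  if (any(duplicated(roster$gene)) || any(roster$gene == "gfp")) {
    stop("roster genes must be unique and must not collide with the 'gfp' control label")
  }
  roster$role <- as.character(roster$role)
  if (!all(roster$role %in% names(class_hit_prob))) {
    stop("every roster role needs an entry in class_hit_prob")
  }
  structure(as.list(environment()), class = "screen_sim_config")
}

# Derive per-class regulator and off-target probabilities from the marginal
# phenotype probability and the off-target share among phenotypes.
class_rates <- function(config) {
  H <- config$class_hit_prob
  f <- config$knockdown_failure_rate
  ofrac <- config$off_target_hit_fraction
  r <- H * (1 - ofrac) / (1 - f)
  if (any(r > 1)) stop("infeasible config: implied regulator probability > 1")
  off_mass <- H * ofrac
  if (any(off_mass > 0 & r >= 1)) {
    stop("infeasible config: no non-regulators left to carry off-target hits")
  }
  o <- ifelse(off_mass > 0, off_mass / (1 - r), 0)
  if (any(o > 1)) stop("infeasible config: implied off-target probability > 1")
  list(regulator_prob = r, off_target_prob = o)
}

# Reported gate means for one dsRNA: start from the 5-part baseline, move
# `shift` points into the affected gate taken proportionally from the other
# four parts, then drop the (unreported) S part.
shifted_baseline <- function(baseline, param, shift) {
  parts <- baseline
  full <- c(pct_g1 = "g1", pct_g2m = "g2m", pct_gt_g2m = "gt_g2m",
            pct_subg1 = "subg1")
  tgt <- full[[param]]
  others <- setdiff(names(parts), tgt)
  avail <- sum(parts[others])
  shift <- min(shift, avail)
  parts[others] <- parts[others] * (1 - shift / avail)
  parts[tgt] <- parts[tgt] + shift
  stats::setNames(parts[c("g1", "g2m", "gt_g2m", "subg1")], PHASE_PARAMS)
}

# Lay out targets on plates and emit wells. `effects` is a data frame with
# columns target, effective, effect_param. RNG staging: layout/controls come
# from `seed`, plate effects from `seed + 1`, well noise from `seed + 2`, so
# switching plate effects off leaves every noise draw unchanged.
build_screen_wells <- function(effects, config, seed) {
  base4 <- shifted_baseline(config$baseline, PHASE_PARAMS[1L], 0)
  shift <- config$effect_size * config$noise_sd
  n <- nrow(effects)

  layout <- with_seed(seed, {
    plates <- list(); i <- 0L; done <- 0L
    while (done < n) {
      i <- i + 1L
      n_ctrl <- if (length(config$controls_per_plate) == 1L)
        config$controls_per_plate else sample(config$controls_per_plate, 1L)
      take <- min(config$plate_size - n_ctrl, n - done)
      plates[[i]] <- list(plate_id = sprintf("P%03d", i),
                          targets = effects$target[done + seq_len(take)],
                          n_ctrl = n_ctrl)
      done <- done + take
    }
    plates
  })

  rows <- lapply(layout, function(pl) {
    n_wells <- length(pl$targets) + pl$n_ctrl
    wid <- paste0(rep(LETTERS[1:8], each = 12), sprintf("%02d", 1:12))[seq_len(n_wells)]
    data.frame(plate_id = pl$plate_id,
               well_id = wid,
               target = c(pl$targets, rep("gfp", pl$n_ctrl)),
               is_control = c(rep(FALSE, length(pl$targets)),
                              rep(TRUE, pl$n_ctrl)),
               stringsAsFactors = FALSE)
  })
  one <- do.call(rbind, rows)
  wells <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    w <- one
    w$replicate_id = sprintf("r%d", r)
    w
  }))

  # expected gate readings per well
  mu <- matrix(rep(base4, each = nrow(wells)), ncol = 4L,
               dimnames = list(NULL, PHASE_PARAMS))
  m <- match(wells$target, effects$target)
  eff <- !is.na(m) & effects$effective[m]
  for (p in PHASE_PARAMS) {
    rows_p <- which(eff & effects$effect_param[m] == p)
    if (length(rows_p) > 0L) {
      mu[rows_p, ] <- matrix(rep(shifted_baseline(config$baseline, p, shift),
                                 each = length(rows_p)), ncol = 4L)
    }
  }

  pk <- unique(paste(wells$plate_id, wells$replicate_id, sep = "\r"))
  fmat <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    f <- matrix(stats::rlnorm(length(pk) * 4L, 0, config$plate_effect_sdlog),
                ncol = 4L, dimnames = list(pk, PHASE_PARAMS))
    f
  })
  noise <- with_seed(if (is.null(seed)) NULL else seed + 2L, {
    matrix(stats::rnorm(nrow(wells) * 4L, 0, config$noise_sd), ncol = 4L)
  })
  vals <- fmat[paste(wells$plate_id, wells$replicate_id, sep = "\r"), ,
               drop = FALSE] * (mu + noise)
  vals[vals < 0] <- 0
  wells[PHASE_PARAMS] <- as.data.frame(vals)
  row.names(wells) <- NULL
  wells[, c("plate_id", "well_id", "replicate_id", "target", "is_control",
            PHASE_PARAMS)]
}

#' Generate a synthetic screen with known ground truth
#'
#' Draws true-regulator status per gene from the class-specific rates, lays
#' targets out on duplicate 96-well plates with 1-3 control (GFP) wells
#' each, and emits gate percentages: a shifted baseline composition for
#' effective dsRNAs (true regulator without knockdown failure, or
#' off-target), scaled by the plate's multiplicative batch effect, plus
#' Gaussian well noise, clipped at 0.
#'
#' @param config A [screen_sim_config()].
#' @return List with `wells` (well table, one row per well) and `truth`
#'   (list with per-gene data frame `genes` and the `config`).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  rates <- class_rates(config)
  genes <- config$roster
  n <- nrow(genes)
  truth <- with_seed(config$seed, {
    r <- unname(rates$regulator_prob[genes$role])
    o <- unname(rates$off_target_prob[genes$role])
    is_reg <- stats::runif(n) < r
    affected <- sample(PHASE_PARAMS, n, replace = TRUE)
    affected[!is_reg] <- NA_character_
    off <- !is_reg & stats::runif(n) < o
    fail <- is_reg & stats::runif(n) < config$knockdown_failure_rate
    off_param <- sample(PHASE_PARAMS, n, replace = TRUE)
    effective <- (is_reg & !fail) | off
    data.frame(gene = genes$gene, role = genes$role,
               regulator_prob = r, off_target_prob = o,
               is_regulator = is_reg, affected_param = affected,
               primary_off_target = off, primary_kd_failure = fail,
               primary_effective = effective,
               primary_effect_param = ifelse(off, off_param,
                                             ifelse(effective, affected,
                                                    NA_character_)),
               stringsAsFactors = FALSE)
  })
  effects <- data.frame(target = truth$gene,
                        effective = truth$primary_effective,
                        effect_param = truth$primary_effect_param,
                        stringsAsFactors = FALSE)
  wells <- build_screen_wells(effects, config,
                              if (is.null(config$seed)) NULL else config$seed + 10L)
  list(wells = wells, truth = list(genes = truth, config = config))
}

#' Generate an independent validation screen for selected genes
#'
#' Re-screens `genes` with a second dsRNA per gene: regulator status and the
#' affected parameter are fixed gene properties, while off-target and
#' knockdown-failure events are redrawn independently of the primary dsRNA.
#'
#' @param truth The `truth` element returned by [generate_screen()].
#' @param genes Genes to re-screen (typically the primary hits).
#' @param seed Optional integer seed (independent of the primary screen's).
#' @return List with `wells` and `truth` (per-gene validation flags).
#' @export
generate_validation_screen <- function(truth, genes, seed = NULL) {
  config <- truth$config
  g <- truth$genes[match(unique(canonicalize_ids(genes)), truth$genes$gene), ,
                   drop = FALSE]
  if (anyNA(g$gene)) stop("genes to validate must come from the simulated roster")
  n <- nrow(g)
  val <- with_seed(seed, {
    off <- !g$is_regulator & stats::runif(n) < g$off_target_prob
    fail <- g$is_regulator & stats::runif(n) < config$knockdown_failure_rate
    off_param <- sample(PHASE_PARAMS, n, replace = TRUE)
    effective <- (g$is_regulator & !fail) | off
    data.frame(gene = g$gene, is_regulator = g$is_regulator,
               validation_off_target = off, validation_kd_failure = fail,
               validation_effective = effective,
               validation_effect_param = ifelse(off, off_param,
                                                ifelse(effective,
                                                       g$affected_param,
                                                       NA_character_)),
               stringsAsFactors = FALSE)
  })
  effects <- data.frame(target = val$gene,
                        effective = val$validation_effective,
                        effect_param = val$validation_effect_param,
                        stringsAsFactors = FALSE)
  wells <- build_screen_wells(effects, config,
                              if (is.null(seed)) NULL else seed + 10L)
  list(wells = wells, truth = list(genes = val, config = config))
}

#' Compare pipeline output with simulation ground truth
#'
#' @param gene_calls Gene-level calls from [analyze_screen()].
#' @param truth The `truth` element returned by [generate_screen()].
#' @param validation_records Optional records from [validate_hits()] run on a
#'   simulated validation screen.
#' @return List: `sensitivity` (hit rate among true regulators), `fdp`
#'   (non-regulator fraction among hits), `class_rates` (observed vs
#'   configured per-class hit rates), and — when validation records are
#'   given — `validation_rate` with its analytic expectation under the
#'   configured off-target and failure rates.
#' @export
recovery_report <- function(gene_calls, truth, validation_records = NULL) {
  g <- truth$genes
  m <- match(gene_calls$gene, g$gene)
  if (anyNA(m)) stop("gene calls do not match the simulation roster")
  hit <- gene_calls$hit
  is_reg <- g$is_regulator[m]
  sens <- if (any(is_reg)) mean(hit[is_reg]) else NA_real_
  fdp <- if (any(hit)) mean(!is_reg[hit]) else NA_real_

  cls <- g$role[m]
  sp <- split(hit, cls)
  class_rates <- data.frame(
    role = names(sp),
    n_tested = lengths(sp),
    n_hits = vapply(sp, sum, 0L),
    observed_rate = vapply(sp, mean, 0),
    configured_rate = unname(truth$config$class_hit_prob[names(sp)]),
    stringsAsFactors = FALSE, row.names = NULL)

  out <- list(sensitivity = sens, fdp = fdp, class_rates = class_rates)
  if (!is.null(validation_records)) {
    vr <- mean(validation_records$validated)
    tested <- g[match(validation_records$gene, g$gene), , drop = FALSE]
    f <- truth$config$knockdown_failure_rate
    # off-target validation hits match the primary class 1/4 of the time
    expected <- mean(ifelse(tested$is_regulator, 1 - f,
                            tested$off_target_prob / 4))
    out$validation_rate <- vr
    out$expected_validation_rate <- expected
    out$n_validation_tested <- nrow(validation_records)
  }
  out
}
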