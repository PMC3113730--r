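test_that("normalization factors follow the global/plate mean arithmetic", {
  single <- toy_wells(list(c(30, 50, 70)), controls = list(50))
  f <- compute_normalization_factors(single)
  expect_equal(unname(as.matrix(f$factor[, PHASE_PARAMS])),
               matrix(1, 1, 4), tolerance = 1e-12)

  two <- toy_wells(list(c(30, 40, 50), c(50, 60, 70)),
                   controls = list(40, 60))
  f2 <- compute_normalization_factors(two)
  expect_equal(unname(f2$global_mean["pct_g1"]), 50)
  fac <- f2$factor[order(f2$factor$plate_id), "pct_g1"]
  expect_equal(fac, c(50 / 40, 50 / 60))

  # extreme control wells leave the factors untouched
  two_extreme <- two
  two_extreme[two_extreme$is_control, PHASE_PARAMS] <- 1e6
  f3 <- compute_normalization_factors(two_extreme)
  expect_equal(f3$factor, f2$factor)

  only_controls <- single
  only_controls$is_control <- TRUE
  expect_error(compute_normalization_factors(only_controls),
               "no non-control wells")
})

test_that("normalization scales every well and equalizes plate means", {
  two <- toy_wells(list(c(10, 20, 30), c(40, 50, 60)),
                   controls = list(20, 50))
  f <- compute_normalization_factors(two)
  norm <- normalize_wells(two, f)
  # raw 20 on a plate with mean 20 and global mean 35 -> 20 * 35/20 = 35
  expect_equal(norm$pct_g1[norm$target == "gene_p1_02"], 35)
  # controls are scaled by the same plate factor
  expect_equal(norm$pct_g1[norm$is_control & norm$plate_id == "P1"],
               20 * 35 / 20)
  for (p in unique(norm$plate_id)) {
    sub <- norm[!norm$is_control & norm$plate_id == p, ]
    expect_equal(colMeans(sub[, PHASE_PARAMS]), f$global_mean,
                 tolerance = 1e-12)
  }

  missing <- two[two$plate_id == "P1", ]
  f1 <- compute_normalization_factors(missing)
  expect_error(normalize_wells(two, f1), "no normalization factor")
})

test_that("replicate averaging is the arithmetic mean with incomplete flags", {
  w1 <- toy_wells(list(c(40, 10)), controls = list(50), replicate_id = "r1")
  w2 <- toy_wells(list(c(50, 10)), controls = list(50), replicate_id = "r2")
  wells <- rbind(w1, w2[w2$target != "gene_p1_02", ])
  avg <- average_replicates(wells)
  expect_equal(avg$pct_g1[avg$target == "gene_p1_01"], 45)
  expect_equal(avg$n_replicates[avg$target == "gene_p1_01"], 2L)
  expect_true(avg$incomplete[avg$target == "gene_p1_02"])
  expect_equal(avg$pct_g1[avg$target == "gene_p1_02"], 10)

  dup <- rbind(w1, transform(w1, replicate_id = "r2"))
  ident <- average_replicates(dup)
  expect_equal(ident$pct_g1, c(40, 10))  # identical duplicates: same vector
})

test_that("control statistics pool control wells with sample SD", {
  w <- toy_wells(list(c(10, 20)), controls = list(c(48, 50, 52)))
  st <- control_statistics(w)
  expect_equal(unname(st$mean["pct_g1"]), 50)
  expect_equal(unname(st$sd["pct_g1"]), 2)
  expect_equal(st$n, 3L)

  same <- toy_wells(list(c(10, 20)), controls = list(c(50, 50, 50)))
  expect_equal(unname(control_statistics(same)$sd), rep(0, 4))

  one <- toy_wells(list(c(10, 20)), controls = list(50))
  expect_error(control_statistics(one), "at least 2 control wells")
})

test_that("hit calling is one-sided with a strict threshold", {
  st <- structure(list(mean = setNames(rep(50, 4), PHASE_PARAMS),
                       sd = setNames(rep(2, 4), PHASE_PARAMS), n = 10),
                  class = "control_stats")
  means <- data.frame(target = c("at_3sd", "subg1_up", "g1_down"),
                      pct_g1 = c(56, 50, 40),
                      pct_g2m = 50, pct_gt_g2m = 50,
                      pct_subg1 = c(50, 57, 50))
  calls <- score_and_call(means, st, k = 3)
  expect_equal(calls$hit, c(FALSE, TRUE, FALSE))  # 3 SD exactly is not a hit
  expect_equal(calls$phenotypes[2], "subG1")
  expect_equal(calls$z_g1[3], -5)  # strong decrease, never flagged

  st0 <- st; st0$sd[1] <- 0
  expect_error(score_and_call(means, st0), "control SD is zero")
})

test_that("gene aggregation uses the any-amplicon rule and unions phenotypes", {
  st <- structure(list(mean = setNames(rep(50, 4), PHASE_PARAMS),
                       sd = setNames(rep(2, 4), PHASE_PARAMS), n = 10),
                  class = "control_stats")
  means <- data.frame(target = c("amp1", "amp2", "amp3", "amp4"),
                      pct_g1 = c(60, 50, 50, 50),
                      pct_g2m = 50, pct_gt_g2m = 50,
                      pct_subg1 = c(50, 60, 50, 50))
  calls <- score_and_call(means, st)
  mapping <- data.frame(amplicon = c("amp1", "amp2", "amp3", "amp4"),
                        gene = c("geneA", "geneA", "geneB", "geneB"))
  genes <- aggregate_genes(calls, mapping)
  expect_equal(genes$hit, c(TRUE, FALSE))
  expect_setequal(strsplit(genes$phenotypes[1], ",")[[1]], c("G1", "subG1"))
  expect_equal(genes$z_g1[1], 5)  # strongest amplicon deviation retained

  expect_warning(aggregate_genes(calls, mapping[-3, ]), "no gene mapping")
  expect_error(aggregate_genes(calls, rbind(mapping, mapping[1, ])),
               "exactly one gene")
})

test_that("class hit rates are percentages of tested genes", {
  calls <- data.frame(gene = sprintf("g%02d", 1:12),
                      hit = rep(c(TRUE, FALSE), c(3, 9)))
  roles <- data.frame(gene = calls$gene, role = "interactor")
  tab <- hit_rate_by_class(calls, roles)
  expect_equal(tab$hit_rate, 25.0)
  expect_equal(tab$n_tested, 12L)

  # the published convention: 160 hits of 1303 tested reads as 12.3%
  expect_equal(round(100 * 160 / 1303, 1), 12.3)

  none <- hit_rate_by_class(transform(calls, hit = FALSE), roles)
  expect_equal(none$hit_rate, 0)

  expect_error(hit_rate_by_class(calls, roles[-1, ]), "no role")
})

test_that("z-scores are invariant to per-plate rescaling of the raw data", {
  roster <- data.frame(gene = sprintf("g%03d", 1:150),
                       role = rep("bait", 150))
  sim <- generate_screen(screen_sim_config(roster, seed = 17))
  base <- analyze_screen(sim$wells)

  scaled <- sim$wells
  pick <- scaled$plate_id == "P001" & scaled$replicate_id == "r1"
  scaled[pick, PHASE_PARAMS] <- scaled[pick, PHASE_PARAMS] * 7.3
  res <- analyze_screen(scaled)
  expect_equal(res$gene_calls$z_g1, base$gene_calls$z_g1, tolerance = 1e-10)
  expect_identical(res$gene_calls$hit, base$gene_calls$hit)
})
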