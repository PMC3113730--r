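test_that("bait neighborhood keeps exactly the bait-incident edges", {
  m <- make_map(c("A", "B"), c("B", "C"))
  nb <- extract_bait_neighborhood(m, "A")
  expect_equal(nrow(nb$edges), 1L)
  expect_setequal(c(nb$edges$a, nb$edges$b), c("a", "b"))
  expect_equal(interactors(nb, "A"), "b")

  all_baits <- extract_bait_neighborhood(m, m$nodes)
  expect_equal(nrow(all_baits$edges), nrow(m$edges))

  absent <- extract_bait_neighborhood(m, "Z")
  expect_equal(nrow(absent$edges), 0L)
  expect_true("z" %in% absent$nodes)
})

star_map <- function(n_partners, datasets = rep("ds1", n_partners)) {
  make_map(rep("HUB", n_partners), sprintf("p%02d", seq_len(n_partners)),
           dataset = datasets)
}

test_that("hub threshold is strict: exactly 30 partners is kept, 31 removed", {
  nb30 <- extract_bait_neighborhood(star_map(30), "HUB")
  expect_equal(nrow(apply_hub_filter(nb30, bait_set("HUB"))$edges), 30L)

  nb31 <- extract_bait_neighborhood(star_map(31), "HUB")
  expect_equal(nrow(apply_hub_filter(nb31, bait_set("HUB"))$edges), 0L)
})

test_that("multi-study and rescue-bait edges are added back", {
  # 31 partners, one pair supported by two datasets
  recs <- data.frame(
    protein_a = c(rep("HUB", 31), "HUB"),
    protein_b = c(sprintf("p%02d", 1:31), "p01"),
    dataset_id = c(rep("ds1", 31), "ds2"))
  nb <- extract_bait_neighborhood(load_interaction_map(recs), "HUB")
  kept <- apply_hub_filter(nb, bait_set("HUB"))
  expect_equal(nrow(kept$edges), 1L)
  expect_setequal(c(kept$edges$a, kept$edges$b), c("hub", "p01"))

  # rescue bait: all 31 single-study edges retained
  rescued <- apply_hub_filter(extract_bait_neighborhood(star_map(31), "HUB"),
                              bait_set("HUB", rescue_baits = "HUB"))
  expect_equal(nrow(rescued$edges), 31L)
})

test_that("an interactor shared with a non-hub bait keeps that connection", {
  recs <- data.frame(
    protein_a = c(rep("HUB", 31), "B2"),
    protein_b = c(sprintf("p%02d", 1:31), "p01"),
    dataset_id = "ds1")
  baits <- bait_set(c("HUB", "B2"))
  nb <- extract_bait_neighborhood(load_interaction_map(recs), baits)
  kept <- apply_hub_filter(nb, baits)
  expect_equal(nrow(kept$edges), 1L)
  expect_setequal(c(kept$edges$a, kept$edges$b), c("b2", "p01"))
  expect_equal(interactors(kept, baits), "p01")
})

test_that("hub filter is contractive, idempotent and preserves rescue baits", {
  set.seed(41)
  for (rep in 1:10) {
    m <- load_interaction_map(random_edge_records(25, p_edge = 0.3))
    bait_genes <- sample(m$nodes, 6)
    baits <- bait_set(bait_genes, rescue_baits = bait_genes[1])
    cfg <- filter_config(max_bait_degree = sample(2:5, 1))
    nb <- extract_bait_neighborhood(m, baits)
    f1 <- apply_hub_filter(nb, baits, cfg)
    key <- function(x) paste(x$edges$a, x$edges$b)
    expect_true(all(key(f1) %in% key(nb)))
    f2 <- apply_hub_filter(f1, baits, cfg)
    expect_identical(f1$edges, f2$edges)
    rb <- baits$rescue_baits
    touches <- function(x) key(x)[x$edges$a %in% rb | x$edges$b %in% rb]
    expect_setequal(touches(f1), touches(nb))
  }
})

test_that("hub filter matches the brute-force removal/rescue oracle", {
  set.seed(99)
  for (rep in 1:25) {
    m <- load_interaction_map(random_edge_records(sample(10:40, 1),
                                                  p_edge = 0.25))
    if (length(m$nodes) < 4) next
    baits <- bait_set(sample(m$nodes, min(5, length(m$nodes))),
                      rescue_baits = character())
    cfg <- filter_config(max_bait_degree = sample(1:4, 1))
    nb <- extract_bait_neighborhood(m, baits)
    got <- apply_hub_filter(nb, baits, cfg)$edges
    want <- brute_hub_filter(nb, baits, cfg)
    expect_equal(got[order(got$a, got$b), c("a", "b")],
                 want[order(want$a, want$b), c("a", "b")],
                 ignore_attr = TRUE)
  }
})

test_that("confidence filter keeps strictly greater scores only", {
  m <- make_map(c("A", "B", "C"), c("B", "C", "D"),
                confidence = c(0.4, 0.5, 0.6))
  kept <- filter_by_confidence(m, 0.5)
  expect_equal(kept$edges$confidence, 0.6)

  expect_equal(nrow(filter_by_confidence(m, 0)$edges), 3L)

  unscored <- make_map("A", "B")
  expect_message(none <- filter_by_confidence(unscored, 0.5),
                 "without a confidence score")
  expect_equal(nrow(none$edges), 0L)

  expect_error(filter_by_confidence(m, 1.2), "\\[0, 1\\]")
})

test_that("roles follow the adjacency rules with bait precedence", {
  # chain A(bait) - B - C - D; B is retained as an interactor
  m <- make_map(c("A", "B", "C"), c("B", "C", "D"))
  baits <- bait_set("A")
  nb <- apply_hub_filter(extract_bait_neighborhood(m, baits), baits)
  roles <- assign_roles(m, baits, nb)
  lookup <- setNames(as.character(roles$role), roles$gene)
  expect_equal(unname(lookup[c("a", "b", "c", "d")]),
               c("bait", "interactor", "unclassified", "non_interactor"))

  # a bait that also interacts with another bait stays a bait
  m2 <- make_map("A", "B")
  baits2 <- bait_set(c("A", "B"))
  nb2 <- extract_bait_neighborhood(m2, baits2)
  roles2 <- assign_roles(m2, baits2, nb2)
  expect_true(all(roles2$role == "bait"))

  # single bait + partner: partner is an interactor, no candidates remain
  roles3 <- assign_roles(m2, bait_set("A"), extract_bait_neighborhood(m2, "A"))
  expect_equal(sum(roles3$role == "non_interactor"), 0L)
  expect_equal(roles3$gene[roles3$role == "interactor"], "b")
})

test_that("every node receives exactly one role", {
  set.seed(7)
  for (rep in 1:10) {
    m <- load_interaction_map(random_edge_records(30, p_edge = 0.1))
    baits <- bait_set(sample(m$nodes, 4))
    nb <- apply_hub_filter(extract_bait_neighborhood(m, baits), baits,
                           filter_config(max_bait_degree = 3))
    roles <- assign_roles(m, baits, nb)
    expect_setequal(roles$gene, union(m$nodes, baits$genes))
    expect_false(any(duplicated(roles$gene)))
    expect_false(anyNA(roles$role))
  }
})

test_that("non-interactor sampling is uniform, seeded and bounded", {
  cand <- sprintf("c%02d", 1:20)
  expect_equal(length(sample_non_interactors(cand, 0)), 0L)
  expect_setequal(sample_non_interactors(cand, 20), tolower(cand))
  expect_identical(sample_non_interactors(cand, 5, seed = 4),
                   sample_non_interactors(cand, 5, seed = 4))
  expect_error(sample_non_interactors(cand, 21), "cannot sample")
})
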