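test_that("Blau's index matches closed forms and stays in [0, 1)", {
  expect_equal(blau_index(c(31, 1)), 1 - (31/32)^2 - (1/32)^2,
               tolerance = 1e-12)
  expect_equal(round(blau_index(c(31, 1)), 2), 0.06)
  expect_equal(blau_index(10), 0)                       # single category
  expect_equal(blau_index(rep(3, 8)), 0.875)            # 1 - 1/k
  expect_error(blau_index(c(0, 0)), "zero")
  expect_error(blau_index(c(-1, 2)))

  set.seed(1)
  for (i in 1:30) {
    counts <- sample(0:20, sample(2:8, 1), replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    b <- blau_index(counts)
    expect_gte(b, 0); expect_lt(b, 1)
    # relabeling invariance
    expect_equal(blau_index(sample(counts)), b, tolerance = 1e-12)
  }
  # splitting a singleton off the majority strictly increases diversity
  expect_gt(blau_index(c(30, 1, 1)), blau_index(c(31, 1)))
})

test_that("distinct recommendation sets categorize by exact set equality", {
  out <- system_output("x", list(p1 = "a", p2 = "a", p3 = "b"))
  counts <- distinct_recommendation_sets(out)
  expect_equal(sort(unname(counts)), c(1L, 2L))
  # all-empty cohort is one category
  empty <- system_output("x", list(p1 = character(0), p2 = character(0)))
  expect_length(distinct_recommendation_sets(empty), 1)
  # order of drugs within a set does not matter
  out2 <- system_output("x", list(p1 = c("a", "b"), p2 = c("b", "a")))
  expect_length(distinct_recommendation_sets(out2), 1)
  # permuting patients leaves counts unchanged
  out3 <- system_output("x", list(p3 = "b", p1 = "a", p2 = "a"))
  expect_equal(sort(unname(distinct_recommendation_sets(out3))),
               sort(unname(counts)))
})

test_that("overlap concordance handles both denominators", {
  a <- system_output("eng", list(p1 = "mph", p2 = "atx", p3 = character(0)))
  b <- system_output("cpg", list(p1 = "mph", p2 = "mph", p3 = "mph"))
  # identical outputs with non-empty sets overlap everywhere
  expect_equal(overlap_concordance(b, b), 100)
  # an empty set never overlaps, not even with itself
  expect_equal(overlap_concordance(a, a), 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(overlap_concordance(a, b, "all_patients"), 100 / 3)
  expect_equal(overlap_concordance(a, b, "favorable_only"), 50)
  disj <- system_output("cpg", list(p1 = "gxr", p2 = "gxr", p3 = "gxr"))
  expect_equal(overlap_concordance(a, disj), 0)
  none <- system_output("eng", list(p1 = character(0), p2 = character(0),
                                    p3 = character(0)))
  expect_error(overlap_concordance(none, b, "favorable_only"), "favorable")
  expect_error(overlap_concordance(a, system_output("c", list(q1 = "m"))),
               "cohort")
})

test_that("all-patients concordance factorizes through the favorable fraction", {
  # identity used by the published arithmetic: when no non-favorable patient
  # overlaps, overall = favorable_only * favorable fraction
  fx <- end_to_end_fixture("overlap_arithmetic")
  fav <- mean(vapply(fx$engine$sets, function(s) length(s) > 0, logical(1)))
  expect_equal(overlap_concordance(fx$engine, fx$nice, "all_patients"),
               overlap_concordance(fx$engine, fx$nice, "favorable_only") * fav,
               tolerance = 1e-12)
})

test_that("the packaged distance matrix reproduces the five anchors", {
  D <- build_distance_matrix()
  expect_equal(D["methylphenidate", "dexmethylphenidate"], 1)
  expect_equal(D["methylphenidate", "bupropion"], 7)
  expect_equal(D["methylphenidate", "atomoxetine"], 15)
  expect_equal(D["methylphenidate", "guanfacine"], 19)
  expect_equal(D["methylphenidate", "no_treatment"], 33)
})

test_that("distance matrix axioms hold and violations error", {
  D <- build_distance_matrix()
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  expect_true(all(D >= 0) && max(D) == 33)
  # deterministic regeneration
  expect_identical(D, build_distance_matrix())
  # prodrug chains accumulate relation steps
  expect_equal(D["methylphenidate", "serdexmethylphenidate"], 2)
  expect_equal(D["dexamphetamine", "lisdexamfetamine"], 1)
  # a weight set that breaks the ceiling errors
  expect_error(build_distance_matrix(scheme = distance_scheme(w_target = 40)),
               "exceeds")
  # no_treatment must be present
  pr <- default_drug_profiles()
  expect_error(build_distance_matrix(pr[names(pr) != "no_treatment"]),
               "no_treatment")
})

test_that("recommendation-set distance is a modified-Hausdorff average", {
  D <- build_distance_matrix()
  expect_equal(recset_distance("methylphenidate", "methylphenidate", D), 0)
  expect_equal(recset_distance(character(0), "methylphenidate", D), 33)
  expect_equal(recset_distance(character(0), character(0), D), 0)
  # hand computation on a 2 x 1 structure
  a <- c("methylphenidate", "atomoxetine"); b <- "dexmethylphenidate"
  h_ab <- mean(c(D["methylphenidate", b], D["atomoxetine", b]))
  h_ba <- min(D[b, a])
  expect_equal(recset_distance(a, b, D), (h_ab + h_ba) / 2)
  expect_equal(recset_distance(a, b, D), recset_distance(b, a, D))
  expect_error(recset_distance("nosuchdrug", "methylphenidate", D),
               "nosuchdrug")
})

test_that("system distance matrix averages per-patient set distances", {
  D <- build_distance_matrix()
  ids <- paste0("p", 1:32)
  s1 <- system_output("A", setNames(rep(list("methylphenidate"), 32), ids))
  s2 <- system_output("B", setNames(rep(list("methylphenidate"), 32), ids))
  s3sets <- setNames(rep(list("methylphenidate"), 32), ids)
  s3sets[[5]] <- character(0)  # one patient at the no-treatment distance 33
  s3 <- system_output("C", s3sets)
  M <- system_distance_matrix(list(s1, s2, s3), D)
  expect_equal(M["A", "B"], 0)
  expect_equal(M["A", "C"], 33 / 32)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  # permuting patient order leaves the matrix unchanged
  s3p <- system_output("C", s3sets[rev(ids)])
  expect_equal(system_distance_matrix(list(s1, s2, s3p), D), M)
})

test_that("UPGMA agglomerates correctly with deterministic ties", {
  lab <- function(m, l) { rownames(m) <- colnames(m) <- l; m }
  # 3 systems: the close pair merges first at its distance
  d3 <- lab(matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3), c("A", "B", "C"))
  tr <- upgma_tree(d3)
  expect_equal(tr$height, c(1, 10))
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))

  # two systems: single merge at their distance
  d2 <- lab(matrix(c(0, 4, 4, 0), 2), c("X", "Y"))
  expect_equal(upgma_tree(d2)$height, 4)

  # duplicate system merges at height 0 first
  d3b <- lab(matrix(c(0, 0, 8, 0, 0, 8, 8, 8, 0), 3), c("A", "A2", "C"))
  expect_equal(upgma_tree(d3b)$height[1], 0)

  # ties broken lexicographically: identical off-diagonals
  d3c <- lab(matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0), 3), c("B", "C", "A"))
  tr3 <- upgma_tree(d3c)
  first <- sort(tr3$labels[-tr3$merge[1, ]])
  expect_equal(first, c("A", "B"))

  expect_error(upgma_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA matches hclust average linkage on random matrices", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * n, 1, 50), n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
    tr <- upgma_tree(m)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-9)
    # same 2- and 3-group partitions
    for (k in 2:3) {
      ca <- stats::cutree(stats::as.hclust(tr), k)
      cb <- stats::cutree(hc, k)
      expect_equal(length(unique(paste(ca, cb))), k)
    }
    # ultrametric: heights non-decreasing
    expect_true(all(diff(tr$height) >= -1e-9))
    # newick serialization covers all leaves
    for (l in rownames(m)) expect_match(tr$newick, l, fixed = TRUE)
  }
})

test_that("evaluation_summary mirrors the comparison-table layout", {
  ids <- paste0("p", 1:4)
  eng <- system_output("engine", setNames(list("methylphenidate",
    c("methylphenidate", "atomoxetine"), "atomoxetine", character(0)), ids))
  cpg <- system_output("NICE", setNames(rep(list("methylphenidate"), 4), ids))
  sm <- evaluation_summary(list(eng, cpg))
  expect_equal(sm$system, c("engine", "NICE"))
  expect_equal(sm$n_distinct, c(4, 1))
  expect_equal(sm$methylphenidate, c(50.0, 100.0))
  expect_equal(sm$blau[2], 0)
})
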