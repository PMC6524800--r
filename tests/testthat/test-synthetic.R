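test_that("generation is deterministic, byte for byte", {
  sp <- synthetic_spec(n_families = 2, members_per_family = 2,
                       core_length = 40, n_decorations = 1, seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- generate_clan(sp, out_dir = d1)
  g2 <- generate_clan(sp, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_identical(g1$truth$clan_core_map, g2$truth$clan_core_map)
})

test_that("zero member noise gives identical coordinate sets", {
  g <- generate_clan(synthetic_spec(
    n_families = 1, members_per_family = 2, core_length = 40,
    n_decorations = 1, member_sigma = 0, mutation_rate_member = 0,
    member_indel_prob = 0, seed = 32))
  expect_identical(model_coords(g$models[[1]]),
                   model_coords(g$models[[2]]))
  expect_identical(model_sequence(g$models[[1]]),
                   model_sequence(g$models[[2]]))
})

test_that("the default clan has the declared shape and truth map", {
  g <- generate_clan(synthetic_spec(seed = 33))
  expect_equal(length(g$models), 16L)
  expect_true(all(vapply(g$models, length, integer(1)) >= 60L))
  expect_equal(nrow(g$truth$clan_core_map), 60L)
  expect_equal(ncol(g$truth$clan_core_map), 16L)
  expect_false(anyNA(g$truth$clan_core_map))
  expect_equal(unname(table(g$truth$family_label)), rep(4L, 4L),
               ignore_attr = TRUE)
})

test_that("pre-noise chains satisfy spacing and clash constraints", {
  g <- generate_clan(synthetic_spec(
    n_families = 2, members_per_family = 1, core_length = 50,
    n_decorations = 2, member_sigma = 0, mutation_rate_member = 0,
    member_indel_prob = 0, seed = 34))
  for (m in g$models) {
    x <- model_coords(m)
    n <- nrow(x)
    bonds <- sqrt(rowSums((x[-1, ] - x[-n, ])^2))
    expect_true(all(abs(bonds - 3.8) <= 0.0101))
    d <- as.matrix(dist(x))
    d[abs(row(d) - col(d)) <= 1] <- Inf
    # non-bonded contacts stay at 4 A, except loop-insertion anchors
    # which legitimately sit at the ancestral bond distance
    expect_gte(min(d), 3.8 - 0.02)
    expect_lt(mean(d < 4.0), 0.005)
  }
})

test_that("core recovery metrics count matches and misses correctly", {
  ids <- paste0("m", 1:4)
  truth_map <- matrix(rep(1:60, 4), 60, 4, dimnames = list(NULL, ids))
  truth <- fake_truth(truth_map)
  expect_equal(core_recovery_metrics(fake_core(truth_map), truth),
               c(precision = 1, recall = 1))
  half <- truth_map[1:30, ]
  expect_equal(core_recovery_metrics(fake_core(half), truth),
               c(precision = 1, recall = 0.5))
  decoy <- truth_map[1:10, ] + 200L
  mixed <- rbind(truth_map[1:10, ], decoy)
  expect_equal(core_recovery_metrics(fake_core(mixed), truth),
               c(precision = 0.5, recall = 10 / 60))
  other <- fake_core(matrix(1:5, 5, 1, dimnames = list(NULL, "q9")))
  expect_error(core_recovery_metrics(other, truth), "absent")
})

test_that("family monophyly flags read off the tree correctly", {
  truth <- fake_truth(matrix(rep(1:5, 4), 5, 4,
                             dimnames = list(NULL, c("a1", "a2", "b1", "b2"))),
                      family_label = c(a1 = "FA", a2 = "FA",
                                       b1 = "FB", b2 = "FB"))
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_true(all(family_recovery_metrics(good, truth)))
  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(unname(family_recovery_metrics(bad, truth)), c(FALSE, FALSE))
})

test_that("core recovery degrades monotonically with member noise", {
  sigmas <- c(0.1, 0.5, 1.0, 2.0)
  mean_recall <- vapply(sigmas, function(sg) {
    mean(vapply(1:10, function(s) {
      g <- generate_clan(synthetic_spec(
        n_families = 2, members_per_family = 3, core_length = 40,
        n_decorations = 1, member_sigma = sg, seed = s))
      core <- root_core(build_hierarchy(g$models))
      core_recovery_metrics(core, g$truth)["recall"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_recall) <= 1e-9))
})
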