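test_that("self-alignment returns the identity mapping with zero rmsd", {
  m <- make_model(make_trace(60, seed = 21),
                  strsplit(random_seq(60, 22), "")[[1]])
  em <- align_pair(m, m)
  expect_equal(em$n_eq, 60L)
  expect_equal(em$pairs[, 1], 1:60)
  expect_equal(em$pairs[, 2], 1:60)
  expect_identical(em$superposition$rmsd, 0)
  expect_equal(merge_score(em), 60)
})

test_that("a perturbed copy is recovered almost completely", {
  for (s in 1:5) {
    n <- 70
    xyz <- make_trace(n, seed = s)
    set.seed(s + 500)
    aa <- strsplit(random_seq(n, s + 900), "")[[1]]
    noisy <- rigid_move(xyz + matrix(rnorm(3 * n, 0, 0.3), n, 3))
    em <- align_pair(make_model(xyz, aa), make_model(noisy, aa))
    expect_gte(em$n_eq, ceiling(0.95 * n))
    expect_lte(em$superposition$rmsd, 0.9)  # 3 x sigma
    # recovered pairs are (mostly) the true correspondence
    expect_gt(mean(em$pairs[, 1] == em$pairs[, 2]), 0.95)
  }
})

test_that("independent random chains share only a small equivalence", {
  # empirical null: unrelated compact traces of equal length
  frac <- vapply(1:20, function(s) {
    a <- make_model(make_trace(60, seed = s), id = "a")
    b <- make_model(make_trace(60, seed = s + 1000), id = "b")
    align_pair(a, b)$n_eq / 60
  }, numeric(1))
  expect_lt(mean(frac), 0.25)
  expect_true(all(frac < 0.4))
})

test_that("alignment is symmetric up to column swap on noisy copies", {
  for (s in 1:3) {
    n <- 50
    xyz <- make_trace(n, seed = s + 30)
    set.seed(s)
    aa <- strsplit(random_seq(n, s + 60), "")[[1]]
    noisy <- rigid_move(xyz + matrix(rnorm(3 * n, 0, 0.3), n, 3))
    a <- make_model(xyz, aa, id = "a")
    b <- make_model(noisy, aa, id = "b")
    ab <- align_pair(a, b)
    ba <- align_pair(b, a)
    expect_equal(ab$pairs, ba$pairs[, c(2, 1)])
  }
})

test_that("every reported pair honours the d_cut contract", {
  p <- align_params()
  for (s in 1:3) {
    n <- 50
    xyz <- make_trace(n, seed = s + 70)
    set.seed(s)
    noisy <- rigid_move(xyz + matrix(rnorm(3 * n, 0, 0.8), n, 3))
    a <- make_model(xyz, id = "a")
    b <- make_model(noisy, id = "b")
    em <- align_pair(a, b, p)
    bt <- apply_superposition(model_coords(b)[em$pairs[, 2], ],
                              em$superposition)
    d <- sqrt(rowSums((model_coords(a)[em$pairs[, 1], ] - bt)^2))
    expect_true(all(d <= p$d_cut + 1e-6))
  }
})

test_that("equivalences shrink and rmsd grows with perturbation size", {
  sigmas <- c(0.1, 0.3, 0.6, 1.0)
  n <- 50
  res <- sapply(sigmas, function(sg) {
    stats <- vapply(1:10, function(s) {
      xyz <- make_trace(n, seed = s + 200)
      set.seed(s * 13)
      noisy <- rigid_move(xyz + matrix(rnorm(3 * n, 0, sg), n, 3))
      em <- align_pair(make_model(xyz, id = "a"),
                       make_model(noisy, id = "b"))
      c(em$n_eq, em$superposition$rmsd)
    }, numeric(2))
    rowMeans(stats)
  })
  expect_true(all(diff(res[1, ]) <= 0))  # mean n_eq non-increasing
  expect_true(all(diff(res[2, ]) >= 0))  # mean rmsd non-decreasing
})

test_that("unalignable inputs yield an empty map, not an error", {
  # a straight rod cannot seed against a compact trace below 5 A rmsd
  a <- make_model(make_trace(40, seed = 91), id = "a")
  b <- make_model(make_straight(40), id = "b")
  em <- align_pair(a, b)
  expect_equal(em$score, 0)
  expect_equal(merge_score(em), 0)
  expect_equal(em$n_eq, 0L)
})

test_that("equivalence maps serialize with per-pair distances and a header", {
  n <- 50
  xyz <- make_trace(n, seed = 88)
  set.seed(88)
  noisy <- rigid_move(xyz + matrix(rnorm(3 * n, 0, 0.3), n, 3))
  a <- make_model(xyz, id = "a")
  b <- make_model(noisy, id = "b")
  em <- align_pair(a, b)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_equivalence_tsv(em, a, b, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), em$n_eq)
  expect_true(all(tab$distance <= em$d_cut + 1e-6))
  hdr <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(hdr$n_eq, em$n_eq)
  expect_equal(hdr$rmsd, em$superposition$rmsd, tolerance = 1e-9)
})

test_that("merge_score combines pair count and rmsd as n/(1+rmsd)", {
  sup <- structcore:::identity_superposition()
  sup$rmsd <- 2.2
  m <- structcore:::new_equivalence_map(cbind(1:72, 1:72), sup, NA, 3.8)
  expect_equal(merge_score(m), 72 / (1 + 2.2))
  expect_equal(merge_score(m), 22.5)
  empty <- structcore:::empty_equivalence_map(3.8)
  expect_equal(merge_score(empty), 0)
})
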