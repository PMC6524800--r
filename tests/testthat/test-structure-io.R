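test_that("PDB writer/reader round-trips coordinates, sequence and metadata", {
  xyz <- make_trace(20, seed = 11)
  aa <- strsplit(random_seq(20, 12), "")[[1]]
  m <- make_model(round(xyz, 3), aa, id = "rt_A", resolution = 2.5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  back <- read_structure(f, chain = "A", model_id = "rt_A")
  expect_equal(model_coords(back), model_coords(m), tolerance = 1e-9)
  expect_equal(model_sequence(back), model_sequence(m))
  expect_equal(back$resolution, 2.5)
  expect_equal(back$n_missing, 0L)
  expect_equal(back$residues$res_seq, m$residues$res_seq)
})

test_that("altloc duplicates keep the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(altloc_pdb_lines(occ_a = 0.60, occ_b = 0.40), f)
  m <- read_structure(f, chain = "A")
  expect_equal(length(m), 3L)
  expect_equal(unname(model_coords(m)[2, ]), c(3.8, 0, 0))
  # flipped occupancies pick the other conformer
  writeLines(altloc_pdb_lines(occ_a = 0.40, occ_b = 0.60), f)
  m2 <- read_structure(f, chain = "A")
  expect_equal(unname(model_coords(m2)[2, ]), c(9.9, 9.9, 9.9))
})

test_that("missing residues come from author-numbering gaps without SEQRES", {
  xyz <- make_straight(4)
  m <- make_model(xyz, id = "gap_A", res_seq = c(10L, 11L, 14L, 15L))
  f <- withr::local_tempfile(fileext = ".pdb")
  # strip SEQRES so the reader must fall back to numbering gaps
  writeLines(grep("^SEQRES", readLines(write_structure(m, f)),
                  value = TRUE, invert = TRUE), f)
  back <- read_structure(f, chain = "A")
  expect_equal(back$n_missing, 2L)
})

test_that("reader errors name the failure", {
  expect_error(read_structure("no_such_file.pdb"), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(make_model(make_straight(5)), f)
  expect_error(read_structure(f, chain = "Z"), "chain 'Z' absent")
})

test_that("trim_to_range keeps the inclusive author-number window", {
  m <- make_model(make_trace(100, seed = 3), id = "tr")
  expect_equal(length(trim_to_range(m, 20, 40)), 21L)
  expect_error(trim_to_range(m, 200, 300), "no residues")
  # insertion-coded residues belong to their base number
  mi <- make_model(make_straight(4), id = "ins",
                   res_seq = c(19L, 20L, 20L, 21L),
                   icode = c("", "", "A", ""))
  expect_equal(length(trim_to_range(mi, 20, 21)), 3L)
})

test_that("curation filters apply the length/missing/resolution thresholds", {
  specs <- list(c(140, 2.0, 0), c(137, 2.0, 0), c(150, 4.5, 0),
                c(139, 3.9, 12), c(200, 2.5, 3))
  models <- lapply(seq_along(specs), function(k) {
    s <- specs[[k]]
    m <- make_model(make_straight(s[1]), id = paste0("m", k),
                    resolution = s[2])
    m$n_missing <- as.integer(s[3])
    m
  })
  res <- filter_dataset(models, filter_config())
  expect_equal(vapply(res$kept, function(m) m$model_id, character(1)),
               c("m1", "m5"))
  expect_equal(res$report$failed_rules,
               c("", "min_length", "max_resolution", "max_missing", ""))
  # boundary: exactly 138 modeled residues is kept
  b <- filter_dataset(list(make_model(make_straight(138), id = "b",
                                      resolution = 2.0)))
  expect_true(b$report$kept)
  # unknown resolution (e.g. NMR) passes the resolution filter
  u <- filter_dataset(list(make_model(make_straight(140), id = "u")))
  expect_true(u$report$kept)
  # empty input and idempotence
  e <- filter_dataset(list())
  expect_equal(length(e$kept), 0L)
  expect_equal(nrow(e$report), 0L)
  again <- filter_dataset(res$kept, filter_config())
  expect_equal(length(again$kept), length(res$kept))
  expect_true(all(again$report$kept))
})

test_that("Smith-Waterman identity matches its definition and is symmetric", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(pairwise_identity("AAAA", "WWWW"), 0)
  expect_error(pairwise_identity("", "ACD"), "non-empty")
  expect_error(pairwise_identity("ACB", "ACD"), "letters")
  for (s in 1:5) {
    a <- random_seq(60, s)
    b <- random_seq(50, s + 100)
    expect_identical(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, a), 1.0)
  }
})

test_that("greedy identity clustering follows length order and threshold", {
  base <- random_seq(100, 42)
  dup1 <- make_model(make_straight(100), strsplit(base, "")[[1]], id = "d1")
  dup2 <- make_model(make_straight(100), strsplit(base, "")[[1]], id = "d2")
  expect_equal(length(identity_cluster(list(dup1, dup2))), 1L)
  # duplicates collapse even at max_identity = 1
  expect_equal(length(identity_cluster(list(dup1, dup2),
                                       max_identity = 1.0)), 1L)
  # three mutually dissimilar sequences (disjoint alphabets) stay apart
  pools <- list(c("A", "C", "D", "E"), c("F", "G", "H", "I"),
                c("K", "L", "M", "N"))
  rnd <- lapply(1:3, function(k)
    make_model(make_straight(60),
               strsplit(segment_seq(60, pools[[k]], k * 7), "")[[1]],
               id = paste0("r", k)))
  ids <- combn(3, 2, function(p)
    pairwise_identity(model_sequence(rnd[[p[1]]]),
                      model_sequence(rnd[[p[2]]])))
  expect_true(all(ids < 0.1))
  expect_equal(length(identity_cluster(rnd)), 3L)
})

test_that("greedy chain A~B~C keeps A and C as representatives", {
  # overlapping-segment design: A and B share s2, B and C share s3,
  # A and C share nothing (disjoint alphabets)
  s1 <- segment_seq(70, c("A", "C", "D", "E"), 101)
  s2 <- segment_seq(50, c("F", "G", "H", "I"), 102)
  s3 <- segment_seq(55, c("K", "L", "M", "N"), 103)
  s4 <- segment_seq(45, c("P", "Q", "R", "S"), 104)
  seq_a <- paste0(s1, s2)   # 120
  seq_b <- paste0(s2, s3)   # 105
  seq_c <- paste0(s3, s4)   # 100
  expect_gt(pairwise_identity(seq_a, seq_b), 0.7)
  expect_gt(pairwise_identity(seq_b, seq_c), 0.7)
  expect_lt(pairwise_identity(seq_a, seq_c), 0.7)
  models <- list(
    make_model(make_straight(120), strsplit(seq_a, "")[[1]], id = "A"),
    make_model(make_straight(105), strsplit(seq_b, "")[[1]], id = "B"),
    make_model(make_straight(100), strsplit(seq_c, "")[[1]], id = "C"))
  reps <- identity_cluster(models, max_identity = 0.7)
  expect_equal(sort(vapply(reps, function(m) m$model_id, character(1))),
               c("A", "C"))
})
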