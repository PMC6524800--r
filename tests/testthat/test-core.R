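test_that("two identical structures merge into a full-length core", {
  xyz <- make_trace(45, seed = 41)
  aa <- strsplit(random_seq(45, 42), "")[[1]]
  a <- make_model(xyz, aa, id = "a")
  b <- make_model(xyz, aa, id = "b")
  root <- build_hierarchy(list(a, b))
  expect_equal(core_size(root_core(root)), 45L)
  expect_equal(root$merge_score, 45)
  expect_equal(core_average_rmsd(root_core(root)), 0)
})

test_that("merged cores keep exactly the matched columns", {
  xyz <- make_trace(100, seed = 43)
  a <- make_model(xyz, id = "a")
  b <- make_model(xyz[1:80, ], id = "b")
  sup <- structcore:::identity_superposition()
  m60 <- structcore:::new_equivalence_map(cbind(11:70, 11:70), sup, 60, 3.8)
  core <- merge_cores(m60, a, b)
  expect_equal(core_size(core), 60L)
  expect_equal(unname(core$columns[, "a"]), 11:70)
  expect_error(merge_cores(structcore:::empty_equivalence_map(3.8), a, b),
               "empty")
  # intersection bound: merging cores can never exceed the smaller child
  ca <- structcore:::leaf_core(make_model(xyz[1:80, ], id = "ca"))
  cb <- structcore:::leaf_core(make_model(xyz[1:75, ], id = "cb"))
  m70 <- structcore:::new_equivalence_map(cbind(1:70, 1:70), sup, 70, 3.8)
  merged <- merge_cores(m70, ca, cb)
  expect_equal(core_size(merged), 70L)
  expect_lte(core_size(merged), min(core_size(ca), core_size(cb)))
})

test_that("core size is non-increasing toward the root of the guide tree", {
  g <- small_clan(seed = 1)
  root <- build_hierarchy(g$models)
  gs <- guide_core_sizes(root)
  internal <- gs[!is.na(gs$parent_core_size), ]
  expect_true(all(internal$parent_core_size <= internal$core_size))
})

test_that("one family of three recovers the template core", {
  g <- generate_clan(synthetic_spec(
    n_families = 1, members_per_family = 3, core_length = 40,
    n_decorations = 1, member_sigma = 0.3, seed = 5))
  root <- build_hierarchy(g$models)
  core <- root_core(root)
  cr <- core_recovery_metrics(core, g$truth)
  expect_gte(cr["recall"], 0.9)
})

test_that("tight families merge within before across", {
  g <- generate_clan(synthetic_spec(
    n_families = 2, members_per_family = 2, core_length = 40,
    n_decorations = 1, member_sigma = 0.2, seed = 9))
  root <- build_hierarchy(g$models)
  fams <- lapply(root$children, function(ch) {
    unique(g$truth$family_label[colnames(root_core(ch)$columns)])
  })
  expect_equal(lengths(fams), c(1L, 1L))
  expect_setequal(unlist(fams), c("F01", "F02"))
})

test_that("the hierarchy is invariant to input order", {
  g <- small_clan(seed = 2, members = 3)
  ref <- build_hierarchy(g$models)
  ref_cols <- root_core(ref)$columns
  ref_nwk <- guide_tree_newick(ref)
  for (s in 1:10) {
    set.seed(s)
    shuffled <- g$models[sample(length(g$models))]
    root <- build_hierarchy(shuffled)
    expect_equal(root_core(root)$columns[, colnames(ref_cols)], ref_cols)
    expect_equal(guide_tree_newick(root), ref_nwk)
  }
})

test_that("every core column sits within d_cut of its representative", {
  p <- align_params()
  g <- small_clan(seed = 3)
  core <- root_core(build_hierarchy(g$models, p))
  for (id in core$members) {
    x <- core$member_data[[id]]$xyz[core$columns[, id], , drop = FALSE]
    fit <- apply_superposition(x, core$superpositions[[id]])
    d <- sqrt(rowSums((core$rep_xyz - fit)^2))
    expect_true(all(d <= p$d_cut + 1e-6))
  }
})

test_that("cores serialize as TSV (author numbering) and JSON", {
  g <- small_clan(seed = 5, members = 2)
  core <- root_core(build_hierarchy(g$models))
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_core_tsv(core, ft)
  tab <- read.delim(ft)
  expect_equal(nrow(tab), core_size(core))
  expect_equal(colnames(tab)[-1], core$members)
  id1 <- core$members[1]
  expect_equal(tab[[id1]],
               core$member_data[[id1]]$res_seq[core$columns[, id1]])
  fj <- withr::local_tempfile(fileext = ".json")
  write_core_json(core, fj)
  back <- jsonlite::read_json(fj)
  expect_equal(back$n_columns, core_size(core))
  expect_equal(unlist(back$members), core$members)
  R1 <- do.call(rbind, lapply(back$superpositions[[id1]]$rotation, unlist))
  expect_equal(R1, core$superpositions[[id1]]$rotation, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("orphan structures abort hierarchy construction by name", {
  g <- generate_clan(synthetic_spec(
    n_families = 1, members_per_family = 2, core_length = 40,
    n_decorations = 0, member_sigma = 0.2, seed = 13))
  rod <- make_model(make_straight(40), id = "zz_rod")
  expect_error(build_hierarchy(c(g$models, list(rod))), "zz_rod")
})

test_that("parameter_scan ranks by core size then rmsd and flags failures", {
  g <- generate_clan(synthetic_spec(
    n_families = 2, members_per_family = 2, core_length = 40,
    n_decorations = 1, member_sigma = 0.3, seed = 4))
  grid <- list(align_params(d_cut = 3.8),
               align_params(d_cut = 0.5),
               align_params(d_cut = 0.05))
  tab <- parameter_scan(g$models, grid)
  expect_equal(nrow(tab), 3L)
  first <- tab[tab$rank %in% 1L & !tab$failed, ]
  expect_equal(first$d_cut, 3.8)
  expect_true(any(tab$failed) || all(tab$core_size[tab$d_cut == 0.5] <
                                       tab$core_size[tab$d_cut == 3.8]))
  one <- parameter_scan(g$models[1:2], list(align_params()))
  expect_equal(one$rank, 1L)
})
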