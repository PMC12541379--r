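test_that("merge heights reproduce single-linkage joins on known configurations", {
  D <- line_distances(c(0, 5), c("a", "b"))
  h <- build_hierarchy(D)
  expect_equal(merge_heights(h), 5)

  h4 <- build_hierarchy(line_distances(c(0, 1, 2, 10)))
  expect_equal(merge_heights(h4), c(1, 1, 8))
  expect_error(build_hierarchy(matrix(0, 1, 1)), class = "phagempr_input_error")
})

test_that("merge heights equal the minimum-spanning-tree oracle on random instances", {
  set.seed(41)
  for (i in 1:12) {
    D <- random_distance_matrix(sample(5:60, 1))
    h <- build_hierarchy(D)
    expect_equal(merge_heights(h), oracle_single_linkage_heights(D),
                 tolerance = 1e-12)
  }
})

test_that("flat cuts equal connected components of the eps-threshold graph", {
  h <- build_hierarchy(line_distances(c(0, 1, 2, 10)))
  cl <- cut_at_eps(h, 1.5)
  expect_equal(cl$cluster, c(1L, 1L, 1L, NA))
  expect_equal(cl$is_noise, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(cl, "n_clusters"), 1L)

  all_one <- cut_at_eps(h, 8)
  expect_equal(attr(all_one, "n_clusters"), 1L)
  expect_false(any(all_one$is_noise))

  all_noise <- cut_at_eps(h, 0.5)
  expect_true(all(all_noise$is_noise))
  expect_equal(attr(all_noise, "n_clusters"), 0L)
  expect_error(cut_at_eps(h, -1), class = "phagempr_input_error")

  set.seed(42)
  for (i in 1:10) {
    D <- random_distance_matrix(sample(5:60, 1))
    hh <- build_hierarchy(D)
    for (eps in c(0, sample(D[upper.tri(D)], 3), runif(3, 0, max(D)))) {
      cl2 <- cut_at_eps(hh, eps)
      expect_true(same_partition(
        canonical_partition(cl2$cluster, cl2$is_noise),
        oracle_components(D, eps)
      ))
    }
  }
})

test_that("partitions coarsen monotonically in eps", {
  set.seed(43)
  for (i in 1:6) {
    D <- random_distance_matrix(sample(8:50, 1))
    h <- build_hierarchy(D)
    grid <- sort(runif(6, 0, max(D) * 1.1))
    parts <- lapply(grid, function(e) {
      cl <- cut_at_eps(h, e)
      canonical_partition(cl$cluster, cl$is_noise)
    })
    for (j in seq_len(length(parts) - 1L)) {
      expect_true(is_coarsening(parts[[j]], parts[[j + 1]]))
    }
  }
})

test_that("input order changes cluster ids but never the partition", {
  set.seed(44)
  D <- random_distance_matrix(25)
  h <- build_hierarchy(D)
  perm <- sample(25)
  hp <- build_hierarchy(D[perm, perm])
  eps <- stats::median(merge_heights(h))
  a <- cut_at_eps(h, eps)
  b <- cut_at_eps(hp, eps)
  b <- b[match(a$accession, b$accession), ]
  expect_equal(a$is_noise, b$is_noise)
  expect_true(same_partition(canonical_partition(a$cluster, a$is_noise),
                             canonical_partition(b$cluster, b$is_noise)))
})

test_that("hierarchy node tables describe a rooted tree with consistent sizes", {
  set.seed(45)
  D <- random_distance_matrix(15)
  h <- build_hierarchy(D)
  nodes <- tidy(h)
  expect_equal(nrow(nodes), 2L * 15L - 1L)
  expect_equal(sum(is.na(nodes$parent)), 1L)
  root <- nodes$node[is.na(nodes$parent)]
  expect_equal(nodes$n_leaves[nodes$node == root], 15L)
  expect_equal(glance(h)$n_merges, 14L)
})

test_that("branch extraction recovers a perfectly separated family exactly", {
  ds <- generate_dataset(family_separable_design())
  h <- build_hierarchy(pairwise_distances(ds$mpr))
  br <- extract_branch(h, ds$annotations, "family", "F01")
  expect_equal(br$precision, 1)
  expect_equal(br$recall, 1)
  expect_setequal(br$leaves,
                  ds$annotations$accession[ds$annotations$family == "F01"])
  expect_equal(br$n_other, 0L)
  expect_error(extract_branch(h, ds$annotations, "family", "F99"),
               class = "phagempr_input_error")
  expect_error(extract_branch(h, ds$annotations, "clade", "F01"),
               class = "phagempr_input_error")
})

test_that("branch extraction tolerates a small fraction of scrambled labels", {
  # F02 forms a single coherent clade on the default dataset (families can
  # legitimately split across branches, as F01 does here); scrambling 5% of
  # the annotations must not stop the branch from recovering the true clade
  ds <- generate_dataset(taxonomy_design(), annotation_noise = 0.05)
  h <- build_hierarchy(pairwise_distances(ds$mpr))
  br <- extract_branch(h, ds$annotations, "family", "F02")
  truth_set <- ds$truth$accession[ds$truth$family == "F02"]
  recall_vs_truth <- length(intersect(br$leaves, truth_set)) / length(truth_set)
  expect_gte(recall_vs_truth, 0.9)
})

test_that("hierarchies serialize to JSON with full node structure", {
  h <- build_hierarchy(line_distances(c(0, 1, 4)))
  path <- tempfile(fileext = ".json")
  write_hierarchy_json(h, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$n_leaves, 3L)
  expect_equal(nrow(parsed$nodes), 5L)
  expect_equal(parsed$min_pts, 2L)
})
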