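test_that("silhouettes match the defining formula on the two-tight-pairs fixture", {
  D <- two_pair_distances()
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  sil <- silhouette_scores(D, labels)
  expect_equal(sil$silhouette, rep(0.99, 4))
  expect_equal(attr(sil, "mean_silhouette"), 0.99)
})

test_that("singleton-cluster samples score zero and sentinels are excluded", {
  D <- line_distances(c(0, 1, 5), c("x", "y", "z"))
  sil <- silhouette_scores(D, c(x = "A", y = "A", z = "B"))
  expect_equal(sil$silhouette[sil$accession == "z"], 0)

  set.seed(51)
  D2 <- random_distance_matrix(12)
  labels <- setNames(rep(c("A", "B", "C"), each = 4), rownames(D2))
  base <- silhouette_scores(D2, labels)
  # append unclassified genomes: the evaluated scores must not move
  D3 <- random_distance_matrix(16)
  D3[1:12, 1:12] <- D2
  dimnames(D3) <- list(c(rownames(D2), sprintf("u%d", 1:4)),
                       c(rownames(D2), sprintf("u%d", 1:4)))
  labels3 <- setNames(c(labels, rep("unclassified", 4)), rownames(D3))
  with_unclassified <- silhouette_scores(D3, labels3)
  expect_equal(with_unclassified$silhouette, base$silhouette)
  expect_equal(nrow(with_unclassified), 12L)

  expect_error(silhouette_scores(D2, setNames(rep("A", 12), rownames(D2))),
               class = "phagempr_input_error")
})

test_that("silhouettes agree with a direct formula oracle on random data", {
  set.seed(52)
  D <- random_distance_matrix(20)
  labels <- setNames(sample(c("A", "B", "C"), 20, TRUE), rownames(D))
  sil <- silhouette_scores(D, labels)
  expect_equal(sil$silhouette, oracle_silhouette(D, unname(labels)),
               tolerance = 1e-12)
})

test_that("labels aligned with structure score higher than random labels", {
  ds <- generate_dataset(small_design(seed = 53))
  D <- pairwise_distances(ds$mpr)
  true_lab <- setNames(ds$truth$genus, ds$truth$accession)
  set.seed(54)
  rand_lab <- setNames(sample(ds$truth$genus), ds$truth$accession)
  s_true <- attr(silhouette_scores(D, true_lab), "mean_silhouette")
  s_rand <- attr(silhouette_scores(D, rand_lab), "mean_silhouette")
  expect_gt(s_true, s_rand)
})

test_that("AMI is 1 for identical partitions up to label permutation", {
  expect_equal(ami(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(ami(letters[1:5], letters[1:5]), 1)
  set.seed(55)
  x <- sample(1:4, 60, TRUE)
  relabel <- sample(4)
  expect_equal(ami(x, relabel[x]), 1)
  expect_error(ami(1:3, 1:4), class = "phagempr_input_error")
})

test_that("AMI matches the exact permutation-enumeration oracle", {
  a <- c(0, 0, 1, 1)
  b <- c(0, 1, 0, 1)
  emi <- oracle_emi_permutations(a, b)
  mi <- oracle_mi(a, b)
  expected <- (mi - emi) / ((oracle_entropy(a) + oracle_entropy(b)) / 2 - emi)
  expect_equal(ami(a, b), expected, tolerance = 1e-12)

  set.seed(56)
  for (i in 1:5) {
    a2 <- sample(1:2, 6, TRUE)
    b2 <- sample(1:3, 6, TRUE)
    if (length(unique(a2)) < 2 || length(unique(b2)) < 2) next
    emi2 <- oracle_emi_permutations(a2, b2)
    denom <- (oracle_entropy(a2) + oracle_entropy(b2)) / 2 - emi2
    if (abs(denom) < 1e-12) next
    expect_equal(ami(a2, b2), (oracle_mi(a2, b2) - emi2) / denom,
                 tolerance = 1e-12)
  }
})

test_that("AMI is permutation invariant and near zero for independent labels", {
  set.seed(57)
  vals <- replicate(30, {
    a <- sample(1:5, 120, TRUE)
    b <- sample(1:4, 120, TRUE)
    stopifnot(abs(ami(a, b) - ami(sample(5)[a], b)) < 1e-12)
    ami(a, b)
  })
  expect_lt(abs(mean(vals)), 0.05)
  expect_true(all(vals > -1 & vals < 1))
})

test_that("AMI profiles scan eps cuts with noise as singleton clusters", {
  ds <- generate_dataset(small_design(seed = 58))
  h <- build_hierarchy(pairwise_distances(ds$mpr))
  profile <- ami_vs_eps(h, ds$annotations, "genus")
  expect_equal(nrow(profile), 64L)
  expect_true(all(profile$ami >= -1 & profile$ami <= 1))
  expect_equal(attr(profile, "n_evaluated"), nrow(ds$mpr))

  # degenerate cuts carry no information about a multi-class labeling
  degenerate <- ami_vs_eps(h, ds$annotations, "genus",
                           eps_grid = c(0, max(merge_heights(h)) * 1.01))
  expect_lt(abs(degenerate$ami[1]), 0.05)   # everything noise
  expect_lt(abs(degenerate$ami[2]), 0.05)   # one all-encompassing cluster
  expect_error(ami_vs_eps(h, ds$annotations, "genus", eps_grid = numeric(0)),
               class = "phagempr_input_error")

  ann1 <- ds$annotations
  ann1$genus <- "G1"
  expect_error(ami_vs_eps(h, ann1, "genus"), class = "phagempr_input_error")
})

test_that("sentinel-labelled genomes do not affect the AMI profile", {
  ds <- generate_dataset(small_design(seed = 59))
  h <- build_hierarchy(pairwise_distances(ds$mpr))
  base <- ami_vs_eps(h, ds$annotations, "genus")
  ann <- ds$annotations
  ann$genus[1:4] <- "unclassified"
  masked <- ami_vs_eps(h, ann, "genus")
  expect_equal(attr(masked, "n_evaluated"), nrow(ds$mpr) - 4L)
  # same grid, values recomputed on the evaluated subset only
  expect_equal(masked$eps, base$eps)
})

test_that("threshold analysis separates a separable design perfectly", {
  ds <- generate_dataset(separable_design())
  D <- pairwise_distances(ds$mpr)
  rep <- threshold_analysis(D, ds$annotations, "genus", n_pairs = 2000, seed = 60)
  expect_equal(rep$tpr, 1.0)
  expect_equal(rep$fpr, 0.0)
  expect_gt(rep$best_threshold, max(rep$within_distances))
  expect_lt(rep$best_threshold, min(rep$between_distances))

  rep2 <- threshold_analysis(D, ds$annotations, "genus", n_pairs = 2000, seed = 60)
  expect_identical(glance(rep), glance(rep2))
})

test_that("threshold analysis finds no signal when labels are independent of distance", {
  set.seed(61)
  D <- random_distance_matrix(60)
  ann <- tibble::tibble(accession = rownames(D),
                        genus = sample(c("G1", "G2", "G3"), 60, TRUE))
  rep <- threshold_analysis(D, ann, "genus", n_pairs = 10000, seed = 62)
  expect_lt(abs(rep$youden), 0.1)

  one <- tibble::tibble(accession = rownames(D), genus = "G1")
  expect_error(threshold_analysis(D, one, "genus"), class = "phagempr_input_error")
})

test_that("atlas projection is deterministic, well-shaped and separation-preserving", {
  ds <- generate_dataset(separable_design(n_genomes_per_genus = 6L))
  at <- atlas_project(ds$mpr, n_neighbors = 8, min_dist = 0.5, seed = 63)
  expect_equal(dim(as.matrix(at[, c("x", "y")])), c(nrow(ds$mpr), 2L))
  at2 <- atlas_project(ds$mpr, n_neighbors = 8, min_dist = 0.5, seed = 63)
  expect_identical(at$x, at2$x)
  expect_identical(at$y, at2$y)

  xy <- as.matrix(at[, c("x", "y")])
  D2 <- as.matrix(dist(xy))
  fam <- ds$truth$family[match(at$accession, ds$truth$accession)]
  same <- outer(fam, fam, "==") & upper.tri(D2)
  diff_ <- outer(fam, fam, "!=") & upper.tri(D2)
  expect_lt(mean(D2[same]), mean(D2[diff_]))

  expect_error(atlas_project(ds$mpr[1:5, ], n_neighbors = 8),
               class = "phagempr_input_error")
})

test_that("result objects expose tidy/glance/autoplot interfaces", {
  ds <- generate_dataset(small_design(seed = 64))
  D <- pairwise_distances(ds$mpr)
  h <- build_hierarchy(D)
  profile <- ami_vs_eps(h, ds$annotations, "genus")
  expect_s3_class(autoplot(profile), "ggplot")
  rep <- threshold_analysis(D, ds$annotations, "genus", n_pairs = 500, seed = 65)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_equal(nrow(tidy(rep)), 1000L)
  at <- atlas_project(ds$mpr, n_neighbors = 5, seed = 66)
  expect_s3_class(autoplot(at, ds$annotations, "genus"), "ggplot")
})
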