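# IBS distances, clustering, MDS and K selection.

test_that("IBS distance is 0 for identical and 1 for opposite homozygotes", {
  d <- rbind(rep(0L, 20), rep(0L, 20), rep(2L, 20))
  x <- toy_geno(d, samples = c("a", "a2", "b"))
  D <- ibs_distance_matrix(x, min_maf = 0, seed = 3)
  expect_equal(D$d["a", "a2"], 0)
  expect_equal(D$d["a", "b"], 1)
  expect_true(isSymmetric(D$d))
  expect_equal(unname(diag(D$d)), rep(0, 3))
})

test_that("pairwise shared-site counts and mismatches match a direct recount", {
  # homozygous-only genotypes with missingness: allele sampling is
  # deterministic, so d must equal a brute-force mismatch recount
  set.seed(17)
  d <- matrix(sample(c(0L, 2L, NA), 5 * 50, replace = TRUE), 5, 50)
  x <- toy_geno(d)
  D <- ibs_distance_matrix(x, min_maf = 0, seed = 9)
  for (i in 1:4) for (j in (i + 1):5) {
    shared <- which(!is.na(d[i, ]) & !is.na(d[j, ]))
    expect_equal(D$n_shared_sites[i, j], length(shared))
    if (length(shared)) {
      expect_equal(D$d[i, j], mean(d[i, shared] != d[j, shared]))
    } else {
      expect_true(is.na(D$d[i, j]))
    }
  }
})

test_that("heterozygote sampling gives the binomial expectation", {
  d <- rbind(rep(0L, 10000), rep(1L, 10000))
  x <- toy_geno(d)
  ds <- vapply(1:50, function(s) ibs_distance_matrix(x, min_maf = 0,
                                                     seed = s)$d[1, 2], 0)
  expect_lt(abs(mean(ds) - 0.5), 0.02)
})

test_that("pairs sharing no sites are undefined and block clustering", {
  d <- rbind(c(0L, NA), c(NA, 2L), c(0L, 2L))
  x <- toy_geno(d)
  D <- ibs_distance_matrix(x, min_maf = 0, seed = 1)
  expect_true(is.na(D$d[1, 2]))
  expect_error(hierarchical_cluster(D), "filter")
})

test_that("hierarchical clustering recovers a hand-built topology", {
  dm <- matrix(c(0, 0.1, 0.4,
                 0.1, 0, 0.4,
                 0.4, 0.4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- hierarchical_cluster(dm)
  expect_equal(sort(cutree(tr$hclust, k = 2)[c("A", "B")]),
               c(A = 1L, B = 1L))
  expect_equal(unname(cutree(tr$hclust, k = 2)["C"]), 2L)
  expect_match(tr$newick, "^\\(")
  # duplicates (d = 0) merge first
  dm2 <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  tr2 <- hierarchical_cluster(dm2)
  expect_equal(tr2$hclust$height[1], 0)
})

test_that("classical MDS recovers planar configurations up to rotation", {
  set.seed(5)
  pts <- cbind(runif(12), runif(12))
  D <- as.matrix(dist(pts))
  fit <- classical_mds(D, n_axes = 2)
  # Procrustes alignment via SVD of the cross-product
  a <- scale(fit$coords, scale = FALSE)
  b <- scale(pts, scale = FALSE)
  sv <- svd(crossprod(b, a))
  rot <- sv$v %*% t(sv$u)
  expect_lt(sqrt(mean((a %*% rot - b)^2)), 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))

  zero <- matrix(0, 4, 4)
  fitz <- suppressWarnings(classical_mds(zero, n_axes = 2))
  expect_true(all(fitz$coords == 0))
})

test_that("BIC selects the generating number of clusters", {
  set.seed(11)
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  coords <- centers[rep(1:4, each = 10), ] + matrix(rnorm(120, sd = 1), 40, 3)
  sel <- select_k_bic(coords, k_range = 1:6, seed = 1)
  expect_equal(sel$selected_k, 4L)
  expect_equal(sel$table$k[which.min(sel$table$bic)], sel$selected_k)

  single <- matrix(rnorm(90), 30, 3)
  expect_equal(select_k_bic(single, k_range = 1:4, seed = 1)$selected_k, 1L)

  small <- matrix(rnorm(10), 5, 2)
  expect_warning(select_k_bic(small, k_range = c(2, 5, 6), seed = 1),
                 "skipping")
})

test_that("a structured island simulation clusters by deme", {
  ds <- simulate_island_model(island_model_config(
    n_demes = 4, deme_size = 150, migration_rate = 0.5 / 600, n_sites = 1200,
    n_generations = 900, sample_sizes = 6, seed = 71))
  D <- ibs_distance_matrix(ds$genotypes, min_maf = 0.01, seed = 1)
  tr <- hierarchical_cluster(D)
  groups <- cutree(tr$hclust, k = 4)
  labels <- ds$population_map$population[match(names(groups),
                                               ds$population_map$sample)]
  expect_equal(length(unique(paste(groups, labels))), 4L)
})
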