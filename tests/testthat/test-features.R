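test_that("compute_fc matches the Pearson definition and its invariances", {
  set.seed(11)
  ts <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("A", "B", "C")))
  fc <- compute_fc(ts)
  # term-by-term covariance-formula oracle
  for (i in 1:2) for (j in (i + 1):3) {
    x <- ts[, i]; y <- ts[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(fc[i, j], r, tolerance = 1e-12)
  }
  expect_equal(diag(unclass(fc)), c(A = 0, B = 0, C = 0))

  # identical and negated series hit the correlation bounds
  ts2 <- cbind(a = ts[, 1], b = ts[, 1], c = -ts[, 1] + rnorm(50, sd = 1e-8))
  fc2 <- compute_fc(ts2)
  expect_equal(fc2["a", "b"], 1)
  expect_lt(fc2["a", "c"], -0.999)

  # invariant to per-ROI affine rescaling
  ts3 <- sweep(sweep(ts, 2, c(2, 3, 0.5), "*"), 2, c(10, -4, 7), "+")
  expect_equal(unclass(compute_fc(ts3)), unclass(fc), tolerance = 1e-12)

  # degenerate series named in the error
  bad <- ts; bad[, 2] <- 5
  expect_error(compute_fc(bad), "zero-variance.*B")
})

test_that("clustering coefficients equal the exhaustive triple-enumeration oracle", {
  # unit-weight triangle scores exactly 1 everywhere
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(as.numeric(clustering_coefficients(as_fc_network(tri))), c(1, 1, 1))

  # path a-b-c: no closed triple anywhere
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(as.numeric(clustering_coefficients(as_fc_network(path))), c(0, 0, 0))

  for (s in 1:50) {
    d <- sample(4:12, 1)
    w <- random_fc(d, density = runif(1, 0.3, 0.9), seed = 1000 + s)
    got <- clustering_coefficients(as_fc_network(w))
    expect_equal(as.numeric(got), cc_oracle(w), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
  }
  # cube-root (geometric-mean) variant against its own oracle
  w <- abs(random_fc(8, seed = 7))
  expect_equal(as.numeric(clustering_coefficients(as_fc_network(w), geometric = TRUE)),
               cc_oracle(w, geometric = TRUE), tolerance = 1e-12)
})

test_that("unit-weight networks reduce to the binary clustering coefficient", {
  for (s in 1:10) {
    d <- sample(4:12, 1)
    set.seed(2000 + s)
    adj <- matrix(rbinom(d * d, 1, 0.5), d, d)
    adj[lower.tri(adj, diag = TRUE)] <- 0
    adj <- adj + t(adj)
    cc <- clustering_coefficients(as_fc_network(adj))
    # binary oracle: closed triples over k(k-1)/2
    for (i in seq_len(d)) {
      nbr <- which(adj[i, ] == 1)
      k <- length(nbr)
      expected <- 0
      if (k >= 2) {
        tri <- 0
        for (a in seq_len(k - 1)) for (b in (a + 1):k)
          tri <- tri + adj[nbr[a], nbr[b]]
        expected <- tri / (k * (k - 1) / 2)
      }
      expect_equal(as.numeric(cc[i]), expected, tolerance = 1e-12)
    }
  }
})

test_that("negative-weight handling and degenerate networks behave as documented", {
  w <- random_fc(6, seed = 3)
  cc_abs <- clustering_coefficients(as_fc_network(w), negative = "abs")
  cc_zero <- clustering_coefficients(as_fc_network(w), negative = "zero")
  expect_equal(as.numeric(cc_abs), cc_oracle(w, "abs"), tolerance = 1e-12)
  expect_equal(as.numeric(cc_zero), cc_oracle(w, "zero"), tolerance = 1e-12)

  empty <- matrix(0, 4, 4)
  expect_warning(cc <- clustering_coefficients(as_fc_network(empty)),
                 "all-zero")
  expect_equal(as.numeric(cc), rep(0, 4))
})

test_that("node-feature extraction equals per-voxel brute force", {
  # hand-computable case: label 1 on voxels {0.2, 0.4}, label 2 on {0.9}
  density <- array(0, c(2, 2, 1))
  atlas <- array(0L, c(2, 2, 1))
  density[1, 1, 1] <- 0.2; density[2, 1, 1] <- 0.4; density[1, 2, 1] <- 0.9
  atlas[1, 1, 1] <- 1L; atlas[2, 1, 1] <- 1L; atlas[1, 2, 1] <- 2L
  got <- extract_node_features(density, atlas, c(r1 = 1, r2 = 2))
  expect_equal(as.numeric(got), c(0.3, 0.9))
  expect_identical(attr(got, "modality"), "node")

  # constant density gives the constant for every region
  dens2 <- array(0.5, c(3, 3, 2))
  atl2 <- array(rep(1:2, length.out = 18), c(3, 3, 2))
  expect_equal(as.numeric(extract_node_features(dens2, atl2, c(a = 1, b = 2))),
               c(0.5, 0.5))

  # random volumes vs voxel-loop oracle
  for (s in 1:5) {
    set.seed(300 + s)
    dims <- c(4, 3, 3)
    atl <- array(sample(0:3, prod(dims), replace = TRUE), dims)
    if (!all(1:3 %in% atl)) next
    dens <- array(rnorm(prod(dims)), dims)
    got <- extract_node_features(dens, atl, c(x = 1, y = 2, z = 3))
    oracle <- sapply(1:3, function(l) {
      tot <- 0; n <- 0
      for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
        if (atl[i, j, k] == l) { tot <- tot + dens[i, j, k]; n <- n + 1 }
      tot / n
    })
    expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  }

  expect_error(extract_node_features(array(0, c(2, 2, 2)), array(0L, c(2, 2, 3)),
                                     c(a = 1)), "dimensions")
  expect_error(extract_node_features(dens2, atl2, c(a = 1, ghost = 9)),
               "ghost")
})

test_that("group-mean FC and top-k edge reports are exact", {
  w1 <- random_fc(6, seed = 21); w2 <- random_fc(6, seed = 22)
  nets <- list(as_fc_network(w1), as_fc_network(w2))
  avg <- group_mean_fc(nets)
  expect_equal(unclass(avg), (w1 + w2) / 2, tolerance = 1e-15)
  expect_equal(unclass(group_mean_fc(nets[1])), w1)
  expect_equal(max(abs(group_mean_fc(list(as_fc_network(w1),
                                          as_fc_network(-w1))))), 0)
  expect_error(group_mean_fc(list()), "empty")

  # star: highest-weight partners in order
  st <- matrix(0, 4, 4,
               dimnames = list(c("c", "p1", "p2", "p3"), c("c", "p1", "p2", "p3")))
  st["c", "p1"] <- st["p1", "c"] <- 0.9
  st["c", "p2"] <- st["p2", "c"] <- 0.5
  st["c", "p3"] <- st["p3", "c"] <- 0.1
  te <- top_k_edges(as_fc_network(st), "c", 2)
  expect_equal(te$partner, c("p1", "p2"))
  expect_equal(te$weight, c(0.9, 0.5))

  # k = d - 1 returns the full sorted incident list; sort-all oracle at k = 7
  w <- random_fc(10, density = 1, seed = 30)
  full <- top_k_edges(as_fc_network(w), "R3", 9)
  expect_setequal(full$partner, setdiff(rownames(w), "R3"))
  expect_false(is.unsorted(rev(full$weight)))
  inc <- sort(w["R3", -3], decreasing = TRUE)[1:7]
  expect_equal(top_k_edges(as_fc_network(w), "R3", 7)$weight, unname(inc))
  expect_error(top_k_edges(as_fc_network(w), "nope", 2), "unknown ROI")
})

test_that("NIfTI volume input reproduces the in-memory extraction", {
  skip_if_not_installed("RNifti")
  tmp <- withr::local_tempdir()
  vol <- simulate_atlas_volume(4, voxels_per_region = 27, noise_sd = 0.02,
                               seed = 17)
  dpath <- file.path(tmp, "density.nii")
  apath <- file.path(tmp, "atlas.nii")
  lpath <- file.path(tmp, "labels.tsv")
  RNifti::writeNifti(RNifti::asNifti(vol$density), dpath)
  RNifti::writeNifti(RNifti::asNifti(vol$atlas * 1), apath)
  write.table(vol$label_map, lpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  got <- node_features_from_nifti(dpath, apath, lpath)
  ref <- extract_node_features(vol$density, vol$atlas,
                               vol$label_map[, c("label", "roi")])
  expect_equal(got, ref, tolerance = 1e-6)
})
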