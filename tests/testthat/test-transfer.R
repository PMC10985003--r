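same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

test_that("transfer_loadings shares its kernel with update_b exactly", {
  set.seed(20)
  Z <- matrix(abs(rnorm(40)), 10, 4,
              dimnames = list(paste0("f", 1:10), paste0("LV", 1:4)))
  D <- matrix(rnorm(30), 10, 3, dimnames = list(rownames(Z), paste0("s", 1:3)))
  tl <- transfer_loadings(D, Z, lambda2 = 0.3)
  expect_identical(unname(tl$B), unname(update_b(D, Z, 0.3)))
})

test_that("transfer recovers the generating loadings in the small-ridge limit", {
  set.seed(21)
  Z <- matrix(abs(rnorm(36)), 12, 3,
              dimnames = list(paste0("f", 1:12), NULL))
  Btrue <- matrix(rnorm(15), 3, 5)
  tl <- transfer_loadings(Z %*% Btrue, Z, lambda2 = 1e-10)
  expect_equal(unname(tl$B), Btrue, tolerance = 1e-6)
})

test_that("single-sample transfers match a per-column linear-solve oracle", {
  set.seed(22)
  Z <- matrix(abs(rnorm(36)), 12, 3, dimnames = list(paste0("f", 1:12), NULL))
  d <- matrix(rnorm(12), 12, 1, dimnames = list(rownames(Z), "only"))
  tl <- transfer_loadings(d, Z, lambda2 = 0.4)
  oracle <- solve(crossprod(Z) + 0.4 * diag(3), crossprod(Z, d))
  expect_equal(unname(tl$B), unname(oracle), tolerance = 1e-10)
})

test_that("sample permutation permutes loadings and feature mismatch errors", {
  set.seed(23)
  Z <- matrix(abs(rnorm(40)), 10, 4, dimnames = list(paste0("f", 1:10), NULL))
  D <- matrix(rnorm(60), 10, 6,
              dimnames = list(rownames(Z), paste0("s", 1:6)))
  perm <- c(4, 1, 6, 2, 5, 3)
  t1 <- transfer_loadings(D, Z, lambda2 = 0.2)
  t2 <- transfer_loadings(D[, perm], Z, lambda2 = 0.2)
  expect_equal(t2$B, t1$B[, perm])

  D_bad <- D; rownames(D_bad)[2] <- "zzz"
  expect_error(transfer_loadings(D_bad, Z, lambda2 = 0.2), "f2")
})

test_that("model-based transfer standardizes new data with training parameters", {
  inst <- realizable_instance(seed = 24)
  D <- inst$D + matrix(rnorm(length(inst$D), sd = 0.05), nrow(inst$D))
  fit <- plier_fit(D, inst$C, k = 3, seed = 1, max_iter = 60)
  tl <- transfer_loadings(D, fit)
  Ds <- (D - fit$row_center) / fit$row_scale
  expect_equal(unname(tl$B), unname(update_b(Ds[rownames(fit$Z), ], fit$Z, fit$lambda2)),
               tolerance = 1e-12)
  expect_equal(tl$lambda2, fit$lambda2)
})

test_that("Ward clustering separates well-separated blobs and is order-invariant", {
  set.seed(25)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  rownames(X) <- paste0("s", 1:40)
  truth <- rep(1:2, each = 20)
  cl <- hca_clusters(X, 2)
  expect_true(same_partition(cl$cluster, truth))

  perm <- sample(40)
  cl2 <- hca_clusters(X[perm, ], 2)
  expect_true(same_partition(cl2$cluster, truth[perm]))

  expect_error(hca_clusters(rbind(X, X[1, , drop = FALSE]), 2), "duplicate")
})

test_that("Ward merges follow the exhaustive Lance-Williams oracle on 6 points", {
  X <- matrix(c(0, 0, 0.4, 0, 5, 0, 5.5, 0, 20, 0, 20.3, 0), ncol = 2,
              byrow = TRUE)
  rownames(X) <- paste0("p", 1:6)

  # oracle: brute-force Ward agglomeration on squared-Euclidean cost
  ward_oracle <- function(X) {
    clusters <- lapply(seq_len(nrow(X)), identity)
    heights <- numeric(0)
    cost <- function(a, b) {
      na <- length(a); nb <- length(b)
      ca <- colMeans(X[a, , drop = FALSE]); cb <- colMeans(X[b, , drop = FALSE])
      na * nb / (na + nb) * sum((ca - cb)^2)
    }
    while (length(clusters) > 1) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
        d <- cost(clusters[[i]], clusters[[j]])
        if (d < best[1]) best <- c(d, j, i)
      }
      heights <- c(heights, sqrt(2 * best[1]))   # ward.D2 height convention
      merged <- c(clusters[[best[2]]], clusters[[best[3]]])
      clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    }
    heights
  }
  cl <- hca_clusters(X, 2)
  tree <- attr(cl, "tree")
  expect_equal(sort(tree$height), sort(ward_oracle(X)), tolerance = 1e-10)
  expect_true(same_partition(cl$cluster, c(1, 1, 1, 1, 2, 2)))
})

test_that("k-means matches the exhaustive best 2-partition on small data", {
  expect_equal(unique(kmeans_clusters(matrix(rnorm(10), 5, 2), 1)$cluster), 1L)

  set.seed(26)
  X <- rbind(matrix(rnorm(10, 0, 0.3), 5, 2), matrix(rnorm(10, 4, 0.3), 5, 2))
  rownames(X) <- paste0("s", 1:10)
  km <- kmeans_clusters(X, 2, seed = 3)

  # oracle: enumerate all 2-partitions of 10 points
  best_ss <- Inf
  for (mask in 1:(2^9)) {
    lab <- as.integer(intToBits(mask))[1:10]
    if (length(unique(lab)) < 2) next
    ss <- sum(vapply(0:1, function(g) {
      pts <- X[lab == g, , drop = FALSE]
      sum(scale(pts, scale = FALSE)^2)
    }, numeric(1)))
    best_ss <- min(best_ss, ss)
  }
  expect_equal(attr(km, "tot_withinss"), best_ss, tolerance = 1e-8)
})

test_that("UMAP keeps duplicated samples together and separates distant blobs", {
  set.seed(27)
  X <- rbind(matrix(rnorm(200, 0, 0.5), 25, 8), matrix(rnorm(200, 10, 0.5), 25, 8))
  rownames(X) <- paste0("s", 1:50)
  X[2, ] <- X[1, ]                       # exact duplicate pair
  emb <- umap_embed(X, seed = 11)
  co <- as.matrix(emb[, c("UMAP1", "UMAP2")])
  expect_true(all(is.finite(co)))
  scale_of <- max(dist(co))
  # duplicates end SGD essentially coincident relative to the embedding span
  expect_lt(sqrt(sum((co[1, ] - co[2, ])^2)), scale_of / 20)

  sil <- cluster::silhouette(rep(1:2, each = 25), dist(co))
  expect_gt(mean(sil[, 3]), 0.5)

  expect_error(umap_embed(X[1:10, ], n_neighbors = 15), "lower n_neighbors")
})
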