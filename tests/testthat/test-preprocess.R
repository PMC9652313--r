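test_that("log-normalisation follows the stated formula and is local", {
  m <- rbind(c(10, 0), c(3, 7))
  out <- normalize_log1p(m, scale = 1e4)
  expect_equal(out[1, ], c(log(10001), 0))
  # locality: a cell's row depends only on that cell
  m2 <- rbind(c(10, 0), c(999, 1))
  expect_equal(normalize_log1p(m2, 1e4)[1, ], out[1, ])

  expect_warning(out0 <- normalize_log1p(rbind(c(0, 0), c(1, 1))), "zero")
  expect_equal(out0[1, ], c(0, 0))
})

test_that("normalisation inverts algebraically", {
  tab <- toy_table(30, 50, seed = 2)
  out <- normalize_log1p(tab, scale = 1e4)
  totals <- rowSums(tab$counts)
  rec <- expm1(out) * totals / 1e4
  expect_lt(max(abs(rec - tab$counts)), 1e-9)
})

test_that("variable-gene selection ranks dispersion and handles edges", {
  set.seed(1)
  norm <- cbind(matrix(rnorm(200, 5, 0.2), 50), matrix(rnorm(200, 5, 3), 50),
                matrix(5, 50, 2))
  colnames(norm) <- sprintf("g%02d", 1:10)
  top <- select_hvg(norm, 4)
  expect_setequal(names(top), sprintf("g%02d", 5:8))
  # constant genes rank last
  all10 <- select_hvg(norm, 10)
  expect_setequal(names(all10)[9:10], c("g09", "g10"))
  expect_setequal(as.integer(all10), 1:10)
  expect_error(select_hvg(norm, 0), "positive")
  expect_error(select_hvg(norm, 11), "exceeds")
})

test_that("a planted high-variance block lands in the selection", {
  hits <- 0
  for (s in 1:10) {
    d <- sim_design(species = "human", shared_subtypes = c("T1", "T2"),
                    specific_subtypes = list(), n_genes = 500,
                    cells_per_subtype = 150, n_markers = 20,
                    module_sizes = integer(0), module_lambda = numeric(0),
                    regulons = list(), seed = s)
    sim <- simulate_species(d)
    norm <- normalize_log1p(sim$tables$human)
    top <- names(select_hvg(norm, 150))
    mk <- sim$truth$markers$gene
    if (mean(mk %in% top) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("PCA embedding matches a truncated SVD and is deterministic", {
  set.seed(3)
  x <- matrix(rnorm(600), 30, 20)
  colnames(x) <- sprintf("g%02d", 1:20)
  emb <- pca_embed(x, 5)
  # independent oracle: svd of the scaled matrix
  s <- scale(x)
  sv <- svd(s)
  recon_pkg <- sum((s - emb$coords %*% t(emb$rotation))^2)
  recon_svd <- sum((s - sv$u[, 1:5] %*% diag(sv$d[1:5]) %*% t(sv$v[, 1:5]))^2)
  expect_lt(abs(recon_pkg - recon_svd), 1e-8)
  # deterministic sign: largest-magnitude loading is positive
  for (j in 1:5) {
    l <- emb$rotation[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_equal(pca_embed(x, 5)$coords, emb$coords)

  # rank-1 data: first component carries >= 99.9% of the variance
  r1 <- outer(rnorm(30), rnorm(20)) + 1e-6 * matrix(rnorm(600), 30)
  colnames(r1) <- colnames(x)
  e1 <- pca_embed(r1, 5)
  expect_gt(e1$sdev[1]^2 / sum(e1$sdev^2), 0.999)

  # identical cells embed identically
  xx <- x[c(1, 1, 2:29), ]
  e2 <- pca_embed(xx, 3)
  expect_equal(e2$coords[1, ], e2$coords[2, ])

  expect_error(pca_embed(x, 0), "between")
  expect_error(pca_embed(x, 21), "between")
})

test_that("mutual-nearest-neighbor anchors are symmetric", {
  set.seed(4)
  xa <- matrix(rnorm(100), 20, 5)
  xb <- matrix(rnorm(120), 24, 5)
  ab <- anchor_pairs(xa, xb, k = 4)
  ba <- anchor_pairs(xb, xa, k = 4)
  expect_setequal(paste(ab[, 1], ab[, 2]), paste(ba[, 2], ba[, 1]))
  expect_gt(nrow(ab), 0)
})

test_that("anchor shift is translation-equivariant", {
  set.seed(5)
  q <- matrix(rnorm(60), 20, 3)
  r <- matrix(rnorm(60), 20, 3) + 1
  a <- anchor_pairs(q, r, 3)
  shifted <- crossneuro:::apply_anchor_shift(q + 2, r + 2, a)
  base <- crossneuro:::apply_anchor_shift(q, r, a)
  expect_equal(shifted, base + 2, tolerance = 1e-12)
})

test_that("anchor correction is exact on an identical query", {
  tab <- toy_table(40, 60, seed = 6)
  n1 <- normalize_log1p(tab)
  n2 <- n1
  rownames(n2) <- paste0("q_", rownames(n1))
  cc <- anchor_correct(n1, n2, d = 10, k_anchor = 5)
  disp <- cc$coords[cc$query_idx, ] - cc$coords[cc$ref_idx, ]
  expect_lt(mean(sqrt(rowSums(disp^2))), 1e-6)
})

test_that("anchor correction removes a planted batch shift", {
  set.seed(7)
  base <- matrix(rnorm(200 * 40), 200, 40)
  colnames(base) <- sprintf("g%02d", 1:40)
  rownames(base) <- sprintf("r%03d", 1:200)
  shift <- rnorm(40, mean = 0, sd = 0.5)
  query <- base[sample(200), ] + rep(shift, each = 200)
  rownames(query) <- paste0("q", rownames(query))
  cc <- anchor_correct(base, query, d = 10, k_anchor = 5)
  post <- sqrt(sum((colMeans(cc$coords[cc$ref_idx, ]) -
                      colMeans(cc$coords[cc$query_idx, ]))^2))
  # pre-correction separation measured in the same kind of space: a joint
  # PCA of the uncorrected data
  raw <- pca_embed(rbind(base, query), 10)$coords
  pre <- sqrt(sum((colMeans(raw[1:200, ]) - colMeans(raw[201:400, ]))^2))
  expect_lt(post, 0.1 * pre)
})

test_that("within-dataset batch merge shrinks batch separation", {
  set.seed(8)
  base <- matrix(rnorm(120 * 30), 120, 30)
  colnames(base) <- sprintf("g%02d", 1:30)
  batches <- rep(c("b1", "b2"), each = 60)
  x <- base
  x[batches == "b2", ] <- x[batches == "b2", ] +
    rep(rnorm(30, 0, 0.5), each = 60)
  pre <- sqrt(sum((colMeans(x[batches == "b1", ]) -
                     colMeans(x[batches == "b2", ]))^2))
  out <- correct_batches(x, batches, d = 10, k_anchor = 5)
  post <- sqrt(sum((colMeans(out[batches == "b1", ]) -
                      colMeans(out[batches == "b2", ]))^2))
  # a single pre-conditioning pass removes a substantial part of the shift;
  # the cross-dataset anchor correction finishes the job
  expect_lt(post, 0.6 * pre)
  # single batch is a no-op
  expect_equal(correct_batches(x, rep("b1", 120)), x)
})

test_that("clustering recovers separated blobs and is deterministic", {
  ok <- 0
  for (s in 1:5) {
    set.seed(s)
    centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
    truth <- rep(1:3, each = 40)
    coords <- centers[truth, ] + matrix(rnorm(240, sd = 0.5), 120, 2)
    cl <- cluster_cells(coords, target_k = 3, seed = s)
    if (ari(cl$labels, truth) == 1) ok <- ok + 1
    expect_equal(cluster_cells(coords, target_k = 3, seed = s)$labels,
                 cl$labels)
  }
  expect_gte(ok, 4)
  expect_error(cluster_cells(matrix(rnorm(20), 10, 2), target_k = 11),
               "cannot form")
})

test_that("default clustering reaches 31 clusters on 500+ cells", {
  set.seed(9)
  coords <- matrix(rnorm(550 * 10), 550, 10)
  cl <- cluster_cells(coords, seed = 1)
  expect_gte(cl$k, 31)
})
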