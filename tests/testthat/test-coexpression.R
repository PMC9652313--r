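test_that("pseudocell partition follows the size rule exactly", {
  tab <- toy_table(n_cells = 34, n_genes = 10, seed = 1,
                   subtypes = c(rep("A", 25), rep("B", 9)),
                   batches = "b1", condition = FALSE)
  pm <- make_pseudocells(tab, size = 10, seed = 1)
  # 25-cell stratum -> 2 pseudocells (5 dropped); 9-cell stratum -> none
  expect_equal(nrow(pm$values), 2)
  expect_true(all(pm$subtype == "A"))

  tab9 <- subset_cells(tab, which(tab$annot$subtype == "B"))
  expect_error(make_pseudocells(tab9, size = 10), "no stratum")
})

test_that("pseudocells are stratum means of normalised expression", {
  tab <- toy_table(n_cells = 40, n_genes = 8, seed = 2, subtypes = "A",
                   batches = "b1", condition = FALSE)
  # plant a constant gene on the normalised scale by fixing totals
  counts <- matrix(5L, 40, 8)
  counts[, 2] <- 10L
  colnames(counts) <- tab$gene_ids
  tab2 <- cell_table(counts, tab$annot)
  pm <- make_pseudocells(tab2, size = 10, seed = 3)
  expect_equal(nrow(pm$values), 4)
  norm1 <- normalize_log1p(tab2)[1, 1]
  expect_true(all(abs(pm$values[, 1] - norm1) < 1e-12))
})

test_that("pseudocells never mix strata", {
  tab <- toy_table(n_cells = 60, n_genes = 5, seed = 3,
                   subtypes = c("A", "B"), batches = c("b1", "b2"))
  pm <- make_pseudocells(tab, size = 5, seed = 1)
  expect_true(all(paste(pm$subtype, pm$condition, pm$batch) %in%
                    paste(tab$annot$subtype, tab$annot$condition,
                          tab$annot$batch)))
  counts <- table(paste(tab$annot$subtype, tab$annot$condition,
                        tab$annot$batch))
  expected <- sum(counts %/% 5)
  expect_equal(nrow(pm$values), expected)
})

test_that("MAD filtering matches the direct formula", {
  m <- cbind(rep(3, 10), rep(c(0, 1), 5), rnorm(10))
  colnames(m) <- c("const", "alt", "noisy")
  kept <- mad_filter(m, threshold = 0.1)
  expect_false("const" %in% kept)
  expect_true("alt" %in% kept)
  # direct formula: median |x - median| * constant
  alt_mad <- stats::median(abs(m[, "alt"] - stats::median(m[, "alt"]))) * 1.4826
  expect_equal(unname(stats::mad(m[, "alt"])), alt_mad)
  expect_equal(alt_mad, 0.5 * 1.4826)
  # raw variant and zero threshold
  expect_length(mad_filter(m, threshold = 0), 3)
  expect_false("const" %in% mad_filter(m, threshold = 0.1, constant = 1))
})

test_that("co-expression gene universe is the union-intersect rule", {
  set.seed(4)
  norm <- matrix(rnorm(50 * 30, sd = rep(seq(0.1, 3, length.out = 30),
                                         each = 50)), 50, 30)
  colnames(norm) <- sprintf("g%02d", 1:30)
  top <- names(select_hvg(norm, 10))
  expect_setequal(select_wgcna_genes(norm, norm, n = 10), top)
  other <- norm
  colnames(other) <- sprintf("h%02d", 1:30)
  expect_error(select_wgcna_genes(norm, other, 10), "share no genes")
})

test_that("topological overlap reproduces the worked 3-gene example", {
  a <- rbind(c(0, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0))
  tom <- tom_from_adjacency(a)
  expect_equal(tom[1, 3], 1 / 6)
  expect_equal(tom[1, 2], (0 + 0.5) / (min(0.5, 1) + 1 - 0.5))
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1))
  # isolated pair: no adjacency, no shared neighbors -> 0
  iso <- diag(0, 4)
  iso[1, 2] <- iso[2, 1] <- 0.9
  expect_equal(tom_from_adjacency(iso)[3, 4], 0)
})

test_that("TOM entries stay in [0,1] on random adjacencies", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_from_adjacency(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("planted modules are recovered and labelled by size", {
  pm <- planted_module_matrix(n_samples = 120, module_sizes = c(20, 14),
                              n_noise = 9, lambda = 2, seed = 6)
  fit <- tom_modules(pm$values, power = 6, min_module_size = 10)
  got <- fit$modules[pm$truth != "noise"]
  expect_equal(ari(got, pm$truth[pm$truth != "noise"]), 1)
  # labels ordered by module size
  expect_equal(unname(table(fit$modules)[["M1"]]), 20)
  # noise genes stay out of modules (an occasional in-sample correlation
  # can rescue at most a stray one)
  expect_gte(mean(fit$modules[pm$truth == "noise"] == "unassigned"), 8 / 9)
  expect_equal(nrow(fit$eigengenes), 2)
})

test_that("modules driven by one latent factor merge", {
  pm <- planted_module_matrix(n_samples = 120, module_sizes = c(15, 15),
                              n_noise = 0, lambda = 2, seed = 7,
                              shared_factor = TRUE)
  fit <- tom_modules(pm$values, power = 6, min_module_size = 10,
                     merge_cut_height = 0.25)
  mods <- setdiff(unique(fit$modules), "unassigned")
  expect_length(mods, 1)
  expect_error(tom_modules(matrix(1, 30, 12)), "constant")
})

test_that("module cell-type profiles are standardised per module", {
  tab <- toy_table(n_cells = 60, n_genes = 12, seed = 8,
                   subtypes = c("A", "B", "C"))
  labels <- stats::setNames(rep(c("M1", "M2", "unassigned"), each = 4),
                            tab$gene_ids)
  prof <- module_celltype_profile(labels, tab)
  expect_equal(dim(prof), c(2L, 3L))
  expect_lt(max(abs(rowMeans(prof))), 1e-12)
  expect_equal(unname(apply(prof, 1, stats::sd)), rep(1, 2))
  # single-gene module equals that gene's scaled cell-type means
  one <- stats::setNames(c("M1", rep("unassigned", 11)), tab$gene_ids)
  prof1 <- module_celltype_profile(one, tab)
  norm <- normalize_log1p(tab)
  means <- vapply(c("A", "B", "C"), function(s)
    mean(norm[tab$annot$subtype == s, 1]), numeric(1))
  expect_equal(unname(prof1[1, ]), unname(as.vector(scale(means))))
})
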