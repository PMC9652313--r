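test_that("subtype subsampling keeps small subtypes whole", {
  tab <- toy_table(n_cells = 290, n_genes = 20, seed = 1,
                   subtypes = c(rep("big", 25), rep("small", 4)))
  sub <- subsample_subtypes(tab, n = 100, seed = 1)
  counts <- table(sub$annot$subtype)
  expect_equal(as.integer(counts["big"]), 100L)
  expect_equal(as.integer(counts["small"]), 40L)
  expect_equal(subsample_subtypes(tab, 100, seed = 1)$cell_ids, sub$cell_ids)
  expect_false(identical(subsample_subtypes(tab, 100, seed = 2)$cell_ids,
                         sub$cell_ids))
})

test_that("overlap score follows its closed forms", {
  p <- c(a = 0.3, b = 0.7)
  expect_equal(overlap_score(p, p), 1.0)
  expect_equal(overlap_score(c(a = 1), c(b = 1)), 0.0)
  expect_equal(overlap_score(c(a = 0.5, b = 0.5, c = 0),
                             c(a = 0.5, b = 0, c = 0.5)), 0.5)
  expect_error(overlap_score(c(a = 0.5, b = 0.6), p), "probability")
  expect_error(overlap_score(c(a = -0.1, b = 1.1), p), "probability")
})

test_that("overlap equals one minus total variation on random pairs", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    pa <- rgamma(k, 1); pa <- pa / sum(pa)
    pb <- rgamma(k, 1); pb <- pb / sum(pb)
    names(pa) <- names(pb) <- paste0("c", seq_len(k))
    l1 <- 1 - 0.5 * sum(abs(pa - pb))
    expect_lt(abs(overlap_score(pa, pb) - l1), 1e-12)
    expect_lt(abs(overlap_score(pa, pb) - overlap_score(pb, pa)), 1e-15)
  }
})

test_that("subtype distributions are proper and respect the universe", {
  labels <- c(1, 1, 2, 3, 3, 3)
  p <- subtype_distribution(labels, 1:6, universe = 1:4)
  expect_equal(sum(p), 1)
  expect_equal(unname(p), c(2, 1, 3, 0) / 6)
  expect_error(subtype_distribution(labels, integer(0)), "no cells")
})

test_that("conservation matrix is invariant to cluster relabeling", {
  set.seed(2)
  n <- 120
  annot <- data.frame(species = rep(c("human", "mouse"), each = n / 2),
                      subtype = rep(rep(c("A", "B"), each = n / 4), 2))
  labels <- sample(1:6, n, replace = TRUE)
  m1 <- conservation_matrix(labels, annot, "mouse", "human")
  perm <- sample(1:6)
  m2 <- conservation_matrix(perm[labels], annot, "mouse", "human")
  expect_equal(m1, m2)
  expect_true(all(m1 >= 0 & m1 <= 1))
})

test_that("a dataset against its own copy is maximally conserved", {
  set.seed(3)
  n <- 100
  annot1 <- data.frame(species = "A", subtype = rep(c("x", "y"), each = n / 2))
  labels <- sample(1:5, n, replace = TRUE)
  annot <- rbind(annot1, transform(annot1, species = "B"))
  m <- conservation_matrix(c(labels, labels), annot, "B", "A")
  expect_true(all(diag(m) >= 0.9))
  expect_equal(diag(m), c(x = 1, y = 1))
})

test_that("missing species and misaligned inputs are reported", {
  annot <- data.frame(species = c("A", "B"), subtype = c("x", "y"))
  expect_error(conservation_matrix(c(1, 2), annot, "C", "A"), "no cells")
  expect_error(conservation_matrix(c(1, 2, 3), annot, "B", "A"),
               "not aligned")
})

test_that("inhibitory extraction keeps marker-positive cells", {
  counts <- rbind(c(0, 0, 5), c(2, 0, 5), c(0, 3, 5))
  colnames(counts) <- c("GAD1", "GAD2", "other")
  annot <- data.frame(cell_id = c("c1", "c2", "c3"), species = "h",
                      batch = "b", subtype = "s")
  tab <- cell_table(counts, annot)
  kept <- extract_inhibitory(tab)
  expect_setequal(kept$cell_ids, c("c2", "c3"))
  expect_error(extract_inhibitory(tab, markers = c("NOPE")), "marker")
})

test_that("planted inhibitory fraction is recovered", {
  d <- sim_design(species = "human",
                  shared_subtypes = c("I1", "I2", "E1", "E2", "E3"),
                  specific_subtypes = list(),
                  inhibitory_subtypes = c("I1", "I2"),
                  cells_per_subtype = 200, n_genes = 600, n_markers = 10,
                  module_sizes = integer(0), module_lambda = numeric(0),
                  regulons = list(), seed = 4)
  sim <- simulate_species(d)
  kept <- extract_inhibitory(sim$tables$human)
  expect_lt(abs(n_cells(kept) / 1000 - 0.4), 0.05)
  expect_gt(mean(kept$annot$subtype %in% c("I1", "I2")), 0.95)
})

test_that("subtype correlation matches the textbook formula", {
  counts <- rbind(c(1, 5, 2, 8, 3), c(1, 5, 2, 8, 3),   # subtype A
                  c(9, 2, 7, 1, 4), c(9, 2, 7, 1, 4),   # subtype B
                  c(2, 2, 9, 1, 7), c(4, 2, 7, 3, 7))   # subtype C
  annot <- data.frame(cell_id = paste0("c", 1:6), species = "h", batch = "b",
                      subtype = rep(c("A", "B", "C"), each = 2))
  colnames(counts) <- paste0("g", 1:5)
  tab <- cell_table(counts, annot)
  r <- subtype_correlation(tab)
  norm <- normalize_log1p(tab)
  manual_cor <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  ma <- colMeans(norm[1:2, ]); mb <- colMeans(norm[3:4, ])
  expect_lt(abs(r["A", "B"] - manual_cor(ma, mb)), 1e-12)
  expect_equal(r["A", "A"], 1)
  expect_equal(r, t(r))
})

test_that("identical and degenerate subtypes are handled", {
  counts <- rbind(c(1, 5, 2), c(1, 5, 2), c(3, 3, 3), c(3, 3, 3))
  colnames(counts) <- paste0("g", 1:3)
  annot <- data.frame(cell_id = paste0("c", 1:4), species = "h", batch = "b",
                      subtype = rep(c("A", "B"), each = 2))
  tab <- cell_table(counts, annot)
  expect_warning(r <- subtype_correlation(tab), "zero-variance")
  expect_true(is.na(r["A", "B"]))
  # two identical subtypes correlate exactly
  annot$subtype <- rep(c("A", "B"), 2)
  tab2 <- cell_table(rbind(counts[1, ], counts[1, ], counts[2, ], counts[2, ]),
                     annot, gene_ids = paste0("g", 1:3))
  expect_equal(subtype_correlation(tab2)["A", "B"], 1)
  expect_error(subtype_correlation(subset_cells(tab, 1:2)), "two subtypes")
})
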