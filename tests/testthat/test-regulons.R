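test_that("activity score matches brute-force recovery-curve integration", {
  # 10-gene toy cell, 3 targets, top fraction 0.5 (cutoff 5)
  expr <- matrix(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), 1, 10)
  colnames(expr) <- sprintf("g%02d", 1:10)
  targets <- c("g02", "g05", "g09")
  s <- activity_score(expr, targets, top_fraction = 0.5)
  # brute force: walk the ranking, integrate the step curve
  ord <- order(-expr[1, ])
  hits <- cumsum(colnames(expr)[ord] %in% targets)[1:5]
  best <- cumsum(c(1, 1, 1, 0, 0))
  expect_equal(unname(s), sum(hits) / sum(best))

  # all targets at the very top / none inside the cutoff
  expect_equal(unname(activity_score(expr, c("g01", "g02", "g03"), 0.3)), 1)
  expect_equal(unname(activity_score(expr, c("g09", "g10"), 0.3)), 0)
  expect_error(activity_score(expr, c("zz"), 0.5), "no regulon target")
})

test_that("activity score only sees within-cell ranks", {
  set.seed(1)
  expr <- matrix(rpois(50 * 40, 4), 50, 40)
  colnames(expr) <- sprintf("g%02d", 1:40)
  targets <- sprintf("g%02d", c(3, 7, 21))
  s1 <- activity_score(expr, targets, 0.2)
  s2 <- activity_score(log1p(expr) * 7, targets, 0.2)
  expect_equal(s1, s2)
  # the batch scorer agrees with the single-regulon path
  regs <- list(gene_set("r1", targets), gene_set("r2", sprintf("g%02d", 1:5)))
  sm <- activity_scores(expr, regs, 0.2)
  expect_equal(unname(sm[, "r1"]), unname(s1))
  expect_equal(unname(sm[, "r2"]),
               unname(activity_score(expr, regs[[2]], 0.2)))
})

test_that("bimodal binarisation finds the between-component threshold", {
  set.seed(2)
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    scores <- c(rnorm(100, 0.1, 0.01), rnorm(100, 0.6, 0.01))
    thr <- binarize_bimodal(scores, seed = s)
    if (thr > 0.2 && thr < 0.5) ok <- ok + 1
  }
  expect_gte(ok, 10)

  expect_warning(thr0 <- binarize_bimodal(rep(0.3, 50)), "constant")
  expect_equal(thr0, Inf)
  expect_equal(sum(rep(0.3, 50) >= thr0), 0)
  expect_error(binarize_bimodal(rnorm(5)), "20 cells")
})

test_that("binarisation threshold is translation-equivariant", {
  set.seed(3)
  scores <- c(rnorm(150, 0.2, 0.03), rnorm(150, 0.7, 0.05))
  t1 <- binarize_bimodal(scores)
  t2 <- binarize_bimodal(scores + 0.25)
  expect_lt(abs(t2 - (t1 + 0.25)), 1e-6)
})

test_that("regulons active in at least one cell are retained", {
  bin <- cbind(a = c(0, 0, 0), b = c(0, 1, 0), c = c(1, 1, 1))
  expect_setequal(filter_active(bin), c("b", "c"))
  expect_length(filter_active(bin[, "a", drop = FALSE]), 0)
})

test_that("activation profiles are exact per-subtype ratios", {
  bin <- cbind(r1 = c(1, 1, 0, 0, 1, 0), r2 = c(1, 1, 1, 1, 1, 1))
  subtypes <- c("A", "A", "A", "B", "B", "B")
  prof <- activation_profile(bin, subtypes)
  expect_equal(prof["r1", "A"], 2 / 3)
  expect_equal(prof["r1", "B"], 1 / 3)
  expect_equal(unname(prof["r2", ]), c(1, 1))
  expect_error(activation_profile(bin, c("A", "B")))
})

test_that("planted activation fractions are recovered end to end", {
  d <- sim_design(species = "human", shared_subtypes = c("T1", "T2"),
                  specific_subtypes = list(), cells_per_subtype = 500,
                  n_genes = 600, n_markers = 5,
                  module_sizes = integer(0), module_lambda = numeric(0),
                  regulons = list(list(name = "R1", n_targets = 100,
                                       fractions = c(T1 = 0.7, T2 = 0.1))),
                  disease_effect = 0, seed = 5)
  sim <- simulate_species(d)
  tab <- sim$tables$human
  scores <- activity_scores(tab, sim$truth$regulons, top_fraction = 0.05)
  bin <- binarize_activity(scores, seed = 1)
  prof <- activation_profile(bin$binarized, tab$annot$subtype)
  expect_lt(abs(prof["R1", "T1"] - 0.7), 0.05)
  expect_lt(abs(prof["R1", "T2"] - 0.1), 0.05)
})

test_that("k-means grouping is deterministic and respects duplicates", {
  set.seed(6)
  prof <- matrix(runif(40), 10, 4,
                 dimnames = list(paste0("r", 1:10), NULL))
  prof[2, ] <- prof[1, ]  # exact duplicate rows
  g1 <- group_regulons(prof, k = 4, seed = 3)
  g2 <- group_regulons(prof, k = 4, seed = 3)
  expect_equal(g1, g2)
  expect_equal(g1[["r1"]], g1[["r2"]])
  expect_setequal(unique(g1), 1:4)
  # relabelling by size: group 1 is (one of) the largest
  sizes <- table(g1)
  expect_equal(unname(sizes[1]), max(sizes))
  expect_error(group_regulons(prof, k = 11), "cannot form")
})

test_that("archetypal activation patterns are recovered by grouping", {
  set.seed(7)
  arch <- rbind(conserved  = rep(0.8, 8),
                absent     = rep(0.02, 8),
                sp1_only   = c(rep(0.8, 4), rep(0.02, 4)),
                sp2_only   = c(rep(0.02, 4), rep(0.8, 4)),
                one_type   = c(0.8, rep(0.02, 7)))
  truth <- rep(rownames(arch), each = 4)
  prof <- arch[truth, ] + matrix(rnorm(160, sd = 0.02), 20, 8)
  rownames(prof) <- paste0("r", 1:20)
  groups <- group_regulons(prof, k = 5, seed = 1)
  expect_equal(ari(groups, truth), 1)
})
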