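test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper(0, M = 5, n = 4, N = 10), 1.0)
  # k = 3, M = 5, n = 4, N = 10 by direct term enumeration
  enum <- (choose(5, 3) * choose(5, 1) + choose(5, 4) * choose(5, 0)) /
    choose(10, 4)
  expect_equal(hypergeom_upper(3, 5, 4, 10), enum, tolerance = 1e-12)
  # k = min(M, n): single closed-form term
  expect_equal(hypergeom_upper(4, 5, 4, 10),
               choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-12)
  expect_error(hypergeom_upper(5, 5, 4, 10), "min")
  expect_error(hypergeom_upper(-1, 5, 4, 10), "min|\\[0")
  expect_error(hypergeom_upper(1, 11, 4, 10), "exceed")
})

test_that("log-space tail agrees with phyper across a grid", {
  for (N in c(7, 20, 41)) {
    for (M in 0:N) {
      for (n in c(0, 1, N %/% 2, N)) {
        k <- 0:min(M, n)
        mine <- hypergeom_upper(k, M, n, N)
        ref <- stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
        expect_lt(max(abs(mine - ref)), 1e-10)
      }
    }
  }
  # extreme tail stays finite and positive in log space
  p <- hypergeom_upper(50, M = 100, n = 50, N = 20000)
  expect_gt(p, 0)
  expect_lt(p, 1e-100)
})

test_that("module enrichment scores overlaps with star tiers", {
  modules <- list(hit = paste0("r", 1:10), miss = paste0("x", 1:10))
  risk <- paste0("r", 1:100)
  res <- module_risk_enrichment(modules, risk, N = 20000)
  expect_equal(res$k[res$module == "hit"], 10L)
  expect_lt(res$p[res$module == "hit"], 1e-10)
  expect_equal(res$stars[res$module == "hit"], "***")
  expect_equal(res$k[res$module == "miss"], 0L)
  expect_equal(res$p[res$module == "miss"], 1)
  expect_equal(res$stars[res$module == "miss"], "")
  expect_error(module_risk_enrichment(modules, character(0)), "empty")

  # label/order permutation invariance
  shuffled <- list(miss = rev(modules$miss), hit = sample(modules$hit))
  res2 <- module_risk_enrichment(shuffled, sample(risk), N = 20000)
  expect_equal(sort(res2$p), sort(res$p))

  # assignment-vector interface matches the list interface
  labels <- stats::setNames(rep(c("hit", "miss", "unassigned"), each = 10),
                            c(paste0("r", 1:10), paste0("x", 1:10),
                              paste0("u", 1:10)))
  res3 <- module_risk_enrichment(labels, risk, N = 20000)
  expect_setequal(res3$module, c("hit", "miss"))
})

test_that("star tiers follow the printed thresholds", {
  expect_equal(crossneuro:::stars_for(0.0005), "***")
  expect_equal(crossneuro:::stars_for(0.005), "**")
  expect_equal(crossneuro:::stars_for(0.03), "*")
  expect_equal(crossneuro:::stars_for(0.2), "")
})

test_that("DEG filters and adjustment behave as specified", {
  set.seed(1)
  n <- 200
  counts <- matrix(rpois(n * 30, 5), n, 30)
  # gene 1: planted 2x effect in disease; gene 2: detected in only 10%
  cond <- rep(c("disease", "control"), each = n / 2)
  counts[cond == "disease", 1] <- rpois(n / 2, 10)
  counts[, 2] <- rbinom(n, 1, 0.1) * 3L
  colnames(counts) <- sprintf("g%02d", 1:30)
  annot <- data.frame(cell_id = sprintf("c%03d", 1:n), species = "h",
                      batch = "b", subtype = "s", condition = cond)
  tab <- cell_table(counts, annot)
  res <- deg_wilcoxon(tab)
  expect_false("g02" %in% res$gene)           # min.pct filter
  expect_true("g01" %in% res$gene)
  expect_lt(res$p_adj[res$gene == "g01"], 0.05)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_true(all(res$p_adj <= 1))
  # BH order preserved
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-15))
  expect_error(deg_wilcoxon(tab, group_by = "missing"), "absent")
  tab2 <- tab; tab2$annot$condition <- "control"
  expect_error(deg_wilcoxon(tab2), "absent|empty")
})

test_that("high-confidence genes are the three-way intersection", {
  degs <- list(ct1 = data.frame(gene = c("a", "b", "c")),
               ct2 = c("b", "d"))
  out <- high_confidence_risk_genes(degs, risk_genes = c("b", "c", "d"),
                                    module_genes = c("c", "b"))
  expect_equal(out$ct1, c("b", "c"))
  expect_equal(out$ct2, "b")
  expect_equal(attr(out, "sizes"), c(ct1 = 2L, ct2 = 1L))
  empty <- high_confidence_risk_genes(degs, character(0), c("b"))
  expect_equal(lengths(empty), c(ct1 = 0L, ct2 = 0L))
})

test_that("cross-species correlation honours Pearson affine structure", {
  tab <- toy_table(n_cells = 40, n_genes = 25, seed = 2,
                   subtypes = c("A", "B"))
  copy <- tab
  copy$annot$species <- "mouse"
  res <- crossspecies_gene_correlation(tab, list(mouse = copy),
                                       genes = tab$gene_ids)
  expect_equal(res$r, rep(1, 2), tolerance = 1e-12)
  expect_equal(res$slope, rep(1, 2), tolerance = 1e-12)
  expect_equal(res$intercept, rep(0, 2), tolerance = 1e-10)

  # affine-transformed mean profile: r = 1, slope = 2 (built directly)
  x <- colMeans(normalize_log1p(tab))
  y <- 2 * x + 1
  fit <- stats::lm(y ~ x)
  expect_equal(unname(stats::cor(x, y)), 1)
  expect_equal(unname(stats::coef(fit)[2]), 2)

  expect_error(crossspecies_gene_correlation(tab, list(mouse = copy),
                                             genes = c("g0001", "g0002")),
               "3 shared")
})

test_that("independent species means are uncorrelated on average", {
  set.seed(3)
  rs <- replicate(20, {
    tab <- toy_table(n_cells = 30, n_genes = 100, seed = sample.int(1e6, 1),
                     subtypes = "A")
    other <- toy_table(n_cells = 30, n_genes = 100,
                       seed = sample.int(1e6, 1), subtypes = "A",
                       species = "mouse")
    crossspecies_gene_correlation(tab, list(mouse = other),
                                  genes = tab$gene_ids)$r
  })
  expect_lt(mean(abs(rs)), 0.15)
})

test_that("cross-species DEG stars need both significance and effect", {
  set.seed(4)
  n <- 200
  counts <- matrix(rpois(2 * n * 12, 8), 2 * n, 12)
  colnames(counts) <- sprintf("g%02d", 1:12)
  # gene 1: 4-fold shift; gene 2: significant but tiny effect
  counts[(n + 1):(2 * n), 1] <- rpois(n, 32)
  counts[(n + 1):(2 * n), 2] <- rpois(n, 9.5)
  annot <- data.frame(cell_id = sprintf("c%03d", 1:(2 * n)),
                      species = rep(c("human", "mouse"), each = n),
                      batch = "b", subtype = "s")
  ref <- cell_table(counts[1:n, ], annot[1:n, ])
  oth <- cell_table(counts[(n + 1):(2 * n), ], annot[(n + 1):(2 * n), ])
  res <- crossspecies_deg_flags(ref, oth, sprintf("g%02d", 1:12))
  g1 <- res[res$gene == "g01", ]
  expect_true(g1$starred)
  expect_gt(abs(g1$avg_logFC), 1)
  g2 <- res[res$gene == "g02", ]
  expect_false(g2$starred)
  # identical distributions: no star anywhere else
  expect_true(all(!res$starred[!res$gene %in% c("g01", "g02")]))
})
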