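# Shared fixtures, built in code at test time.

# A random count table with annotation; counts ~ Poisson around gene means.
toy_table <- function(n_cells = 50, n_genes = 100, seed = 1,
                      subtypes = c("A", "B"), batches = c("b1", "b2"),
                      species = "human", condition = TRUE) {
  set.seed(seed)
  mu <- rgamma(n_genes, 2, 0.5)
  counts <- t(replicate(n_cells, rpois(n_genes, mu)))
  annot <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n_cells)),
    species = species,
    batch = rep_len(batches, n_cells),
    subtype = rep_len(subtypes, n_cells),
    stringsAsFactors = FALSE)
  if (condition)
    annot$condition <- rep_len(c("control", "disease"), n_cells)
  colnames(counts) <- sprintf("g%04d", seq_len(n_genes))
  cell_table(counts, annot)
}

# Adjusted Rand index between two label vectors (independent of the
# package's own code paths; used as the clustering-recovery metric).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A pseudocell-like matrix with planted latent-factor modules.
planted_module_matrix <- function(n_samples = 100, module_sizes = c(15, 15),
                                  n_noise = 20, lambda = 2, noise_sd = 0.3,
                                  seed = 1, shared_factor = FALSE) {
  set.seed(seed)
  n_genes <- sum(module_sizes) + n_noise
  x <- matrix(rnorm(n_samples * n_genes, sd = noise_sd), n_samples, n_genes)
  z0 <- rnorm(n_samples)
  start <- 0
  truth <- rep("noise", n_genes)
  for (m in seq_along(module_sizes)) {
    z <- if (shared_factor) z0 else rnorm(n_samples)
    cols <- start + seq_len(module_sizes[m])
    x[, cols] <- x[, cols] + lambda * z
    truth[cols] <- paste0("T", m)
    start <- start + module_sizes[m]
  }
  colnames(x) <- sprintf("g%04d", seq_len(n_genes))
  list(values = x, truth = stats::setNames(truth, colnames(x)))
}
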