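#' Design of a synthetic multi-species single-cell experiment
#'
#' Describes the generative model for planted-truth count data: a set of
#' species sharing conserved inhibitory subtypes (each with a disjoint marker
#' block), optional species-specific subtypes, per-batch and per-species
#' lognormal perturbations of gene means, planted co-expression modules driven
#' by per-cell latent factors, planted regulons with per-subtype activation
#' fractions, and a disease condition that up-regulates a designated risk
#' module. Counts are negative binomial (gamma-Poisson) around a
#' library-size-scaled softmax of the per-cell gene means.
#'
#' The default design mirrors the cross-species study conditions at desk
#' scale: two species, the four conserved GABAergic subclasses (PVALB, SST,
#' LAMP5, VIP) plus one species-specific type (`Meis2` in the second species),
#' 200 cells per subtype, two batches per species, modest batch/divergence
#' jitter, three 50-gene modules with unit latent loading (the first being the
#' disease-risk module), and ten regulons covering conserved,
#' species-specific and silent activation archetypes.
#'
#' @param species character vector; the first entry is the reference species
#' @param n_genes total genes simulated
#' @param shared_subtypes conserved subtype names
#' @param specific_subtypes named list mapping a species to its private
#'   subtype names
#' @param inhibitory_subtypes subtypes expressing the inhibitory markers
#'   GAD1/GAD2 (default: all subtypes)
#' @param n_markers marker genes per subtype (disjoint blocks)
#' @param marker_lfc log2 fold-change of a marker in its subtype
#' @param cells_per_subtype cells per subtype per species
#' @param n_batches batches per species
#' @param batch_lognormal_sd sd of the per-batch lognormal gene-mean jitter
#' @param divergence_sd sd of the per-species lognormal gene-mean jitter
#'   (0 for the reference species)
#' @param library_size_mean expected total counts per cell
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2)
#' @param module_sizes,module_lambda sizes and latent-factor loadings of the
#'   planted co-expression modules; the first module is the risk module
#' @param regulons list of planted regulons; each element is a list with
#'   `name`, `n_targets`, and `fractions` — either a single activation
#'   fraction, a vector over subtypes, or a named list `species -> fraction
#'   (scalar or per-subtype vector)`
#' @param regulon_lfc log2 fold-change on a regulon's TF and targets in
#'   active cells
#' @param disease_effect log2 fold-change on risk-module genes in disease
#'   cells
#' @param disease_fraction fraction of cells labelled `disease`
#' @param homolog_fraction fraction of genes carried by each one-to-one
#'   homology map
#' @param seed integer seed
#' @return object of class `sim_design`
#' @export
sim_design <- function(species = c("human", "mouse"),
                       n_genes = 2000L,
                       shared_subtypes = c("PVALB", "SST", "LAMP5", "VIP"),
                       specific_subtypes = list(mouse = "Meis2"),
                       inhibitory_subtypes = NULL,
                       n_markers = 25L,
                       marker_lfc = 2,
                       cells_per_subtype = 200L,
                       n_batches = 2L,
                       batch_lognormal_sd = 0.15,
                       divergence_sd = 0.1,
                       library_size_mean = 5000,
                       nb_dispersion = 0.3,
                       module_sizes = c(50L, 50L, 50L),
                       module_lambda = c(1, 1, 1),
                       regulons = default_regulons(),
                       regulon_lfc = 1,
                       disease_effect = 1,
                       disease_fraction = 0.5,
                       homolog_fraction = 0.9,
                       seed = 1L) {
  specific_subtypes <- specific_subtypes[intersect(names(specific_subtypes), species)]
  all_subtypes <- c(shared_subtypes, unlist(specific_subtypes, use.names = FALSE))
  if (anyDuplicated(all_subtypes)) stop("subtype names must be unique")
  if (is.null(inhibitory_subtypes)) inhibitory_subtypes <- all_subtypes
  stopifnot(length(species) >= 1, n_genes > 0, cells_per_subtype > 0,
            n_batches >= 1, batch_lognormal_sd >= 0, divergence_sd >= 0,
            library_size_mean > 0, nb_dispersion > 0,
            length(module_sizes) == length(module_lambda),
            all(module_sizes > 0), disease_fraction >= 0, disease_fraction <= 1,
            homolog_fraction >= 0, homolog_fraction <= 1, n_markers >= 0,
            all(vapply(regulons, function(r) r$n_targets > 0, logical(1))))
  d <- list(species = species, n_genes = as.integer(n_genes),
            shared_subtypes = shared_subtypes,
            specific_subtypes = specific_subtypes,
            inhibitory_subtypes = inhibitory_subtypes,
            n_markers = as.integer(n_markers), marker_lfc = marker_lfc,
            cells_per_subtype = as.integer(cells_per_subtype),
            n_batches = as.integer(n_batches),
            batch_lognormal_sd = batch_lognormal_sd,
            divergence_sd = divergence_sd,
            library_size_mean = library_size_mean,
            nb_dispersion = nb_dispersion,
            module_sizes = as.integer(module_sizes),
            module_lambda = module_lambda,
            regulons = regulons, regulon_lfc = regulon_lfc,
            disease_effect = disease_effect,
            disease_fraction = disease_fraction,
            homolog_fraction = homolog_fraction,
            seed = as.integer(seed))
  class(d) <- "sim_design"
  # gene layout is fixed by the design; fails early if blocks do not fit
  d$layout <- sim_gene_layout(d)
  d
}

#' Default planted regulon archetypes
#'
#' Ten regulons spanning the activation patterns the grouping stage is meant
#' to separate: subtype-specific but conserved across species, broadly active
#' in all species, active in a single species only, and silent.
#'
#' @return list of regulon descriptions for [sim_design()]
#' @export
default_regulons <- function() {
  list(
    list(name = "R_PVALB", n_targets = 100L, fractions = c(PVALB = 0.8)),
    list(name = "R_SST",   n_targets = 100L, fractions = c(SST = 0.8)),
    list(name = "R_LAMP5", n_targets = 100L, fractions = c(LAMP5 = 0.8)),
    list(name = "R_VIP",   n_targets = 100L, fractions = c(VIP = 0.8)),
    list(name = "R_all",   n_targets = 100L, fractions = 0.7),
    # species-specific programs are smaller than the conserved core ones,
    # so a private regulon marks its species without swamping the shared
    # subtype structure
    list(name = "R_human", n_targets = 40L,
         fractions = list(human = 0.8)),
    list(name = "R_mouse", n_targets = 40L,
         fractions = list(mouse = 0.8)),
    list(name = "R_silent", n_targets = 100L, fractions = 0),
    list(name = "R_broad1", n_targets = 100L, fractions = 0.6),
    list(name = "R_broad2", n_targets = 100L, fractions = 0.4)
  )
}

# Assign disjoint gene blocks: GAD markers, subtype markers, modules,
# regulon targets + TF genes; remaining genes are unstructured background.
sim_gene_layout <- function(d) {
  gene_ids <- sprintf("g%04d", seq_len(d$n_genes))
  gene_ids[1:2] <- c("GAD1", "GAD2")
  ptr <- 3L
  take <- function(n) {
    if (n == 0L) return(integer(0))
    if (ptr + n - 1L > d$n_genes)
      stop("planted gene blocks exceed n_genes; enlarge the design")
    out <- ptr:(ptr + n - 1L); ptr <<- ptr + n; out
  }
  all_subtypes <- c(d$shared_subtypes, unlist(d$specific_subtypes, use.names = FALSE))
  markers <- lapply(all_subtypes, function(s) take(d$n_markers))
  names(markers) <- all_subtypes
  modules <- lapply(d$module_sizes, take)
  if (length(modules)) names(modules) <- paste0("M", seq_along(modules))
  reg_targets <- list(); reg_tf <- integer(0)
  for (r in d$regulons) {
    reg_targets[[r$name]] <- take(r$n_targets)
    reg_tf[r$name] <- take(1L)
  }
  list(gene_ids = gene_ids, markers = markers, modules = modules,
       regulon_targets = reg_targets, regulon_tf = reg_tf)
}

# activation fraction of regulon r for (species, subtype)
regulon_fraction <- function(r, species, subtype) {
  fr <- r$fractions
  if (is.list(fr)) {
    fr <- fr[[species]]
    if (is.null(fr)) return(0)
  }
  if (!is.null(names(fr))) {
    f <- fr[subtype]
    if (is.na(f)) 0 else unname(f)
  } else unname(fr[1])
}

#' Simulate multi-species single-cell count data with planted truth
#'
#' Draws one count table per species under the generative model of
#' [sim_design()]: per-cell gene means are the product of a shared gamma
#' baseline, marker fold-changes, lognormal batch and species-divergence
#' factors, module latent factors, regulon activation effects and the disease
#' effect; means are softmax-normalised per cell, scaled to the library size,
#' and counts drawn negative-binomially. Non-reference species receive their
#' own gene identifiers plus a one-to-one homology map back to the reference
#' (covering `homolog_fraction` of genes; the inhibitory markers are always
#' mapped).
#'
#' @param design a `sim_design`
#' @return list with elements `tables` (named list of `cell_table` per
#'   species), `homology` (named list of `homology_map` per non-reference
#'   species), `truth` (planted assignments; see [truth_report()])
#' @export
simulate_species <- function(design) {
  d <- design
  lay <- d$layout
  G <- d$n_genes
  ref <- d$species[1]

  set.seed(derive_seed(d$seed, "sim_baseline"))
  w <- stats::rgamma(G, shape = 0.5, rate = 0.5) + 1e-4
  # marker and module blocks live on expressed genes (as curated marker and
  # co-expression gene sets do): floor those baselines at the mean
  # expression level. Regulon targets keep the natural expression spread —
  # rank-based activity scoring relies on targets rising INTO the top ranks
  # when the regulon switches on, not on uniformly high expression.
  planted <- unique(c(unlist(lay$markers), unlist(lay$modules)))
  if (length(planted)) w[planted] <- pmax(w[planted], 1)
  # inhibitory markers: high in inhibitory subtypes, ~silent elsewhere
  gad_high <- 5 * G / d$library_size_mean * 2
  w[1:2] <- gad_high / 2^10

  size_nb <- 1 / d$nb_dispersion
  tables <- list(); hmaps <- list()
  activity_rows <- list()

  for (sp in d$species) {
    subtypes <- c(d$shared_subtypes, d$specific_subtypes[[sp]])
    n_cells <- length(subtypes) * d$cells_per_subtype
    set.seed(derive_seed(d$seed, paste0("sim_", sp)))
    batch_fac <- matrix(
      exp(stats::rnorm(d$n_batches * G, 0, d$batch_lognormal_sd)),
      nrow = d$n_batches)
    div_fac <- if (sp == ref) rep(1, G) else
      exp(stats::rnorm(G, 0, d$divergence_sd))

    subtype <- rep(subtypes, each = d$cells_per_subtype)
    batch <- rep_len(seq_len(d$n_batches), n_cells)
    n_dis <- round(d$disease_fraction * d$cells_per_subtype)
    condition <- rep(rep(c("disease", "control"),
                         c(n_dis, d$cells_per_subtype - n_dis)),
                     length(subtypes))

    logmu <- matrix(rep(log2(w), each = n_cells), nrow = n_cells)
    for (s in subtypes) {
      rows <- which(subtype == s)
      logmu[rows, lay$markers[[s]]] <- logmu[rows, lay$markers[[s]]] + d$marker_lfc
      if (s %in% d$inhibitory_subtypes)
        logmu[rows, 1:2] <- logmu[rows, 1:2] + 10
    }
    for (j in seq_along(lay$modules)) {
      z <- stats::rnorm(n_cells)
      logmu[, lay$modules[[j]]] <- logmu[, lay$modules[[j]]] +
        d$module_lambda[j] * z
    }
    act <- matrix(FALSE, n_cells, length(d$regulons),
                  dimnames = list(NULL, names(lay$regulon_targets)))
    for (ri in seq_along(d$regulons)) {
      r <- d$regulons[[ri]]
      fr <- vapply(subtype, function(s) regulon_fraction(r, sp, s), numeric(1))
      on <- stats::runif(n_cells) < fr
      act[, ri] <- on
      cols <- c(lay$regulon_targets[[r$name]], lay$regulon_tf[[r$name]])
      logmu[on, cols] <- logmu[on, cols] + d$regulon_lfc
    }
    if (d$disease_effect != 0 && length(lay$modules)) {
      dis <- condition == "disease"
      logmu[dis, lay$modules[[1]]] <- logmu[dis, lay$modules[[1]]] +
        d$disease_effect
    }
    mu <- 2^logmu
    mu <- mu * matrix(rep(div_fac, each = n_cells), nrow = n_cells)
    mu <- mu * batch_fac[batch, , drop = FALSE]
    mu <- mu / rowSums(mu) * d$library_size_mean
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = size_nb),
                     nrow = n_cells)

    gene_ids <- lay$gene_ids
    if (sp != ref) {
      gene_ids <- paste0(sp, "_", lay$gene_ids)
      gene_ids[1:2] <- lay$gene_ids[1:2]  # shared marker symbols
      n_map <- round(d$homolog_fraction * G)
      mapped <- sort(unique(c(1:2, sample.int(G, n_map))))
      hmaps[[sp]] <- homology_map(
        data.frame(source_gene = gene_ids[mapped],
                   reference_gene = lay$gene_ids[mapped],
                   stringsAsFactors = FALSE),
        source_species = sp)
    }
    annot <- data.frame(cell_id = sprintf("%s_c%05d", sp, seq_len(n_cells)),
                        species = sp,
                        batch = sprintf("%s_b%d", sp, batch),
                        subtype = subtype, condition = condition,
                        stringsAsFactors = FALSE)
    tables[[sp]] <- cell_table(counts, annot, gene_ids = gene_ids)
    on_idx <- which(act, arr.ind = TRUE)
    if (nrow(on_idx))
      activity_rows[[sp]] <- data.frame(
        species = sp, cell_id = annot$cell_id[on_idx[, 1]],
        regulon = colnames(act)[on_idx[, 2]], stringsAsFactors = FALSE)
  }

  truth <- build_truth(d, tables, activity_rows)
  list(tables = tables, homology = hmaps, truth = truth)
}

build_truth <- function(d, tables, activity_rows) {
  lay <- d$layout
  modules <- do.call(rbind, lapply(names(lay$modules), function(m)
    data.frame(gene = lay$gene_ids[lay$modules[[m]]], module = m,
               stringsAsFactors = FALSE)))
  if (is.null(modules))
    modules <- data.frame(gene = character(0), module = character(0))
  markers <- do.call(rbind, lapply(names(lay$markers), function(s)
    if (length(lay$markers[[s]]))
      data.frame(gene = lay$gene_ids[lay$markers[[s]]], subtype = s,
                 lfc = d$marker_lfc, stringsAsFactors = FALSE)))
  if (is.null(markers))
    markers <- data.frame(gene = character(0), subtype = character(0),
                          lfc = numeric(0))
  regs <- lapply(d$regulons, function(r)
    gene_set(r$name, lay$gene_ids[lay$regulon_targets[[r$name]]],
             tf = lay$gene_ids[lay$regulon_tf[[r$name]]]))
  frac_rows <- list()
  all_subtypes <- c(d$shared_subtypes, unlist(d$specific_subtypes, use.names = FALSE))
  for (r in d$regulons) for (sp in d$species) for (s in all_subtypes) {
    if (s %in% c(d$shared_subtypes, d$specific_subtypes[[sp]]))
      frac_rows[[length(frac_rows) + 1]] <- data.frame(
        regulon = r$name, species = sp, subtype = s,
        fraction = regulon_fraction(r, sp, s), stringsAsFactors = FALSE)
  }
  fractions <- if (length(frac_rows)) do.call(rbind, frac_rows) else
    data.frame(regulon = character(0), species = character(0),
               subtype = character(0), fraction = numeric(0))
  cells <- do.call(rbind, lapply(tables, function(t) t$annot))
  rownames(cells) <- NULL
  risk <- if (length(lay$modules)) lay$gene_ids[lay$modules[[1]]] else character(0)
  de <- if (d$disease_effect != 0 && length(risk))
    data.frame(gene = risk, lfc = d$disease_effect, stringsAsFactors = FALSE)
  else data.frame(gene = character(0), lfc = numeric(0))
  activity <- if (length(activity_rows)) do.call(rbind, activity_rows) else
    data.frame(species = character(0), cell_id = character(0),
               regulon = character(0))
  rownames(activity) <- NULL
  structure(list(cells = cells, modules = modules, markers = markers,
                 regulons = regs, regulon_fractions = fractions,
                 regulon_activity = activity, risk_genes = risk,
                 de_genes = de),
            class = "sim_truth")
}

#' Tabular summary of planted ground truth
#'
#' @param truth a `sim_truth` from [simulate_species()]
#' @return named list of data.frames: `subtypes` (cell counts per species x
#'   subtype), `modules`, `markers`, `regulons` (TF and target count),
#'   `regulon_fractions`, `de_genes`
#' @export
truth_report <- function(truth) {
  subtypes <- if (nrow(truth$cells)) {
    agg <- stats::aggregate(list(n_cells = truth$cells$cell_id),
                            by = list(species = truth$cells$species,
                                      subtype = truth$cells$subtype),
                            FUN = length)
    agg[order(agg$species, agg$subtype), , drop = FALSE]
  } else data.frame(species = character(0), subtype = character(0),
                    n_cells = integer(0))
  rownames(subtypes) <- NULL
  regulons <- if (length(truth$regulons))
    data.frame(regulon = vapply(truth$regulons, `[[`, character(1), "name"),
               tf = vapply(truth$regulons, `[[`, character(1), "tf"),
               n_targets = vapply(truth$regulons,
                                  function(r) length(r$genes), integer(1)),
               stringsAsFactors = FALSE)
  else data.frame(regulon = character(0), tf = character(0),
                  n_targets = integer(0))
  list(subtypes = subtypes, modules = truth$modules, markers = truth$markers,
       regulons = regulons, regulon_fractions = truth$regulon_fractions,
       de_genes = truth$de_genes)
}

#' Write / read the truth tables as TSVs
#' @param truth a `sim_truth`
#' @param dir output directory
#' @return invisibly (write) / the list of data.frames (read)
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- truth_report(truth)
  tabs$regulon_activity <- truth$regulon_activity
  for (nm in names(tabs))
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  files <- c("subtypes", "modules", "markers", "regulons",
             "regulon_fractions", "de_genes", "regulon_activity")
  out <- lapply(files, function(nm)
    utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                      stringsAsFactors = FALSE))
  names(out) <- files
  out
}
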