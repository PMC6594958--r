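#' Configuration for the synthetic count-matrix generator
#'
#' Emulates droplet scRNA-seq of the developing germline: cells lie on a
#' latent differentiation continuum `u` in \[0, 1\] along which an
#' SSC-program gene panel decreases and a differentiation-program panel
#' increases (anti-correlated programs), a rare planted population
#' (default 10%, the size of the functional SSC pool within the germline)
#' carries its own marker panel, and per-cell library size, mitochondrial
#' content and dropout mimic routine QC covariates. Counts are
#' negative-binomial at the matrix level; no read-level simulation.
#'
#' @param n_cells named integer vector of cells per age/library.
#' @param n_genes total genes, including the named panels and mito genes.
#' @param ssc_panel,diff_panel,pluri_panel,housekeeping_panel,rare_markers
#'   disjoint character vectors of gene names.
#' @param n_mito_genes number of `mt-` genes.
#' @param effect_size log2-fold range of each program across the continuum.
#' @param rare_fraction fraction of cells in the planted rare population
#'   (must lie in (0, 0.5); membership is a seeded sample of exactly
#'   `round(fraction * n)` cells).
#' @param rare_effect extra log2-fold expression of `rare_markers` in rare
#'   cells. The default 20-gene panel reflects that such a population is
#'   set apart by a broad transcriptional program, not a handful of genes.
#' @param u_shape named list per age of `c(shape1, shape2)` Beta parameters
#'   for the continuum position; rare cells are pinned near u = 0.
#' @param dispersion negative-binomial size parameter.
#' @param dropout_rate extra zero-inflation probability.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param mito_mean,mito_sd per-cell target mitochondrial fraction (normal,
#'   truncated to (0.001, 0.9)).
#' @param lowq_fraction fraction of cells rendered low-quality (mito target
#'   around `lowq_mito_mean`), flagged in the truth.
#' @param lowq_mito_mean mitochondrial target for low-quality cells.
#' @param gene_param_seed seed for the gene-level parameters (baseline
#'   expression per gene). Kept separate from the simulation seed so that
#'   replicate libraries simulated with different seeds share the same
#'   underlying gene-expression biology, as real replicates do.
#' @return list of class `continuum_sim_config`.
#' @export
continuum_sim_config <- function(
    n_cells = c(E16.5 = 600, P0 = 600, P3 = 600, P6 = 600),
    n_genes = 500,
    ssc_panel = c("Id4", "Etv5", "Lhx1", "Ret", "Nanos2", "Eomes"),
    diff_panel = c("Dnmt3a", "Dnmt3b", "Sohlh1", "Sox3", "Kit", "Stra8"),
    pluri_panel = c("Dppa3", "Nanog", "Sox2"),
    housekeeping_panel = c("Actb", "Gapdh", "Dazl", "Ddx4"),
    rare_markers = paste0("RareMk", 1:20),
    n_mito_genes = 8,
    effect_size = 2,
    rare_fraction = 0.10,
    rare_effect = 3,
    u_shape = NULL,
    dispersion = 2,
    dropout_rate = 0.1,
    libsize_meanlog = log(6000),
    libsize_sdlog = 0.3,
    mito_mean = 0.05,
    mito_sd = 0.02,
    lowq_fraction = 0,
    lowq_mito_mean = 0.55,
    gene_param_seed = 1000L) {
  panels <- list(ssc = ssc_panel, diff = diff_panel, pluri = pluri_panel,
                 housekeeping = housekeeping_panel, rare = rare_markers)
  all_panel_genes <- unlist(panels)
  if (anyDuplicated(all_panel_genes))
    stop("gene panels overlap: ",
         paste(unique(all_panel_genes[duplicated(all_panel_genes)]),
               collapse = ", "))
  if (!(rare_fraction > 0 && rare_fraction < 0.5))
    stop("rare_fraction must lie in (0, 0.5)")
  stopifnot(all(n_cells > 0), n_genes >= length(all_panel_genes) + n_mito_genes,
            effect_size >= 0, dispersion > 0,
            dropout_rate >= 0, dropout_rate < 1,
            lowq_fraction >= 0, lowq_fraction < 1)
  if (is.null(u_shape)) {
    defaults <- list(E16.5 = c(2, 6), P0 = c(3, 4), P3 = c(4, 3),
                     P6 = c(5, 2.5))
    u_shape <- lapply(names(n_cells), function(a)
      if (!is.null(defaults[[a]])) defaults[[a]] else c(3, 3))
    names(u_shape) <- names(n_cells)
  }
  structure(list(n_cells = n_cells, n_genes = as.integer(n_genes),
                 panels = panels, n_mito_genes = as.integer(n_mito_genes),
                 effect_size = effect_size, rare_fraction = rare_fraction,
                 rare_effect = rare_effect, u_shape = u_shape,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 mito_mean = mito_mean, mito_sd = mito_sd,
                 lowq_fraction = lowq_fraction,
                 lowq_mito_mean = lowq_mito_mean,
                 gene_param_seed = as.integer(gene_param_seed)),
            class = "continuum_sim_config")
}

#' Simulate a germ-cell count matrix along a differentiation continuum
#'
#' Expected (pre-noise) expression of the SSC program decreases
#' monotonically in the latent coordinate `u` and the differentiation
#' program increases; the pluripotency panel decreases steeply; the rare
#' planted population (exactly `round(rare_fraction * n)` cells, seeded
#' sample) sits at low `u` with its marker panel boosted. Counts are
#' negative binomial around per-cell library-size-scaled means with extra
#' dropout zeros.
#'
#' @param config a [continuum_sim_config()].
#' @param seed integer RNG seed.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (genes x cells, sparse) and colData columns `library_id`, `age`,
#'   `u`, `rare`, `low_quality`, `mito_target`, `mito_fraction`,
#'   `n_genes_detected`, `total_umi`.
#' @export
simulate_counts <- function(config, seed) {
  stopifnot(inherits(config, "continuum_sim_config"))
  cfg <- config
  ages <- names(cfg$n_cells)
  n_total <- sum(cfg$n_cells)

  panels <- cfg$panels
  mito_genes <- sprintf("mt-Gene%02d", seq_len(cfg$n_mito_genes))
  named <- c(unlist(panels, use.names = FALSE), mito_genes)
  n_filler <- cfg$n_genes - length(named)
  genes <- c(named, sprintf("Filler%04d", seq_len(n_filler)))

  # gene-level biology is shared across replicate simulations
  set.seed(cfg$gene_param_seed)
  base <- setNames(runif(cfg$n_genes, -1, 3), genes)  # log2 baseline
  base[panels$housekeeping] <- 4
  slope <- setNames(rep(0, cfg$n_genes), genes)
  slope[panels$ssc] <- -cfg$effect_size
  slope[panels$diff] <- cfg$effect_size
  slope[panels$pluri] <- -1.5 * cfg$effect_size

  set.seed(as.integer(seed))
  age <- rep(ages, cfg$n_cells)
  library_id <- paste0(age, "_1")
  u <- numeric(n_total)
  off <- 0L
  for (a in ages) {
    n <- cfg$n_cells[[a]]
    sh <- cfg$u_shape[[a]]
    u[off + seq_len(n)] <- rbeta(n, sh[1], sh[2])
    off <- off + n
  }
  n_rare <- round(cfg$rare_fraction * n_total)
  rare <- rep(FALSE, n_total)
  rare[sample.int(n_total, n_rare)] <- TRUE
  u[rare] <- rbeta(n_rare, 1, 12)   # rare population sits at the SSC end
  n_lowq <- round(cfg$lowq_fraction * n_total)
  lowq <- rep(FALSE, n_total)
  if (n_lowq > 0) lowq[sample.int(n_total, n_lowq)] <- TRUE

  # log2 expected expression: genes x cells
  logmu <- matrix(base, nrow = cfg$n_genes, ncol = n_total) +
    outer(slope, u - 0.5)
  rare_idx <- which(genes %in% panels$rare)
  logmu[rare_idx, rare] <- logmu[rare_idx, rare] + cfg$rare_effect
  m <- 2^logmu

  libsize <- rlnorm(n_total, cfg$libsize_meanlog, cfg$libsize_sdlog)
  # low-quality targets are clamped well above typical QC cutoffs so the
  # two populations stay separable after count-level noise
  mito_target <- pmin(pmax(rnorm(n_total, cfg$mito_mean, cfg$mito_sd),
                           0.001), 0.2)
  mito_target[lowq] <- pmin(pmax(rnorm(sum(lowq), cfg$lowq_mito_mean, 0.04),
                                 0.45), 0.9)

  mito_idx <- which(genes %in% mito_genes)
  nonmito_sum <- colSums(m[-mito_idx, , drop = FALSE])
  m[mito_idx, ] <- rep(mito_target / (1 - mito_target) * nonmito_sum /
                         length(mito_idx), each = length(mito_idx))
  mu <- sweep(m, 2, libsize / colSums(m), "*")

  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                   nrow = cfg$n_genes)
  if (cfg$dropout_rate > 0) {
    counts[runif(length(counts)) < cfg$dropout_rate] <- 0L
  }
  dimnames(counts) <- list(genes, sprintf("cell%05d", seq_len(n_total)))

  total_umi <- colSums(counts)
  mito_fraction <- ifelse(total_umi > 0,
                          colSums(counts[mito_idx, , drop = FALSE]) /
                            pmax(total_umi, 1), 0)
  cd <- S4Vectors::DataFrame(
    library_id = library_id, age = age, u = u, rare = rare,
    low_quality = lowq, mito_target = mito_target,
    mito_fraction = mito_fraction,
    n_genes_detected = colSums(counts > 0),
    total_umi = total_umi,
    row.names = colnames(counts))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = cd,
    metadata = list(panels = panels, mito_genes = mito_genes, seed = seed))
}
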