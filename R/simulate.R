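#' Simulate the tumor-mixture toy expression data
#'
#' Generates the 10-gene / 500-cell / 5-population toy data used to benchmark
#' the heterogeneity indices. Each population `i` has a unit-norm centroid with
#' `1/sqrt(2)` in genes `2i-1` and `2i` and zero elsewhere; each cell is its
#' population centroid plus i.i.d. Gaussian noise with standard deviation
#' `sigma`. Cells are allocated to tumors in three compositions:
#' case 1 - each tumor holds one population exclusively; case 2 - each tumor
#' holds 60 cells from one population and 10 from each other population;
#' case 3 - each tumor holds 20 cells from every population. The allocation is
#' deterministic (cells of each population are dealt out in fixed order), so a
#' fixed seed makes the data bit-reproducible.
#'
#' @param case tumor composition, 1, 2 or 3.
#' @param sigma noise standard deviation (> 0).
#' @param n_populations number of populations (= tumors; default 5).
#' @param cells_per_population cells per population (default 100; cases 2-3
#'   scale the 60/10 and 20-cell compositions proportionally).
#' @param n_genes number of genes (default `2 * n_populations`).
#' @param seed optional integer seed.
#' @return an `ExpressionMatrix` with tumor labels and the ground-truth
#'   population of each cell in `$population`.
#' @export
simulate_mixture <- function(case, sigma, n_populations = 5,
                             cells_per_population = 100, n_genes = NULL,
                             seed = NULL) {
  if (!case %in% 1:3) stop("`case` must be 1, 2 or 3")
  if (sigma <= 0) stop("`sigma` must be positive")
  if (is.null(n_genes)) n_genes <- 2L * n_populations
  if (n_genes < 2 * n_populations)
    stop("need >= 2 genes per population")
  if (!is.null(seed)) set.seed(seed)
  P <- n_populations
  per <- cells_per_population
  if (case == 2 && (per - round(per * 0.6)) %% (P - 1) != 0)
    stop("case 2 requires the 40% minority to split evenly over the other populations")
  if (case == 3 && per %% P != 0)
    stop("case 3 requires cells_per_population divisible by n_populations")
  centroids <- matrix(0, n_genes, P)
  for (i in seq_len(P)) centroids[c(2 * i - 1, 2 * i), i] <- 1 / sqrt(2)
  pop <- rep(seq_len(P), each = per)
  values <- centroids[, pop] +
    matrix(stats::rnorm(n_genes * length(pop), sd = sigma), n_genes)
  tumor <- integer(length(pop))
  for (i in seq_len(P)) {
    idx <- which(pop == i)
    if (case == 1) {
      tumor[idx] <- rep(i, per)
    } else if (case == 2) {
      n_major <- round(per * 0.6)
      n_minor <- (per - n_major) %/% (P - 1)
      tumor[idx] <- c(rep(i, n_major),
                      rep(setdiff(seq_len(P), i), each = n_minor))
    } else {
      tumor[idx] <- rep(seq_len(P), each = per %/% P)
    }
  }
  rownames(values) <- sprintf("gene%02d", seq_len(n_genes))
  colnames(values) <- sprintf("cell%03d", seq_along(pop))
  expression_matrix(values, tumor = paste0("tumor", tumor),
                    population = paste0("pop", pop))
}

#' Simulate a suite of datasets with planted shared gene-cluster structure
#'
#' Produces one expression matrix per dataset, each containing co-expressed
#' gene blocks: `shared_blocks` blocks whose genes (same identifiers) appear in
#' every dataset, and `private_blocks` blocks per dataset whose genes appear in
#' that dataset only. Every block has substructure: its genes load on a
#' block-level latent factor plus one of two sub-block factors, where the
#' split of the block's genes into halves is drawn independently in every
#' dataset. Clustering therefore recovers a two-level lineage per block
#' (block, then halves), and because the splits differ across datasets,
#' sibling sub-clusters of the same block overlap partially between datasets -
#' the situation hierarchy alignment is designed for. The block-level factor
#' carries a tumor-level shift so blocks also show intra-tumoral structure;
#' background genes are independent noise. Alignment should group the shared
#' blocks into meta clusters while private blocks stay orphaned.
#'
#' @param n_datasets number of datasets (default 3).
#' @param shared_blocks number of blocks shared by all datasets (default 2).
#' @param private_blocks number of dataset-private blocks (default 1).
#' @param block_size genes per block, even (default 24).
#' @param n_background independent background genes per dataset (default 12).
#' @param n_cells cells per dataset (default 120).
#' @param n_tumors tumors per dataset (default 4).
#' @param factor_sd block-factor standard deviation (default 1); the
#'   sub-block factors use 0.8 of it.
#' @param noise_sd residual noise standard deviation (default 0.5).
#' @param seed optional integer seed.
#' @return list with `datasets` (list of `ExpressionMatrix`) and `blocks`
#'   (list of list(genes, datasets, shared)) describing the ground truth.
#' @export
simulate_hierarchy_suite <- function(n_datasets = 3, shared_blocks = 2,
                                     private_blocks = 1, block_size = 24,
                                     n_background = 12, n_cells = 120,
                                     n_tumors = 4, factor_sd = 1,
                                     noise_sd = 0.5, seed = NULL) {
  if (block_size %% 2 != 0) stop("`block_size` must be even")
  if (!is.null(seed)) set.seed(seed)
  blocks <- list()
  for (b in seq_len(shared_blocks)) {
    blocks[[length(blocks) + 1L]] <- list(
      genes = sprintf("SB%d_g%03d", b, seq_len(block_size)),
      datasets = seq_len(n_datasets), shared = TRUE)
  }
  for (d in seq_len(n_datasets)) {
    for (b in seq_len(private_blocks)) {
      blocks[[length(blocks) + 1L]] <- list(
        genes = sprintf("D%d_PB%d_g%03d", d, b, seq_len(block_size)),
        datasets = d, shared = FALSE)
    }
  }
  gene_sets <- lapply(blocks, `[[`, "genes")
  if (anyDuplicated(unlist(gene_sets))) stop("overlapping block definitions")
  datasets <- vector("list", n_datasets)
  tumor <- paste0("tumor", rep(seq_len(n_tumors), length.out = n_cells))
  for (d in seq_len(n_datasets)) {
    ds_blocks <- Filter(function(b) d %in% b$datasets, blocks)
    rows <- list()
    for (b in ds_blocks) {
      ng <- length(b$genes)
      shift <- stats::rnorm(n_tumors, sd = factor_sd)  # tumor-level component
      f_block <- shift[as.integer(factor(tumor))] +
        stats::rnorm(n_cells, sd = factor_sd)
      # dataset-specific split of the block's genes into halves
      perm <- sample(ng)
      sub_of <- integer(ng)
      sub_of[perm] <- rep(1:2, each = ng / 2)
      f_sub <- replicate(2, stats::rnorm(n_cells, sd = 0.8 * factor_sd))
      block_vals <- outer(rep(1, ng), f_block) + t(f_sub[, sub_of]) +
        matrix(stats::rnorm(ng * n_cells, sd = noise_sd), ng)
      rownames(block_vals) <- b$genes
      rows[[length(rows) + 1L]] <- block_vals
    }
    bg <- matrix(stats::rnorm(n_background * n_cells), n_background)
    rownames(bg) <- sprintf("D%d_bg_g%03d", d, seq_len(n_background))
    values <- do.call(rbind, c(rows, list(bg)))
    colnames(values) <- sprintf("D%d_cell%03d", d, seq_len(n_cells))
    datasets[[d]] <- expression_matrix(values, tumor = tumor)
  }
  list(datasets = datasets, blocks = blocks)
}

#' Simulate bulk expression with a planted coherent, prognostic gene block
#'
#' The genes of `coherent_block` share a latent factor so their pairwise
#' correlation is approximately `target_rho`; survival times follow an
#' exponential model whose per-sample log-hazard is `hazard_beta` times the
#' latent factor, with censoring at a fixed quantile of the survival times.
#' Background genes are independent noise.
#'
#' @param n_samples number of bulk samples (default 300).
#' @param coherent_block character vector of planted block gene names.
#' @param hazard_beta log-hazard coefficient of the latent factor (0 = null).
#' @param target_rho target within-block pairwise correlation (default 0.6).
#' @param n_background background genes (default 200).
#' @param censor_quantile censoring time quantile (default 0.7).
#' @param seed optional integer seed.
#' @return list with `expression` (fully observed `ExpressionMatrix`, one
#'   pseudo-tumor) and `survival` (a `SurvivalTable`).
#' @export
simulate_bulk_survival <- function(n_samples = 300,
                                   coherent_block = sprintf("blk_g%03d", 1:40),
                                   hazard_beta = 0, target_rho = 0.6,
                                   n_background = 200,
                                   censor_quantile = 0.7, seed = NULL) {
  if (!is.finite(hazard_beta)) stop("`hazard_beta` must be finite")
  if (!is.null(seed)) set.seed(seed)
  f <- stats::rnorm(n_samples)
  a <- sqrt(target_rho)
  block <- outer(rep(a, length(coherent_block)), f) +
    matrix(stats::rnorm(length(coherent_block) * n_samples,
                        sd = sqrt(1 - target_rho)),
           length(coherent_block))
  rownames(block) <- coherent_block
  bg <- matrix(stats::rnorm(n_background * n_samples), n_background)
  rownames(bg) <- sprintf("bg_g%03d", seq_len(n_background))
  values <- rbind(block, bg)
  colnames(values) <- sprintf("sample%03d", seq_len(n_samples))
  surv_time <- stats::rexp(n_samples, rate = exp(hazard_beta * f))
  cens_time <- stats::quantile(surv_time, censor_quantile)
  event <- surv_time <= cens_time
  time <- pmin(surv_time, cens_time)
  list(expression = expression_matrix(values, tumor = rep("bulk", n_samples)),
       survival = survival_table(colnames(values), time, event))
}
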