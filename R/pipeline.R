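#' Run the single-dataset analysis pipeline
#'
#' Orchestrates preprocess -> heterogeneity -> hierarchy -> reduction ->
#' annotation for one dataset and writes human-diffable intermediates (TSV /
#' JSON) to an output directory. All randomness is governed by `config$seed`.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{matrix, labels}{input paths (see [read_expression()]), or}
#'     \item{expression}{an `ExpressionMatrix` supplied directly;}
#'     \item{out_dir}{output directory;}
#'     \item{max_missing}{gene filter threshold (default 0.7);}
#'     \item{impute}{`"mean"` or `"zero"` (default `"mean"`);}
#'     \item{epsilon, n_samples}{p_diff parameters (defaults 0.05, 1e5);}
#'     \item{k_max, inherit_threshold, n_runs, subsample_frac}{hierarchy
#'       parameters (defaults 12, 0.15, 100, 0.8);}
#'     \item{entropy}{also compute the entropy baseline (default FALSE);}
#'     \item{seed}{integer seed (default 1).}
#'   }
#' @return (invisibly) a list with `report`, `hierarchy`, `reduced`, and the
#'   paths of the written artifacts.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(max_missing = 0.7, impute = "mean",
                                epsilon = 0.05, n_samples = 1e5, k_max = 12,
                                inherit_threshold = 0.15, n_runs = 100,
                                subsample_frac = 0.8, entropy = FALSE,
                                seed = 1L), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  m <- if (!is.null(cfg$expression)) cfg$expression
       else read_expression(cfg$matrix, labels = cfg$labels)
  raw <- filter_sparse_genes(m, cfg$max_missing)
  imp <- impute(raw, cfg$impute)
  report <- heterogeneity_report(imp, epsilon = cfg$epsilon,
                                 n_samples = cfg$n_samples,
                                 entropy = cfg$entropy)
  hier <- build_full_hierarchy(imp, k_max = cfg$k_max,
                               inherit_threshold = cfg$inherit_threshold,
                               n_runs = cfg$n_runs,
                               subsample_frac = cfg$subsample_frac)
  hier <- annotate_clusters(hier, imp, mask_m = raw, epsilon = cfg$epsilon,
                            n_samples = cfg$n_samples)
  reduced <- reduce_hierarchy(hier)
  reduced <- annotate_clusters(reduced, imp, mask_m = raw,
                               epsilon = cfg$epsilon,
                               n_samples = cfg$n_samples)
  paths <- list(
    report = file.path(cfg$out_dir, "heterogeneity.json"),
    hierarchy = file.path(cfg$out_dir, "hierarchy_full.json"),
    reduced = file.path(cfg$out_dir, "hierarchy_reduced.json"),
    memberships = file.path(cfg$out_dir, "cluster_members.tsv"))
  jsonlite::write_json(list(avg_nsv = report$avg_nsv, p_diff = report$p_diff,
                            nsv_per_tumor = as.list(report$nsv_per_tumor),
                            avg_entropy = report$avg_entropy,
                            epsilon = report$epsilon,
                            n_samples = report$n_samples, seed = cfg$seed),
                       paths$report, auto_unbox = TRUE, digits = NA)
  write_hierarchy(hier, paths$hierarchy)
  write_hierarchy(reduced, paths$reduced)
  mem <- do.call(rbind, lapply(names(reduced$graph$members), function(id)
    data.frame(gene = reduced$graph$members[[id]], cluster = id)))
  utils::write.table(mem, paths$memberships, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(report = report, hierarchy = hier, reduced = reduced,
                 paths = paths))
}
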