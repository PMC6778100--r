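# End-to-end orchestration: one configuration drives connectome construction,
# the density sweep with group comparisons, rich-club analysis and NBS, and a
# manifest records every parameter, seed and achieved density so a run can be
# re-executed exactly from the manifest alone.

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration with sections `simulate` (or `input`), `build`,
#' `inference`, plus top-level `control_group`, `seed` and `out`. Missing
#' values fall back to the documented defaults of the underlying functions.
#'
#' @param path YAML file.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

default_build <- function() {
  list(fisher_z = TRUE, distance_mm = 20, reference_density = 0.45,
       density_grid = c(0.10, 0.34, 0.01), apply_reference_mask = TRUE)
}

default_inference <- function() {
  list(n_perm = 1000L, q = 0.05, R = 1000L, p_primary = 0.005,
       richclub_density = 0.07, direction = "less")
}

merge_defaults <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
  }
  user
}

# Numeric covariate design (no intercept) from the subject table columns
# age, gender and site; site enters as dummy codes.
covariate_design <- function(subjects) {
  cols <- intersect(c("age", "gender", "site"), names(subjects))
  if (length(cols) == 0L) return(NULL)
  fml <- stats::as.formula(paste("~", paste(cols, collapse = " + ")))
  sub <- subjects[, cols, drop = FALSE]
  if ("site" %in% cols) sub$site <- factor(sub$site)
  mm <- stats::model.matrix(fml, data = sub)
  x <- mm[, -1L, drop = FALSE]
  # a single-site cohort contributes no site column
  x[, apply(x, 2L, function(cc) stats::sd(cc) > 0), drop = FALSE]
  }

#' Run the full connectome group-analysis pipeline
#'
#' Executes the stages in order: load or simulate the cohort; per-subject
#' correlation matrices (optional Fisher z); covariate residualization;
#' analyzable-edge mask (distance exclusion intersected with the
#' control-group positive reference mask); density sweep of topology metrics;
#' pairwise permutation group comparisons with BH-FDR across the grid;
#' group-average rich-club analysis with normalization and pairwise
#' difference tests; pairwise NBS. Writes metrics.tsv, comparisons.json,
#' richclub.json, nbs.json and manifest.json into `config$out` (when set)
#' and returns all results invisibly. Two runs with an identical
#' configuration produce byte-identical outputs.
#'
#' @param config Nested list as from [read_run_config()]. Required: either
#'   `simulate` (arguments to [cohort_config()]) or `input` (paths
#'   `timeseries_dir`, `atlas`, `subjects`); `control_group` naming the
#'   reference group; `seed`.
#' @return Invisibly, a list with `metrics`, `comparisons`, `richclub`,
#'   `nbs`, `manifest`.
#' @export
run_pipeline <- function(config) {
  build <- merge_defaults(config$build, default_build())
  inf <- merge_defaults(config$inference, default_inference())
  seed <- config$seed %||% 1L
  if (is.null(config$control_group)) {
    stop("config$control_group is required", call. = FALSE)
  }

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    if (!is.null(sim_args$groups)) sim_args$groups <- unlist(sim_args$groups)
    cfg <- do.call(cohort_config, sim_args)
    atlas <- generate_atlas(cfg$n_rois, seed = derive_seed(seed, 101L))
    cohort <- sample_cohort(cfg)
    timeseries <- cohort$timeseries
    subjects <- cohort$subjects
  } else if (!is.null(config$input)) {
    atlas <- read_atlas(config$input$atlas)
    subjects <- read_subjects(config$input$subjects)
    timeseries <- lapply(subjects$subject_id, function(id) {
      read_timeseries(file.path(config$input$timeseries_dir,
                                paste0(id, ".tsv")), atlas)
    })
    names(timeseries) <- subjects$subject_id
  } else {
    stop("config needs either a 'simulate' or an 'input' section",
         call. = FALSE)
  }
  groups <- unique(subjects$group)
  if (!config$control_group %in% groups) {
    stop("control_group '", config$control_group,
         "' not present in subject table", call. = FALSE)
  }

  # --- stage: connectome construction -------------------------------------
  matrices <- lapply(timeseries, correlation_matrix,
                     fisher_z = isTRUE(build$fisher_z))
  dmask <- distance_mask(atlas, build$distance_mm)
  hc_idx <- subjects$group == config$control_group
  ref_mask <- reference_positive_mask(matrices[hc_idx],
                                      build$reference_density)
  mask <- if (isTRUE(build$apply_reference_mask)) dmask & ref_mask else dmask
  covs <- covariate_design(subjects)
  adj_matrices <- regress_covariates(matrices, covs)
  grid <- seq(build$density_grid[1L], build$density_grid[2L],
              by = build$density_grid[3L])

  # --- stage: density sweep + group comparisons ---------------------------
  metrics <- density_sweep(adj_matrices, mask = mask, grid = grid,
                           subjects = subjects)
  pairs_of_groups <- utils::combn(groups, 2L, simplify = FALSE)
  comparisons <- list()
  for (pg in pairs_of_groups) {
    for (metric in c("assortativity", "clustering", "efficiency")) {
      key <- paste(pg[1L], "vs", pg[2L], metric, sep = "_")
      comparisons[[key]] <- sweep_group_comparison(
        metrics, metric, pg[1L], pg[2L],
        n_perm = inf$n_perm, q = inf$q,
        seed = derive_seed(seed, 200L + length(comparisons))
      )
    }
  }

  # --- stage: rich-club ----------------------------------------------------
  group_graphs <- lapply(groups, function(g) {
    group_average_graph(adj_matrices[subjects$group == g],
                        density = inf$richclub_density, mask = mask)
  })
  names(group_graphs) <- groups
  richclub <- list(
    curves = lapply(seq_along(groups), function(i) {
      normalized_rich_club(group_graphs[[i]], R = inf$R,
                           seed = derive_seed(seed, 300L + i))
    }),
    differences = lapply(seq_along(pairs_of_groups), function(i) {
      pg <- pairs_of_groups[[i]]
      richclub_group_difference(group_graphs[[pg[1L]]],
                                group_graphs[[pg[2L]]],
                                R = inf$R, q = inf$q,
                                seed = derive_seed(seed, 400L + i))
    })
  )
  names(richclub$curves) <- groups
  names(richclub$differences) <- vapply(pairs_of_groups, paste,
                                        "", collapse = "_vs_")

  # --- stage: NBS ----------------------------------------------------------
  nbs <- lapply(seq_along(pairs_of_groups), function(i) {
    pg <- pairs_of_groups[[i]]
    nbs_test(matrices, subjects$group, pg[1L], pg[2L], covariates = covs,
             mask = mask, p_primary = inf$p_primary, n_perm = inf$n_perm,
             direction = inf$direction, seed = derive_seed(seed, 500L + i))
  })
  names(nbs) <- vapply(pairs_of_groups, paste, "", collapse = "_vs_")

  manifest <- list(
    package_version = as.character(utils::packageVersion("connectostat")),
    seed = seed,
    control_group = config$control_group,
    groups = as.list(table(subjects$group)),
    build = build,
    inference = inf,
    density_grid = grid,
    comparisons = names(comparisons),
    nbs_contrasts = names(nbs),
    reference_density_achieved = attr(ref_mask, "density_achieved"),
    n_analyzable_edges = sum(mask[upper.tri(mask)])
  )

  result <- list(metrics = metrics, comparisons = comparisons,
                 richclub = richclub, nbs = nbs, manifest = manifest)
  if (!is.null(config$out)) write_pipeline_outputs(result, config$out)
  invisible(result)
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- lapply(result$comparisons, function(x) as.list(as.data.frame(x)))
  jsonlite::write_json(comp, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  rc <- list(
    curves = lapply(result$richclub$curves, function(x)
      as.list(x$curve)),
    differences = lapply(result$richclub$differences, function(x)
      as.list(as.data.frame(x)))
  )
  jsonlite::write_json(rc, file.path(dir, "richclub.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  nbs_out <- lapply(result$nbs, function(x) {
    list(t_threshold = x$t_threshold, df = x$df, n_perm = x$n_perm,
         direction = x$direction,
         components = lapply(x$components, function(cm) {
           list(nodes = cm$nodes,
                edges = apply(cm$edges, 1L, as.list, simplify = FALSE),
                extent = cm$extent, fwer_p = cm$fwer_p)
         }))
  })
  jsonlite::write_json(nbs_out, file.path(dir, "nbs.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
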