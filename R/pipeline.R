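#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end run: inputs (file paths, or a
#' [synthetic_config()] to generate them), the split strategy, preprocessing
#' thresholds, the GA / hill-climb selection settings, the SVR grid, and the
#' output directory. All seeds derive from `seed`.
#'
#' @param out_dir Output directory for the run reports.
#' @param seed Master integer seed.
#' @param synthetic A [synthetic_config()], or `NULL` when file inputs are
#'   given.
#' @param inputs When not synthetic: named list with `metabolite_table`,
#'   `descriptors` (CSV, first column metabolite_id), `reactant_pairs` (named
#'   list of per-organism TSV paths), `organism_pathways` (named list of
#'   pathway-key vectors), `pathway_membership` (TSV path).
#' @param split List: `strategy` — `"random"`, `"non_overlap"`, or both (the
#'   first is the primary; with both, a strategy-comparison table is also
#'   written) — and `n_train`.
#' @param sd_threshold,pathway_min_minority See [preprocess_features()].
#' @param ga A [ga_config()].
#' @param svr List: either `grid = TRUE` (grid search with `scheme`,
#'   `folds`) or explicit `gamma`, `epsilon`, `cost`.
#' @param scale_features Standardize descriptors before the SVR (recorded in
#'   the manifest).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            inputs = NULL,
                            split = list(strategy = "random", n_train = 91L),
                            sd_threshold = 0.001,
                            pathway_min_minority = 2L,
                            ga = ga_config(seed = seed),
                            svr = list(grid = FALSE, gamma = 0.01,
                                       epsilon = 0.20, cost = 11,
                                       scheme = "kfold", folds = 10L),
                            scale_features = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, inputs = inputs, split = split,
                 sd_threshold = sd_threshold,
                 pathway_min_minority = pathway_min_minority,
                 ga = ga, svr = svr, scale_features = scale_features),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `ga`,
#' `synthetic` and `svr` are nested maps passed to their constructors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  syn <- if (!is.null(y$synthetic)) {
    args <- y$synthetic
    if (isTRUE(args)) args <- list()
    if (!is.null(args$organisms)) args$organisms <- unlist(args$organisms)
    if (!is.null(args$informative)) args$informative <- unlist(args$informative)
    if (is.null(args$seed)) args$seed <- seed
    do.call(synthetic_config, args)
  } else NULL
  ga_args <- if (!is.null(y$ga)) y$ga else list()
  if (!is.null(ga_args$regressor))
    ga_args$regressor <- fitness_regressor(ga_args$regressor)
  if (is.null(ga_args$seed)) ga_args$seed <- seed
  pipeline_config(
    out_dir = y$out_dir, seed = seed, synthetic = syn, inputs = y$inputs,
    split = if (!is.null(y$split)) y$split else list(strategy = "random",
                                                     n_train = 91L),
    sd_threshold = if (!is.null(y$sd_threshold)) y$sd_threshold else 0.001,
    pathway_min_minority = if (!is.null(y$pathway_min_minority))
      y$pathway_min_minority else 2L,
    ga = do.call(ga_config, ga_args),
    svr = if (!is.null(y$svr)) y$svr else list(grid = FALSE, gamma = 0.01,
                                               epsilon = 0.20, cost = 11,
                                               scheme = "kfold", folds = 10L),
    scale_features = isTRUE(y$scale_features))
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    study <- generate_synthetic(cfg$synthetic)
    return(list(dataset = study$dataset, molecular = study$molecular,
                networks = study$networks, members = study$members,
                pathways = study$pathways, study = study,
                files = character(0)))
  }
  inp <- cfg$inputs
  if (is.null(inp)) stop("pipeline_config has neither synthetic nor file inputs",
                         call. = FALSE)
  dataset <- read_metabolite_table(inp$metabolite_table)
  raw <- utils::read.csv(inp$descriptors, check.names = FALSE,
                         stringsAsFactors = FALSE)
  molecular <- as.matrix(raw[, -1, drop = FALSE])
  rownames(molecular) <- as.character(raw[[1]])
  members <- read_pathway_membership(inp$pathway_membership)
  pathways <- sort(unique(unlist(members)))
  networks <- lapply(names(inp$reactant_pairs), function(o) {
    pairs <- read_reactant_pairs(inp$reactant_pairs[[o]])
    opw <- if (!is.null(inp$organism_pathways[[o]])) inp$organism_pathways[[o]]
           else unique(unlist(pairs$pathway_ids))
    reconstruct_network(pairs, opw)
  })
  names(networks) <- names(inp$reactant_pairs)
  list(dataset = dataset, molecular = molecular, networks = networks,
       members = members, pathways = pathways, study = NULL,
       files = unlist(inp[c("metabolite_table", "descriptors",
                            "pathway_membership")], use.names = FALSE))
}

apply_split <- function(dataset, strategy, n_train, seed) {
  switch(strategy,
         random = split_random(dataset, n_train, seed),
         non_overlap = split_non_overlap(dataset, n_train, seed),
         stop(sprintf("unknown split strategy '%s'", strategy), call. = FALSE))
}

resolve_svr_cfg <- function(svr, X_train, y_train, seed, scale) {
  if (isTRUE(svr$grid)) {
    grid <- if (!is.null(svr$grid_table)) svr$grid_table else default_svr_grid()
    scheme <- if (!is.null(svr$scheme)) svr$scheme else "kfold"
    gs <- grid_search(X_train, y_train, grid = grid, scheme = scheme,
                      folds = if (!is.null(svr$folds)) svr$folds else 10L,
                      seed = seed, scale = scale)
    gs$best
  } else {
    svr_config(gamma = svr$gamma, epsilon = svr$epsilon, cost = svr$cost)
  }
}

validation_row <- function(vr, label) {
  data.frame(strategy = label, n_train = vr$n_train, m = vr$m,
             r2_train = vr$r2_train,
             rmse_10fold = vr$rmse_10fold, q2_10fold = vr$q2_10fold,
             rmse_loo = vr$rmse_loo, q2_loo = vr$q2_loo,
             r2_test = if (!is.null(vr$r2_test)) vr$r2_test else NA_real_,
             rmse_test = if (!is.null(vr$rmse_test)) vr$rmse_test else NA_real_,
             q2_test = if (!is.null(vr$q2_test)) vr$q2_test else NA_real_,
             error_variance_loo = vr$error_variance_loo,
             error_variance_test = if (!is.null(vr$error_variance_test))
               vr$error_variance_test else NA_real_,
             stringsAsFactors = FALSE)
}

#' Run the full modelling pipeline
#'
#' Network reconstruction (or synthetic generation), feature assembly and
#' preprocessing, training/test split, GA + hill-climb variable selection on
#' the training set, collapse of surviving pathway variables into the MPF
#' descriptor, SVR hyperparameter resolution, internal (10-fold, LOO) and
#' external validation, leverage-based applicability domain, and descriptive
#' reports — all written under `cfg$out_dir` together with a JSON manifest.
#' Reruns with an identical configuration produce byte-identical reports.
#'
#' @param cfg A [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the key in-memory results (`subset`,
#'   `validation`, `leverage`, `trace`, `svr_cfg`, `paths`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "inputs"
  res <- tryCatch({
    inp <- load_pipeline_inputs(cfg)
    seeds <- with_seed(cfg$seed,
                       as.list(stats::setNames(
                         sample.int(.Machine$integer.max - 1L, 4L),
                         c("split", "cv", "ga", "extra"))))

    stage <- "features"
    X <- assemble_features(inp$dataset, inp$molecular,
                           topology = inp$networks,
                           pathway = inp$members, pathways = inp$pathways)
    prep <- preprocess_features(X, sd_threshold = cfg$sd_threshold,
                                pathway_min_minority = cfg$pathway_min_minority)
    Xp <- prep$matrix
    y <- inp$dataset$neg_log_c

    stage <- "split"
    strategies <- cfg$split$strategy
    primary <- strategies[1L]
    dataset <- apply_split(inp$dataset, primary, cfg$split$n_train,
                           seeds$split)
    tr <- dataset$split == "train"

    stage <- "selection"
    ga_cfg <- cfg$ga
    sel <- select_variables(colnames(Xp), Xp[tr, , drop = FALSE], y[tr],
                            cfg = ga_cfg,
                            svr_cfg = svr_config(
                              gamma = if (!is.null(cfg$svr$gamma)) cfg$svr$gamma else 0.01,
                              epsilon = if (!is.null(cfg$svr$epsilon)) cfg$svr$epsilon else 0.2,
                              cost = if (!is.null(cfg$svr$cost)) cfg$svr$cost else 11),
                            cv_seed = seeds$cv)
    col <- collapse_pathways_to_mpf(sel$subset$members, Xp)
    members <- col$members
    Xm <- col$matrix

    stage <- "model"
    svr_cfg <- resolve_svr_cfg(cfg$svr, Xm[tr, members, drop = FALSE], y[tr],
                               seeds$cv, cfg$scale_features)
    vr <- validation_report(Xm[tr, members, drop = FALSE], y[tr],
                            Xm[!tr, members, drop = FALSE], y[!tr],
                            cfg = svr_cfg, seed = seeds$cv,
                            scale = cfg$scale_features)

    stage <- "applicability_domain"
    lev <- williams_data(vr$fit, Xm[tr, members, drop = FALSE], y[tr],
                         Xm[!tr, members, drop = FALSE], y[!tr],
                         ids = rownames(Xm)[c(which(tr), which(!tr))])

    stage <- "reports"
    paths <- c(selection_trace = file.path(cfg$out_dir, "selection_trace.tsv"),
               subset = file.path(cfg$out_dir, "selected_variables.txt"),
               validation = file.path(cfg$out_dir, "validation_report.tsv"),
               leverage = file.path(cfg$out_dir, "leverage_report.tsv"),
               dataset = file.path(cfg$out_dir, "dataset_with_split.tsv"),
               manifest = file.path(cfg$out_dir, "manifest.json"))
    write_selection_trace(sel$trace, paths[["selection_trace"]])
    write_subset(members, paths[["subset"]])
    val_rows <- validation_row(vr, primary)
    write_leverage_report(lev, paths[["leverage"]])
    write_metabolite_table(dataset, paths[["dataset"]])

    # tertile report per organism with >= 3 records
    for (o in unique(inp$dataset$organism)) {
      if (sum(inp$dataset$organism == o) < 3L) next
      p <- file.path(cfg$out_dir, sprintf("tertile_report_%s.tsv", o))
      write_tsv_det(tertile_cluster_report(inp$dataset, inp$networks[[o]], o), p)
      paths[[paste0("tertile_", o)]] <- p
    }
    # CLogP bin report when a ClogP column exists
    if ("ClogP" %in% colnames(inp$molecular)) {
      clogp <- stats::setNames(inp$molecular[, "ClogP"], rownames(inp$molecular))
      rep_ <- tryCatch(clogp_bin_report(inp$dataset, clogp),
                       error = function(e) NULL)
      if (!is.null(rep_)) {
        p <- file.path(cfg$out_dir, "clogp_bins.tsv")
        write_tsv_det(cbind(rep_$bins, fit_r_squared = rep_$r_squared), p)
        paths[["clogp_bins"]] <- p
      }
      # pathway-deviation table over the metabolites behind the MPF column
      if (length(col$selected_pathways)) {
        mem_ids <- unique(inp$dataset$metabolite_id[
          build_mpf(inp$members, col$selected_pathways,
                    inp$dataset$metabolite_id) == 1])
        if (length(mem_ids)) {
          pd <- pathway_deviation_table(inp$dataset, mem_ids, clogp)
          p <- file.path(cfg$out_dir, "pathway_deviation.tsv")
          write_tsv_det(pd$members, p)
          paths[["pathway_deviation"]] <- p
        }
      }
    }
    # optional second-strategy comparison on the same selected variables
    if (length(strategies) > 1L) {
      rows <- val_rows
      for (s in strategies[-1L]) {
        ds2 <- apply_split(inp$dataset, s, cfg$split$n_train, seeds$split)
        tr2 <- ds2$split == "train"
        cfg2 <- resolve_svr_cfg(cfg$svr, Xm[tr2, members, drop = FALSE],
                                y[tr2], seeds$cv, cfg$scale_features)
        vr2 <- validation_report(Xm[tr2, members, drop = FALSE], y[tr2],
                                 Xm[!tr2, members, drop = FALSE], y[!tr2],
                                 cfg = cfg2, seed = seeds$cv,
                                 scale = cfg$scale_features)
        rows <- rbind(rows, validation_row(vr2, s))
      }
      p <- file.path(cfg$out_dir, "split_strategy_comparison.tsv")
      write_tsv_det(rows, p)
      paths[["strategy_comparison"]] <- p
    }
    write_tsv_det(val_rows, paths[["validation"]])
    write_run_manifest(paths[["manifest"]],
                       seeds = c(list(master = cfg$seed), seeds),
                       files = inp$files,
                       counts = list(n_records = nrow(inp$dataset),
                                     n_descriptors_assembled = ncol(X),
                                     n_descriptors_kept = ncol(Xp),
                                     n_selected = length(members),
                                     n_train = sum(tr), n_test = sum(!tr)),
                       extra = list(split_strategy = primary,
                                    scale_features = cfg$scale_features,
                                    svr = unclass(svr_cfg),
                                    selected_variables = members,
                                    filter_report = prep$report))
    list(subset = members, validation = vr, leverage = lev,
         trace = sel$trace, svr_cfg = svr_cfg, selection = sel,
         paths = paths)
  }, error = function(e) {
    stop(sprintf("[metaconc:%s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
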