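#' Build a validated pipeline configuration
#'
#' A configuration drives one end-to-end analysis: either a dataset
#' manifest (real identification lists) or a simulation block (synthetic
#' data with ground truth), plus the averaging policy, thresholds,
#' presence stringency, optional annotation/edge tables, output directory
#' and seed. Exactly one of `manifest` / `simulation` must be present.
#'
#' @param config a named list, typically parsed from a YAML file by
#'   [read_pipeline_config()]. Recognized keys: `manifest` (path) or
#'   `simulation` (list of [generate_ground_truth()] / [sim_design()]
#'   arguments), `reference` (default "WT"), `policy`, `nested`,
#'   `min_unique`, `thresholds` (list with `t_dave`, `t_dci`), `min_runs`,
#'   `annotation` (path), `edges` (path), `min_score`, `out_dir`, `seed`,
#'   and `benchmark` (see [run_recovery_benchmark()]).
#' @return The completed configuration, class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(reference = "WT", policy = "zeros_included",
                   nested = FALSE, min_unique = 1L,
                   thresholds = list(t_dave = 0.4, t_dci = 5),
                   min_runs = 1L, min_score = 0.4,
                   out_dir = "spcompare_out", seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  has_manifest <- !is.null(config$manifest)
  has_sim <- !is.null(config$simulation)
  if (has_manifest == has_sim) {
    stop("config must contain exactly one of 'manifest' or 'simulation'",
         call. = FALSE)
  }
  config$thresholds <- spc_thresholds(config$thresholds$t_dave,
                                      config$thresholds$t_dci)
  structure(config, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  pipeline_config(yaml::read_yaml(path))
}

# run expr, prefixing any error with the pipeline stage name
.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

.sim_args <- function(fn, block, extra = list()) {
  args <- block[intersect(names(block), names(formals(fn)))]
  do.call(fn, utils::modifyList(args, extra))
}

#' Run the full differential analysis pipeline
#'
#' Executes ingest (or simulate) -> align -> average -> pairwise compare ->
#' report from a single configuration. Writes to the output directory: the
#' aligned count matrix, per-strain aSpC profiles, one comparison TSV per
#' reference-vs-strain pair, the Venn partition summary, the color-coded
#' differential table, node/edge network tables when an edge table is
#' supplied, a run log with per-stage row counts, and the resolved
#' configuration. Reruns with the same configuration and seed give
#' identical numeric outputs.
#'
#' @param config a [pipeline_config()], or a path to a YAML config file.
#' @param out_dir optional override of the configured output directory.
#' @return Invisibly, a list with the in-memory objects: `runs`, `matrix`,
#'   `profile`, `comparisons`, `venn`, `table`, `network` (if edges
#'   given), `ground_truth` (if simulated), and `out_dir`.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  log("spcompare %s | seed %d | thresholds DAve %.3g DCI %.3g | policy %s",
      as.character(utils::packageVersion("spcompare")), config$seed,
      config$thresholds$t_dave, config$thresholds$t_dci, config$policy)

  ingested <- .with_stage("ingest", {
    if (!is.null(config$manifest)) {
      rr <- read_manifest(config$manifest,
                          min_unique = config$min_unique)
      log("read %d runs from manifest %s", length(rr), config$manifest)
      list(runs = rr, gt = NULL)
    } else {
      sim <- config$simulation
      gt <- .sim_args(generate_ground_truth, sim,
                      list(seed = config$seed))
      design <- .sim_args(sim_design, sim,
                          list(seed = config$seed + 1L))
      rr <- simulate_runs(gt, design)
      rr <- lapply(rr, filter_min_unique_peptides, config$min_unique)
      log("simulated %d runs (%d proteins, %d planted differential per drawn mutant)",
          length(rr), nrow(gt$proteins),
          floor(nrow(gt$proteins) * (sim$prop_diff %||% 0.15)))
      list(runs = rr, gt = gt)
    }
  })
  runs <- ingested$runs
  gt <- ingested$gt
  log("proteins per run after unique-peptide filter (>= %d): %s",
      config$min_unique,
      paste(vapply(runs, function(r) nrow(r$records), integer(1)),
            collapse = ", "))

  mat <- .with_stage("align", align_lists(runs))
  log("aligned %d distinct proteins x %d runs", nrow(mat$counts),
      ncol(mat$counts))
  profile <- .with_stage("average",
                         average_strain_profiles(mat,
                                                 policy = config$policy,
                                                 nested = config$nested))

  strains <- unique(mat$runs$strain)
  others <- setdiff(strains, config$reference)
  comparisons <- .with_stage("compare", {
    cmp <- lapply(others, function(s) {
      compare_strains(profile, config$reference, s,
                      th = config$thresholds)
    })
    names(cmp) <- paste0(config$reference, "_vs_", others)
    cmp
  })
  for (nm in names(comparisons)) {
    cnt <- significance_counts(comparisons[[nm]])
    log("%s: %d significant (%d up in %s, %d up in mutant) of %d comparable",
        nm, cnt[["significant"]], cnt[["up_in_x"]], config$reference,
        cnt[["up_in_y"]], cnt[["comparable"]])
  }

  venn <- .with_stage("venn", {
    venn_partition(presence_sets(mat, min_runs = config$min_runs),
                   reference = config$reference)
  })
  log("venn: %d in union, %d shared with %s, %d absent (%s vs %s of union)",
      venn$union_size, venn$with_reference, config$reference,
      venn$absent_from_reference,
      format_percent(venn$with_reference, venn$union_size),
      format_percent(venn$absent_from_reference, venn$union_size))

  ann <- NULL
  if (!is.null(config$annotation)) {
    ann <- .with_stage("annotation",
                       read_annotation_table(config$annotation))
  }
  diff_table <- .with_stage("table",
                            build_differential_table(comparisons, ann))
  log("differential table: %d proteins significant in >= 1 comparison",
      nrow(diff_table))

  network <- NULL
  if (!is.null(config$edges)) {
    network <- .with_stage("network", {
      edges <- utils::read.delim(config$edges, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      export_network(diff_table, edges, min_score = config$min_score)
    })
    log("network: %d nodes, %d edges at confidence >= %.2g",
        nrow(network$nodes), nrow(network$edges), config$min_score)
  }

  .with_stage("write", {
    out <- config$out_dir
    write_counts_tsv(mat, file.path(out, "aligned_matrix.tsv"))
    write_counts_tsv(profile, file.path(out, "strain_profiles.tsv"))
    for (nm in names(comparisons)) {
      write_comparison_tsv(comparisons[[nm]],
                           file.path(out, paste0("comparison_", nm,
                                                 ".tsv")),
                           annotations = ann)
    }
    write_venn_tsv(venn, file.path(out, "venn_summary.tsv"))
    utils::write.table(diff_table,
                       file.path(out, "differential_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    if (!is.null(network)) {
      utils::write.table(network$nodes,
                         file.path(out, "network_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(network$edges,
                         file.path(out, "network_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(gt)) {
      write_ground_truth_tsv(gt, file.path(out, "ground_truth.tsv"))
    }
    resolved <- unclass(config)
    resolved$thresholds <- list(t_dave = config$thresholds$t_dave,
                                t_dci = config$thresholds$t_dci)
    yaml::write_yaml(resolved, file.path(out, "config_resolved.yaml"))
    writeLines(log_lines, file.path(out, "run_log.txt"))
  })

  invisible(list(runs = runs, matrix = mat, profile = profile,
                 comparisons = comparisons, venn = venn,
                 table = diff_table, network = network,
                 ground_truth = gt, out_dir = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recovery benchmark over a fold-by-abundance grid
#'
#' For every combination of fold factor, baseline abundance and seed,
#' simulates a two-strain experiment (reference plus one mutant) with all
#' proteins at the given baseline, plants differential proteins at the
#' given fold (direction randomized), runs the full align -> average ->
#' DAve/DCI pipeline, and scores recovery against the ground truth. A fold
#' of 1 gives a pure null dataset (false-positive-rate calibration).
#'
#' @param folds numeric vector of fold factors (1 allowed, meaning null).
#' @param lambdas numeric vector of baseline expected spectral counts.
#' @param seeds integer vector of simulation seeds.
#' @param n_proteins proteins per dataset.
#' @param prop_diff fraction planted differential (ignored for fold 1).
#' @param bio_reps,tech_reps replicates per strain.
#' @param noise,dispersion,dropout,dropout_scale,bio_sd see [sim_design()].
#' @param th an [spc_thresholds()].
#' @param policy averaging policy, see [average_strain_profiles()].
#' @return data.frame with one row per (fold, lambda, seed):
#'   `sensitivity`, `fdp`, `fpr`, `n_true_diff`, `n_significant`,
#'   `n_null_comparable`.
#' @export
recovery_grid <- function(folds, lambdas, seeds, n_proteins = 200L,
                          prop_diff = 0.5, bio_reps = 2L, tech_reps = 2L,
                          noise = "poisson", dispersion = 0.05,
                          dropout = TRUE, dropout_scale = 3, bio_sd = 0,
                          th = spc_thresholds(),
                          policy = "zeros_included") {
  grid <- expand.grid(fold = folds, lambda = lambdas, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fold <- grid$fold[i]
    lambda <- grid$lambda[i]
    seed <- grid$seed[i]
    null_only <- fold <= 1
    gt <- generate_ground_truth(
      n_proteins = n_proteins,
      prop_diff = if (null_only) 0 else prop_diff,
      fold_range = if (null_only) c(1.5, 1.5) else c(fold, fold),
      baseline_meanlog = log(lambda), baseline_sdlog = 0,
      strains = c("WT", "mut"), reference = "WT",
      product_strain = NULL, seed = seed
    )
    design <- sim_design(strains = c("WT", "mut"), bio_reps = bio_reps,
                         tech_reps = tech_reps, noise = noise,
                         dispersion = dispersion, dropout = dropout,
                         dropout_scale = dropout_scale, bio_sd = bio_sd,
                         seed = seed + 1L)
    runs <- simulate_runs(gt, design)
    profile <- average_strain_profiles(align_lists(runs), policy = policy)
    cmp <- compare_strains(profile, "WT", "mut", th = th)
    met <- evaluate_recovery(cmp, gt, mutant = "mut")
    data.frame(fold = fold, lambda = lambda, seed = seed,
               sensitivity = met$sensitivity, fdp = met$fdp,
               fpr = met$fpr, n_true_diff = met$n_true_diff,
               n_significant = met$n_significant,
               n_null_comparable = met$n_null_comparable)
  })
  do.call(rbind, rows)
}

#' Run the configured recovery benchmark and write its tables
#'
#' Reads the `benchmark` block of the configuration (`folds`, `lambdas`,
#' `seeds`, `n_proteins`, `prop_diff`; replicate structure and noise come
#' from the `simulation` block) and writes two TSVs to the output
#' directory: the per-cell results and a per-(fold, lambda) summary
#' averaged over seeds (sensitivity is reported as `NA` for null-only
#' cells).
#'
#' @param config a [pipeline_config()] (or YAML path) containing a
#'   `simulation` block.
#' @param out_dir optional override of the configured output directory.
#' @return Invisibly, list with `cells` and `summary` data.frames.
#' @export
run_recovery_benchmark <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$simulation)) {
    stop("benchmark requires a simulation block in the config",
         call. = FALSE)
  }
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulation
  bm <- config$benchmark %||% list()
  cells <- recovery_grid(
    folds = bm$folds %||% c(1, 2, 3),
    lambdas = bm$lambdas %||% c(20, 50, 100),
    seeds = bm$seeds %||% (config$seed + seq_len(20L) - 1L),
    n_proteins = bm$n_proteins %||% 200L,
    prop_diff = bm$prop_diff %||% 0.5,
    bio_reps = sim$bio_reps %||% 2L, tech_reps = sim$tech_reps %||% 2L,
    noise = sim$noise %||% "poisson",
    dispersion = sim$dispersion %||% 0.05,
    dropout = sim$dropout %||% TRUE,
    dropout_scale = sim$dropout_scale %||% 3,
    bio_sd = sim$bio_sd %||% 0,
    th = config$thresholds, policy = config$policy
  )
  agg <- stats::aggregate(cells[c("sensitivity", "fdp", "fpr")],
                          by = cells[c("fold", "lambda")],
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg$sensitivity[is.nan(agg$sensitivity)] <- NA_real_
  utils::write.table(cells, file.path(config$out_dir,
                                      "benchmark_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(agg, file.path(config$out_dir,
                                    "benchmark_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cells = cells, summary = agg))
}
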