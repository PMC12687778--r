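#' Run the end-to-end saliency-network analysis pipeline
#'
#' Executes simulate -> train (feature model + optional head comparison +
#' kNN/SVM hybrids) -> saliency -> region aggregation -> correlation
#' networks (cortical-cortical and subcortical-involving scopes, full
#' threshold sweep) -> functional-network involvement -> score-region
#' correlations -> hemisphere and average/STD statistics -> control
#' congruence, writing TSV/JSON/GraphML outputs plus a run manifest with
#' content digests.
#'
#' @param config a configuration list, or the path to a JSON file holding
#'   one. Recognised blocks: `seed` (integer, reused by every stage);
#'   `cohort` (arguments of [cohort_config()]) *or* `inputs` (paths:
#'   `volumes` directory of per-subject NIfTI files, `atlas_labels`,
#'   `atlas_regions`, `phenotypes`); `model` (arguments of
#'   [model_config()]; the pipeline model uses a feature head); `train`
#'   (`epochs`, `batch_size`, `lr`, `test_n`); `network` (`alpha`,
#'   `thresholds`, `top_n`, `top_edges_n`); flags `compare_heads` and
#'   `save_model`.
#' @param out_dir output directory (created if needed).
#' @param stages optional character subset of
#'   `c("simulate", "train", "saliency", "corrnet", "networks",
#'   "phenotype", "report")` for partial reruns on an existing run
#'   directory; stages later in the order are recomputed from the on-disk
#'   artifacts of earlier ones.
#' @return The output directory, invisibly; side effect: files under
#'   `out_dir` including `manifest.json` and `report.txt`.
#' @export
run_pipeline <- function(config, out_dir, stages = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  all_stages <- c("simulate", "train", "saliency", "corrnet", "networks",
                  "phenotype", "report")
  stages <- if (is.null(stages)) all_stages else match.arg(stages,
                                                           all_stages,
                                                           several.ok = TRUE)
  if (is.null(config$cohort) && is.null(config$inputs)) {
    stop_salnet("pipeline configuration needs either a 'cohort' block ",
                "(synthetic generation) or an 'inputs' block (paths)",
                class = "salnet_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  timing <- list()
  state <- new.env(parent = emptyenv())
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    on.exit(timing[[name]] <<- as.numeric(Sys.time() - t0, units = "secs"))
    tryCatch(expr, error = function(e) {
      stop_salnet("pipeline stage '", name, "' failed: ",
                  conditionMessage(e), class = "salnet_stage_error")
    })
  }

  # ---- simulate / load -----------------------------------------------------
  if ("simulate" %in% stages) {
    t_stage("simulate", {
      if (!is.null(config$cohort)) {
        cc <- do.call(cohort_config,
                      c(config$cohort, list(seed = seed)))
        cohort <- generate_cohort(cc)
      } else {
        inp <- config$inputs
        atlas <- read_atlas(inp$atlas_labels, inp$atlas_regions)
        records <- read_phenotypes(inp$phenotypes)
        files <- list.files(inp$volumes, pattern = "\\.nii(\\.gz)?$",
                            full.names = TRUE)
        volumes <- lapply(files, read_volume)
        names(volumes) <- sub("\\.nii(\\.gz)?$", "", basename(files))
        cohort <- list(records = records, volumes = volumes, atlas = atlas,
                       truth = NULL)
      }
      state$cohort <- cohort
      write_phenotypes(cohort$records, file.path(out_dir, "phenotypes.tsv"))
      write_atlas(cohort$atlas, file.path(out_dir, "atlas_labels.nii.gz"),
                  file.path(out_dir, "atlas_regions.tsv"))
    })
  } else {
    state$cohort <- NULL
  }

  get_atlas <- function() {
    if (!is.null(state$cohort)) return(state$cohort$atlas)
    read_atlas(file.path(out_dir, "atlas_labels.nii.gz"),
               file.path(out_dir, "atlas_regions.tsv"))
  }
  get_records <- function() {
    if (!is.null(state$cohort)) return(state$cohort$records)
    read_phenotypes(file.path(out_dir, "phenotypes.tsv"))
  }

  # ---- train ---------------------------------------------------------------
  if ("train" %in% stages) {
    t_stage("train", {
      cohort <- state$cohort
      if (is.null(cohort)) {
        stop_salnet("the train stage needs volumes in memory; include ",
                    "'simulate' in the stages", class = "salnet_config_error")
      }
      tr <- config$train %||% list()
      sp <- make_split(cohort$records, test_n = tr$test_n %||% 31L,
                       seed = seed)
      spec <- train_spec(sp$train_ids, sp$test_ids,
                         epochs = tr$epochs %||% 10L,
                         batch_size = tr$batch_size %||% 8L,
                         lr = tr$lr %||% 1e-3, seed = seed)
      mc <- config$model %||% list()
      cfg <- model_config(
        dimensionality = 3,
        depth_preset = mc$depth_preset %||% "small",
        width_scale = mc$width_scale %||% 1,
        head = "feature",
        feature_dim = mc$feature_dim %||% 64L,
        activation = mc$activation %||% "energy",
        seed = seed
      )
      fit <- severity_cnn(cohort$volumes, cohort$records, spec, config = cfg)
      knn <- hybrid_classify(fit, cohort$volumes, cohort$records, spec,
                             head = "knn", k = config$knn_k %||% 5L)
      svm <- hybrid_classify(fit, cohort$volumes, cohort$records, spec,
                             head = "svm")
      acc <- list(feature_softmax = fit$result$accuracy,
                  hybrid_knn = knn$result$accuracy,
                  hybrid_svm = svm$result$accuracy)
      if (isTRUE(config$compare_heads)) {
        hc <- compare_heads(cohort$volumes, cohort$records, spec,
                            base_config = model_config(
                              dimensionality = 3,
                              depth_preset = cfg$depth_preset,
                              width_scale = cfg$width_scale,
                              activation = cfg$activation %||% "energy",
                              seed = seed))
        acc$heads <- stats::setNames(as.list(hc$accuracy), hc$head)
      }
      controls <- cohort$records$subject_id[cohort$records$group ==
                                              "control"]
      if (length(controls)) {
        acc$control_low_fraction <-
          classify_controls(knn, cohort$volumes[controls])
      }
      state$fit <- fit
      state$spec <- spec
      jsonlite::write_json(
        list(split = sp, accuracies = acc),
        file.path(out_dir, "classifier.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE
      )
      utils::write.table(fit$history, file.path(out_dir, "history.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (isTRUE(config$save_model)) {
        saveRDS(fit, file.path(out_dir, "model.rds"))
      }
    })
  }

  # ---- saliency ------------------------------------------------------------
  if ("saliency" %in% stages) {
    t_stage("saliency", {
      cohort <- state$cohort
      fit <- state$fit
      if (is.null(cohort) || is.null(fit)) {
        stop_salnet("the saliency stage needs the trained model in memory; ",
                    "include 'simulate' and 'train' in the stages",
                    class = "salnet_config_error")
      }
      maps <- saliency_maps(fit, cohort$volumes)
      mat <- region_mean_saliency(maps, cohort$atlas, cohort$records)
      state$mat <- mat
      df <- data.frame(subject_id = mat$subject_ids, group = mat$groups,
                       mat$values, check.names = FALSE)
      utils::write.table(df, file.path(out_dir, "region_saliency.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  get_matrix <- function() {
    if (!is.null(state$mat)) return(state$mat)
    df <- utils::read.delim(file.path(out_dir, "region_saliency.tsv"),
                            check.names = FALSE)
    values <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(values) <- df$subject_id
    structure(list(values = values, subject_ids = df$subject_id,
                   region_ids = as.integer(colnames(values)),
                   groups = df$group),
              class = "region_saliency_matrix")
  }

  net_cfg <- config$network %||% list()
  thresholds <- net_cfg$thresholds %||% seq(0.1, 0.6, by = 0.1)
  alpha <- net_cfg$alpha %||% 0.01
  top_n <- net_cfg$top_n %||% 50L

  # ---- correlation networks ------------------------------------------------
  if ("corrnet" %in% stages) {
    t_stage("corrnet", {
      mat <- get_matrix()
      atlas <- get_atlas()
      edges_cc <- pairwise_region_correlations(mat, atlas,
                                               scope = "cortical-cortical")
      edges_cs <- pairwise_region_correlations(mat, atlas,
                                               scope = "cortical-subcortical")
      utils::write.table(edges_cc, file.path(out_dir, "edges_cortical.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(edges_cs,
                         file.path(out_dir, "edges_subcortical.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      g04 <- filter_edges(edges_cc, atlas, alpha = alpha,
                          tau_threshold = 0.4)
      write_correlation_graph(g04,
                              file.path(out_dir, "graph_cc_tau04.graphml"),
                              file.path(out_dir, "graph_cc_tau04_edges.tsv"))
      top <- top_edges(edges_cc[edges_cc$p < alpha, ],
                       n = net_cfg$top_edges_n %||% 500L)
      utils::write.table(top, file.path(out_dir, "top_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sweep_counts <- vapply(thresholds, function(th) {
        nrow(filter_edges(edges_cc, atlas, alpha = alpha,
                          tau_threshold = th)$edges)
      }, numeric(1))
      g04_cs <- filter_edges(edges_cs, atlas, alpha = alpha,
                             tau_threshold = 0.4)
      comp_cc <- composition_stats(g04)
      comp_cs <- composition_stats(g04_cs)
      jsonlite::write_json(
        list(thresholds = thresholds, edge_counts = sweep_counts,
             composition_cortical = unclass(comp_cc),
             composition_subcortical = unclass(comp_cs)),
        file.path(out_dir, "corrnet_summary.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE
      )
      state$edges_cc <- edges_cc
    })
  }

  get_edges_cc <- function() {
    if (!is.null(state$edges_cc)) return(state$edges_cc)
    e <- utils::read.delim(file.path(out_dir, "edges_cortical.tsv"))
    structure(e, scope = "cortical-cortical",
              class = c("correlation_edges", "data.frame"))
  }

  # ---- hub ranking + involvement -------------------------------------------
  if ("networks" %in% stages) {
    t_stage("networks", {
      mat <- get_matrix()
      atlas <- get_atlas()
      hubs <- hub_ranking(mat, atlas, thresholds = thresholds,
                          top_n = top_n, alpha = alpha,
                          edges = get_edges_cc())
      for (nm in names(hubs$per_threshold)) {
        utils::write.table(hubs$per_threshold[[nm]],
                           file.path(out_dir, paste0("hubs_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      utils::write.table(hubs$averaged,
                         file.path(out_dir, "hubs_averaged.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      inv04 <- network_involvement(
        hubs$per_threshold[["tau_0.4"]] %||% hubs$per_threshold[[1]],
        atlas, threshold_label = "tau_0.4")
      avg <- averaged_involvement(mat, atlas, hubs = hubs)
      utils::write.table(inv04, file.path(out_dir, "involvement_tau04.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(avg,
                         file.path(out_dir, "involvement_averaged.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  # ---- phenotype statistics ------------------------------------------------
  if ("phenotype" %in% stages) {
    t_stage("phenotype", {
      mat <- get_matrix()
      atlas <- get_atlas()
      records <- get_records()
      srt <- score_region_correlations(mat, records, atlas)
      utils::write.table(srt$table, file.path(out_dir, "score_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts <- as.data.frame.matrix(srt$hemisphere_counts)
      counts <- cbind(subscore = rownames(counts), counts)
      utils::write.table(counts,
                         file.path(out_dir, "score_region_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hs <- hemisphere_summary(mat, atlas)
      grid <- avg_std_grid(mat, atlas)
      cong <- if (any(mat$groups == "control")) {
        unclass(control_congruence(mat))[c("r", "slope", "intercept",
                                           "n_regions")]
      } else {
        NULL
      }
      jsonlite::write_json(
        list(hemisphere = unclass(hs),
             avg_std = list(r = grid$r, slope = grid$slope,
                            shapiro_w = grid$shapiro_w,
                            shapiro_p = grid$shapiro_p),
             control_congruence = cong),
        file.path(out_dir, "phenotype_stats.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE
      )
    })
  }

  # ---- manifest + report ---------------------------------------------------
  files <- setdiff(list.files(out_dir), c("manifest.json", "report.txt"))
  digests <- tools::md5sum(file.path(out_dir, files))
  names(digests) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("salnet")),
    seed = seed,
    config = config,
    stages_run = stages,
    files = as.list(digests),
    timing_seconds = timing
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if ("report" %in% stages) {
    writeLines(pipeline_report(out_dir), file.path(out_dir, "report.txt"))
  }
  invisible(out_dir)
}

read_json_if <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else NULL
}

#' Human-readable summary of a completed pipeline run
#'
#' Regenerates the headline tables of a run from its on-disk TSV/JSON
#' artifacts alone: classifier and hybrid accuracies, the most salient
#' regions, threshold-averaged hub and network-involvement tables, the
#' score-region correlation counts, the hemisphere comparison, and the
#' control-congruence block (marked absent when the run had no controls).
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
pipeline_report <- function(run_dir) {
  need <- c("classifier.json", "region_saliency.tsv",
            "involvement_averaged.tsv", "score_region_counts.tsv",
            "phenotype_stats.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop_salnet("incomplete run; missing stages for: ",
                paste(missing, collapse = ", "),
                class = "salnet_config_error")
  }
  cls <- read_json_if(file.path(run_dir, "classifier.json"))
  lines <- c("== Classifier performance ==")
  acc <- cls$accuracies
  lines <- c(lines,
             sprintf("  feature-model softmax accuracy: %.4f",
                     acc$feature_softmax),
             sprintf("  hybrid kNN accuracy:            %.4f",
                     acc$hybrid_knn),
             sprintf("  hybrid SVM accuracy:            %.4f",
                     acc$hybrid_svm))
  if (!is.null(acc$heads)) {
    lines <- c(lines, sprintf("  %s-head accuracy: %.4f",
                              names(acc$heads), unlist(acc$heads)))
  }

  sal <- utils::read.delim(file.path(run_dir, "region_saliency.tsv"),
                           check.names = FALSE)
  vals <- as.matrix(sal[, -(1:2), drop = FALSE])
  region_means <- colMeans(vals)
  topr <- sort(region_means, decreasing = TRUE)[1:min(10,
                                                      length(region_means))]
  regions <- read_region_table(file.path(run_dir, "atlas_regions.tsv"))
  nm <- regions$name[match(as.integer(names(topr)), regions$region_id)]
  lines <- c(lines, "", "== Regional saliency (top 10 by mean) ==",
             sprintf("  %-14s %.5g", nm, topr))
  ph <- read_json_if(file.path(run_dir, "phenotype_stats.json"))
  h <- ph$hemisphere
  lines <- c(lines,
             sprintf("  hemisphere means: LH %.5g vs RH %.5g (t = %.3f, df = %d, p = %.3g)",
                     h$lh_mean, h$rh_mean, h$statistic, h$df, h$p_value))

  inv <- utils::read.delim(file.path(run_dir, "involvement_averaged.tsv"))
  lines <- c(lines, "", "== Functional-network involvement (threshold-averaged) ==",
             sprintf("  %-24s count %5.2f  %5.2f%%", inv$network,
                     inv$mean_count, inv$mean_percentage))
  if (file.exists(file.path(run_dir, "hubs_averaged.tsv"))) {
    hubs <- utils::read.delim(file.path(run_dir, "hubs_averaged.tsv"))
    hn <- regions$name[match(hubs$region_id[1:min(10, nrow(hubs))],
                             regions$region_id)]
    lines <- c(lines, "", "== Threshold-averaged hub regions (top 10) ==",
               sprintf("  %-14s avg degree %.2f", hn,
                       hubs$average_degree[1:min(10, nrow(hubs))]))
  }

  counts <- utils::read.delim(file.path(run_dir, "score_region_counts.tsv"))
  lines <- c(lines, "", "== Score-region correlations (L/R counts) ==",
             sprintf("  %-14s %d/%d", counts$subscore, counts$L, counts$R))

  lines <- c(lines, "", "== Control congruence ==")
  if (!length(ph$control_congruence)) {
    lines <- c(lines, "  (no control subjects in this run)")
  } else {
    cg <- ph$control_congruence
    lines <- c(lines,
               sprintf("  control vs low-severity regional means: r = %.3f, slope = %.3f, intercept = %.4g",
                       cg$r, cg$slope, cg$intercept))
    if (!is.null(cls$accuracies$control_low_fraction)) {
      lines <- c(lines,
                 sprintf("  controls classified low: %.4f",
                         cls$accuracies$control_low_fraction))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
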