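#' Functional-network involvement of a hub list
#'
#' Counts how many regions of a ranked hub list belong to each functional
#' network and expresses each count as a percentage of the total across
#' networks. Regions mapped to no network (`"none"`) are excluded from the
#' total.
#'
#' @param top_regions vector of region ids (e.g. a per-threshold top-n hub
#'   list) or a `hub_ranking` per-threshold table.
#' @param atlas the matching `parcellation_atlas`.
#' @param threshold_label label describing the tau threshold (or
#'   `"averaged"`).
#' @return An object of class `network_involvement`: data frame with
#'   `network`, `count`, `percentage` (summing to 100 up to rounding), plus
#'   attributes `total` and `threshold`.
#' @export
#' @examples
#' # 22 Language regions of 95 networked regions -> 23.2%
network_involvement <- function(top_regions, atlas,
                                threshold_label = "unspecified") {
  if (is.data.frame(top_regions)) top_regions <- top_regions$region_id
  r <- atlas$regions
  missing <- setdiff(top_regions, r$region_id)
  if (length(missing)) {
    stop_salnet("unknown region ids: ", paste(missing, collapse = ", "),
                class = "salnet_consistency_error")
  }
  nets <- r$network[match(top_regions, r$region_id)]
  known <- unique(r$network)
  bad <- setdiff(nets, known)
  if (length(bad)) {
    stop_salnet("unknown network label: ", paste(bad, collapse = ", "),
                class = "salnet_vocabulary_error")
  }
  nets <- nets[nets != "none"]
  levels <- intersect(network_names(), unique(r$network))
  if (!length(levels)) levels <- setdiff(sort(unique(r$network)), "none")
  counts <- table(factor(nets, levels = levels))
  total <- sum(counts)
  out <- data.frame(network = names(counts),
                    count = as.integer(counts),
                    percentage = if (total > 0)
                      100 * as.integer(counts) / total else
                      rep(NA_real_, length(counts)),
                    stringsAsFactors = FALSE)
  structure(out, total = total, threshold = threshold_label,
            class = c("network_involvement", "data.frame"))
}

#' Threshold-averaged functional-network involvement
#'
#' Repeats the involvement count at every tau threshold of a hub ranking
#' and reports the arithmetic means of the per-threshold counts and of the
#' per-threshold percentages side by side.
#'
#' @param mat a `region_saliency_matrix`.
#' @param atlas the matching `parcellation_atlas`.
#' @param thresholds tau thresholds (default 0.1-0.6 by 0.1).
#' @param top_n hub-list size per threshold (default 50).
#' @param alpha significance filter (default 0.01).
#' @param hubs optionally a precomputed [hub_ranking()] (overrides the
#'   other arguments).
#' @return A `network_involvement` data frame with columns `network`,
#'   `mean_count`, `mean_percentage`, and the per-threshold involvements in
#'   attribute `per_threshold`.
#' @export
averaged_involvement <- function(mat, atlas,
                                 thresholds = seq(0.1, 0.6, by = 0.1),
                                 top_n = 50L, alpha = 0.01, hubs = NULL) {
  if (is.null(hubs)) {
    hubs <- hub_ranking(mat, atlas, thresholds = thresholds, top_n = top_n,
                        alpha = alpha)
  }
  per <- Map(function(tab, label) {
    network_involvement(tab$region_id, atlas, threshold_label = label)
  }, hubs$per_threshold, names(hubs$per_threshold))
  counts <- sapply(per, `[[`, "count")
  pcts <- sapply(per, `[[`, "percentage")
  out <- data.frame(network = per[[1]]$network,
                    mean_count = rowMeans(counts),
                    mean_percentage = rowMeans(pcts, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  structure(out, per_threshold = per, threshold = "averaged",
            class = c("network_involvement", "data.frame"))
}

#' Kendall correlations between behavioural subscores and regional saliency
#'
#' For each of the five behavioural subscores and each cortical region,
#' computes the Kendall tau between the subscore and the region's saliency
#' across the scored (high and low severity) subjects, and keeps the
#' significant rows (p < alpha). Controls carry no scores and are excluded.
#'
#' @param mat a `region_saliency_matrix` with group labels.
#' @param records phenotype data frame.
#' @param alpha significance level (default 0.05).
#' @param scope `"cortical"` (default, the 2 x 75 cortical regions) or
#'   `"all"`.
#' @param atlas the matching `parcellation_atlas`.
#' @return An object of class `score_region_table`: list with `table`
#'   (data frame `subscore`, `region_id`, `hemisphere`, `lobe`, `tau`, `p`),
#'   `hemisphere_counts` (subscores x hemispheres), `lobe_counts`, `alpha`
#'   and `n_regions` (the tested scope size).
#' @export
score_region_correlations <- function(mat, records, atlas, alpha = 0.05,
                                      scope = c("cortical", "all")) {
  scope <- match.arg(scope)
  r <- atlas$regions
  ids <- if (scope == "cortical") r$region_id[r$is_cortical] else
    r$region_id
  scored_ids <- records$subject_id[records$group %in% c("high", "low")]
  scored_ids <- intersect(mat$subject_ids, scored_ids)
  if (length(scored_ids) < 3L) {
    stop_salnet("need at least 3 scored subjects",
                class = "salnet_value_error")
  }
  X <- mat$values[scored_ids, as.character(ids), drop = FALSE]
  sc <- records[match(scored_ids, records$subject_id), SUBSCORE_NAMES,
                drop = FALSE]
  rows <- list()
  for (k in SUBSCORE_NAMES) {
    s <- sc[[k]]
    if (length(unique(s)) == 1L) {
      warning("subscore ", k, " is constant across scored subjects; skipped",
              call. = FALSE)
      next
    }
    for (j in seq_along(ids)) {
      kt <- kendall_tau(s, X[, j])
      # alpha = 1 disables the filter entirely (every pair is reported)
      if (!kt$constant && (alpha >= 1 || kt$p_value < alpha)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subscore = k, region_id = ids[j],
          hemisphere = r$hemisphere[match(ids[j], r$region_id)],
          lobe = r$lobe[match(ids[j], r$region_id)],
          tau = kt$tau, p = kt$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subscore = character(0), region_id = integer(0),
               hemisphere = character(0), lobe = character(0),
               tau = numeric(0), p = numeric(0))
  hemi_counts <- table(factor(tab$subscore, levels = SUBSCORE_NAMES),
                       factor(tab$hemisphere, levels = c("L", "R")))
  lobe_counts <- table(
    factor(tab$subscore, levels = SUBSCORE_NAMES),
    paste(tab$hemisphere, tab$lobe)
  )
  structure(
    list(table = tab, hemisphere_counts = hemi_counts,
         lobe_counts = lobe_counts, alpha = alpha,
         n_regions = length(ids)),
    class = "score_region_table"
  )
}

#' @export
print.score_region_table <- function(x, ...) {
  cat(sprintf("Score-region correlations (alpha %.3g, %d regions tested)\n",
              x$alpha, x$n_regions))
  cat(sprintf("  %d significant subscore-region pairs\n", nrow(x$table)))
  cat("  per-hemisphere counts (L/R):\n")
  hc <- x$hemisphere_counts
  for (k in rownames(hc)) {
    cat(sprintf("    %-14s %d/%d\n", k, hc[k, "L"], hc[k, "R"]))
  }
  invisible(x)
}

#' Per-hemisphere average/STD saliency panel statistics
#'
#' Builds the eight per-region summary vectors \{LH, RH\} x \{Avg, STD\} x
#' \{High, Low\} over the cortical regions (each of length 75 under the
#' default parcellation) and reports, for every ordered pair of distinct
#' vectors, the Pearson correlation and ordinary-least-squares slope, and on
#' the diagonal the Shapiro-Wilk normality statistic of each vector.
#'
#' @param mat a `region_saliency_matrix` with both severity groups present.
#' @param atlas the matching `parcellation_atlas`.
#' @return An object of class `avg_std_grid`: list with `vectors` (named
#'   list of 8 per-region vectors), `r` and `slope` (8 x 8 matrices,
#'   diagonal `NA`), `shapiro_w` and `shapiro_p` (length-8 vectors).
#' @export
avg_std_grid <- function(mat, atlas) {
  r <- atlas$regions
  groups <- mat$groups
  for (g in c("high", "low")) {
    if (sum(groups == g, na.rm = TRUE) < 2L) {
      stop_salnet("need at least 2 subjects per severity group for the ",
                  "standard-deviation panels", class = "salnet_statistics_error")
    }
  }
  vectors <- list()
  for (hemi in c("L", "R")) {
    ids <- as.character(r$region_id[r$is_cortical & r$hemisphere == hemi])
    for (grp in c("high", "low")) {
      V <- mat$values[groups == grp, ids, drop = FALSE]
      hl <- if (hemi == "L") "LH" else "RH"
      gl <- if (grp == "high") "High" else "Low"
      vectors[[paste(hl, "Avg", gl)]] <- colMeans(V)
      vectors[[paste(hl, "STD", gl)]] <- apply(V, 2, stats::sd)
    }
  }
  k <- length(vectors)
  rmat <- smat <- matrix(NA_real_, k, k,
                         dimnames = list(names(vectors), names(vectors)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      x <- vectors[[j]]
      y <- vectors[[i]]
      rmat[i, j] <- stats::cor(x, y)
      smat[i, j] <- stats::cov(x, y) / stats::var(x)
    }
  }
  sw <- lapply(vectors, function(v) {
    if (length(unique(v)) < 3L) return(list(statistic = NA, p.value = NA))
    stats::shapiro.test(v)
  })
  structure(
    list(vectors = vectors, r = rmat, slope = smat,
         shapiro_w = vapply(sw, function(s) unname(s$statistic), numeric(1)),
         shapiro_p = vapply(sw, function(s) unname(s$p.value), numeric(1))),
    class = "avg_std_grid"
  )
}

#' @export
print.avg_std_grid <- function(x, ...) {
  cat("Average/STD saliency grid (8 per-region vectors)\n")
  cat(sprintf("  LH High Avg~STD: r = %.3f; RH High Avg~STD: r = %.3f\n",
              x$r["LH STD High", "LH Avg High"],
              x$r["RH STD High", "RH Avg High"]))
  cat("  Shapiro-Wilk p by vector:\n")
  print(round(x$shapiro_p, 4))
  invisible(x)
}

#' Control-versus-low regional saliency congruence
#'
#' Computes each region's mean saliency separately for the unscored control
#' subjects and for the low-severity subjects, and summarises the
#' cross-region linear association between the two mean vectors (Pearson r,
#' ordinary-least-squares slope and intercept of control on low).
#'
#' @param mat a `region_saliency_matrix` containing both groups.
#' @return A list of class `control_congruence`: `r`, `slope`, `intercept`,
#'   `n_regions`, plus the two mean vectors.
#' @export
control_congruence <- function(mat) {
  groups <- mat$groups
  if (!any(groups == "control", na.rm = TRUE) ||
      !any(groups == "low", na.rm = TRUE)) {
    stop_salnet("need both control and low-severity subjects",
                class = "salnet_value_error")
  }
  ctrl <- colMeans(mat$values[groups == "control", , drop = FALSE])
  low <- colMeans(mat$values[groups == "low", , drop = FALSE])
  fit <- stats::lm.fit(cbind(1, low), ctrl)
  structure(
    list(r = stats::cor(low, ctrl),
         slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         n_regions = length(low),
         control_means = ctrl, low_means = low),
    class = "control_congruence"
  )
}

#' @export
print.control_congruence <- function(x, ...) {
  cat(sprintf("Control vs low-severity regional saliency: r = %.3f, slope = %.3f, intercept = %.4g (%d regions)\n",
              x$r, x$slope, x$intercept, x$n_regions))
  invisible(x)
}
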