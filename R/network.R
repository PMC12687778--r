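#' Pairwise Kendall correlations between regional saliencies
#'
#' Computes one tie-corrected Kendall tau edge per unordered region pair in
#' scope, across all subjects in the matrix (severity groups pooled).
#' Region columns that are constant across subjects have no defined rank
#' correlation; their pairs are skipped with a warning.
#'
#' @param mat a `region_saliency_matrix`.
#' @param atlas the matching `parcellation_atlas`.
#' @param scope `"cortical-cortical"` (pairs of cortical regions),
#'   `"cortical-subcortical"` (pairs involving at least one non-cortical
#'   region), or `"all"`.
#' @return A data frame of class `correlation_edges` with columns
#'   `region_a`, `region_b` (`region_a < region_b`), `tau`, `p`, plus the
#'   candidate pair count in attribute `n_candidates`.
#' @export
pairwise_region_correlations <- function(mat, atlas,
                                         scope = c("cortical-cortical",
                                                   "cortical-subcortical",
                                                   "all")) {
  stopifnot(inherits(mat, "region_saliency_matrix"))
  scope <- match.arg(scope)
  if (nrow(mat$values) < 3L) {
    stop_salnet("need at least 3 subjects for rank correlations",
                class = "salnet_value_error")
  }
  r <- atlas$regions
  cortical <- r$region_id[r$is_cortical]
  keep_ids <- switch(scope,
                     "cortical-cortical" = cortical,
                     "cortical-subcortical" = r$region_id,
                     "all" = r$region_id)
  X <- mat$values[, as.character(keep_ids), drop = FALSE]
  ids <- keep_ids
  R <- length(ids)
  # all unordered pairs (a < b) by column index
  idx <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  a <- idx[, 1]
  b <- idx[, 2]
  if (scope == "cortical-subcortical") {
    is_ctx <- ids %in% cortical
    keep <- !(is_ctx[a] & is_ctx[b])
    a <- a[keep]
    b <- b[keep]
  }
  n_candidates <- length(a)

  n <- nrow(X)
  if (n <= 9L) {
    tau <- p <- numeric(length(a))
    for (q in seq_along(a)) {
      kt <- kendall_tau(X[, a[q]], X[, b[q]])
      tau[q] <- kt$tau
      p[q] <- kt$p_value
    }
  } else {
    km <- kendall_tau_matrix(X)
    tau <- km$tau[cbind(a, b)]
    p <- km$p[cbind(a, b)]
  }
  edges <- data.frame(region_a = ids[a], region_b = ids[b],
                      tau = tau, p = p)
  if (anyNA(edges$tau)) {
    const <- ids[apply(X, 2, function(v) length(unique(v)) == 1L)]
    warning("skipping pairs with constant region saliency: ",
            paste(const, collapse = ", "), call. = FALSE)
    edges <- edges[!is.na(edges$tau), ]
  }
  structure(edges, n_candidates = n_candidates, scope = scope,
            class = c("correlation_edges", "data.frame"))
}

#' Significance- and threshold-filtered correlation graph
#'
#' Keeps the edges with `p < alpha` and `tau > tau_threshold` (or
#' `|tau| > tau_threshold` with `mode = "absolute"`) and recomputes node
#' degrees. An optional Benjamini-Hochberg correction can replace the raw
#' p-value filter.
#'
#' @param edges a `correlation_edges` data frame.
#' @param atlas the matching `parcellation_atlas` (provides node
#'   attributes).
#' @param alpha significance level (default 0.01).
#' @param tau_threshold minimum tau (default 0.4, the midlevel threshold).
#' @param mode `"positive"` (default) keeps tau > threshold; `"absolute"`
#'   keeps |tau| > threshold.
#' @param correction `"none"` (default, raw p) or `"BH"`.
#' @return An object of class `correlation_graph`: list with `nodes`
#'   (region table plus `degree`), `edges`, `alpha`, `tau_threshold`.
#' @export
filter_edges <- function(edges, atlas, alpha = 0.01, tau_threshold = 0.4,
                         mode = c("positive", "absolute"),
                         correction = c("none", "BH")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  if (tau_threshold < 0 || tau_threshold > 1) {
    stop_salnet("tau_threshold must be in [0, 1]",
                class = "salnet_value_error")
  }
  p <- if (correction == "BH") stats::p.adjust(edges$p, "BH") else edges$p
  tau_ok <- if (mode == "absolute") abs(edges$tau) > tau_threshold else
    edges$tau > tau_threshold
  kept <- edges[p < alpha & tau_ok, , drop = FALSE]
  nodes <- atlas$regions
  deg <- table(factor(c(kept$region_a, kept$region_b),
                      levels = nodes$region_id))
  nodes$degree <- as.integer(deg)
  structure(
    list(nodes = nodes, edges = kept, alpha = alpha,
         tau_threshold = tau_threshold, mode = mode,
         scope = attr(edges, "scope") %||% "all"),
    class = "correlation_graph"
  )
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("Correlation graph (%s scope): %d edges over %d regions (alpha %.3g, tau > %.2g)\n",
              x$scope, nrow(x$edges), sum(x$nodes$degree > 0), x$alpha,
              x$tau_threshold))
  invisible(x)
}

#' Top edges by correlation strength
#'
#' The n largest-tau edges, with deterministic tie-breaking (p ascending,
#' then the region-id pair).
#'
#' @param edges a `correlation_edges` data frame (pre-filtered as desired).
#' @param n number of edges to keep (default 500).
#' @return The sorted head of the edge table; all edges (with a message) if
#'   fewer than `n` are available.
#' @export
top_edges <- function(edges, n = 500L) {
  ord <- order(-edges$tau, edges$p, edges$region_a, edges$region_b)
  out <- edges[ord, , drop = FALSE]
  if (nrow(out) < n) {
    message("only ", nrow(out), " edges available (requested ", n, ")")
  } else {
    out <- out[seq_len(n), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

graph_to_igraph <- function(graph) {
  active <- graph$nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$region_a),
               to = as.character(graph$edges$region_b),
               tau = graph$edges$tau, p = graph$edges$p),
    directed = FALSE,
    vertices = data.frame(name = as.character(active$region_id),
                          label = active$name,
                          hemisphere = active$hemisphere,
                          lobe = active$lobe,
                          is_cortical = active$is_cortical,
                          network = active$network,
                          degree = active$degree)
  )
  g
}

#' Force-directed (spring) layout of a correlation graph
#'
#' Seeded Fruchterman-Reingold layout on the binary connection structure.
#' The convention that edge length reflects 1 - tau is implemented
#' by weighting the attraction of each edge by 1 / (1 - tau), so highly
#' correlated regions are pulled closer together while node repulsion
#' pushes weakly connected regions to the periphery.
#'
#' @param graph a `correlation_graph`.
#' @param seed layout seed.
#' @return Matrix of 2D coordinates (rownames = region ids) with the node
#'   degree in attribute `size`.
#' @export
spring_layout <- function(graph, seed = 1L) {
  if (!nrow(graph$edges)) {
    stop_salnet("cannot lay out an empty graph", class = "salnet_value_error")
  }
  ig <- graph_to_igraph(graph)
  w <- pmin(1 / (1 - igraph::E(ig)$tau + 1e-3), 100)
  coords <- with_seed(seed, igraph::layout_with_fr(ig, weights = w))
  rownames(coords) <- igraph::V(ig)$name
  attr(coords, "size") <- igraph::V(ig)$degree
  coords
}

#' Hub ranking across a tau-threshold sweep
#'
#' For each threshold, builds the filtered graph, ranks regions by degree
#' (connection count) and keeps the top n. The threshold-averaged table
#' sums each region's degrees across the per-threshold top-n tables in
#' which it appears, divides by the number of thresholds, and re-ranks.
#'
#' @param mat a `region_saliency_matrix`.
#' @param atlas the matching `parcellation_atlas`.
#' @param thresholds strictly increasing tau thresholds (default 0.1-0.6 in
#'   steps of 0.1).
#' @param top_n regions kept per threshold (default 50).
#' @param alpha significance filter (default 0.01).
#' @param scope correlation scope (see
#'   [pairwise_region_correlations()]).
#' @param edges optionally, precomputed `correlation_edges` (skips the
#'   correlation step).
#' @return An object of class `hub_ranking`: list with `per_threshold`
#'   (named list of data frames `region_id`, `degree`, `mean_tau`),
#'   `averaged` (data frame `region_id`, `average_degree`, ranked), and
#'   `divisor` (the threshold count).
#' @export
hub_ranking <- function(mat, atlas, thresholds = seq(0.1, 0.6, by = 0.1),
                        top_n = 50L, alpha = 0.01,
                        scope = "cortical-cortical", edges = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_salnet("thresholds must be strictly increasing",
                class = "salnet_value_error")
  }
  if (is.null(edges)) {
    edges <- pairwise_region_correlations(mat, atlas, scope = scope)
  }
  per <- lapply(thresholds, function(th) {
    gr <- filter_edges(edges, atlas, alpha = alpha, tau_threshold = th)
    ids <- gr$nodes$region_id
    deg <- gr$nodes$degree
    mean_tau <- vapply(ids, function(id) {
      inc <- gr$edges$tau[gr$edges$region_a == id | gr$edges$region_b == id]
      if (length(inc)) mean(inc) else 0
    }, numeric(1))
    ord <- order(-deg, -mean_tau, ids)
    keep <- ord[seq_len(min(top_n, sum(deg > 0)))]
    data.frame(region_id = ids[keep], degree = deg[keep],
               mean_tau = mean_tau[keep])
  })
  names(per) <- sprintf("tau_%.1f", thresholds)
  all_ids <- sort(unique(unlist(lapply(per, `[[`, "region_id"))))
  avg <- vapply(all_ids, function(id) {
    sum(vapply(per, function(tab) {
      d <- tab$degree[tab$region_id == id]
      if (length(d)) d else 0
    }, numeric(1))) / length(thresholds)
  }, numeric(1))
  ord <- order(-avg, all_ids)
  averaged <- data.frame(region_id = all_ids[ord],
                         average_degree = avg[ord])
  if (nrow(averaged) > top_n) {
    averaged <- averaged[seq_len(top_n), , drop = FALSE]
  }
  rownames(averaged) <- NULL
  structure(list(per_threshold = per, averaged = averaged,
                 thresholds = thresholds, divisor = length(thresholds),
                 top_n = top_n),
            class = "hub_ranking")
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat(sprintf("Hub ranking over %d thresholds (%s), top %d regions\n",
              x$divisor, paste(sprintf("%.1f", x$thresholds), collapse = ", "),
              x$top_n))
  cat("Threshold-averaged top regions:\n")
  print(utils::head(x$averaged, 10))
  invisible(x)
}

#' Composition statistics of a correlation graph
#'
#' Fractions of surviving edges by lobe and hemisphere: the within-lobe
#' fraction (both ends in the same lobe of the same hemisphere), per
#' hemisphere-lobe fractions, hemisphere pairing fractions, and -- when the
#' graph contains non-cortical regions -- the attachment of
#' subcortical-involving correlations to left/right cortex or within the
#' subcortical set. An empty graph yields `NA` fractions (undefined, not
#' zero).
#'
#' @param graph a `correlation_graph`.
#' @return A list of class `composition_stats`.
#' @export
composition_stats <- function(graph) {
  nodes <- graph$nodes
  e <- graph$edges
  if (!nrow(e)) {
    return(structure(list(n_edges = 0L, within_lobe_fraction = NA_real_,
                          per_lobe_fractions = NULL,
                          hemisphere_fractions = c(LL = NA_real_,
                                                   RR = NA_real_,
                                                   cross = NA_real_),
                          subcortical_attachment = NULL),
                     class = "composition_stats"))
  }
  ia <- match(e$region_a, nodes$region_id)
  ib <- match(e$region_b, nodes$region_id)
  hemi_a <- nodes$hemisphere[ia]
  hemi_b <- nodes$hemisphere[ib]
  lobe_a <- nodes$lobe[ia]
  lobe_b <- nodes$lobe[ib]
  ctx_a <- nodes$is_cortical[ia]
  ctx_b <- nodes$is_cortical[ib]

  same <- hemi_a == hemi_b & lobe_a == lobe_b
  within_lobe_fraction <- mean(same)
  per <- table(paste(hemi_a[same], lobe_a[same])) / nrow(e)
  per_lobe <- data.frame(
    hemisphere = sub(" .*", "", names(per)),
    lobe = sub("^[^ ]+ ", "", names(per)),
    fraction = as.numeric(per),
    stringsAsFactors = FALSE
  )
  per_lobe <- per_lobe[order(-per_lobe$fraction), ]
  rownames(per_lobe) <- NULL

  hemi_pair <- ifelse(hemi_a == "L" & hemi_b == "L", "LL",
                      ifelse(hemi_a == "R" & hemi_b == "R", "RR", "cross"))
  hemisphere_fractions <- c(
    LL = mean(hemi_pair == "LL"),
    RR = mean(hemi_pair == "RR"),
    cross = mean(hemi_pair == "cross")
  )

  subcortical_attachment <- NULL
  sub_involved <- !ctx_a | !ctx_b
  if (any(sub_involved)) {
    sa <- which(sub_involved)
    # hemisphere of the cortical end; both-subcortical pairs are "within"
    ctx_hemi <- ifelse(ctx_a[sa], hemi_a[sa],
                       ifelse(ctx_b[sa], hemi_b[sa], "within"))
    subcortical_attachment <- c(
      left_cortex = mean(ctx_hemi == "L"),
      right_cortex = mean(ctx_hemi == "R"),
      within_subcortical = mean(ctx_hemi == "within"),
      midline_cortexless = mean(!ctx_hemi %in% c("L", "R", "within"))
    )
  }
  structure(
    list(n_edges = nrow(e), within_lobe_fraction = within_lobe_fraction,
         per_lobe_fractions = per_lobe,
         hemisphere_fractions = hemisphere_fractions,
         subcortical_attachment = subcortical_attachment),
    class = "composition_stats"
  )
}

#' @export
print.composition_stats <- function(x, ...) {
  if (!x$n_edges) {
    cat("Composition stats: empty graph (fractions undefined)\n")
    return(invisible(x))
  }
  cat(sprintf("Composition over %d edges: %.1f%% within-lobe\n",
              x$n_edges, 100 * x$within_lobe_fraction))
  if (nrow(x$per_lobe_fractions)) {
    top <- x$per_lobe_fractions[1, ]
    cat(sprintf("  largest lobe share: %s %s (%.1f%%)\n", top$hemisphere,
                top$lobe, 100 * top$fraction))
  }
  hf <- x$hemisphere_fractions
  cat(sprintf("  hemisphere pairing: LL %.1f%%, RR %.1f%%, cross %.1f%%\n",
              100 * hf["LL"], 100 * hf["RR"], 100 * hf["cross"]))
  if (!is.null(x$subcortical_attachment)) {
    sa <- x$subcortical_attachment
    cat(sprintf("  subcortical-involving edges: %.2f%% to left cortex, %.2f%% to right cortex, %.2f%% within subcortical\n",
                100 * sa["left_cortex"], 100 * sa["right_cortex"],
                100 * sa["within_subcortical"]))
  }
  invisible(x)
}

#' Export a correlation graph as GraphML plus a TSV edge list
#'
#' @param graph a `correlation_graph`.
#' @param graphml_path destination `.graphml` file.
#' @param edges_path destination `.tsv` edge list (`region_a`, `region_b`,
#'   `tau`, `p`).
#' @return Invisibly, the paths.
#' @export
write_correlation_graph <- function(graph, graphml_path, edges_path) {
  ig <- graph_to_igraph(graph)
  igraph::write_graph(ig, graphml_path, format = "graphml")
  utils::write.table(graph$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(graphml_path, edges_path))
}
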