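toy_edges <- function(df, scope = "cortical-cortical") {
  structure(df, scope = scope, n_candidates = nrow(df),
            class = c("correlation_edges", "data.frame"))
}

test_that("edge filtering keeps exactly the significant, above-threshold edges", {
  atlas <- mock_atlas(n_cortical_per_hemi = 3, n_sub_per_hemi = 0)
  edges <- toy_edges(data.frame(
    region_a = c(1L, 1L, 2L, 3L, 4L),
    region_b = c(2L, 3L, 4L, 5L, 6L),
    tau = c(0.9, 0.45, 0.41, 0.39, 0.8),
    p = c(0.001, 0.005, 0.02, 0.0001, 0.009)
  ))
  g <- filter_edges(edges, atlas, alpha = 0.01, tau_threshold = 0.4)
  # manual filter: p < 0.01 AND tau > 0.4 -> edges 1, 2, 5
  expect_equal(nrow(g$edges), 3)
  expect_setequal(paste(g$edges$region_a, g$edges$region_b),
                  c("1 2", "1 3", "4 6"))
  expect_equal(sum(g$nodes$degree), 2 * nrow(g$edges))
  expect_equal(g$nodes$degree[g$nodes$region_id == 1], 2)

  # nothing exceeds tau = 1
  empty <- filter_edges(edges, atlas, alpha = 0.01, tau_threshold = 1)
  expect_equal(nrow(empty$edges), 0)

  # the absolute-tau mode admits strong negative correlations
  edges$tau[1] <- -0.9
  expect_equal(nrow(filter_edges(edges, atlas, alpha = 0.01,
                                 tau_threshold = 0.4)$edges), 2)
  expect_equal(nrow(filter_edges(edges, atlas, alpha = 0.01,
                                 tau_threshold = 0.4,
                                 mode = "absolute")$edges), 3)
})

test_that("edge counts and node degrees are non-increasing in the threshold", {
  co <- shared_cohort()
  mat <- shared_matrix()
  edges <- pairwise_region_correlations(mat, co$atlas,
                                        scope = "cortical-cortical")
  prev <- NULL
  for (th in seq(0, 0.6, by = 0.1)) {
    g <- filter_edges(edges, co$atlas, alpha = 0.01, tau_threshold = th)
    if (!is.null(prev)) {
      expect_lte(nrow(g$edges), nrow(prev$edges))
      expect_true(all(g$nodes$degree <= prev$nodes$degree))
    }
    prev <- g
  }
})

test_that("top-edge selection is sorted, capped and deterministic under ties", {
  few <- toy_edges(data.frame(region_a = 1:3, region_b = 4:6,
                              tau = c(0.5, 0.7, 0.6), p = rep(0.001, 3)))
  expect_message(out <- top_edges(few, n = 500), "3 edges")
  expect_equal(nrow(out), 3)
  expect_true(all(diff(out$tau) <= 0))

  tied <- toy_edges(data.frame(
    region_a = c(5L, 1L, 3L, 1L), region_b = c(6L, 4L, 7L, 2L),
    tau = c(0.5, 0.5, 0.5, 0.5), p = c(0.002, 0.002, 0.001, 0.002)
  ))
  first <- top_edges(tied, n = 3)
  for (i in 1:5) expect_identical(top_edges(tied, n = 3), first)
  # p ascending breaks the first tie, then the region-id pair
  expect_equal(first$region_a, c(3L, 1L, 1L))
  expect_equal(first$region_b, c(7L, 2L, 4L))
})

test_that("the spring layout is seeded and respects correlation distances", {
  atlas <- mock_atlas(n_cortical_per_hemi = 3, n_sub_per_hemi = 0)
  pair <- filter_edges(toy_edges(data.frame(
    region_a = 1L, region_b = 2L, tau = 0.9, p = 1e-4)),
    atlas, alpha = 0.01, tau_threshold = 0)
  path <- filter_edges(toy_edges(data.frame(
    region_a = c(1L, 2L), region_b = c(2L, 3L), tau = c(0.1, 0.1),
    p = c(1e-4, 1e-4))),
    atlas, alpha = 0.01, tau_threshold = 0)

  c1 <- spring_layout(pair, seed = 4)
  expect_identical(spring_layout(pair, seed = 4), c1)

  d_pair <- dist(c1[c("1", "2"), ])[1]
  c2 <- spring_layout(path, seed = 4)
  d_path <- min(dist(c2[c("1", "2", "3"), ]))
  expect_lt(d_pair, d_path)

  # an isolated node is pushed beyond the connected component
  iso <- filter_edges(toy_edges(data.frame(
    region_a = c(1L, 2L, 1L), region_b = c(2L, 3L, 3L),
    tau = c(0.8, 0.8, 0.8), p = rep(1e-4, 3))),
    atlas, alpha = 0.01, tau_threshold = 0)
  c3 <- spring_layout(iso, seed = 7)
  comp <- c3[c("1", "2", "3"), ]
  centroid <- colMeans(comp)
  r_comp <- max(sqrt(rowSums(sweep(comp, 2, centroid)^2)))
  r_iso <- sqrt(sum((c3[rownames(c3) %in% c("4", "5", "6"), ][1, ] -
                       centroid)^2))
  expect_gt(r_iso, r_comp)
})

test_that("hub ranking averages degrees over the six thresholds and re-ranks", {
  atlas <- mock_atlas(n_cortical_per_hemi = 2, n_sub_per_hemi = 0)
  # 4 regions; taus chosen so degrees change across thresholds
  set.seed(30)
  n <- 30
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  X <- cbind(z1 + 0.1 * rnorm(n), z1 + 0.1 * rnorm(n),
             z1 + 0.8 * rnorm(n), z2)
  ids <- atlas$regions$region_id
  colnames(X) <- ids
  rownames(X) <- sprintf("s%03d", 1:n)
  mat <- structure(list(values = X, subject_ids = rownames(X),
                        region_ids = ids,
                        groups = rep(NA_character_, n)),
                   class = "region_saliency_matrix")
  hr <- hub_ranking(mat, atlas, top_n = 4)
  expect_equal(hr$divisor, 6)

  # oracle: recompute each region's averaged degree by brute force
  edges <- pairwise_region_correlations(mat, atlas, scope = "all")
  brute <- sapply(ids, function(id) {
    degs <- sapply(seq(0.1, 0.6, by = 0.1), function(th) {
      kept <- edges[edges$p < 0.01 & edges$tau > th, ]
      sum(kept$region_a == id | kept$region_b == id)
    })
    sum(degs) / 6
  })
  brute <- sort(brute[brute > 0], decreasing = TRUE)
  expect_equal(hr$averaged$average_degree, unname(brute))

  # a region at top with the same degree d at every threshold averages d
  expect_error(hub_ranking(mat, atlas, thresholds = c(0.3, 0.2)),
               class = "salnet_value_error")
})

test_that("constant-degree regions average to their degree", {
  atlas <- mock_atlas(n_cortical_per_hemi = 2, n_sub_per_hemi = 0)
  # two perfectly correlated regions survive every threshold: degree 1 each
  X <- cbind(1:20, 1:20, rnorm(20), rnorm(20)) + 0
  ids <- atlas$regions$region_id
  colnames(X) <- ids
  rownames(X) <- sprintf("s%03d", 1:20)
  mat <- structure(list(values = X, subject_ids = rownames(X),
                        region_ids = ids, groups = rep(NA, 20)),
                   class = "region_saliency_matrix")
  hr <- hub_ranking(mat, atlas, top_n = 4)
  expect_equal(hr$averaged$average_degree[hr$averaged$region_id == 1], 1)
  expect_equal(hr$averaged$average_degree[hr$averaged$region_id == 2], 1)
})

test_that("composition statistics match a hand tally and degrade to NA when empty", {
  atlas <- mock_atlas(n_cortical_per_hemi = 6, n_lobes = 2,
                      n_sub_per_hemi = 2)
  r <- atlas$regions
  # hand-built 10-edge graph. With n_lobes = 2 the right-hemisphere lobes
  # alternate frontal/insula over ids 1..6, mirrored on 7..12; 13:16 are
  # subcortical (R 13:14, L 15:16).
  e <- toy_edges(data.frame(
    region_a = c(1L, 3L, 2L, 7L, 9L, 8L, 1L, 13L, 15L, 13L),
    region_b = c(3L, 5L, 4L, 9L, 11L, 10L, 7L, 7L, 1L, 14L),
    tau = rep(0.8, 10), p = rep(1e-5, 10)
  ), scope = "all")
  g <- filter_edges(e, atlas, alpha = 0.01, tau_threshold = 0.4)
  cs <- composition_stats(g)
  expect_equal(cs$n_edges, 10)
  # same lobe AND same hemisphere: (1,3) (3,5) (2,4) (7,9) (9,11) (8,10)
  # plus the within-subcortical pair (13,14)
  expect_equal(cs$within_lobe_fraction, 7 / 10)
  expect_equal(cs$hemisphere_fractions[["LL"]], 3 / 10)  # (7,9) (9,11) (8,10)
  expect_equal(cs$hemisphere_fractions[["RR"]], 4 / 10)
  expect_equal(cs$hemisphere_fractions[["cross"]], 3 / 10)
  # subcortical-involving: (13,7)->L, (15,1)->R, (13,14)->within
  sa <- cs$subcortical_attachment
  expect_equal(sa[["left_cortex"]], 1 / 3)
  expect_equal(sa[["right_cortex"]], 1 / 3)
  expect_equal(sa[["within_subcortical"]], 1 / 3)
  pl <- cs$per_lobe_fractions
  expect_equal(sum(pl$fraction), cs$within_lobe_fraction)

  # all edges within one lobe and hemisphere
  e2 <- toy_edges(data.frame(region_a = c(1L, 1L), region_b = c(3L, 5L),
                             tau = c(0.8, 0.8), p = c(1e-5, 1e-5)))
  g2 <- filter_edges(e2, atlas, alpha = 0.01, tau_threshold = 0.4)
  expect_equal(composition_stats(g2)$within_lobe_fraction, 1)

  g0 <- filter_edges(e2, atlas, alpha = 0.01, tau_threshold = 1)
  cs0 <- composition_stats(g0)
  expect_equal(cs0$n_edges, 0)
  expect_true(is.na(cs0$within_lobe_fraction))
  expect_true(all(is.na(cs0$hemisphere_fractions)))
})

test_that("graphs export to GraphML and a TSV edge list", {
  atlas <- mock_atlas(n_cortical_per_hemi = 3, n_sub_per_hemi = 0)
  e <- toy_edges(data.frame(region_a = c(1L, 2L), region_b = c(2L, 3L),
                            tau = c(0.8, 0.6), p = c(1e-4, 1e-3)))
  g <- filter_edges(e, atlas, alpha = 0.01, tau_threshold = 0.4)
  gf <- withr::local_tempfile(fileext = ".graphml")
  ef <- withr::local_tempfile(fileext = ".tsv")
  write_correlation_graph(g, gf, ef)
  ig <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::ecount(ig), 2)
  expect_setequal(igraph::vertex_attr(ig, "hemisphere"),
                  c("R", "R", "R", "L", "L", "L"))
  back <- read.delim(ef)
  expect_equal(back$tau, g$edges$tau)
})
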