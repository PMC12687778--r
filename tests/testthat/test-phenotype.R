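test_that("network involvement reproduces the 22-of-95 Language share", {
  # hub list: 22 Language regions and 73 spread over the other networks
  atlas <- mock_atlas(n_cortical_per_hemi = 75,
                      networks = c("Language", "DefaultMode", "Salience"))
  r <- atlas$regions
  lang <- r$region_id[r$network == "Language"][1:22]
  rest <- r$region_id[r$network != "Language" & r$network != "none"][1:73]
  inv <- network_involvement(c(lang, rest), atlas, "tau_0.4")
  expect_equal(attr(inv, "total"), 95)
  expect_equal(inv$count[inv$network == "Language"], 22)
  expect_equal(round(inv$percentage[inv$network == "Language"], 1), 23.2)
  expect_equal(sum(inv$count), 95)
  expect_equal(sum(inv$percentage), 100, tolerance = 1e-9)
})

test_that("involvement handles concentrated and uniform hub lists", {
  atlas <- mock_atlas(n_cortical_per_hemi = 75)
  r <- atlas$regions
  sal_only <- r$region_id[r$network == "Salience"][1:8]
  inv1 <- network_involvement(sal_only, atlas)
  expect_equal(inv1$percentage[inv1$network == "Salience"], 100)
  expect_true(all(inv1$percentage[inv1$network != "Salience"] == 0))

  four <- unlist(lapply(network_names()[1:4], function(nw) {
    r$region_id[r$network == nw][1:10]
  }))
  inv2 <- network_involvement(four, atlas)
  expect_true(all(inv2$percentage[inv2$count > 0] == 25))

  # percentages always sum to 100 (within rounding) for random hub lists
  set.seed(4)
  for (i in 1:20) {
    ids <- sample(r$region_id, sample(5:60, 1))
    inv <- network_involvement(ids, atlas)
    if (attr(inv, "total") > 0) {
      expect_equal(sum(inv$percentage), 100, tolerance = 0.1)
    }
  }
  # subcortical regions (network "none") never enter the total
  subc <- r$region_id[r$network == "none"]
  inv3 <- network_involvement(c(sal_only, subc), atlas)
  expect_equal(attr(inv3, "total"), 8)
  expect_error(network_involvement(c(1, 99999), atlas),
               class = "salnet_consistency_error")
})

test_that("threshold-averaged involvement averages counts and percentages", {
  atlas <- mock_atlas(n_cortical_per_hemi = 75)
  r <- atlas$regions
  dmn <- r$region_id[r$network == "DefaultMode"]
  sal <- r$region_id[r$network == "Salience"]
  hubs <- structure(
    list(per_threshold = list(
      tau_0.1 = data.frame(region_id = c(dmn[1:4], sal[1:6])),
      tau_0.2 = data.frame(region_id = c(dmn[1:6], sal[1:4]))
    ), thresholds = c(0.1, 0.2), divisor = 2, top_n = 10),
    class = "hub_ranking")
  avg <- averaged_involvement(NULL, atlas, hubs = hubs)
  expect_equal(avg$mean_count[avg$network == "DefaultMode"], 5)
  expect_equal(avg$mean_count[avg$network == "Salience"], 5)
  expect_equal(avg$mean_percentage[avg$network == "DefaultMode"], 50)

  # identical involvement at every threshold averages to itself
  hubs2 <- structure(
    list(per_threshold = list(
      tau_0.1 = data.frame(region_id = dmn[1:5]),
      tau_0.2 = data.frame(region_id = dmn[1:5]),
      tau_0.3 = data.frame(region_id = dmn[1:5])
    ), thresholds = c(0.1, 0.2, 0.3), divisor = 3, top_n = 5),
    class = "hub_ranking")
  avg2 <- averaged_involvement(NULL, atlas, hubs = hubs2)
  one <- network_involvement(dmn[1:5], atlas)
  expect_equal(avg2$mean_count, one$count + 0)
  expect_equal(avg2$mean_percentage[avg2$network == "DefaultMode"], 100)
})

score_fixture <- function(n = 14, n_regions = 10, seed = 1) {
  atlas <- mock_atlas(n_cortical_per_hemi = n_regions / 2,
                      n_sub_per_hemi = 0)
  set.seed(seed)
  vals <- matrix(rnorm(n * n_regions), n, n_regions)
  colnames(vals) <- atlas$regions$region_id
  rownames(vals) <- sprintf("s%03d", seq_len(n))
  groups <- rep(c("high", "low"), length.out = n)
  records <- data.frame(
    subject_id = rownames(vals), group = groups,
    srs_total = ifelse(groups == "high", 80, 40),
    cognition = rnorm(n, 10), awareness = rnorm(n, 10),
    communication = rnorm(n, 10), mannerisms = rnorm(n, 10),
    motivation = rnorm(n, 10), stringsAsFactors = FALSE
  )
  mat <- structure(list(values = vals, subject_ids = rownames(vals),
                        region_ids = atlas$regions$region_id,
                        groups = groups),
                   class = "region_saliency_matrix")
  list(atlas = atlas, mat = mat, records = records)
}

test_that("a noiseless monotone subscore-region relation is recovered with tau 1", {
  fx <- score_fixture()
  fx$records$mannerisms <- fx$mat$values[, 3]^3  # exact monotone transform
  srt <- score_region_correlations(fx$mat, fx$records, fx$atlas)
  hit <- srt$table[srt$table$subscore == "mannerisms" &
                     srt$table$region_id == fx$mat$region_ids[3], ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$tau, 1)
  expect_lt(hit$p, 0.05)
})

test_that("score-region tables obey the alpha limits and count consistency", {
  fx <- score_fixture()
  all_rows <- score_region_correlations(fx$mat, fx$records, fx$atlas,
                                        alpha = 1)
  expect_equal(nrow(all_rows$table), 10 * 5)
  none <- score_region_correlations(fx$mat, fx$records, fx$atlas, alpha = 0)
  expect_equal(nrow(none$table), 0)

  srt <- score_region_correlations(fx$mat, fx$records, fx$atlas,
                                   alpha = 0.3)
  hc <- srt$hemisphere_counts
  for (k in rownames(hc)) {
    for (h in c("L", "R")) {
      expect_equal(hc[k, h],
                   sum(srt$table$subscore == k & srt$table$hemisphere == h))
    }
  }
  # a constant subscore is skipped with a warning, not an error
  fx$records$motivation <- 5
  expect_warning(srt2 <- score_region_correlations(fx$mat, fx$records,
                                                   fx$atlas, alpha = 1),
                 "motivation")
  expect_equal(nrow(srt2$table), 10 * 4)
})

test_that("the avg/std grid detects exact proportionality and stays seed-calibrated", {
  atlas <- mock_atlas(n_cortical_per_hemi = 20, n_sub_per_hemi = 0)
  ids <- atlas$regions$region_id
  set.seed(7)
  m_r <- runif(40, 1, 3)                 # per-region target means
  # two subjects per group at m * (1 +/- 0.3): sd = 0.3 * m * sqrt(2)
  vals <- rbind(m_r * 1.3, m_r * 0.7, m_r * 1.3, m_r * 0.7)
  colnames(vals) <- ids
  rownames(vals) <- sprintf("s%d", 1:4)
  mat <- structure(list(values = vals, subject_ids = rownames(vals),
                        region_ids = ids,
                        groups = c("high", "high", "low", "low")),
                   class = "region_saliency_matrix")
  grid <- avg_std_grid(mat, atlas)
  expect_equal(grid$r["LH STD High", "LH Avg High"], 1)
  expect_equal(grid$slope["LH STD High", "LH Avg High"], 0.3 * sqrt(2),
               tolerance = 1e-12)
  expect_true(all(is.na(diag(grid$r))))

  # independent hemispheres: cross-hemisphere r consistent with zero
  rs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    v <- matrix(rexp(12 * 40), 12, 40)
    colnames(v) <- ids
    rownames(v) <- sprintf("s%d", 1:12)
    m2 <- structure(list(values = v, subject_ids = rownames(v),
                         region_ids = ids,
                         groups = rep(c("high", "low"), each = 6)),
                    class = "region_saliency_matrix")
    avg_std_grid(m2, atlas)$r["RH STD High", "LH Avg High"]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 4 * sd(rs) / sqrt(length(rs)) + 0.1)

  # Shapiro-Wilk p-values are reported, and uniform under Gaussian nulls
  ps <- vapply(1:40, function(s) {
    set.seed(200 + s)
    v <- matrix(rnorm(8 * 40, mean = 10), 8, 40)
    colnames(v) <- ids
    rownames(v) <- sprintf("s%d", 1:8)
    m2 <- structure(list(values = v, subject_ids = rownames(v),
                         region_ids = ids,
                         groups = rep(c("high", "low"), each = 4)),
                    class = "region_saliency_matrix")
    avg_std_grid(m2, atlas)$shapiro_p[["LH Avg High"]]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # a single-subject group cannot provide a standard deviation
  bad <- structure(list(values = vals[1:3, ], subject_ids = rownames(vals)[1:3],
                        region_ids = ids,
                        groups = c("high", "high", "low")),
                   class = "region_saliency_matrix")
  expect_error(avg_std_grid(bad, atlas), class = "salnet_statistics_error")
})

test_that("the grid is invariant to subject and region reordering", {
  atlas <- mock_atlas(n_cortical_per_hemi = 6, n_sub_per_hemi = 0)
  ids <- atlas$regions$region_id
  set.seed(3)
  vals <- matrix(rexp(8 * 12), 8, 12,
                 dimnames = list(sprintf("s%d", 1:8), ids))
  groups <- rep(c("high", "low"), 4)
  mk <- function(v, g) structure(
    list(values = v, subject_ids = rownames(v), region_ids = ids,
         groups = g),
    class = "region_saliency_matrix")
  g1 <- avg_std_grid(mk(vals, groups), atlas)
  perm <- sample(8)
  g2 <- avg_std_grid(mk(vals[perm, ], groups[perm]), atlas)
  expect_equal(g1$r, g2$r)
  expect_equal(g1$shapiro_p, g2$shapiro_p)
})

test_that("control congruence is exact for identical groups and reported otherwise", {
  atlas <- mock_atlas(n_cortical_per_hemi = 10, n_sub_per_hemi = 0)
  ids <- atlas$regions$region_id
  set.seed(9)
  base <- matrix(rexp(6 * 20), 6, 20, dimnames = list(sprintf("s%d", 1:6),
                                                      ids))
  vals <- rbind(base, base)
  rownames(vals) <- sprintf("s%d", 1:12)
  mat <- structure(list(values = vals, subject_ids = rownames(vals),
                        region_ids = ids,
                        groups = c(rep("low", 6), rep("control", 6))),
                   class = "region_saliency_matrix")
  cc <- control_congruence(mat)
  expect_equal(cc$r, 1)
  expect_equal(cc$slope, 1)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)

  # a shifted control group keeps r high but moves the intercept
  vals2 <- rbind(base, base + 2)
  rownames(vals2) <- sprintf("s%d", 1:12)
  mat2 <- structure(list(values = vals2, subject_ids = rownames(vals2),
                         region_ids = ids,
                         groups = c(rep("low", 6), rep("control", 6))),
                    class = "region_saliency_matrix")
  cc2 <- control_congruence(mat2)
  expect_equal(cc2$intercept, 2, tolerance = 1e-12)

  mat3 <- mat
  mat3$groups <- rep("low", 12)
  expect_error(control_congruence(mat3), class = "salnet_value_error")
})
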