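# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

tiny_config <- function(...) {
  cohort_config(n_high = 10, n_low = 10, n_control = 5, grid = 32,
                n_cortical_per_hemi = 10, n_subcortical_per_hemi = 3,
                n_latents = 2, effect_scale = 2.5, seed = 101, ...)
}

shared_cohort <- function() {
  memo("cohort", generate_cohort(tiny_config()))
}

shared_split <- function() {
  memo("split", make_split(shared_cohort()$records, test_n = 6, seed = 2))
}

shared_spec <- function() {
  sp <- shared_split()
  memo("spec", train_spec(sp$train_ids, sp$test_ids, epochs = 8,
                          batch_size = 8, seed = 5))
}

# a trained feature-head model on the shared cohort
shared_fit <- function() {
  memo("fit", {
    co <- shared_cohort()
    severity_cnn(co$volumes, co$records, shared_spec(),
                 config = model_config(depth_preset = "small",
                                       width_scale = 0.5, head = "feature",
                                       feature_dim = 16, seed = 7))
  })
}

shared_matrix <- function() {
  memo("matrix", {
    co <- shared_cohort()
    region_mean_saliency(saliency_maps(shared_fit(), co$volumes), co$atlas,
                         co$records)
  })
}

# a hand-made atlas object (no label volume checks) for statistics tests
mock_atlas <- function(n_cortical_per_hemi = 75, n_sub_per_hemi = 2,
                       n_lobes = 6, networks = network_names()) {
  nc <- n_cortical_per_hemi
  ns <- n_sub_per_hemi
  lobes <- rep_len(rep(lobe_names()[seq_len(n_lobes)],
                       length.out = nc), nc)
  regions <- data.frame(
    region_id = seq_len(2 * nc + 2 * ns),
    name = c(sprintf("ctx_rh_%03d", seq_len(nc)),
             sprintf("ctx_lh_%03d", seq_len(nc)),
             sprintf("sub_rh_%02d", seq_len(ns)),
             sprintf("sub_lh_%02d", seq_len(ns))),
    hemisphere = c(rep("R", nc), rep("L", nc), rep("R", ns), rep("L", ns)),
    lobe = c(lobes, lobes, rep("subcortical", 2 * ns)),
    is_cortical = c(rep(TRUE, 2 * nc), rep(FALSE, 2 * ns)),
    network = c(rep_len(networks, nc), rep_len(networks, nc),
                rep("none", 2 * ns)),
    stringsAsFactors = FALSE
  )
  structure(list(labels = array(0L, c(2, 2, 2)), regions = regions,
                 voxel_size = 1),
            class = "parcellation_atlas")
}

# brute-force tau-b oracle: explicit pair counting with tie correction
oracle_tau <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  tie_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
  if (den == 0) return(NA_real_)
  S / den
}

# a deterministic "feature extractor" whose features are two chosen voxels,
# for hand-enumerable kNN/SVM tests
probe_feature_model <- function(grid = 4, voxels = c(1, 2)) {
  cfg <- model_config(depth_preset = "linear", head = "feature",
                      feature_dim = 2, seed = 1)
  m <- build_classifier(cfg, grid)
  W <- matrix(0, 2, grid^3)
  W[1, voxels[1]] <- 1
  W[2, voxels[2]] <- 1
  m$layers[[2]]$W <- W
  m$layers[[2]]$b <- c(0, 0)
  m$trained <- TRUE
  m
}

vol_from_xy <- function(x, y, grid = 4) {
  a <- array(0, dim = rep(grid, 3))
  a[1] <- x
  a[2] <- y
  brain_volume(a)
}
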