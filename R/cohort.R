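#' Construct a brain volume
#'
#' A 3D nonnegative scalar field on a fixed voxel grid. Axis 1 indexes
#' sagittal slices (index 1 = rightmost), axis 2 coronal, axis 3 axial.
#'
#' @param data numeric 3D array, finite and nonnegative.
#' @param voxel_size isotropic voxel edge length (arbitrary units).
#' @return An object of class `brain_volume` (a 3D array with attributes).
#' @export
brain_volume <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_salnet("a brain volume must be a 3D array",
                class = "salnet_dimension_error")
  }
  if (!all(is.finite(data))) {
    stop_salnet("brain volume contains non-finite values",
                class = "salnet_value_error")
  }
  structure(data,
            voxel_size = as.numeric(voxel_size),
            axes = c("sagittal", "coronal", "axial"),
            class = c("brain_volume", "array"))
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("Brain volume %s (voxel size %.3g), intensity range [%.3g, %.3g]\n",
              paste(dim(x), collapse = "x"), attr(x, "voxel_size"),
              min(x), max(x)))
  invisible(x)
}

# smooth texture field in [-1, 1], shared across subjects; gives the
# planted perturbation within-region spatial structure that convolution
# filters (and hence gradient saliency) can latch onto
texture_field <- function(g) {
  s <- sin(2 * pi * 3 * seq_len(g) / g)
  c2 <- cos(2 * pi * 2 * seq_len(g) / g)
  outer(outer(s, c2, `*`), s, `*`)
}

# shared anatomical template: bright core, mid-intensity shell, dark outside
cohort_template <- function(g) {
  mask <- ellipsoid_mask(g)
  core <- ellipsoid_mask(g, scale = c(0.45, 0.42, 0.42) * 0.52)
  tpl <- array(0, dim = c(g, g, g))
  tpl[mask] <- 10
  tpl[core] <- 13
  tpl + 0.5 * texture_field(g) * mask
}

#' Generate a synthetic MRI cohort with planted severity effects
#'
#' Produces subject records, intensity volumes, the parcellation atlas and
#' the ground-truth effect map for a synthetic severity-spectrum cohort.
#' Each subject's volume is a shared template plus voxel noise; within each
#' affected region an intensity/texture perturbation of magnitude
#' `effect_scale * (loadings %*% latents)` is added, scaled on the left
#' hemisphere by `asymmetry_factor`. Latent effect magnitudes are drawn from
#' disjoint ranges per group (high > low > control), so planted effects order
#' the groups and unscored controls sit on the low tail of the spectrum.
#'
#' Each latent factor loads on the cortical regions of one functional
#' network, giving cross-region saliency correlations a block structure.
#' Behavioural subscores are noisy linear functions of the latents; the
#' SRS-style total is an exact affine function of the mean latent, placing
#' every high-severity subject strictly above the severity split and every
#' low-severity subject strictly below it. Controls carry no scores.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `records`
#'   (data frame of subject phenotypes), `volumes` (named list of
#'   [brain_volume()]s), `atlas` (the [generate_atlas()] result) and
#'   `truth` (class `cohort_truth`: `affected_regions`, `loadings`,
#'   `subject_latents`, `subscore_weights`, `asymmetry_factor`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_high = 4, n_low = 4,
#'   n_control = 2, grid = 24, n_cortical_per_hemi = 8,
#'   n_subcortical_per_hemi = 2, n_latents = 2))
#' head(cohort$records)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_latents > config$n_networks) {
    stop_salnet("n_latents cannot exceed n_networks (one latent factor per ",
                "planted network)", class = "salnet_value_error")
  }
  if (config$effect_scale == 0) {
    warning("effect_scale = 0: groups are inseparable by construction; ",
            "recovery analyses on this cohort measure the null",
            call. = FALSE)
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  atlas <- generate_atlas_impl(config)
  g <- config$grid
  regions <- atlas$regions
  n_regions <- nrow(regions)
  n_lat <- config$n_latents

  # --- ground truth ---------------------------------------------------------
  nets_present <- setdiff(unique(regions$network), "none")
  affected_networks <- sample(nets_present, min(n_lat, length(nets_present)))
  loadings <- matrix(0, nrow = n_regions, ncol = n_lat,
                     dimnames = list(regions$region_id, affected_networks))
  for (l in seq_along(affected_networks)) {
    in_block <- regions$network == affected_networks[l]
    loadings[in_block, l] <- runif(sum(in_block), 0.7, 1.3)
  }
  loadings <- loadings * ifelse(regions$hemisphere == "L",
                                config$asymmetry_factor, 1)
  affected_regions <- regions$region_id[rowSums(abs(loadings)) > 0]

  groups <- c(rep("high", config$n_high), rep("low", config$n_low),
              rep("control", config$n_control))
  n_subj <- length(groups)
  subject_id <- sprintf("s%03d", seq_len(n_subj))

  # latent 1 is the severity factor: disjoint ranges per group give strict
  # group ordering and drive the SRS-style total. The remaining latents are
  # group-independent phenotype factors shared by their region block, so
  # cross-region saliency correlations have block structure that is not a
  # mere restatement of the group contrast.
  sev_range <- list(high = c(2.6, 4.4), low = c(0.8, 1.9),
                    control = c(0.1, 1.0))
  latents <- matrix(0, nrow = n_subj, ncol = n_lat,
                    dimnames = list(subject_id, NULL))
  for (i in seq_len(n_subj)) {
    r <- sev_range[[groups[i]]]
    latents[i, 1] <- runif(1, r[1], r[2])
  }
  if (n_lat > 1L) {
    latents[, -1] <- runif(n_subj * (n_lat - 1L), 0.3, 3.3)
  }

  # --- phenotype scores -----------------------------------------------------
  # total = 20 + 20 * latent_1: high in (72, 108), low in (36, 58)
  subscore_names <- c("cognition", "awareness", "communication",
                      "mannerisms", "motivation")
  W <- matrix(runif(n_lat * 5, 0.3, 1.3), nrow = n_lat,
              dimnames = list(NULL, subscore_names))
  W[1, ] <- runif(5, 1, 2)   # every subscore tracks the severity factor
  raw <- latents %*% W
  colsum <- colSums(W)
  a <- 25 / (4.4 * colsum)
  b <- 5 - a * 0.3 * colsum
  subscores <- sweep(sweep(raw, 2, a, `*`), 2, b, `+`) +
    matrix(rnorm(n_subj * 5, 0, config$subscore_noise_sd), n_subj, 5)
  srs_total <- 20 + 20 * latents[, 1]
  scored <- groups != "control"
  records <- data.frame(
    subject_id = subject_id,
    group = groups,
    srs_total = ifelse(scored, srs_total, NA_real_),
    stringsAsFactors = FALSE
  )
  for (k in subscore_names) {
    records[[k]] <- ifelse(scored, subscores[, k], NA_real_)
  }

  # --- volumes --------------------------------------------------------------
  tpl <- cohort_template(g)
  mask <- ellipsoid_mask(g)
  mask_idx <- which(mask)
  tex <- texture_field(g)
  region_idx <- split(which(atlas$labels > 0),
                      atlas$labels[atlas$labels > 0])
  effect_per_region <- latents %*% t(loadings) * config$effect_scale

  volumes <- vector("list", n_subj)
  names(volumes) <- subject_id
  for (i in seq_len(n_subj)) {
    vol <- tpl
    vol[mask_idx] <- vol[mask_idx] + rnorm(length(mask_idx), 0,
                                           config$noise_sd)
    for (r in as.character(affected_regions)) {
      idx <- region_idx[[r]]
      vol[idx] <- vol[idx] +
        effect_per_region[i, r] * (0.7 + 0.3 * tex[idx])
    }
    vol[vol < 0] <- 0
    volumes[[i]] <- brain_volume(vol)
  }

  truth <- structure(
    list(affected_regions = affected_regions,
         affected_networks = affected_networks,
         loadings = loadings,
         subject_latents = latents,
         subscore_weights = W,
         asymmetry_factor = config$asymmetry_factor),
    class = "cohort_truth"
  )

  structure(
    list(records = records, volumes = volumes, atlas = atlas, truth = truth,
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic MRI cohort\n")
  cat(sprintf("  %d subjects (%d high / %d low / %d control), grid %s\n",
              nrow(x$records), sum(x$records$group == "high"),
              sum(x$records$group == "low"),
              sum(x$records$group == "control"),
              paste(dim(x$volumes[[1]]), collapse = "x")))
  cat(sprintf("  %d regions, %d affected by %d latent factors\n",
              nrow(x$atlas$regions), length(x$truth$affected_regions),
              ncol(x$truth$loadings)))
  invisible(x)
}

#' Binary affected/unaffected labels from the planted-effect ground truth
#'
#' @param truth the `cohort_truth` from [generate_cohort()].
#' @param atlas the matching `parcellation_atlas`.
#' @return Integer vector (0/1) over the atlas regions, in region-table
#'   order, with ones exactly on the planted (affected) regions.
#' @export
truth_recovery_labels <- function(truth, atlas) {
  stopifnot(inherits(truth, "cohort_truth"),
            inherits(atlas, "parcellation_atlas"))
  ids <- atlas$regions$region_id
  truth_ids <- as.integer(rownames(truth$loadings))
  if (!setequal(truth_ids, ids)) {
    stop_salnet("truth and atlas refer to different region sets",
                class = "salnet_consistency_error")
  }
  as.integer(ids %in% truth$affected_regions)
}
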