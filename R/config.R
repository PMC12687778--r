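#' Synthetic cohort configuration
#'
#' Defines the study conditions for a synthetic structural-MRI cohort:
#' cohort sizes for the two scored severity groups plus an unscored control
#' group, the voxel grid, the parcellation layout (cortical and subcortical
#' regions per hemisphere, lobes, functional networks), the latent effect
#' structure that plants correlated regional perturbations, and the noise
#' levels for image intensities and phenotype scores.
#'
#' The default parcellation mirrors a Destrieux-style cortical scheme with an
#' ASEG-style subcortical scheme: 75 cortical and 13 subcortical regions per
#' hemisphere plus two midline structures (brain-stem and fornix analogues),
#' 178 regions in total. The default cohort holds 150 subjects (60 high
#' severity, 60 low severity, 30 unscored controls).
#'
#' @param n_high number of high-severity subjects.
#' @param n_low number of low-severity subjects.
#' @param n_control number of unscored control subjects.
#' @param grid isotropic voxel grid size (even, >= 16).
#' @param n_cortical_per_hemi cortical regions per hemisphere.
#' @param n_subcortical_per_hemi subcortical regions per hemisphere.
#' @param n_midline midline regions not split across hemispheres.
#' @param n_lobes number of cortical lobes.
#' @param n_networks number of functional networks assigned to cortex.
#' @param n_latents number of latent effect factors; each factor loads on the
#'   regions of one functional network, giving the planted cross-region
#'   saliency correlations a block structure.
#' @param effect_scale dimensionless amplitude of the planted regional
#'   perturbation (0 disables all group differences).
#' @param noise_sd standard deviation of the voxel intensity noise
#'   (template intensities are O(10)).
#' @param subscore_noise_sd standard deviation of the noise added to the five
#'   behavioural subscores (score units).
#' @param asymmetry_factor multiplier (>= 1) applied to left-hemisphere
#'   loadings, planting the left-dominant effect the analysis is designed to
#'   recover.
#' @param seed integer random seed; the whole cohort is a deterministic
#'   function of the configuration including this seed.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_atlas()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_high = 10, n_low = 10, n_control = 4, grid = 24,
#'                      n_cortical_per_hemi = 8, n_subcortical_per_hemi = 2)
#' cfg
cohort_config <- function(n_high = 60, n_low = 60, n_control = 30,
                          grid = 48,
                          n_cortical_per_hemi = 75,
                          n_subcortical_per_hemi = 13,
                          n_midline = 2,
                          n_lobes = 6,
                          n_networks = 8,
                          n_latents = 4,
                          effect_scale = 1,
                          noise_sd = 0.5,
                          subscore_noise_sd = 2,
                          asymmetry_factor = 1.5,
                          seed = 1L) {
  cfg <- list(
    n_high = assert_count(n_high, "n_high", min = 1L),
    n_low = assert_count(n_low, "n_low", min = 1L),
    n_control = assert_count(n_control, "n_control", min = 0L),
    grid = assert_count(grid, "grid", min = 16L),
    n_cortical_per_hemi = assert_count(n_cortical_per_hemi,
                                       "n_cortical_per_hemi", min = 1L),
    n_subcortical_per_hemi = assert_count(n_subcortical_per_hemi,
                                          "n_subcortical_per_hemi", min = 0L),
    n_midline = assert_count(n_midline, "n_midline", min = 0L),
    n_lobes = assert_count(n_lobes, "n_lobes", min = 1L),
    n_networks = assert_count(n_networks, "n_networks", min = 1L),
    n_latents = assert_count(n_latents, "n_latents", min = 1L),
    effect_scale = assert_number(effect_scale, "effect_scale", min = 0),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0, strict = TRUE),
    subscore_noise_sd = assert_number(subscore_noise_sd, "subscore_noise_sd",
                                      min = 0),
    asymmetry_factor = assert_number(asymmetry_factor, "asymmetry_factor",
                                     min = 1),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$grid %% 2L != 0L) {
    stop_salnet("grid must be even so the mid-sagittal plane falls between ",
                "two voxel columns", class = "salnet_value_error")
  }
  if (cfg$n_lobes > cfg$n_cortical_per_hemi) {
    stop_salnet("n_lobes cannot exceed n_cortical_per_hemi",
                class = "salnet_value_error")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d high / %d low / %d control\n",
              x$n_high, x$n_low, x$n_control))
  cat(sprintf("  grid: %d^3, regions: %d cortical + %d subcortical per hemisphere, %d midline\n",
              x$grid, x$n_cortical_per_hemi, x$n_subcortical_per_hemi,
              x$n_midline))
  cat(sprintf("  lobes: %d, networks: %d, latent factors: %d\n",
              x$n_lobes, x$n_networks, x$n_latents))
  cat(sprintf("  effect_scale: %.3g, noise_sd: %.3g, subscore_noise_sd: %.3g, asymmetry: %.3g\n",
              x$effect_scale, x$noise_sd, x$subscore_noise_sd,
              x$asymmetry_factor))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# severity split on the SRS-style total score: totals at or above
# `high` are high severity, at or below `low` are low severity; the
# generator never produces totals in the open interval between them.
severity_split <- function() {
  list(low = 59, high = 70)
}
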