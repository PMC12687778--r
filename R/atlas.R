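#' @importFrom stats rnorm runif sd
NULL

# --- geometry helpers -------------------------------------------------------

# logical ellipsoid mask centred in the grid; symmetric about the
# mid-sagittal plane by construction
ellipsoid_mask <- function(grid, scale = c(0.45, 0.42, 0.42)) {
  cx <- (grid + 1) / 2
  x <- ((seq_len(grid) - cx) / (scale[1] * grid))^2
  y <- ((seq_len(grid) - cx) / (scale[2] * grid))^2
  z <- ((seq_len(grid) - cx) / (scale[3] * grid))^2
  q <- outer(outer(x, y, `+`), z, `+`)
  q <= 1
}

# greedy farthest-point seed selection over voxel coordinates; fully
# deterministic (starts from the voxel closest to the domain centroid)
farthest_seeds <- function(coords, k) {
  n <- nrow(coords)
  centroid <- colMeans(coords)
  d2c <- rowSums(sweep(coords, 2, centroid)^2)
  seeds <- integer(k)
  seeds[1] <- which.min(d2c)
  if (k == 1L) return(seeds)
  d2 <- rowSums(sweep(coords, 2, coords[seeds[1], ])^2)
  for (i in 2:k) {
    seeds[i] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(coords, 2, coords[seeds[i], ])^2))
  }
  seeds
}

# multi-source breadth-first region growing on the 6-connected voxel
# lattice restricted to `domain`; every domain voxel reachable from a seed
# receives the label of the first frontier that touches it
grow_regions <- function(domain, seed_idx, labels = seq_along(seed_idx)) {
  dims <- dim(domain)
  lab <- array(0L, dims)
  lab[seed_idx] <- as.integer(labels)
  shifts <- list(
    function(a) { b <- array(0L, dims); b[-1, , ] <- a[-dims[1], , ]; b },
    function(a) { b <- array(0L, dims); b[-dims[1], , ] <- a[-1, , ]; b },
    function(a) { b <- array(0L, dims); b[, -1, ] <- a[, -dims[2], ]; b },
    function(a) { b <- array(0L, dims); b[, -dims[2], ] <- a[, -1, ]; b },
    function(a) { b <- array(0L, dims); b[, , -1] <- a[, , -dims[3]]; b },
    function(a) { b <- array(0L, dims); b[, , -dims[3]] <- a[, , -1]; b }
  )
  repeat {
    changed <- FALSE
    for (sh in shifts) {
      cand <- sh(lab)
      fill <- domain & lab == 0L & cand > 0L
      if (any(fill)) {
        lab[fill] <- cand[fill]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# evenly-as-possible partition sizes of n into k parts
even_partition <- function(n, k) {
  diff(floor(seq(0, n, length.out = k + 1)))
}

#' Names of the functional networks used for involvement summaries
#'
#' @return Character vector of the eight network labels.
#' @export
network_names <- function() {
  c("DefaultMode", "Salience", "Frontoparietal", "Social",
    "Language", "Sensorimotor", "DorsalVentralAttention", "LimbicEmotion")
}

lobe_names <- function() {
  c("frontal", "insula", "limbic", "parietal", "temporal", "occipital")
}

# --- atlas generation -------------------------------------------------------

#' Generate a synthetic two-hemisphere brain parcellation
#'
#' Builds an integer label volume plus a region table emulating a
#' Destrieux-style cortical parcellation with an ASEG-style subcortical
#' segmentation. Cortical regions tile an ellipsoidal shell, subcortical
#' regions tile the core, and midline structures (brain-stem and fornix
#' analogues) straddle the mid-sagittal plane. Left cortical and subcortical
#' regions are exact mirror images of their right-hemisphere counterparts.
#' Axis 1 is sagittal with index 1 the rightmost slice.
#'
#' Region growing is a deterministic multi-source breadth-first flood from
#' farthest-point seeds, so regions are connected blobs; lobes are
#' anterior-to-posterior bands of cortical regions; functional networks are
#' assigned to mirror pairs of cortical regions (balanced across networks,
#' shuffled by the configuration seed).
#'
#' @param config a [cohort_config()].
#' @return An object of class `parcellation_atlas`: a list with `labels`
#'   (integer 3D array, 0 = background), `regions` (data frame with
#'   `region_id`, `name`, `hemisphere`, `lobe`, `is_cortical`, `network`)
#'   and `voxel_size`.
#' @export
#' @examples
#' atlas <- generate_atlas(cohort_config(grid = 24, n_cortical_per_hemi = 6,
#'                                       n_subcortical_per_hemi = 2))
#' table(atlas$regions$hemisphere)
generate_atlas <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_atlas_impl(config))
}

generate_atlas_impl <- function(config) {
  g <- config$grid
  n_cort <- config$n_cortical_per_hemi
  n_sub <- config$n_subcortical_per_hemi
  n_mid <- config$n_midline

  mask <- ellipsoid_mask(g)
  core <- ellipsoid_mask(g, scale = c(0.45, 0.42, 0.42) * 0.52)
  shell <- mask & !core

  X <- slice.index(mask, 1)
  right <- X <= g / 2

  # midline slab: the two voxel columns around the mid-sagittal plane
  mid_slab <- abs(X - (g + 1) / 2) <= 1
  mid_domain <- core & mid_slab
  sub_domain <- core & !mid_slab

  check_capacity <- function(domain, n, what) {
    if (n > 0 && sum(domain) < 8L * n) {
      stop_salnet(
        "grid ", g, " too small: ", what, " domain has ", sum(domain),
        " voxels for ", n, " regions (need >= ", 8L * n, ")",
        class = "salnet_sizing_error"
      )
    }
  }
  check_capacity(shell & right, n_cort, "cortical")
  check_capacity(sub_domain & right, n_sub, "subcortical")
  check_capacity(mid_domain, n_mid, "midline")

  labels <- array(0L, dim = c(g, g, g))
  regions <- list()
  next_id <- 1L

  grow_hemi_pair <- function(domain_right, n) {
    # label the right hemisphere, then mirror to the left
    idx <- which(domain_right)
    coords <- which(domain_right, arr.ind = TRUE)
    fs <- farthest_seeds(coords, n)
    lab_r <- grow_regions(domain_right, idx[fs])
    list(right = lab_r, seeds = coords[fs, , drop = FALSE])
  }

  seed_coords_cort <- NULL
  if (n_cort > 0) {
    hp <- grow_hemi_pair(shell & right, n_cort)
    lab_r <- hp$right
    seed_coords_cort <- hp$seeds
    lab_l <- flip_sagittal(lab_r)
    ids_r <- seq_len(n_cort)                 # right cortical: 1..n_cort
    ids_l <- n_cort + seq_len(n_cort)        # left cortical: mirror partners
    labels[lab_r > 0] <- lab_r[lab_r > 0]
    labels[lab_l > 0] <- lab_l[lab_l > 0] + n_cort
  }
  next_id <- 2L * n_cort + 1L

  if (n_sub > 0) {
    hp <- grow_hemi_pair(sub_domain & right, n_sub)
    lab_r <- hp$right
    lab_l <- flip_sagittal(lab_r)
    labels[lab_r > 0] <- lab_r[lab_r > 0] + (next_id - 1L)
    labels[lab_l > 0] <- lab_l[lab_l > 0] + (next_id - 1L) + n_sub
  }
  next_id <- next_id + 2L * n_sub

  if (n_mid > 0) {
    # split the midline domain into z-bands (brain-stem analogue lowest)
    idx <- which(mid_domain)
    z <- slice.index(mid_domain, 3)[idx]
    ord <- order(z, idx)
    sizes <- even_partition(length(idx), n_mid)
    band <- rep.int(seq_len(n_mid), sizes)
    lab_m <- array(0L, dim = dim(labels))
    lab_m[idx[ord]] <- band
    labels[lab_m > 0] <- lab_m[lab_m > 0] + (next_id - 1L)
  }

  # ---- region table --------------------------------------------------------
  lobes_r <- character(0)
  nets_r <- character(0)
  if (n_cort > 0) {
    # lobes: anterior-to-posterior bands of the right-hemisphere seeds,
    # mirrored to the left so lobe structure is hemisphere-symmetric
    ord <- order(-seed_coords_cort[, 2], seed_coords_cort[, 3])
    sizes <- even_partition(n_cort, config$n_lobes)
    lob <- character(n_cort)
    lob[ord] <- rep.int(rep_len(lobe_names(), config$n_lobes), sizes)
    lobes_r <- lob
    nets <- rep_len(network_names()[seq_len(min(config$n_networks, 8L))],
                    n_cort)
    nets_r <- sample(nets)
  }

  mid_names <- c("brain_stem", "fornix",
                 if (n_mid > 2) paste0("midline_", seq_len(n_mid - 2) + 2L))

  regions <- data.frame(
    region_id = seq_len(2L * n_cort + 2L * n_sub + n_mid),
    name = c(sprintf("ctx_rh_%03d", seq_len(n_cort)),
             sprintf("ctx_lh_%03d", seq_len(n_cort)),
             sprintf("sub_rh_%02d", seq_len(n_sub)),
             sprintf("sub_lh_%02d", seq_len(n_sub)),
             mid_names[seq_len(n_mid)]),
    hemisphere = c(rep("R", n_cort), rep("L", n_cort),
                   rep("R", n_sub), rep("L", n_sub),
                   rep("midline", n_mid)),
    lobe = c(lobes_r, lobes_r,
             rep("subcortical", 2L * n_sub), rep("midline", n_mid)),
    is_cortical = c(rep(TRUE, 2L * n_cort), rep(FALSE, 2L * n_sub + n_mid)),
    network = c(nets_r, nets_r, rep("none", 2L * n_sub + n_mid)),
    stringsAsFactors = FALSE
  )

  atlas <- structure(
    list(labels = labels, regions = regions, voxel_size = 1),
    class = "parcellation_atlas"
  )
  validate_atlas(atlas, min_voxels = 8L)
  atlas
}

# cross-validates label volume against the region table
validate_atlas <- function(atlas, min_voxels = 1L) {
  lab <- atlas$labels
  present <- sort(unique(as.integer(lab[lab > 0])))
  ids <- sort(atlas$regions$region_id)
  if (anyDuplicated(ids)) {
    stop_salnet("duplicate region_id in region table: ",
                paste(ids[duplicated(ids)], collapse = ", "),
                class = "salnet_consistency_error")
  }
  if (!identical(present, ids)) {
    missing_in_table <- setdiff(present, ids)
    missing_in_volume <- setdiff(ids, present)
    stop_salnet(
      "label volume and region table disagree",
      if (length(missing_in_table)) {
        paste0("; labels absent from table: ",
               paste(missing_in_table, collapse = ", "))
      } else "",
      if (length(missing_in_volume)) {
        paste0("; table ids absent from volume: ",
               paste(missing_in_volume, collapse = ", "))
      } else "",
      class = "salnet_consistency_error"
    )
  }
  counts <- region_voxel_counts(atlas)
  if (any(counts < min_voxels)) {
    small <- atlas$regions$region_id[counts < min_voxels]
    stop_salnet("regions with fewer than ", min_voxels, " voxels: ",
                paste(small, collapse = ", "),
                class = "salnet_sizing_error")
  }
  invisible(atlas)
}

#' Voxel counts per atlas region
#'
#' @param atlas a `parcellation_atlas`.
#' @return Integer vector of voxel counts, in region-table order.
#' @export
region_voxel_counts <- function(atlas) {
  tab <- tabulate(atlas$labels[atlas$labels > 0],
                  nbins = max(atlas$regions$region_id))
  tab[atlas$regions$region_id]
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  r <- x$regions
  cat("Parcellation atlas\n")
  cat(sprintf("  grid: %s, %d regions (%d cortical, %d subcortical, %d midline)\n",
              paste(dim(x$labels), collapse = "x"), nrow(r),
              sum(r$is_cortical),
              sum(!r$is_cortical & r$hemisphere != "midline"),
              sum(r$hemisphere == "midline")))
  cat(sprintf("  lobes: %s\n",
              paste(unique(r$lobe[r$is_cortical]), collapse = ", ")))
  cat(sprintf("  networks: %s\n",
              paste(setdiff(unique(r$network), "none"), collapse = ", ")))
  invisible(x)
}
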