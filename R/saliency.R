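#' Voxel-level gradient saliency for a classified volume
#'
#' Attribution of the classifier's decision to input voxels. The default
#' (`method = "gradient_input"`) is gradient-times-input in the model's
#' input space: the gradient of the target-class pre-activation score is
#' weighted by the encoded deviation of the voxel from the reference
#' anatomy, so attribution concentrates where structure actually deviates.
#' `method = "gradient"` is the plain absolute input gradient. Both are
#' taken through the model's input encoding, so maps are on a per-cohort
#' scale.
#'
#' @param fit a trained `severity_cnn`.
#' @param volume a [brain_volume()] (or, for 2D models, a `(1, H, W)` array).
#' @param target `"predicted"` (default: the model's predicted class for
#'   this volume), `"high"`, `"low"`, or `"contrast"` (the high-minus-low
#'   severity score direction).
#' @param method `"gradient_input"` (default) or `"gradient"`.
#' @return An object of class `saliency_volume`: a nonnegative array of the
#'   input shape with attributes `target` (the class used) and `method`.
#' @export
compute_saliency <- function(fit, volume,
                             target = c("predicted", "high", "low",
                                        "contrast"),
                             method = c("gradient_input", "gradient")) {
  stopifnot(inherits(fit, "severity_cnn"))
  target <- match.arg(target)
  method <- match.arg(method)
  x <- batch_input(list(v = volume), "v", fit$norm)
  fw <- net_forward(fit, x, 1L)
  head <- fit$config$head
  if (target == "contrast") {
    dz <- matrix(0, nrow(fw$out), 1L)
    if (head %in% c("softmax", "feature")) {
      dz[2, ] <- 1
      dz[1, ] <- -1
    } else {
      dz[1, ] <- 1
    }
    used <- "contrast"
  } else {
    cls <- switch(target,
                  predicted = head_predict(head, fw$out),
                  high = 1L,
                  low = 0L)
    dz <- head_class_score_grad(head, fw$out, cls)
    used <- fit$classes[cls + 1L]
  }
  bw <- net_backward(fit, dz, fw$caches, 1L)
  g <- bw$dX / fit$norm$scale
  if (!all(is.finite(g))) {
    stop_salnet("non-finite input gradients (model diverged?)",
                class = "salnet_numerical_error")
  }
  # gradient x input in the model's input space: weight the Jacobian by the
  # encoded deviation from the reference anatomy
  if (method == "gradient_input") g <- g * x
  structure(array(abs(g), dim = dim(volume)),
            target = used, method = method,
            class = c("saliency_volume", "array"))
}

#' @export
print.saliency_volume <- function(x, ...) {
  cat(sprintf("Saliency volume %s (target %s, %s), range [%.3g, %.3g]\n",
              paste(dim(x), collapse = "x"), attr(x, "target"),
              attr(x, "method"), min(x), max(x)))
  invisible(x)
}

#' Saliency maps for a set of subjects
#'
#' @inheritParams compute_saliency
#' @param volumes named list of [brain_volume()]s.
#' @return Named list of `saliency_volume`s.
#' @export
saliency_maps <- function(fit, volumes, target = "predicted",
                          method = "gradient_input") {
  out <- lapply(volumes, compute_saliency, fit = fit, target = target,
                method = method)
  names(out) <- names(volumes)
  out
}

#' Aggregate voxel saliency into a subjects-by-regions matrix
#'
#' Entry (s, r) is the mean saliency over the voxels labelled r for subject
#' s; background voxels are excluded.
#'
#' @param sal_volumes named list of `saliency_volume`s sharing the atlas
#'   grid (names = subject ids).
#' @param atlas a `parcellation_atlas`.
#' @param records optional phenotype data frame supplying group labels.
#' @return An object of class `region_saliency_matrix`: a list with `values`
#'   (subjects x regions matrix, dimnames set), `region_ids` and `groups`.
#' @export
region_mean_saliency <- function(sal_volumes, atlas, records = NULL) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  counts <- region_voxel_counts(atlas)
  if (any(counts == 0L)) {
    stop_salnet("atlas regions without voxels: ",
                paste(atlas$regions$region_id[counts == 0L], collapse = ", "),
                class = "salnet_consistency_error")
  }
  nz <- atlas$labels > 0
  lv <- atlas$labels[nz]
  ids <- names(sal_volumes) %||% as.character(seq_along(sal_volumes))
  region_ids <- atlas$regions$region_id
  values <- matrix(NA_real_, length(ids), length(region_ids),
                   dimnames = list(ids, region_ids))
  for (i in seq_along(sal_volumes)) {
    v <- sal_volumes[[i]]
    if (!identical(dim(v), dim(atlas$labels))) {
      stop_salnet("saliency volume ", ids[i], " does not match the atlas ",
                  "grid", class = "salnet_dimension_error")
    }
    sums <- rowsum(v[nz], group = lv)
    values[i, ] <- sums[as.character(region_ids), 1] / counts
  }
  groups <- if (!is.null(records)) {
    records$group[match(ids, records$subject_id)]
  } else {
    rep(NA_character_, length(ids))
  }
  structure(
    list(values = values, subject_ids = ids, region_ids = region_ids,
         groups = groups),
    class = "region_saliency_matrix"
  )
}

#' @export
print.region_saliency_matrix <- function(x, ...) {
  cat(sprintf("Region saliency matrix: %d subjects x %d regions\n",
              nrow(x$values), ncol(x$values)))
  if (!all(is.na(x$groups))) {
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                   table(x$groups)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hemispheric saliency summary
#'
#' Compares per-region average saliency between the left and right
#' hemispheres over the cortical regions: hemisphere means, a pooled-variance
#' two-sample t test over per-region averages (df = n_L + n_R - 2), and the
#' same comparison for the per-region saliency range, defined as the absolute
#' difference between the high-severity and low-severity group means of each
#' region.
#'
#' @param mat a `region_saliency_matrix` (with group labels if the range
#'   comparison is wanted).
#' @param atlas the matching `parcellation_atlas`.
#' @return A list of class `hemisphere_summary`: `lh_mean`, `rh_mean`,
#'   `statistic`, `df`, `p_value`, and (when both severity groups are
#'   present) `range_lh_mean`, `range_rh_mean`, `range_statistic`,
#'   `range_p_value`.
#' @export
hemisphere_summary <- function(mat, atlas) {
  stopifnot(inherits(mat, "region_saliency_matrix"),
            inherits(atlas, "parcellation_atlas"))
  r <- atlas$regions
  lh <- r$region_id[r$is_cortical & r$hemisphere == "L"]
  rh <- r$region_id[r$is_cortical & r$hemisphere == "R"]
  if (length(lh) < 2L || length(rh) < 2L) {
    stop_salnet("need at least two cortical regions per hemisphere",
                class = "salnet_statistics_error")
  }
  region_means <- colMeans(mat$values)
  x <- region_means[as.character(lh)]
  y <- region_means[as.character(rh)]
  tt <- pooled_t(x, y)
  out <- list(lh_mean = mean(x), rh_mean = mean(y),
              statistic = tt$statistic, df = tt$df, p_value = tt$p_value)
  if (all(c("high", "low") %in% mat$groups)) {
    hi <- colMeans(mat$values[mat$groups == "high", , drop = FALSE])
    lo <- colMeans(mat$values[mat$groups == "low", , drop = FALSE])
    rng <- abs(hi - lo)
    rt <- pooled_t(rng[as.character(lh)], rng[as.character(rh)])
    out$range_lh_mean <- mean(rng[as.character(lh)])
    out$range_rh_mean <- mean(rng[as.character(rh)])
    out$range_statistic <- rt$statistic
    out$range_df <- rt$df
    out$range_p_value <- rt$p_value
  }
  structure(out, class = "hemisphere_summary")
}

# classic pooled-variance two-sample t test
pooled_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    stat <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
  } else {
    stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  list(statistic = stat, df = df,
       p_value = 2 * stats::pt(-abs(stat), df))
}

#' @export
print.hemisphere_summary <- function(x, ...) {
  cat(sprintf("Hemisphere saliency summary: LH %.4g vs RH %.4g (t = %.3f, df = %d, p = %.3g)\n",
              x$lh_mean, x$rh_mean, x$statistic, x$df, x$p_value))
  if (!is.null(x$range_p_value)) {
    cat(sprintf("  high-low range: LH %.4g vs RH %.4g (t = %.3f, df = %d, p = %.3g)\n",
                x$range_lh_mean, x$range_rh_mean, x$range_statistic,
                x$range_df, x$range_p_value))
  }
  invisible(x)
}

#' Hemisphere-wise sagittal projection of a saliency volume
#'
#' Averages over each hemisphere's sagittal slices, producing one 2D
#' (coronal x axial) overlay field per hemisphere. With the package axis
#' convention, the right hemisphere is the lower half of axis 1.
#'
#' @param sal_volume a `saliency_volume` (or any 3D array).
#' @return List with 2D matrices `right` and `left`.
#' @export
sagittal_projection <- function(sal_volume) {
  if (length(dim(sal_volume)) != 3L) {
    stop_salnet("expected a 3D saliency volume",
                class = "salnet_dimension_error")
  }
  g <- dim(sal_volume)[1]
  half <- g %/% 2L
  list(
    right = apply(sal_volume[seq_len(half), , , drop = FALSE], c(2, 3), mean),
    left = apply(sal_volume[(half + 1L):g, , , drop = FALSE], c(2, 3), mean)
  )
}
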