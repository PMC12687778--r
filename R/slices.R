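axis_index <- function(axis) {
  switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
}

# pull slice `s` (1-based) of `vol` along `axis` as a (1, H, W) array
extract_slice <- function(vol, axis, s) {
  sl <- switch(axis,
               sagittal = vol[s, , , drop = TRUE],
               coronal = vol[, s, , drop = TRUE],
               axial = vol[, , s, drop = TRUE])
  array(sl, dim = c(1L, dim(sl)))
}

#' Slice-range evaluation with 2D classifiers
#'
#' Trains one 2D residual classifier per contiguous group of slices along a
#' chosen axis and reports per-group accuracy. Every slice of a training
#' subject in the group is a training image labelled with the subject's
#' severity group; held-out subjects are classified by majority vote over
#' their slices in the group (ties broken toward low). Slice indices are
#' 0-based; the default range 24-103 in groups of 8 yields 10 groups on a
#' 128-length axis.
#'
#' @param volumes named list of [brain_volume()]s.
#' @param records phenotype data frame.
#' @param spec a [train_spec()] giving the subject-level train/test split
#'   (slices never cross the split).
#' @param axis `"sagittal"`, `"axial"` or `"coronal"`.
#' @param start,stop first and last slice index (0-based, inclusive).
#' @param group_size slices per group; must divide `stop - start + 1`.
#' @param config a 2D [model_config()] used for every group.
#' @return A data frame of class `slice_range_result` with one row per
#'   group: `start`, `stop`, `accuracy` (subject-level majority vote) and
#'   `slice_accuracy`.
#' @export
slice_range_evaluation <- function(volumes, records, spec,
                                   axis = c("sagittal", "axial", "coronal"),
                                   start = 24L, stop = 103L, group_size = 8L,
                                   config = model_config(
                                     dimensionality = 2,
                                     depth_preset = "small")) {
  axis <- match.arg(axis)
  stopifnot(inherits(spec, "train_spec"))
  if (config$dimensionality != 2L) {
    stop_salnet("slice-range evaluation needs a 2D model configuration",
                class = "salnet_value_error")
  }
  dims <- dim(volumes[[1]])
  ax_len <- dims[axis_index(axis)]
  if (ax_len < stop + 1L) {
    stop_salnet("axis length ", ax_len, " is smaller than stop + 1 = ",
                stop + 1L, class = "salnet_value_error")
  }
  if ((stop - start + 1L) %% group_size != 0L) {
    stop_salnet("stop - start + 1 must be divisible by group_size",
                class = "salnet_value_error")
  }
  y_train <- subject_labels(records, spec$train_ids)
  y_test <- subject_labels(records, spec$test_ids)

  slice_dims <- dims[-axis_index(axis)]
  starts <- seq(start, stop, by = group_size)
  rows <- vector("list", length(starts))
  for (gi in seq_along(starts)) {
    s0 <- starts[gi]
    s_idx <- s0:(s0 + group_size - 1L) + 1L  # to 1-based
    make_slices <- function(ids) {
      out <- list()
      for (id in ids) {
        for (s in s_idx) {
          out[[paste0(id, "#", s)]] <- extract_slice(volumes[[id]], axis, s)
        }
      }
      out
    }
    train_slices <- make_slices(spec$train_ids)
    test_slices <- make_slices(spec$test_ids)
    slice_records <- data.frame(
      subject_id = c(names(train_slices), names(test_slices)),
      group = c(rep(records$group[match(spec$train_ids,
                                        records$subject_id)],
                    each = group_size),
                rep(records$group[match(spec$test_ids,
                                        records$subject_id)],
                    each = group_size)),
      stringsAsFactors = FALSE
    )
    slice_spec <- train_spec(names(train_slices), names(test_slices),
                             epochs = spec$epochs,
                             batch_size = max(spec$batch_size, 16L),
                             lr = spec$lr, seed = spec$seed)
    model <- build_classifier(config, slice_dims)
    fit <- train_classifier(model, c(train_slices, test_slices),
                            slice_records, slice_spec)
    pred <- fit$result$predictions
    pred$subject <- sub("#[0-9]+$", "", pred$subject_id)
    by_subj <- split(pred$predicted, pred$subject)
    subj_pred <- vapply(by_subj, function(p) {
      nh <- sum(p == "high")
      if (nh > length(p) / 2) "high" else "low"
    }, character(1))
    truth <- records$group[match(names(subj_pred), records$subject_id)]
    rows[[gi]] <- data.frame(
      start = s0, stop = s0 + group_size - 1L,
      accuracy = mean(subj_pred == truth),
      slice_accuracy = fit$result$accuracy
    )
  }
  out <- do.call(rbind, rows)
  structure(out, axis = axis, class = c("slice_range_result", "data.frame"))
}
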