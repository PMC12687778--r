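#' @importFrom RNifti readNifti writeNifti asNifti orientation `orientation<-`
#'   xform `sform<-` pixdim
NULL

# canonical on-disk orientation: axis 1 sagittal with index 1 the rightmost
# slice (increasing toward the left), axis 2 coronal (toward anterior),
# axis 3 axial (toward superior)
CANONICAL_ORIENTATION <- "LAS"

las_affine <- function(voxel_size = 1) {
  structure(diag(c(-voxel_size, voxel_size, voxel_size, 1)), code = 2L)
}

#' Read and write brain volumes in NIfTI-1 format
#'
#' `read_volume()` reads a 3D NIfTI image and normalizes its axis order and
#' polarity to the package convention (sagittal, coronal, axial, with sagittal
#' index 1 on the right hemisphere) using the file's qform/sform orientation
#' metadata. Files without orientation metadata are rejected rather than
#' silently assumed. `write_volume()` writes the volume with an explicit
#' canonical orientation so that `read_volume(write_volume(v))` reproduces the
#' data and voxel size exactly.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param volume a [brain_volume()] (or plain 3D array).
#' @param integer_labels write as 32-bit integers (for label volumes) rather
#'   than doubles.
#' @return `read_volume()` returns a [brain_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop_salnet("expected a 3D image, got ", length(dim(img)),
                " dimensions in ", path, class = "salnet_dimension_error")
  }
  code <- attr(RNifti::xform(img), "code")
  if (is.null(code) || code == 0L) {
    stop_salnet("image has no orientation metadata (qform and sform codes ",
                "are zero); refusing to guess axis order for ", path,
                class = "salnet_orientation_error")
  }
  RNifti::orientation(img) <- CANONICAL_ORIENTATION
  vx <- RNifti::pixdim(img)[1]
  arr <- array(as.numeric(img), dim = dim(img))
  brain_volume(arr, voxel_size = vx)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, integer_labels = FALSE) {
  if (!is.array(volume) || length(dim(volume)) != 3L) {
    stop_salnet("expected a 3D array", class = "salnet_dimension_error")
  }
  vx <- attr(volume, "voxel_size") %||% 1
  img <- RNifti::asNifti(array(as.numeric(volume), dim = dim(volume)))
  RNifti::pixdim(img) <- rep(vx, 3)
  RNifti::sform(img) <- las_affine(vx)
  RNifti::writeNifti(img, path,
                     datatype = if (integer_labels) "int32" else "double")
  invisible(path)
}

# --- region tables ----------------------------------------------------------

REGION_COLUMNS <- c("region_id", "name", "hemisphere", "lobe", "is_cortical",
                    "network")

region_vocab <- function(regions) {
  list(hemisphere = sort(unique(regions$hemisphere)),
       lobe = sort(unique(regions$lobe)),
       network = sort(unique(regions$network)))
}

#' Read and write a parcellation atlas (label volume + region table)
#'
#' The region table is tab-separated with columns `region_id`, `name`,
#' `hemisphere`, `lobe`, `is_cortical`, `network`, preceded by `#vocab`
#' header lines declaring the controlled vocabularies for the categorical
#' columns. Reading cross-validates the label volume against the table and
#' fails listing the offending labels if they disagree.
#'
#' @param atlas a `parcellation_atlas`.
#' @param label_path NIfTI path for the integer label volume.
#' @param table_path TSV path for the region table.
#' @return `read_atlas()` returns a `parcellation_atlas`; `write_atlas()`
#'   returns invisibly.
#' @export
write_atlas <- function(atlas, label_path, table_path) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  lab <- brain_volume(array(as.numeric(atlas$labels), dim = dim(atlas$labels)),
                      voxel_size = atlas$voxel_size)
  write_volume(lab, label_path, integer_labels = TRUE)
  vocab <- region_vocab(atlas$regions)
  con <- file(table_path, "w")
  on.exit(close(con))
  for (v in names(vocab)) {
    writeLines(sprintf("#vocab %s: %s", v, paste(vocab[[v]], collapse = ",")),
               con)
  }
  utils::write.table(atlas$regions[, REGION_COLUMNS], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(label_path, table_path) {
  vol <- read_volume(label_path)
  labels <- array(as.integer(round(vol)), dim = dim(vol))
  regions <- read_region_table(table_path)
  atlas <- structure(
    list(labels = labels, regions = regions,
         voxel_size = attr(vol, "voxel_size")),
    class = "parcellation_atlas"
  )
  validate_atlas(atlas, min_voxels = 1L)
  atlas
}

read_region_table <- function(table_path) {
  lines <- readLines(table_path)
  vocab_lines <- grep("^#vocab ", lines, value = TRUE)
  vocab <- list()
  for (v in vocab_lines) {
    m <- regmatches(v, regexec("^#vocab ([a-z_]+): (.*)$", v))[[1]]
    vocab[[m[2]]] <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  }
  body <- lines[!startsWith(lines, "#")]
  regions <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  if (!identical(sort(names(regions)), sort(REGION_COLUMNS))) {
    stop_salnet("region table must have columns ",
                paste(REGION_COLUMNS, collapse = ", "),
                class = "salnet_format_error")
  }
  regions <- regions[, REGION_COLUMNS]
  if (anyDuplicated(regions$region_id)) {
    stop_salnet("duplicate region_id in region table: ",
                paste(unique(regions$region_id[duplicated(regions$region_id)]),
                      collapse = ", "),
                class = "salnet_consistency_error")
  }
  regions$is_cortical <- as.logical(regions$is_cortical)
  for (v in intersect(names(vocab), c("hemisphere", "lobe", "network"))) {
    bad <- setdiff(unique(regions[[v]]), vocab[[v]])
    if (length(bad)) {
      stop_salnet("region table column ", v,
                  " contains values outside the declared vocabulary: ",
                  paste(bad, collapse = ", "),
                  class = "salnet_vocabulary_error")
    }
  }
  regions
}

# --- phenotype tables -------------------------------------------------------

SUBSCORE_NAMES <- c("cognition", "awareness", "communication", "mannerisms",
                    "motivation")

#' Read and write phenotype tables
#'
#' Tab-separated with columns `subject_id`, `group` (`high`, `low` or
#' `control`), `srs_total` and the five behavioural subscores (`cognition`,
#' `awareness`, `communication`, `mannerisms`, `motivation`). Controls are
#' unscored: their score fields must be blank. Scored subjects must respect
#' the severity split (high totals at or above 70, low totals at or below
#' 59).
#'
#' @param path TSV path.
#' @param records data frame of subject records.
#' @return `read_phenotypes()` returns the validated data frame of subject
#'   records; `write_phenotypes()` returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  records <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(records)
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(records, path) {
  validate_phenotypes(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_phenotypes <- function(records) {
  needed <- c("subject_id", "group", "srs_total", SUBSCORE_NAMES)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_salnet("phenotype table lacks columns: ",
                paste(missing, collapse = ", "),
                class = "salnet_format_error")
  }
  records <- records[, needed]
  bad_group <- setdiff(unique(records$group), c("high", "low", "control"))
  if (length(bad_group)) {
    stop_salnet("unknown severity group: ", paste(bad_group, collapse = ", "),
                class = "salnet_vocabulary_error")
  }
  if (anyDuplicated(records$subject_id)) {
    stop_salnet("duplicate subject_id in phenotype table",
                class = "salnet_consistency_error")
  }
  score_cols <- c("srs_total", SUBSCORE_NAMES)
  is_control <- records$group == "control"
  scored_na <- rowSums(is.na(records[, score_cols])) > 0
  if (any(is_control & rowSums(!is.na(records[, score_cols])) > 0)) {
    stop_salnet("control subjects must have blank score fields: ",
                paste(records$subject_id[is_control &
                        rowSums(!is.na(records[, score_cols])) > 0],
                      collapse = ", "),
                class = "salnet_validation_error")
  }
  if (any(!is_control & scored_na)) {
    stop_salnet("scored subjects with missing scores: ",
                paste(records$subject_id[!is_control & scored_na],
                      collapse = ", "),
                class = "salnet_validation_error")
  }
  split <- severity_split()
  hi_bad <- records$group == "high" & records$srs_total < split$high
  lo_bad <- records$group == "low" & records$srs_total > split$low
  hi_bad[is.na(hi_bad)] <- FALSE
  lo_bad[is.na(lo_bad)] <- FALSE
  if (any(hi_bad) || any(lo_bad)) {
    stop_salnet(
      "severity totals violate the split (high >= ", split$high,
      ", low <= ", split$low, "): ",
      paste(records$subject_id[hi_bad | lo_bad], collapse = ", "),
      class = "salnet_validation_error"
    )
  }
  records
}
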