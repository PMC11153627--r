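## S3 containers for volumetric objects and the subject x ROI x system value
## array. Volumetric data are stored over in-mask voxels only (V x K or V x T
## matrices) together with the logical 3D mask and the affine needed to
## reconstitute full volumes for NIfTI output.

#' Construct a molecular template set
#'
#' A set of K named molecular density maps (e.g. PET/SPECT-derived transporter
#' or receptor distributions) on a common voxel grid, restricted to a binary
#' grey-matter mask.
#'
#' @param maps numeric matrix, in-mask voxels x K, all values finite and
#'   nonnegative
#' @param mask logical 3D array; `sum(mask)` must equal `nrow(maps)`
#' @param system_names character vector of K unique system labels
#' @param affine 4x4 voxel-to-world matrix
#' @return an object of class `template_set`
#' @export
template_set <- function(maps, mask, system_names = NULL, affine = default_affine()) {
  maps <- as.matrix(maps)
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a logical 3D array")
  }
  if (nrow(maps) != sum(mask)) {
    abort("nrow(maps) [", nrow(maps), "] does not match mask voxel count [",
          sum(mask), "]")
  }
  K <- ncol(maps)
  if (K < 1L) abort("need at least one template map")
  if (is.null(system_names)) system_names <- default_system_names(K)
  if (length(system_names) != K || anyDuplicated(system_names)) {
    abort("`system_names` must be ", K, " unique labels")
  }
  if (any(!is.finite(maps))) abort("template maps contain non-finite values")
  if (any(maps < 0)) abort("template maps must be nonnegative inside the mask")
  colnames(maps) <- system_names
  structure(list(maps = maps, mask = mask, system_names = system_names,
                 affine = affine),
            class = "template_set")
}

#' Default molecular system labels
#'
#' The first six labels follow the common transporter/receptor naming used for
#' molecular-enriched connectivity (noradrenaline, dopamine and serotonin
#' transporters, vesicular acetylcholine transporter, metabotropic glutamate
#' receptor 5 and GABA-A); further systems get generic labels.
#'
#' @param k number of systems
#' @return character vector of length `k`
#' @export
default_system_names <- function(k) {
  base <- c("NAT", "DAT", "SERT", "VAChT", "mGluR5", "GABAA")
  if (k <= length(base)) base[seq_len(k)] else c(base, paste0("sys", seq_len(k - length(base))))
}

default_affine <- function(voxel_size = 2) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a
}

#' Construct a BOLD run
#'
#' @param data numeric matrix, in-mask voxels x T timepoints
#' @param mask logical 3D array matching the acquisition grid
#' @param subject_id subject identifier
#' @param affine 4x4 voxel-to-world matrix
#' @return an object of class `bold_run`
#' @export
bold_run <- function(data, mask, subject_id = "subject", affine = default_affine()) {
  data <- as.matrix(data)
  if (nrow(data) != sum(mask)) abort("BOLD voxel count does not match mask")
  if (any(!is.finite(data))) abort("BOLD data contain non-finite values")
  structure(list(data = data, mask = mask, subject_id = subject_id,
                 affine = affine),
            class = "bold_run")
}

#' Construct a parcellation atlas
#'
#' @param labels integer 3D array of ROI ids; 0 marks background. Ids must be
#'   contiguous positive integers `1..R` and every ROI must be nonempty.
#' @param roi_names character vector naming ids `1..R`
#' @param affine 4x4 voxel-to-world matrix
#' @return an object of class `parcellation_atlas`
#' @export
parcellation_atlas <- function(labels, roi_names = NULL, affine = default_affine()) {
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.integer(labels[labels > 0L])))
  if (length(ids) == 0L) abort("atlas has no foreground ROI labels")
  if (!identical(ids, seq_along(ids))) {
    abort("atlas labels must be contiguous 1..R; found gaps (use relabel_atlas())")
  }
  if (is.null(roi_names)) roi_names <- sprintf("roi%03d", ids)
  if (length(roi_names) != length(ids)) abort("`roi_names` length must equal ROI count")
  structure(list(labels = labels, roi_names = roi_names, affine = affine),
            class = "parcellation_atlas")
}

#' Number of ROIs in an atlas
#' @param atlas a `parcellation_atlas`
#' @return integer ROI count
#' @export
n_rois <- function(atlas) length(atlas$roi_names)

#' Relabel an atlas with non-contiguous ids to contiguous 1..R
#'
#' @param labels integer 3D array with arbitrary positive labels
#' @param roi_names optional names for the original ids (in sorted id order)
#' @param affine 4x4 matrix
#' @return a `parcellation_atlas`; the original-id mapping is stored in the
#'   `label_map` attribute (named integer vector old -> new)
#' @export
relabel_atlas <- function(labels, roi_names = NULL, affine = default_affine()) {
  ids <- sort(unique(as.integer(labels[labels > 0L])))
  new <- integer(length = max(ids))
  new[ids] <- seq_along(ids)
  out <- array(0L, dim = dim(labels))
  fg <- labels > 0L
  out[fg] <- new[as.integer(labels[fg])]
  atl <- parcellation_atlas(out, roi_names = roi_names, affine = affine)
  attr(atl, "label_map") <- setNames(seq_along(ids), ids)
  atl
}

#' Construct a subject x ROI x system value array
#'
#' The canonical container for parcellated molecular-enriched FC values and
#' for deviation z-scores: a 3D numeric array with dimnames
#' `(subject_ids, roi_names, system_names)`.
#'
#' @param values numeric 3D array
#' @param subject_ids,roi_names,system_names dimension names; taken from
#'   `dimnames(values)` when omitted
#' @return an object of class `roi_matrix` (a named 3D array)
#' @export
roi_matrix <- function(values, subject_ids = NULL, roi_names = NULL,
                       system_names = NULL) {
  if (length(dim(values)) != 3L) abort("`values` must be a 3D array")
  dn <- dimnames(values)
  subject_ids <- subject_ids %||% dn[[1L]] %||% paste0("sub", seq_len(dim(values)[1L]))
  roi_names <- roi_names %||% dn[[2L]] %||% sprintf("roi%03d", seq_len(dim(values)[2L]))
  system_names <- system_names %||% dn[[3L]] %||% default_system_names(dim(values)[3L])
  dimnames(values) <- list(subject = subject_ids, roi = roi_names,
                           system = system_names)
  class(values) <- c("roi_matrix", class(values))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set>", ncol(x$maps), "systems (",
      paste(x$system_names, collapse = ", "), ") on",
      paste(dim(x$mask), collapse = "x"), "grid,", nrow(x$maps),
      "mask voxels\n")
  invisible(x)
}

#' @export
print.roi_matrix <- function(x, ...) {
  d <- dim(x)
  cat("<roi_matrix>", d[1L], "subjects x", d[2L], "ROIs x", d[3L], "systems\n")
  invisible(x)
}

## Unpack an in-mask matrix column into a full 3D (or 4D) array.
unmask <- function(values, mask) {
  values <- as.matrix(values)
  out <- array(0, dim = c(dim(mask), ncol(values)))
  idx <- which(mask)
  nv <- prod(dim(mask))
  for (j in seq_len(ncol(values))) out[idx + (j - 1L) * nv] <- values[, j]
  if (ncol(values) == 1L) array(out, dim = dim(mask)) else out
}
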