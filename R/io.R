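## Shared I/O and end-to-end orchestration. Volumes are NIfTI-1 (via RNifti),
## tables are long-format TSV with "NA" sentinels and 9 significant digits,
## manifests are JSON. Voxel correspondence between volumes is by identical
## shape and affine; mismatches are hard errors (no resampling).

AFFINE_TOL <- 1e-4

check_grids <- function(dim_a, aff_a, dim_b, aff_b, what_a, what_b) {
  if (!identical(as.integer(dim_a), as.integer(dim_b))) {
    abort(what_a, " and ", what_b, " differ in shape: ",
          paste(dim_a, collapse = "x"), " vs ", paste(dim_b, collapse = "x"))
  }
  if (max(abs(aff_a - aff_b)) > AFFINE_TOL) {
    abort(what_a, " and ", what_b, " differ in affine beyond ", AFFINE_TOL,
          " (no resampling is performed)")
  }
  invisible(TRUE)
}

rnifti_affine <- function(img) {
  x <- RNifti::xform(img)
  matrix(as.numeric(x), 4L, 4L)
}

#' Write a template set (and its mask) as NIfTI-1 volumes
#'
#' @param templates a [template_set()]
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_templates_nifti <- function(templates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(templates$system_names)) {
    vol <- unmask(templates$maps[, k], templates$mask)
    p <- file.path(dir, paste0("template_", templates$system_names[k], ".nii.gz"))
    img <- RNifti::asNifti(vol)
    img <- RNifti::`sform<-`(img, structure(templates$affine, code = 2L))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  pm <- file.path(dir, "mask.nii.gz")
  img <- RNifti::asNifti(array(as.integer(templates$mask), dim = dim(templates$mask)))
  img <- RNifti::`sform<-`(img, structure(templates$affine, code = 2L))
  RNifti::writeNifti(img, pm)
  invisible(c(paths, pm))
}

#' Read molecular templates + mask from NIfTI-1 files
#'
#' @param template_paths one path per system map (3D)
#' @param mask_path binary mask volume (3D), same grid
#' @param system_names labels; default derived from file names
#' @return a [template_set()]
#' @export
read_templates_nifti <- function(template_paths, mask_path,
                                 system_names = NULL) {
  mi <- RNifti::readNifti(mask_path)
  if (length(dim(mi)) != 3L) abort(mask_path, ": expected a 3D mask volume")
  mask <- array(as.numeric(mi) != 0, dim = dim(mi))
  aff <- rnifti_affine(mi)
  maps <- NULL
  for (p in template_paths) {
    img <- RNifti::readNifti(p)
    if (length(dim(img)) != 3L) abort(p, ": expected a 3D template volume")
    check_grids(dim(img), rnifti_affine(img), dim(mask), aff, p, mask_path)
    maps <- cbind(maps, as.numeric(img)[as.logical(mask)])
  }
  if (is.null(system_names)) {
    system_names <- sub("\\.nii(\\.gz)?$", "", basename(template_paths))
    system_names <- sub("^template_", "", system_names)
  }
  template_set(maps, mask, system_names = system_names, affine = aff)
}

#' Write a 4D BOLD run as NIfTI-1
#' @param bold a [bold_run()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_bold_nifti <- function(bold, path) {
  vol <- unmask(bold$data, bold$mask)
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(bold$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D BOLD run from NIfTI-1, masked
#' @param path 4D NIfTI file
#' @param mask_path 3D mask on the same grid
#' @param subject_id identifier to attach
#' @return a [bold_run()]
#' @export
read_bold_nifti <- function(path, mask_path, subject_id = "subject") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) abort(path, ": expected a 4D BOLD volume")
  mi <- RNifti::readNifti(mask_path)
  mask <- array(as.numeric(mi) != 0, dim = dim(mi))
  check_grids(dim(img)[1:3], rnifti_affine(img), dim(mask), rnifti_affine(mi),
              path, mask_path)
  dat <- matrix(as.numeric(img), prod(dim(img)[1:3]), dim(img)[4L])
  bold_run(dat[as.logical(mask), , drop = FALSE], mask,
           subject_id = subject_id, affine = rnifti_affine(mi))
}

#' Write / read a parcellation atlas as NIfTI-1
#' @param atlas a [parcellation_atlas()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_atlas_nifti <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$labels)
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_atlas_nifti
#' @param roi_names optional names for the sorted original labels
#' @return `read_atlas_nifti`: a [parcellation_atlas()]; non-contiguous
#'   labels are relabelled contiguously with the mapping recorded in the
#'   `label_map` attribute
#' @export
read_atlas_nifti <- function(path, roi_names = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) abort(path, ": expected a 3D atlas volume")
  lab <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  relabel_atlas(lab, roi_names = roi_names, affine = rnifti_affine(img))
}

#' Write per-subject enriched maps as a 4D NIfTI (4th dim = system)
#' @param maps an `enriched_maps` object
#' @param path output path
#' @return invisibly, `path`
#' @export
write_enriched_nifti <- function(maps, path) {
  vol <- unmask(maps$betas, maps$mask)
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(maps$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- tables ----------------------------------------------------------------

fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
}

#' Write a subject x ROI x system array as long-format TSV
#'
#' Columns: `subject_id`, `roi`, `system`, `value`; floats at 9 significant
#' digits; missing values written as the literal sentinel `NA` (never 0).
#'
#' @param rm a [roi_matrix()] (or `deviation_tensor`)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_roi_matrix <- function(rm, path) {
  dn <- dimnames(rm)
  df <- expand.grid(subject_id = dn[[1L]], roi = dn[[2L]], system = dn[[3L]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- as.numeric(rm)
  write_tsv(df, path)
}

#' Read a long-format TSV back into a subject x ROI x system array
#'
#' @param path TSV written by [write_roi_matrix()]
#' @return a [roi_matrix()]
#' @export
read_roi_matrix <- function(path) {
  df <- read_tsv(path)
  subs <- unique(df$subject_id); rois <- unique(df$roi); sys <- unique(df$system)
  arr <- array(NA_real_, dim = c(length(subs), length(rois), length(sys)))
  i <- match(df$subject_id, subs)
  j <- match(df$roi, rois)
  k <- match(df$system, sys)
  arr[cbind(i, j, k)] <- df$value
  roi_matrix(arr, subject_ids = subs, roi_names = rois, system_names = sys)
}

#' Write a cohort or symptom table as TSV
#' @param df data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_table_tsv <- function(df, path) write_tsv(df, path)

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) read_tsv(path)

## ---- pipeline --------------------------------------------------------------

#' Run the full synthetic-study pipeline end to end
#'
#' Simulation -> REACT (two-stage regression + parcellation) -> planted
#' patient deviations -> stratified split -> normative fitting -> explained
#' variance and ROI retention -> deviation z-scores and summaries ->
#' symptom PCA -> similarity analyses -> permutation group ANOVA and
#' deviation-symptom mapping. Every intermediate artefact is written to
#' `out_dir` as TSV/JSON (and the templates/mask/atlas as NIfTI), plus a
#' machine-readable `manifest.json`. Reruns with the same configuration
#' reproduce all outputs bit for bit.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory
#' @param mode normative inference mode (`"eb"` default, or `"gibbs"`)
#' @param n_perm permutations for the mapping stage
#' @param write_volumes also write templates/mask/atlas NIfTI volumes
#' @return invisibly, a list of the in-memory results (`cohort`, `roi`,
#'   `fit`, `ev`, `retained`, `z`, `summary`, `pca`, `similarity`, `anova`,
#'   `symptom_map`, `manifest`)
#' @export
run_pipeline <- function(config, out_dir, mode = "eb", n_perm = 500,
                         write_volumes = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[molnorm] %-22s %s", name, format(Sys.time(), "%H:%M:%S")))
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  artefacts <- character(0)
  keep <- function(p) { artefacts <<- c(artefacts, p); p }

  ## simulate
  templates <- stage("simulate/templates", make_templates(config))
  atlas <- stage("simulate/atlas", make_atlas(config))
  cohort <- stage("simulate/cohort", make_cohort(config))
  truth <- stage("simulate/truth",
                 make_ground_truth(config, templates = templates,
                                   roi_names = atlas$roi_names))
  if (write_volumes) {
    stage("write/volumes", {
      write_templates_nifti(templates, file.path(out_dir, "volumes"))
      write_atlas_nifti(atlas, keep(file.path(out_dir, "volumes", "atlas.nii.gz")))
    })
  }
  keep(write_table_tsv(cohort, file.path(out_dir, "cohort.tsv")))

  ## REACT
  roi <- stage("react", react_cohort(cohort, templates, atlas, truth, config))
  roi <- stage("inject_deviations", inject_deviations(roi, cohort, truth))
  keep(write_roi_matrix(roi, file.path(out_dir, "roi_matrix.tsv")))

  ## normative
  healthy <- cohort[cohort$diagnosis == "HC", ]
  split <- stage("split", stratified_split(healthy, 0.30,
                                           seed = substream_seed(config$seed, "split")))
  fit <- stage("normative/fit",
               fit_normative(roi, cohort, split$train_ids, mode = mode,
                             seed = substream_seed(config$seed, "hbr")))
  ev <- stage("normative/ev", explained_variance(fit, roi, cohort, split$test_ids))
  retained <- retain_rois(ev, fit$converged)
  score_ids <- c(split$test_ids, cohort$id[cohort$diagnosis != "HC"])
  z <- stage("normative/deviations",
             deviation_scores(fit, roi, cohort, score_ids, retained))
  summ <- stage("normative/summary", summary_deviation(z))
  keep(write_roi_matrix(z, file.path(out_dir, "deviations.tsv")))
  ev_df <- data.frame(roi = rep(rownames(ev), ncol(ev)),
                      system = rep(colnames(ev), each = nrow(ev)),
                      ev = as.numeric(ev), retained = as.logical(retained))
  keep(write_table_tsv(ev_df, file.path(out_dir, "explained_variance.tsv")))
  keep(write_table_tsv(data.frame(id = rownames(summ), summ,
                                  check.names = FALSE),
                       file.path(out_dir, "summary_deviation.tsv")))

  ## symptoms
  patients <- cohort$diagnosis != "HC"
  symptoms <- stage("symptoms/simulate", make_symptoms(cohort, truth, config))
  sym_pat <- symptoms[patients, ]
  pca <- stage("symptoms/pca", pca_reduce(sym_pat))
  keep(write_table_tsv(
    data.frame(component = colnames(pca$loadings),
               eigenvalue = pca$eigenvalues,
               explained = pca$explained),
    file.path(out_dir, "pca_eigenvalues.tsv")))
  keep(write_table_tsv(
    data.frame(id = sym_pat$id, retained_scores(pca), check.names = FALSE),
    file.path(out_dir, "pca_scores.tsv")))

  ## similarity (per system, over retained ROIs; UCLA-like clinical site only)
  score_groups <- cohort$diagnosis[match(score_ids, cohort$id)]
  sims <- list()
  stage("similarity", {
    for (k in seq_along(fit$system_names)) {
      keep_rois <- which(retained[, k])
      if (length(keep_rois) < 3L) next
      feats <- matrix(z[, keep_rois, k, drop = TRUE], nrow = length(score_ids))
      rownames(feats) <- score_ids
      sims[[fit$system_names[k]]] <- subject_similarity_matrix(feats, score_groups)
    }
  })

  ## mapping
  an <- stage("mapping/anova",
              roi_group_anova(z, score_groups, n_perm = n_perm,
                              seed = substream_seed(config$seed, "perm")))
  keep(write_table_tsv(an$stats, file.path(out_dir, "roi_anova.tsv")))
  pat_in_scored <- score_groups != "HC"
  zpat <- z[pat_in_scored, , , drop = FALSE]
  attr(zpat, "retained") <- retained
  class(zpat) <- class(z)
  sym_map <- stage("mapping/symptom",
                   deviation_symptom_regression(
                     zpat, retained_scores(pca), n_perm = n_perm,
                     seed = substream_seed(config$seed, "permsym")))
  keep(write_table_tsv(sym_map, file.path(out_dir, "deviation_symptom_map.tsv")))

  manifest <- list(
    tool = "molnorm",
    version = as.character(utils::packageVersion("molnorm")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    normative_mode = mode,
    n_perm = n_perm,
    split = list(train = length(split$train_ids), test = length(split$test_ids)),
    retained_per_system = as.list(setNames(colSums(retained), fit$system_names)),
    artefacts = basename(artefacts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = config, cohort = cohort, truth = truth, roi = roi,
                 split = split, fit = fit, ev = ev, retained = retained,
                 z = z, summary = summ, pca = pca, similarity = sims,
                 anova = an, symptom_map = sym_map, manifest = manifest))
}
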