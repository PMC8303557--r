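#' Write a cohort to disk
#'
#' Writes every slice as an 8-bit grayscale PNG (`images/<subject>_<index>.png`),
#' lesion masks as binary PNGs (`masks/<subject>_<index>_<k>.png`) and the
#' manifest as `manifest.csv`. Intensities are stored in `[0,1]` throughout
#' the package; quantization to 8 bits happens only at this export step.
#'
#' @param cohort list with `subjects` and `manifest`, as returned by
#'   [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return The updated manifest (with `image_path` filled in), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  manifest <- cohort$manifest
  for (ex in cohort$subjects) {
    for (s in ex$slices) {
      rel <- file.path("images", sprintf("%s_%03d.png", s$subject_id, s$slice_index))
      png::writePNG(s$image, file.path(dir, rel))
      manifest$image_path[manifest$subject_id == s$subject_id &
                          manifest$slice_index == s$slice_index] <- rel
      for (k in seq_along(s$lesion_masks)) {
        mrel <- file.path("masks", sprintf("%s_%03d_%d.png", s$subject_id,
                                           s$slice_index, k))
        png::writePNG(s$lesion_masks[[k]] * 1, file.path(dir, mrel))
      }
    }
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_cohort
#' @param manifest a manifest data.frame.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(subject_id = "character", image_path = "character"))
}

#' Read a cohort written by [write_cohort()]
#'
#' Rebuilds the `subject_exam` list from the manifest, PNG slices and mask
#' files. Images come back 8-bit quantized (see [write_cohort()]).
#'
#' @param dir cohort directory.
#' @return List with `subjects` and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  subjects <- lapply(split(manifest, manifest$subject_id), function(mf) {
    mf <- mf[order(mf$slice_index), ]
    slices <- lapply(seq_len(nrow(mf)), function(i) {
      row <- mf[i, ]
      img <- png::readPNG(file.path(dir, row$image_path))
      if (length(dim(img)) == 3L) img <- img[, , 1]
      masks <- list()
      k <- 1L
      repeat {
        mpath <- file.path(dir, "masks", sprintf("%s_%03d_%d.png",
                                                 row$subject_id,
                                                 row$slice_index, k))
        if (!file.exists(mpath)) break
        mm <- png::readPNG(mpath)
        if (length(dim(mm)) == 3L) mm <- mm[, , 1]
        masks[[k]] <- mm > 0.5
        k <- k + 1L
      }
      structure(list(image = img, subject_id = row$subject_id,
                     slice_index = row$slice_index,
                     left_box = bbox(row$l_r0, row$l_r1, row$l_c0, row$l_c1),
                     right_box = bbox(row$r_r0, row$r_r1, row$r_c0, row$r_c1),
                     lesion_masks = masks,
                     slice_label = as.integer(row$slice_label)),
                class = "slice_record")
    })
    structure(list(subject_id = mf$subject_id[1], slices = slices,
                   subject_label = as.integer(mf$subject_label[1])),
              class = "subject_exam")
  })
  subjects <- subjects[order(names(subjects))]
  list(subjects = unname(subjects), manifest = manifest)
}

#' Export one subject stack as NIfTI
#'
#' Stacks the subject's slices (in anatomical order) into a 3-D volume and
#' writes it with the RNifti package, when available.
#'
#' @param exam a `subject_exam`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_subject_nifti <- function(exam, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  vol <- simplify2array(lapply(exam$slices, function(s) s$image))
  RNifti::writeNifti(vol, path)
  invisible(path)
}
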