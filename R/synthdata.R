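#' Parameters of the synthetic sacroiliac-joint phantom
#'
#' The phantom emulates the gross appearance of a fat-suppressed
#' gadolinium-enhanced oblique-coronal slice through the sacroiliac joints:
#' two bright lateral iliac bones and a central sacrum separated by dark
#' joint lines, with optional hyperintense bone-marrow-edema lesions placed
#' at the joint margin, plus Rician-like acquisition noise. It exists so the
#' full pipeline (ROI extraction, classifier training, median-filter
#' correction, subject diagnosis) can be exercised and validated without
#' clinical data.
#'
#' @param image_size integer `c(rows, cols)`, at least 64x64.
#' @param n_slices_range_pos inclusive range of slices per positive
#'   (active sacroiliitis) subject; default 4-23.
#' @param n_slices_range_neg inclusive range of slices per negative (normal)
#'   subject; default 18-25.
#' @param lesion_contrast intensity uplift of lesion pixels over bone, on the
#'   normalized `[0,1]` scale; must be > 0.
#' @param lesion_radius_range inclusive range of lesion radii in pixels.
#' @param bone_intensity,background_intensity normalized intensities in `[0,1]`.
#' @param rician_sigma scale of the Rician-like acquisition noise applied to
#'   every slice (`sqrt((I + s*g1)^2 + (s*g2)^2)` with `g1, g2` standard
#'   normal); 0 disables it.
#' @param seed default integer seed used when the generating functions are
#'   called without one.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(96L, 96L),
                           n_slices_range_pos = c(4L, 23L),
                           n_slices_range_neg = c(18L, 25L),
                           lesion_contrast = 0.35,
                           lesion_radius_range = c(2L, 4L),
                           bone_intensity = 0.55,
                           background_intensity = 0.05,
                           rician_sigma = 0.02,
                           seed = 1L) {
  p <- list(image_size = as.integer(image_size),
            n_slices_range_pos = as.integer(n_slices_range_pos),
            n_slices_range_neg = as.integer(n_slices_range_neg),
            lesion_contrast = lesion_contrast,
            lesion_radius_range = as.integer(lesion_radius_range),
            bone_intensity = bone_intensity,
            background_intensity = background_intensity,
            rician_sigma = rician_sigma,
            seed = as.integer(seed))
  if (length(p$image_size) != 2L || any(p$image_size < 64L))
    stop("image_size must be at least 64x64")
  for (fld in c("n_slices_range_pos", "n_slices_range_neg", "lesion_radius_range")) {
    r <- p[[fld]]
    if (length(r) != 2L || r[2] < r[1] || r[1] < 1L)
      stop(sprintf("%s must be a non-empty positive range", fld))
  }
  if (!is.numeric(p$lesion_contrast) || p$lesion_contrast <= 0)
    stop("lesion_contrast must be > 0")
  if (p$background_intensity < 0 || p$bone_intensity > 1 ||
      p$background_intensity >= p$bone_intensity)
    stop("need 0 <= background_intensity < bone_intensity <= 1")
  if (p$rician_sigma < 0) stop("rician_sigma must be >= 0")
  structure(p, class = "phantom_params")
}

# Anatomy of one slice, before lesions and noise. `size_scale` in (0,1] shrinks
# the bones to mimic the slice position within the stack.
# Returns image, iliac boxes, and the medial (joint-side) edge columns.
render_slice_anatomy <- function(params, size_scale) {
  H <- params$image_size[1]; W <- params$image_size[2]
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  in_ellipse <- function(r0, c0, ar, ac) {
    ((rr - r0) / ar)^2 + ((cc - c0) / ac)^2 <= 1
  }
  img <- matrix(params$background_intensity, H, W)
  # central sacrum: slightly darker than the ilia
  sac <- in_ellipse(0.52 * H, 0.50 * W, 0.27 * H * size_scale, 0.105 * W)
  img[sac] <- 0.85 * params$bone_intensity
  # lateral ilia
  il_l <- in_ellipse(0.50 * H, 0.24 * W, 0.30 * H * size_scale, 0.135 * W * size_scale)
  il_r <- in_ellipse(0.50 * H, 0.76 * W, 0.30 * H * size_scale, 0.135 * W * size_scale)
  img[il_l] <- params$bone_intensity
  img[il_r] <- params$bone_intensity
  box_of <- function(mask) {
    rows <- which(apply(mask, 1, any)); cols <- which(apply(mask, 2, any))
    bbox(min(rows) - 1L, max(rows), min(cols) - 1L, max(cols))
  }
  bl <- box_of(il_l); br <- box_of(il_r)
  list(image = img,
       left_box = bl, right_box = br,
       left_edge = bl$c1 - 1L,   # medial-most iliac column, left side
       right_edge = br$c0)       # medial-most iliac column, right side
}

disk_mask <- function(dim, row, col, radius) {
  rr <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  cc <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  (rr - row)^2 + (cc - col)^2 <= radius^2
}

apply_rician_noise <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n <- length(img)
  out <- sqrt((img + sigma * rnorm(n))^2 + (sigma * rnorm(n))^2)
  matrix(clamp01(out), nrow(img), ncol(img))
}

#' Generate one synthetic subject examination
#'
#' Produces an ordered stack of phantom slices (lower to upper pelvis) for a
#' single subject. A positive exam consists of the clearly lesioned slices
#' of an active-sacroiliitis subject (mirroring the labeling rule in which
#' only such slices enter the dataset): every slice carries a hyperintense
#' lesion adjacent to a joint line, the lesion center drifting by at most
#' ~2 px between adjacent slices, and some exams additionally carry a
#' bilateral slice with two lesions. The exam therefore satisfies the ASAS
#' positivity rule (two consecutive lesioned slices, or two lesions on one
#' slice). Negative subjects have no lesions.
#'
#' @param params a [phantom_params()] object.
#' @param positive logical; generate an active-sacroiliitis subject?
#' @param seed integer seed; defaults to `params$seed`. Fixed seed gives a
#'   bit-identical exam.
#' @param subject_id subject identifier stored on every slice.
#' @return A `subject_exam`: list with `subject_id`, `slices` (list of
#'   `slice_record`), and `subject_label` (1 = active sacroiliitis,
#'   0 = normal). Each `slice_record` holds `image` (matrix in `[0,1]`),
#'   `subject_id`, `slice_index` (0-based), `left_box`, `right_box`
#'   ([bbox()] of the iliac bones), `lesion_masks` (list of logical
#'   matrices), and `slice_label` (1 = lesion present).
#' @export
generate_subject <- function(params, positive, seed = NULL,
                             subject_id = if (positive) "P001" else "N001") {
  stopifnot(inherits(params, "phantom_params"))
  if (is.null(seed)) seed <- params$seed
  with_seed(seed, {
    rng <- if (positive) params$n_slices_range_pos else params$n_slices_range_neg
    n <- sample(rng[1]:rng[2], 1L)
    dimg <- params$image_size
    # Lesion plan. Mirroring the reference labeling rule, a positive exam
    # consists of the clearly lesioned slices: one inflammation site per
    # exam whose center drifts <= 2 px between adjacent slices, plus
    # occasional bilateral slices (two lesions on one slice). Every slice of
    # a positive exam carries a lesion, so the ASAS rule holds whenever
    # n >= 2 (and via the two-lesion clause on bilateral slices otherwise).
    plan <- vector("list", n)
    if (positive) {
      side <- sample(c("left", "right"), 1L)
      rad <- sample(params$lesion_radius_range[1]:params$lesion_radius_range[2], 1L)
      coff <- sample(-1:1, 1L)
      row <- runif(1, 0.40, 0.60) * dimg[1]
      bilateral <- runif(1) < 0.4
      bi_slice <- if (bilateral) sample.int(n, 1L) else 0L
      for (t in seq_len(n)) {
        plan[[t]] <- list(list(side = side, row = row, col_off = coff, rad = rad))
        if (t == bi_slice) {
          other <- if (side == "left") "right" else "left"
          plan[[t]] <- c(plan[[t]], list(list(side = other, row = row,
                                              col_off = 0L, rad = rad)))
        }
        row <- row + sample(-2:2, 1L)
        row <- min(max(row, 0.35 * dimg[1]), 0.65 * dimg[1])
      }
    }
    slices <- vector("list", n)
    for (t in seq_len(n)) {
      sz <- 0.85 + 0.15 * sin(pi * (t - 0.5) / n)
      anat <- render_slice_anatomy(params, sz)
      img <- anat$image
      masks <- list()
      for (les in plan[[t]] %||% list()) {
        col <- if (les$side == "left") anat$left_edge - 1L + les$col_off
               else anat$right_edge + 1L - les$col_off
        m <- disk_mask(dimg, round(les$row), col, les$rad)
        img[m] <- clamp01(params$bone_intensity + params$lesion_contrast)
        masks[[length(masks) + 1L]] <- m
      }
      img <- apply_rician_noise(img, params$rician_sigma)
      slices[[t]] <- structure(list(
        image = img, subject_id = subject_id, slice_index = t - 1L,
        left_box = anat$left_box, right_box = anat$right_box,
        lesion_masks = masks,
        slice_label = as.integer(length(masks) > 0L)), class = "slice_record")
    }
    counts <- vapply(slices, function(s) length(s$lesion_masks), integer(1))
    structure(list(subject_id = subject_id, slices = slices,
                   subject_label = as.integer(asas_label(counts))),
              class = "subject_exam")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.subject_exam <- function(x, ...) {
  cat(sprintf("<subject_exam %s: %d slices, %s>\n", x$subject_id,
              length(x$slices),
              if (x$subject_label == 1L) "active sacroiliitis" else "normal"))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param n_pos,n_neg number of positive (active sacroiliitis) and negative
#'   (normal) subjects.
#' @param params a [phantom_params()] object.
#' @param seed integer master seed; per-subject seeds are drawn from it, so a
#'   fixed seed reproduces the whole cohort exactly.
#' @return List with `subjects` (list of `subject_exam`, positives first) and
#'   `manifest` (one data.frame row per slice; see [build_manifest()]).
#' @export
generate_cohort <- function(n_pos, n_neg, params = phantom_params(), seed = NULL) {
  if (n_pos < 0 || n_neg < 0) stop("n_pos and n_neg must be >= 0")
  if (is.null(seed)) seed <- params$seed
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max, n_pos + n_neg))
  subjects <- vector("list", n_pos + n_neg)
  i <- 0L
  for (k in seq_len(n_pos)) {
    i <- i + 1L
    subjects[[i]] <- generate_subject(params, TRUE, seed = subseeds[i],
                                      subject_id = sprintf("P%03d", k))
  }
  for (k in seq_len(n_neg)) {
    i <- i + 1L
    subjects[[i]] <- generate_subject(params, FALSE, seed = subseeds[i],
                                      subject_id = sprintf("N%03d", k))
  }
  list(subjects = subjects, manifest = build_manifest(subjects))
}

#' Build a slice manifest for a list of subject exams
#'
#' One row per slice: subject id, 0-based slice index, slice and subject
#' labels (1 = positive), lesion count, iliac bounding boxes as 0-based
#' half-open coordinates, and (after [write_cohort()]) the image path.
#'
#' @param subjects list of `subject_exam` objects.
#' @return A data.frame.
#' @export
build_manifest <- function(subjects) {
  rows <- lapply(subjects, function(ex) {
    do.call(rbind, lapply(ex$slices, function(s) {
      data.frame(subject_id = s$subject_id, slice_index = s$slice_index,
                 slice_label = s$slice_label, subject_label = ex$subject_label,
                 n_lesions = length(s$lesion_masks),
                 l_r0 = s$left_box$r0, l_r1 = s$left_box$r1,
                 l_c0 = s$left_box$c0, l_c1 = s$left_box$c1,
                 r_r0 = s$right_box$r0, r_r1 = s$right_box$r1,
                 r_c0 = s$right_box$c0, r_c1 = s$right_box$c1,
                 image_path = NA_character_, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
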