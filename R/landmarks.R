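#' Construct a 2D sagittal-plane point
#'
#' Points live in a frame with x positive toward the patient's anterior and
#' y positive superior, in millimetres after calibration.
#'
#' @param x,y Finite coordinates.
#' @return A named numeric vector of length 2 with class `"point2d"`.
#' @export
point2d <- function(x, y) {
  if (!is_finite_number(x) || !is_finite_number(y)) {
    cm_stop("point2d coordinates must be finite numbers", "validation_error")
  }
  structure(c(x = x, y = y), class = "point2d")
}

as_point2d <- function(p, what = "point") {
  if (inherits(p, "point2d")) return(p)
  if (is.numeric(p) && length(p) == 2L && all(is.finite(p))) {
    return(point2d(p[[1]], p[[2]]))
  }
  cm_stop(sprintf("%s is not a valid 2D point", what), "validation_error")
}

# Signed area of the body polygon as -> ps -> pi -> ai (shoelace).
quad_signed_area <- function(as, ps, pi_, ai) {
  xs <- c(as[1], ps[1], pi_[1], ai[1])
  ys <- c(as[2], ps[2], pi_[2], ai[2])
  nxt <- c(2L, 3L, 4L, 1L)
  sum(xs * ys[nxt] - xs[nxt] * ys) / 2
}

#' Construct a vertebral body corner quad
#'
#' The four digitized corners of a vertebral body on a lateral view:
#' anterior-superior (`as`), posterior-superior (`ps`), anterior-inferior
#' (`ai`), and posterior-inferior (`pi`).
#'
#' @param label Vertebral level, one of `"C2"` ... `"C7"`.
#' @param as,ps,ai,pi Corner points (`point2d` or length-2 numeric).
#' @return A list with class `"vertebra_quad"`.
#' @export
vertebra_quad <- function(label, as, ps, ai, pi) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% CERVICAL_LEVELS)) {
    cm_stop(sprintf("vertebra label must be one of %s",
                    paste(CERVICAL_LEVELS, collapse = ", ")),
            "validation_error")
  }
  as <- as_point2d(as, paste(label, "as"))
  ps <- as_point2d(ps, paste(label, "ps"))
  ai <- as_point2d(ai, paste(label, "ai"))
  pi <- as_point2d(pi, paste(label, "pi"))
  if (identical(unname(ps), unname(pi))) {
    cm_stop(sprintf("%s: ps and pi coincide; posterior tangent undefined",
                    label), "degenerate_geometry")
  }
  if (identical(unname(as), unname(ai))) {
    cm_stop(sprintf("%s: as and ai coincide", label), "degenerate_geometry")
  }
  if (abs(quad_signed_area(as, ps, pi, ai)) <= 1e-9) {
    cm_stop(sprintf("%s: body corners are collinear (degenerate quad)", label),
            "degenerate_geometry")
  }
  structure(list(label = label, as = as, ps = ps, ai = ai, pi = pi),
            class = "vertebra_quad")
}

#' Construct the three atlas (C1) landmarks
#'
#' @param ant_tubercle Anterior tubercle of C1.
#' @param dens_post_mid Midpoint of C1 at the posterior margin of the dens
#'   (digitized and stored; not used by any measurement).
#' @param post_laminar_mid Midpoint of the posterior spinal laminar line.
#' @return A list with class `"atlas_landmarks"`.
#' @export
atlas_landmarks <- function(ant_tubercle, dens_post_mid, post_laminar_mid) {
  ant_tubercle <- as_point2d(ant_tubercle, "C1 ant_tubercle")
  dens_post_mid <- as_point2d(dens_post_mid, "C1 dens_post_mid")
  post_laminar_mid <- as_point2d(post_laminar_mid, "C1 post_laminar_mid")
  if (identical(unname(ant_tubercle), unname(post_laminar_mid))) {
    cm_stop("C1: ant_tubercle and post_laminar_mid coincide; atlas plane undefined",
            "degenerate_geometry")
  }
  structure(list(ant_tubercle = ant_tubercle,
                 dens_post_mid = dens_post_mid,
                 post_laminar_mid = post_laminar_mid),
            class = "atlas_landmarks")
}

#' Construct the landmark set of one lateral cervical image
#'
#' Coordinates are converted to millimetres at construction by multiplying by
#' `mm_per_unit`; the stored object always has `mm_per_unit = 1`, so all
#' downstream geometry is in mm.
#'
#' @param image_id Image identifier (non-empty string).
#' @param vertebrae Named list of [vertebra_quad()] objects keyed by level
#'   (any subset of C2..C7, each at most once).
#' @param atlas Optional [atlas_landmarks()] (C1 may be absent; then only the
#'   atlas plane angle C1H is unmeasurable).
#' @param mm_per_unit Positive scale factor converting input units to mm.
#' @param metadata Named list of free-form metadata (e.g. sex, degeneration
#'   stratum, trial label).
#' @return A list with class `"landmark_set"`.
#' @export
landmark_set <- function(image_id, vertebrae, atlas = NULL, mm_per_unit = 1,
                         metadata = list()) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id)) {
    cm_stop("image_id must be a non-empty string", "validation_error")
  }
  if (!is_finite_number(mm_per_unit) || mm_per_unit <= 0) {
    cm_stop(sprintf("image %s: mm_per_unit must be > 0", image_id),
            "validation_error")
  }
  if (!is.list(vertebrae)) {
    cm_stop(sprintf("image %s: vertebrae must be a list", image_id),
            "validation_error")
  }
  labels <- vapply(vertebrae, function(v) {
    if (!inherits(v, "vertebra_quad")) {
      cm_stop(sprintf("image %s: vertebrae entries must be vertebra_quad",
                      image_id), "validation_error")
    }
    v$label
  }, character(1))
  if (anyDuplicated(labels)) {
    cm_stop(sprintf("image %s: duplicate vertebra labels: %s", image_id,
                    paste(unique(labels[duplicated(labels)]), collapse = ", ")),
            "validation_error")
  }
  names(vertebrae) <- labels
  vertebrae <- vertebrae[intersect(CERVICAL_LEVELS, labels)]
  if (!is.null(atlas) && !inherits(atlas, "atlas_landmarks")) {
    cm_stop(sprintf("image %s: atlas must be atlas_landmarks or NULL",
                    image_id), "validation_error")
  }
  if (mm_per_unit != 1) {
    vertebrae <- lapply(vertebrae, scale_quad, s = mm_per_unit)
    if (!is.null(atlas)) atlas <- scale_atlas(atlas, mm_per_unit)
  }
  structure(list(image_id = image_id,
                 mm_per_unit = 1,
                 atlas = atlas,
                 vertebrae = vertebrae,
                 metadata = metadata),
            class = "landmark_set")
}

scale_quad <- function(v, s) {
  vertebra_quad(v$label, v$as * s, v$ps * s, v$ai * s, v$pi * s)
}

scale_atlas <- function(a, s) {
  atlas_landmarks(a$ant_tubercle * s, a$dens_post_mid * s,
                  a$post_laminar_mid * s)
}

#' Is a landmark set complete?
#'
#' Complete means all six body quads C2..C7 are present.  C1 is not required
#' for completeness: with the atlas absent only C1H is missing while the other
#' 17 variables remain computable.
#'
#' @param set A [landmark_set()].
#' @return Logical scalar.
#' @export
is_complete <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  all(CERVICAL_LEVELS %in% names(set$vertebrae))
}

#' Construct a study set (one digitization trial)
#'
#' @param trial_id Trial identifier (e.g. `"trial1"`).
#' @param rater_id Rater identifier (e.g. `"US1"`, `"US2"`, `"CV"`).
#' @param sets List of [landmark_set()] objects with unique image ids.
#' @return A list with class `"study_set"`.
#' @export
study_set <- function(trial_id, rater_id, sets) {
  if (!is.character(trial_id) || length(trial_id) != 1L) {
    cm_stop("trial_id must be a string", "validation_error")
  }
  if (!is.character(rater_id) || length(rater_id) != 1L) {
    cm_stop("rater_id must be a string", "validation_error")
  }
  if (!is.list(sets)) cm_stop("sets must be a list", "validation_error")
  ids <- vapply(sets, function(s) {
    if (!inherits(s, "landmark_set")) {
      cm_stop("sets entries must be landmark_set objects", "validation_error")
    }
    s$image_id
  }, character(1))
  if (anyDuplicated(ids)) {
    cm_stop(sprintf("duplicate image_ids within trial %s: %s", trial_id,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "validation_error")
  }
  names(sets) <- ids
  structure(list(trial_id = trial_id, rater_id = rater_id, sets = sets),
            class = "study_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set %s: %d vertebrae%s%s>\n", x$image_id,
              length(x$vertebrae),
              if (!is.null(x$atlas)) " + C1" else "",
              if (is_complete(x)) ", complete" else ""))
  invisible(x)
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("<study_set trial=%s rater=%s: %d images>\n",
              x$trial_id, x$rater_id, length(x$sets)))
  invisible(x)
}

#' Apply a global rigid (plus uniform scale) transform to a landmark set
#'
#' Every point p is mapped to `scale * R(rotation_deg) p + translation`.
#' Labels and metadata are preserved.  Used to exercise the invariance
#' properties of the alignment variables.
#'
#' @param set A [landmark_set()].
#' @param rotation_deg Counterclockwise rotation in degrees.
#' @param translation Length-2 numeric, mm.
#' @param scale Positive uniform scale factor.
#' @return The transformed [landmark_set()].
#' @export
apply_rigid_transform <- function(set, rotation_deg = 0,
                                  translation = c(0, 0), scale = 1) {
  stopifnot(inherits(set, "landmark_set"))
  if (!is_finite_number(scale) || scale <= 0) {
    cm_stop("scale must be > 0", "validation_error")
  }
  th <- deg2rad(rotation_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tp <- function(p) {
    q <- scale * as.vector(R %*% unname(p)) + translation
    point2d(q[1], q[2])
  }
  vertebrae <- lapply(set$vertebrae, function(v) {
    vertebra_quad(v$label, tp(v$as), tp(v$ps), tp(v$ai), tp(v$pi))
  })
  atlas <- if (!is.null(set$atlas)) {
    atlas_landmarks(tp(set$atlas$ant_tubercle), tp(set$atlas$dens_post_mid),
                    tp(set$atlas$post_laminar_mid))
  }
  landmark_set(set$image_id, vertebrae, atlas = atlas, mm_per_unit = 1,
               metadata = set$metadata)
}
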