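#' Signed angle between two direction vectors
#'
#' Counterclockwise rotation, in degrees, that maps `from_dir` onto `to_dir`
#' in the x-anterior / y-superior frame.  Antisymmetric and confined to
#' (-180, 180].
#'
#' @param from_dir,to_dir Length-2 numeric direction vectors (any nonzero
#'   length; normalised internally).
#' @return Angle in degrees.
#' @export
signed_angle <- function(from_dir, to_dir) {
  a <- unname(as.vector(from_dir))
  b <- unname(as.vector(to_dir))
  if (sqrt(sum(a^2)) < 1e-12 || sqrt(sum(b^2)) < 1e-12) {
    cm_stop("signed_angle: zero-length direction vector",
            "degenerate_geometry")
  }
  cross <- a[1] * b[2] - a[2] * b[1]
  dot <- a[1] * b[1] + a[2] * b[2]
  rad2deg(atan2(cross, dot))
}

unit_vec <- function(v, what = "direction") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    cm_stop(sprintf("%s has zero length", what), "degenerate_geometry")
  }
  unname(as.vector(v)) / n
}

#' Posterior body tangent of a vertebra
#'
#' The line through the posterior-inferior and posterior-superior body
#' corners, directed superiorly (Harrison posterior tangent method).
#'
#' @param v A [vertebra_quad()].
#' @return A list with class `"directed_line"`: `anchor` (the pi corner) and
#'   a unit `direction`.
#' @export
posterior_tangent <- function(v) {
  stopifnot(inherits(v, "vertebra_quad"))
  d <- unit_vec(unname(v$ps) - unname(v$pi),
                sprintf("%s posterior tangent", v$label))
  structure(list(anchor = v$pi, direction = d), class = "directed_line")
}

#' Endplate line of a vertebra
#'
#' Superior endplate: through ps and as; inferior endplate: through pi and
#' ai.  Both are directed anteriorly.
#'
#' @param v A [vertebra_quad()].
#' @param which `"superior"` or `"inferior"`.
#' @return A `"directed_line"` (anchor at the posterior corner).
#' @export
endplate_line <- function(v, which = c("superior", "inferior")) {
  stopifnot(inherits(v, "vertebra_quad"))
  which <- match.arg(which)
  if (which == "superior") {
    d <- unit_vec(unname(v$as) - unname(v$ps),
                  sprintf("%s superior endplate", v$label))
    structure(list(anchor = v$ps, direction = d), class = "directed_line")
  } else {
    d <- unit_vec(unname(v$ai) - unname(v$pi),
                  sprintf("%s inferior endplate", v$label))
    structure(list(anchor = v$pi, direction = d), class = "directed_line")
  }
}

#' Relative rotation angle between adjacent vertebrae
#'
#' Angle between the posterior body tangents of the upper and lower vertebra;
#' positive = extension (lordotic segmental contribution).
#'
#' @param upper,lower [vertebra_quad()] objects (upper = more cranial).
#' @return Degrees.
#' @export
compute_rra <- function(upper, lower) {
  signed_angle(posterior_tangent(lower)$direction,
               posterior_tangent(upper)$direction)
}

#' Absolute rotation angle (C2--C7)
#'
#' The overall cervical curve: angle between the posterior body tangents of
#' C2 and C7.  Equals the sum of the five segmental RRAs (telescoping).
#'
#' @param set A [landmark_set()].
#' @return Degrees, or `NA` when C2 or C7 is absent.
#' @export
compute_ara <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  if (is.null(set$vertebrae$C2) || is.null(set$vertebrae$C7)) return(NA_real_)
  compute_rra(set$vertebrae$C2, set$vertebrae$C7)
}

#' Segmental Cobb angle across a disc space
#'
#' Angle between the superior endplate of the lower vertebra and the inferior
#' endplate of the upper vertebra (the facing endplates); positive =
#' extension.  For parallelogram-shaped bodies (zero endplate wedging) KA
#' equals RRA at the same level.
#'
#' @param upper,lower [vertebra_quad()] objects.
#' @return Degrees.
#' @export
compute_ka <- function(upper, lower) {
  signed_angle(endplate_line(lower, "superior")$direction,
               endplate_line(upper, "inferior")$direction)
}

#' Segmental translation (listhesis offset)
#'
#' Signed perpendicular distance, in mm, from the upper vertebra's
#' posterior-inferior corner to the (infinite) posterior tangent line of the
#' lower vertebra; positive when the corner lies anterior to the line
#' (a George's-line step-off).
#'
#' @param upper,lower [vertebra_quad()] objects.
#' @return Millimetres.
#' @export
compute_st <- function(upper, lower) {
  tan_lo <- posterior_tangent(lower)
  d <- tan_lo$direction
  n <- c(d[2], -d[1])            # direction rotated -90 deg: anterior normal
  p <- unname(upper$pi) - unname(tan_lo$anchor)
  sum(p * n)
}

#' Atlas plane angle relative to true horizontal
#'
#' Inclination of the C1 plane line (anterior tubercle to posterior laminar
#' midpoint) above the horizontal; positive when the anterior tubercle sits
#' superior to the posterior laminar midpoint.
#'
#' @param atlas An [atlas_landmarks()] or `NULL`.
#' @return Degrees, or `NA` when the atlas is absent.
#' @export
compute_c1h <- function(atlas) {
  if (is.null(atlas)) return(NA_real_)
  stopifnot(inherits(atlas, "atlas_landmarks"))
  v <- unname(atlas$ant_tubercle) - unname(atlas$post_laminar_mid)
  signed_angle(c(1, 0), v)
}

#' Anterior head translation (C2 over C7)
#'
#' Horizontal offset, in mm, of the C2 posterior-superior corner from a
#' vertical line through the C7 posterior-inferior corner; positive =
#' anterior.
#'
#' @param set A [landmark_set()].
#' @return Millimetres, or `NA` when C2 or C7 is absent.
#' @export
compute_tr <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  c2 <- set$vertebrae$C2
  c7 <- set$vertebrae$C7
  if (is.null(c2) || is.null(c7)) return(NA_real_)
  unname(c2$ps["x"] - c7$pi["x"])
}

#' Measure all 18 sagittal alignment variables of one image
#'
#' Computes ARA, C1H, TR and the five segmental KA, RRA and ST values.  A
#' variable whose prerequisite landmarks are absent (or degenerate) is
#' reported as `NA` with a warning rather than failing the whole image.  The
#' function is pure: identical input always yields bit-identical output.
#'
#' @param set A [landmark_set()].
#' @return A one-row data frame: `image_id` plus the 18 variables in fixed
#'   column order (angles in degrees, translations in mm).
#' @export
measure_all <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  out <- stats::setNames(as.list(rep(NA_real_, length(MEASUREMENT_VARS))),
                         MEASUREMENT_VARS)
  grab <- function(var, expr) {
    val <- tryCatch(expr, cervimetrics_degenerate_geometry = function(e) {
      warning(sprintf("image %s: %s unmeasurable (%s)", set$image_id, var,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    out[[var]] <<- val
  }
  grab("ARA", compute_ara(set))
  grab("C1H", compute_c1h(set$atlas))
  grab("TR", compute_tr(set))
  for (i in seq_along(LEVEL_PAIRS)) {
    pair <- LEVEL_PAIRS[i]
    up <- set$vertebrae[[CERVICAL_LEVELS[i]]]
    lo <- set$vertebrae[[CERVICAL_LEVELS[i + 1]]]
    if (is.null(up) || is.null(lo)) next   # stays NA
    grab(paste0("KA", pair), compute_ka(up, lo))
    grab(paste0("RRA", pair), compute_rra(up, lo))
    grab(paste0("ST", pair), compute_st(up, lo))
  }
  cbind(data.frame(image_id = set$image_id, stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Measure every image of a study set
#'
#' @param study A [study_set()].
#' @return Data frame with one row per image (see [measure_all()]).
#' @export
measure_study <- function(study) {
  stopifnot(inherits(study, "study_set"))
  if (!length(study$sets)) {
    empty <- stats::setNames(
      as.data.frame(as.list(rep(NA_real_, length(MEASUREMENT_VARS)))),
      MEASUREMENT_VARS)
    return(cbind(data.frame(image_id = character(0)), empty[0, ]))
  }
  do.call(rbind, lapply(unname(study$sets), measure_all))
}
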