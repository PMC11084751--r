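#' Read a landmark file into a study set
#'
#' Two on-disk schemas are supported.  JSON: one object per trial with
#' `trial_id`, `rater_id` and an `images` array; each image carries
#' `image_id`, `mm_per_unit`, optional `metadata`, an optional `C1` block with
#' the three atlas points, and `C2` ... `C7` blocks with the four body corners
#' `as`, `ps`, `ai`, `pi` as `[x, y]`.  CSV (long): columns
#' `image_id, vertebra, point, x, y, mm_per_unit`.
#'
#' Coordinates are multiplied by `mm_per_unit` on read, so all in-memory
#' geometry is in millimetres.
#'
#' @param source Path to the file.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @param trial_id,rater_id Identifiers used for CSV input (which does not
#'   carry them); ignored for JSON.
#' @return A [study_set()].
#' @export
read_landmark_file <- function(source, format = c("auto", "json", "csv"),
                               trial_id = "trial", rater_id = "unknown") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json"
              else if (grepl("\\.csv$", source, ignore.case = TRUE)) "csv"
              else cm_stop(sprintf("cannot infer format of '%s'", source),
                           "parse_error")
  }
  if (!file.exists(source)) {
    cm_stop(sprintf("landmark file '%s' does not exist", source), "io_error")
  }
  switch(format,
         json = read_landmark_json(source),
         csv  = read_landmark_csv(source, trial_id, rater_id))
}

parse_xy <- function(v, image_id, what) {
  if (is.null(v) || length(v) != 2L || !is.numeric(unlist(v)) ||
      !all(is.finite(unlist(v)))) {
    cm_stop(sprintf("image %s: field %s is not a finite [x, y] pair",
                    image_id, what), "parse_error")
  }
  unlist(v)
}

read_landmark_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) cm_stop(sprintf("cannot parse JSON '%s': %s",
                                        path, conditionMessage(e)),
                                "parse_error"))
  for (field in c("trial_id", "rater_id", "images")) {
    if (is.null(doc[[field]])) {
      cm_stop(sprintf("JSON '%s' lacks required field '%s'", path, field),
              "parse_error")
    }
  }
  sets <- lapply(doc$images, function(img) {
    id <- img$image_id
    if (is.null(id)) cm_stop("image record lacks image_id", "parse_error")
    mmpu <- if (is.null(img$mm_per_unit)) 1 else img$mm_per_unit
    quads <- list()
    for (lev in CERVICAL_LEVELS) {
      blk <- img[[lev]]
      if (is.null(blk)) next
      pts <- lapply(QUAD_POINTS, function(pt) {
        parse_xy(blk[[pt]], id, paste0(lev, ".", pt))
      })
      names(pts) <- QUAD_POINTS
      quads[[lev]] <- vertebra_quad(lev, pts$as, pts$ps, pts$ai, pts$pi)
    }
    atlas <- NULL
    if (!is.null(img$C1)) {
      pts <- lapply(ATLAS_POINTS, function(pt) {
        parse_xy(img$C1[[pt]], id, paste0("C1.", pt))
      })
      atlas <- atlas_landmarks(pts[[1]], pts[[2]], pts[[3]])
    }
    meta <- if (is.null(img$metadata)) list() else img$metadata
    landmark_set(id, quads, atlas = atlas, mm_per_unit = mmpu,
                 metadata = meta)
  })
  study_set(doc$trial_id, doc$rater_id, sets)
}

read_landmark_csv <- function(path, trial_id, rater_id) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) cm_stop(sprintf("cannot parse CSV '%s': %s",
                                        path, conditionMessage(e)),
                                "parse_error"))
  need <- c("image_id", "vertebra", "point", "x", "y", "mm_per_unit")
  if (!all(need %in% names(df))) {
    cm_stop(sprintf("CSV '%s' lacks columns: %s", path,
                    paste(setdiff(need, names(df)), collapse = ", ")),
            "parse_error")
  }
  key <- paste(df$image_id, df$vertebra, df$point)
  if (anyDuplicated(key)) {
    cm_stop(sprintf("duplicate (image_id, vertebra, point) rows: %s",
                    paste(unique(key[duplicated(key)]), collapse = "; ")),
            "parse_error")
  }
  sets <- lapply(split(df, df$image_id), function(rows) {
    id <- rows$image_id[1]
    mmpu <- unique(rows$mm_per_unit)
    if (length(mmpu) != 1L) {
      cm_stop(sprintf("image %s: inconsistent mm_per_unit", id), "parse_error")
    }
    getpt <- function(vert, pt) {
      r <- rows[rows$vertebra == vert & rows$point == pt, ]
      if (nrow(r) == 0L) {
        cm_stop(sprintf("image %s: missing point %s.%s", id, vert, pt),
                "parse_error")
      }
      if (!is.finite(r$x) || !is.finite(r$y)) {
        cm_stop(sprintf("image %s: non-finite coordinates at %s.%s",
                        id, vert, pt), "parse_error")
      }
      c(r$x, r$y)
    }
    quads <- list()
    for (lev in intersect(CERVICAL_LEVELS, unique(rows$vertebra))) {
      quads[[lev]] <- vertebra_quad(lev,
                                    as = getpt(lev, "as"),
                                    ps = getpt(lev, "ps"),
                                    ai = getpt(lev, "ai"),
                                    pi = getpt(lev, "pi"))
    }
    atlas <- NULL
    if ("C1" %in% rows$vertebra) {
      atlas <- atlas_landmarks(getpt("C1", "ant_tubercle"),
                               getpt("C1", "dens_post_mid"),
                               getpt("C1", "post_laminar_mid"))
    }
    landmark_set(id, quads, atlas = atlas, mm_per_unit = mmpu)
  })
  # split() orders by factor level; restore file order of first appearance
  sets <- sets[unique(df$image_id)]
  study_set(trial_id, rater_id, unname(sets))
}

#' Write a study set to a landmark file
#'
#' Coordinates are written in millimetres with `mm_per_unit = 1`;
#' `read_landmark_file()` on the output reproduces every coordinate to
#' better than 1e-9 mm.
#'
#' @param study A [study_set()].
#' @param dest Output path.
#' @param format `"json"` or `"csv"`; inferred from the extension when
#'   omitted.  CSV is the long format and does not carry trial/rater ids or
#'   metadata.
#' @return `dest`, invisibly.
#' @export
write_landmark_file <- function(study, dest, format = c("auto", "json", "csv")) {
  stopifnot(inherits(study, "study_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", dest, ignore.case = TRUE)) "json"
              else if (grepl("\\.csv$", dest, ignore.case = TRUE)) "csv"
              else cm_stop(sprintf("cannot infer format of '%s'", dest),
                           "parse_error")
  }
  switch(format,
         json = write_landmark_json(study, dest),
         csv  = write_landmark_csv(study, dest))
  invisible(dest)
}

write_landmark_json <- function(study, dest) {
  images <- lapply(study$sets, function(s) {
    img <- list(image_id = s$image_id, mm_per_unit = 1)
    if (length(s$metadata)) img$metadata <- s$metadata
    if (!is.null(s$atlas)) {
      img$C1 <- lapply(s$atlas[ATLAS_POINTS], function(p) unname(as.vector(p)))
    }
    for (lev in names(s$vertebrae)) {
      v <- s$vertebrae[[lev]]
      img[[lev]] <- lapply(v[QUAD_POINTS], function(p) unname(as.vector(p)))
    }
    img
  })
  doc <- list(trial_id = study$trial_id, rater_id = study$rater_id,
              images = unname(images))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tryCatch(writeLines(json, dest),
           error = function(e) cm_stop(sprintf("cannot write '%s': %s", dest,
                                               conditionMessage(e)),
                                       "io_error"))
}

write_landmark_csv <- function(study, dest) {
  rows <- list()
  for (s in study$sets) {
    if (!is.null(s$atlas)) {
      for (pt in ATLAS_POINTS) {
        p <- s$atlas[[pt]]
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = s$image_id, vertebra = "C1", point = pt,
          x = p[[1]], y = p[[2]], mm_per_unit = 1)
      }
    }
    for (lev in names(s$vertebrae)) {
      v <- s$vertebrae[[lev]]
      for (pt in QUAD_POINTS) {
        p <- v[[pt]]
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = s$image_id, vertebra = lev, point = pt,
          x = p[[1]], y = p[[2]], mm_per_unit = 1)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(image_id = character(), vertebra = character(),
                        point = character(), x = numeric(), y = numeric(),
                        mm_per_unit = numeric())
  tryCatch(utils::write.csv(df, dest, row.names = FALSE),
           error = function(e) cm_stop(sprintf("cannot write '%s': %s", dest,
                                               conditionMessage(e)),
                                       "io_error"))
}

#' Write a wide measurement table to CSV
#'
#' Column order is fixed (`image_id`, then the 18 variables) for
#' diff-stability; missing values are written as empty fields.
#'
#' @param measurements Data frame as returned by [measure_study()].
#' @param dest Output path.
#' @return `dest`, invisibly.
#' @export
write_measurement_csv <- function(measurements, dest) {
  cols <- c("image_id", MEASUREMENT_VARS)
  missing_cols <- setdiff(cols, names(measurements))
  if (length(missing_cols)) {
    cm_stop(sprintf("measurement table lacks columns: %s",
                    paste(missing_cols, collapse = ", ")), "validation_error")
  }
  extra <- setdiff(names(measurements), cols)
  utils::write.csv(measurements[, c(cols, extra)], dest, row.names = FALSE,
                   na = "")
  invisible(dest)
}

#' Read a wide measurement table from CSV
#'
#' @param path CSV written by [write_measurement_csv()].
#' @return Data frame with `image_id` and the 18 variable columns; empty
#'   fields become `NA`.
#' @export
read_measurement_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (!"image_id" %in% names(df)) {
    cm_stop(sprintf("'%s' is not a measurement table (no image_id)", path),
            "parse_error")
  }
  df$image_id <- as.character(df$image_id)
  df
}
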