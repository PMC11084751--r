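#' Configuration of the synthetic cervical spine generator
#'
#' The generator parametrizes a sagittal cervical spine directly by its
#' posterior-tangent direction angles, so the rotational ground truth is
#' exact by construction: the C7 tangent is tilted by `base_tilt`, and each
#' level's tangent adds the segmental share `ara_total * segment_weight` so
#' that the C2--C7 angle equals `ara_total` exactly.  Vertebral bodies are
#' quadrilaterals of the given heights/depths stacked along the curve with
#' disc gaps; segmental listhesis is injected as an offset along the anterior
#' normal of the disc space, and endplate wedging rotates the anterior
#' corners about the posterior ones.  An atlas plane line of span
#' `atlas_span` is placed above C2 at absolute inclination `atlas_angle`.
#'
#' Per-image variation (draws): `ara_total ~ N(ara_mean, ara_sd)`,
#' `base_tilt ~ N(base_tilt_mean, base_tilt_sd)`, per-level listhesis
#' `~ N(injected_translations, listhesis_sd)`, per-endplate wedges
#' `~ N(0, wedge_sd)`, `atlas_angle ~ N(atlas_angle_mean, atlas_angle_sd)`,
#' plus a global rotation/translation (and optional log-normal scale) of the
#' whole image.
#'
#' @param n_images Number of images per simulated study.
#' @param seed Master seed; every random substream is derived from it.
#' @param ara_mean,ara_sd Population mean and between-patient SD of the total
#'   C2--C7 lordosis (degrees).
#' @param segment_weights Five fractions (C2/C3 ... C6/C7) summing to 1.
#' @param base_tilt_mean,base_tilt_sd C7 posterior tangent tilt (degrees).
#' @param body_heights Named vector, posterior body heights of C2..C7 (mm).
#' @param body_depths Named vector, body depths of C2..C7 (mm).
#' @param disc_gaps Disc-space gaps for the five levels (mm).
#' @param injected_translations Fixed anterior (+) listhesis offsets per level
#'   (mm).
#' @param listhesis_sd SD of random per-level listhesis (mm).
#' @param wedge_sd SD of random per-endplate wedge rotations (degrees).
#' @param atlas Include the C1 landmarks?
#' @param atlas_angle_mean,atlas_angle_sd Atlas plane inclination (degrees).
#' @param atlas_span Length of the atlas plane line (mm).
#' @param global_rotation_sd,global_translation_sd,global_log_scale_sd
#'   SDs of the per-image global rotation (degrees), translation (mm, each
#'   axis) and log scale factor.
#' @return A list with class `"generator_config"`.
#' @export
generator_config <- function(n_images = 254,
                             seed = 1234,
                             ara_mean = 20, ara_sd = 10,
                             segment_weights = rep(0.2, 5),
                             base_tilt_mean = 0, base_tilt_sd = 5,
                             body_heights = c(C2 = 18, C3 = 11, C4 = 11,
                                              C5 = 11, C6 = 11, C7 = 11),
                             body_depths = stats::setNames(rep(16, 6),
                                                           CERVICAL_LEVELS),
                             disc_gaps = rep(5, 5),
                             injected_translations = rep(0, 5),
                             listhesis_sd = 0.5,
                             wedge_sd = 1,
                             atlas = TRUE,
                             atlas_angle_mean = 0, atlas_angle_sd = 5,
                             atlas_span = 45,
                             global_rotation_sd = 2,
                             global_translation_sd = 5,
                             global_log_scale_sd = 0) {
  cfg <- list(n_images = n_images, seed = seed,
              ara_mean = ara_mean, ara_sd = ara_sd,
              segment_weights = as.numeric(segment_weights),
              base_tilt_mean = base_tilt_mean, base_tilt_sd = base_tilt_sd,
              body_heights = expand_levels(body_heights, "body_heights"),
              body_depths = expand_levels(body_depths, "body_depths"),
              disc_gaps = expand_pairs(disc_gaps, "disc_gaps"),
              injected_translations = expand_pairs(injected_translations,
                                                   "injected_translations"),
              listhesis_sd = listhesis_sd, wedge_sd = wedge_sd,
              atlas = isTRUE(atlas),
              atlas_angle_mean = atlas_angle_mean,
              atlas_angle_sd = atlas_angle_sd, atlas_span = atlas_span,
              global_rotation_sd = global_rotation_sd,
              global_translation_sd = global_translation_sd,
              global_log_scale_sd = global_log_scale_sd)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

expand_levels <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 6)
  if (length(x) != 6L) {
    cm_stop(sprintf("%s must have 6 values (C2..C7)", what), "config_error")
  }
  stats::setNames(as.numeric(x), CERVICAL_LEVELS)
}

expand_pairs <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 5)
  if (length(x) != 5L) {
    cm_stop(sprintf("%s must have 5 values (levels 23..67)", what),
            "config_error")
  }
  stats::setNames(as.numeric(x), LEVEL_PAIRS)
}

validate_generator_config <- function(cfg) {
  if (!is_finite_number(cfg$n_images) || cfg$n_images < 1) {
    cm_stop("n_images must be a positive count", "config_error")
  }
  if (length(cfg$segment_weights) != 5L ||
      abs(sum(cfg$segment_weights) - 1) > 1e-12) {
    cm_stop("segment_weights must be 5 fractions summing to 1",
            "config_error")
  }
  for (fld in c("body_heights", "body_depths", "disc_gaps")) {
    if (any(cfg[[fld]] <= 0)) {
      cm_stop(sprintf("%s must be positive", fld), "config_error")
    }
  }
  for (fld in c("ara_sd", "base_tilt_sd", "listhesis_sd", "wedge_sd",
                "atlas_angle_sd", "global_rotation_sd",
                "global_translation_sd", "global_log_scale_sd")) {
    if (cfg[[fld]] < 0) {
      cm_stop(sprintf("%s must be >= 0", fld), "config_error")
    }
  }
  if (cfg$atlas_span <= 0) cm_stop("atlas_span must be > 0", "config_error")
  invisible(cfg)
}

#' Annotator noise model
#'
#' Isotropic Gaussian displacement of every landmark, independently per axis
#' and per trial.  `sigma = 0` reproduces the input bit-exactly.  A named
#' `per_landmark_sigma` can override the global sigma for specific point
#' types (e.g. larger noise on endplate corners of degenerated bodies).
#'
#' @param sigma Human annotator landmark SD (mm).
#' @param cv_sigma Landmark SD of the computer-vision annotator's single
#'   fixed deviation from ground truth (mm); 0 makes the CV annotator exact.
#' @param per_landmark_sigma Optional named numeric overriding `sigma` per
#'   point name (`as`, `ps`, `ai`, `pi`, `ant_tubercle`, `dens_post_mid`,
#'   `post_laminar_mid`).
#' @return A list with class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0.15, cv_sigma = 0.15,
                        per_landmark_sigma = NULL) {
  if (!is_finite_number(sigma) || sigma < 0) {
    cm_stop("sigma must be >= 0", "config_error")
  }
  if (!is_finite_number(cv_sigma) || cv_sigma < 0) {
    cm_stop("cv_sigma must be >= 0", "config_error")
  }
  if (!is.null(per_landmark_sigma)) {
    if (is.null(names(per_landmark_sigma)) || any(per_landmark_sigma < 0)) {
      cm_stop("per_landmark_sigma must be a named non-negative vector",
              "config_error")
    }
  }
  structure(list(sigma = sigma, cv_sigma = cv_sigma,
                 per_landmark_sigma = per_landmark_sigma),
            class = "noise_model")
}

#' Draw the per-image spine parameters
#'
#' Samples one image's parameters from the population distributions in the
#' config, using the current RNG stream.
#'
#' @param cfg A [generator_config()].
#' @return A list of parameters accepted by [generate_spine()].
#' @export
draw_spine_params <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  wedges <- matrix(stats::rnorm(12, 0, cfg$wedge_sd), nrow = 6, ncol = 2,
                   dimnames = list(CERVICAL_LEVELS, c("sup", "inf")))
  list(ara_total = stats::rnorm(1, cfg$ara_mean, cfg$ara_sd),
       base_tilt = stats::rnorm(1, cfg$base_tilt_mean, cfg$base_tilt_sd),
       translations = cfg$injected_translations +
         stats::rnorm(5, 0, cfg$listhesis_sd),
       wedges = wedges,
       atlas_angle = stats::rnorm(1, cfg$atlas_angle_mean,
                                  cfg$atlas_angle_sd),
       global_rotation = stats::rnorm(1, 0, cfg$global_rotation_sd),
       global_translation = stats::rnorm(2, 0, cfg$global_translation_sd),
       global_scale = exp(stats::rnorm(1, 0, cfg$global_log_scale_sd)))
}

#' Fixed spine parameters (no sampling)
#'
#' Convenience constructor of a fully deterministic parameter set, useful for
#' forcing exact ground-truth values.
#'
#' @param ara_total Total C2--C7 lordosis (degrees).
#' @param base_tilt C7 tangent tilt (degrees).
#' @param translations Five anterior listhesis offsets (mm).
#' @param wedges 6 x 2 matrix of endplate wedge angles (degrees; columns
#'   sup/inf, rows C2..C7), or a single number recycled.
#' @param atlas_angle Atlas plane inclination (degrees).
#' @param global_rotation,global_translation,global_scale Global image pose.
#' @return Parameter list for [generate_spine()].
#' @export
spine_params <- function(ara_total = 20, base_tilt = 0,
                         translations = rep(0, 5), wedges = 0,
                         atlas_angle = 0, global_rotation = 0,
                         global_translation = c(0, 0), global_scale = 1) {
  if (length(wedges) == 1L) {
    wedges <- matrix(wedges, 6, 2,
                     dimnames = list(CERVICAL_LEVELS, c("sup", "inf")))
  }
  list(ara_total = ara_total, base_tilt = base_tilt,
       translations = as.numeric(translations), wedges = wedges,
       atlas_angle = atlas_angle, global_rotation = global_rotation,
       global_translation = global_translation, global_scale = global_scale)
}

#' Generate one synthetic spine with exact ground truth
#'
#' Builds the landmark set bottom-up from the posterior tangent angles and
#' records the implied true value of each of the 18 alignment variables.
#' With zero endplate wedging KA equals RRA; with a straight spine
#' (`ara_total = base_tilt = 0`) the segmental translations equal the
#' injected offsets exactly.
#'
#' @param cfg A [generator_config()] (fixed anatomy: heights, depths, gaps,
#'   atlas span).
#' @param image_id Image identifier.
#' @param params Per-image parameters from [draw_spine_params()] or
#'   [spine_params()].
#' @return List with `set` (the noiseless [landmark_set()]) and `truth`
#'   (one-row data frame of the 18 true values).
#' @export
generate_spine <- function(cfg, image_id, params) {
  stopifnot(inherits(cfg, "generator_config"))
  w <- cfg$segment_weights
  alpha <- params$ara_total
  # tangent polar angles (deg, CCW from +y): index 1 = C2 ... 6 = C7
  psi <- numeric(6)
  psi[6] <- params$base_tilt
  for (i in 5:1) psi[i] <- psi[i + 1] + alpha * w[i]
  u <- function(a_deg) c(-sin(deg2rad(a_deg)), cos(deg2rad(a_deg)))
  nrm <- function(a_deg) c(cos(deg2rad(a_deg)), sin(deg2rad(a_deg)))
  h <- cfg$body_heights
  d <- cfg$body_depths
  g <- cfg$disc_gaps
  s <- params$translations
  wedge <- params$wedges
  pi_pts <- ps_pts <- vector("list", 6)
  pi_pts[[6]] <- c(0, 0)
  ps_pts[[6]] <- pi_pts[[6]] + h[6] * u(psi[6])
  for (i in 5:1) {
    mid <- (psi[i] + psi[i + 1]) / 2
    pi_pts[[i]] <- ps_pts[[i + 1]] + g[i] * u(mid) + s[i] * nrm(mid)
    ps_pts[[i]] <- pi_pts[[i]] + h[i] * u(psi[i])
  }
  quads <- vector("list", 6)
  for (i in 1:6) {
    lev <- CERVICAL_LEVELS[i]
    quads[[i]] <- vertebra_quad(
      lev,
      as = ps_pts[[i]] + d[i] * nrm(psi[i] + wedge[i, "sup"]),
      ps = ps_pts[[i]],
      ai = pi_pts[[i]] + d[i] * nrm(psi[i] + wedge[i, "inf"]),
      pi = pi_pts[[i]])
  }
  atlas <- NULL
  if (cfg$atlas) {
    center <- ps_pts[[1]] + 8 * u(psi[1]) + (d[1] / 2) * nrm(psi[1])
    dir <- c(cos(deg2rad(params$atlas_angle)),
             sin(deg2rad(params$atlas_angle)))
    half <- cfg$atlas_span / 2
    atlas <- atlas_landmarks(
      ant_tubercle = center + half * dir,
      dens_post_mid = center - 0.1 * cfg$atlas_span * dir +
        c(-dir[2], dir[1]) * 2,
      post_laminar_mid = center - half * dir)
  }
  set <- landmark_set(image_id, quads, atlas = atlas, mm_per_unit = 1)
  set <- apply_rigid_transform(set,
                               rotation_deg = params$global_rotation,
                               translation = params$global_translation,
                               scale = params$global_scale)
  truth <- stats::setNames(as.list(rep(NA_real_, length(MEASUREMENT_VARS))),
                           MEASUREMENT_VARS)
  truth$ARA <- alpha
  truth$C1H <- if (cfg$atlas) params$atlas_angle + params$global_rotation
               else NA_real_
  truth$TR <- unname(set$vertebrae$C2$ps["x"] - set$vertebrae$C7$pi["x"])
  for (i in seq_along(LEVEL_PAIRS)) {
    pair <- LEVEL_PAIRS[i]
    rra <- alpha * w[i]
    truth[[paste0("RRA", pair)]] <- rra
    truth[[paste0("KA", pair)]] <- rra + wedge[i, "inf"] - wedge[i + 1, "sup"]
    half_rad <- deg2rad(rra) / 2
    truth[[paste0("ST", pair)]] <- params$global_scale *
      (s[i] * cos(half_rad) - g[i] * sin(half_rad))
  }
  truth_df <- cbind(data.frame(image_id = image_id, stringsAsFactors = FALSE),
                    as.data.frame(truth))
  list(set = set, truth = truth_df)
}

#' Perturb a landmark set with annotation noise
#'
#' Displaces every landmark by independent Normal(0, sigma^2) in x and y.
#' Deterministic given `seed`; `sigma = 0` returns the input unchanged.
#'
#' @param set A [landmark_set()].
#' @param noise A [noise_model()] (the `sigma` field is used).
#' @param seed Integer seed for this (rater, trial, image) substream.
#' @param sigma Override of `noise$sigma` (used internally for the CV rater).
#' @return The perturbed [landmark_set()].
#' @export
perturb <- function(set, noise, seed, sigma = NULL) {
  stopifnot(inherits(set, "landmark_set"), inherits(noise, "noise_model"))
  if (is.null(sigma)) sigma <- noise$sigma
  if (sigma == 0 && is.null(noise$per_landmark_sigma)) return(set)
  pt_sigma <- function(name) {
    ovr <- noise$per_landmark_sigma
    if (!is.null(ovr) && name %in% names(ovr)) ovr[[name]] else sigma
  }
  with_seed(seed, {
    jitter_pt <- function(p, name) {
      sg <- pt_sigma(name)
      q <- unname(as.vector(p)) + stats::rnorm(2, 0, sg)
      point2d(q[1], q[2])
    }
    vertebrae <- lapply(set$vertebrae, function(v) {
      vertebra_quad(v$label,
                    as = jitter_pt(v$as, "as"), ps = jitter_pt(v$ps, "ps"),
                    ai = jitter_pt(v$ai, "ai"), pi = jitter_pt(v$pi, "pi"))
    })
    atlas <- if (!is.null(set$atlas)) {
      atlas_landmarks(
        jitter_pt(set$atlas$ant_tubercle, "ant_tubercle"),
        jitter_pt(set$atlas$dens_post_mid, "dens_post_mid"),
        jitter_pt(set$atlas$post_laminar_mid, "post_laminar_mid"))
    }
    landmark_set(set$image_id, vertebrae, atlas = atlas, mm_per_unit = 1,
                 metadata = set$metadata)
  })
}

#' Simulate a complete repeated-measures study
#'
#' Generates `cfg$n_images` ground-truth spines and three annotation trials:
#' `US1` and `US2` are independent noisy digitizations by the (simulated)
#' human rater, and `CV` is the computer-vision annotator — a single fixed
#' deviation from truth (at `noise$cv_sigma`) that is bit-identical every
#' time it is re-measured, reproducing the deterministic-annotator identity
#' experiment.
#'
#' Every random substream is derived from `cfg$seed` and labelled by
#' (rater, trial, image), so results are reproducible and independent of
#' evaluation order.
#'
#' @param cfg A [generator_config()].
#' @param noise A [noise_model()].
#' @return List: `truth` (data frame of true values), `noiseless`
#'   (ground-truth [study_set()]), `trials` (named list of [study_set()]s
#'   `US1`, `US2`, `CV`).
#' @export
simulate_study <- function(cfg, noise = noise_model()) {
  stopifnot(inherits(cfg, "generator_config"))
  ids <- sprintf("img%04d", seq_len(cfg$n_images))
  spines <- lapply(ids, function(id) {
    params <- with_seed(substream_seed(cfg$seed, paste0("truth/", id)),
                        draw_spine_params(cfg))
    generate_spine(cfg, id, params)
  })
  truth <- do.call(rbind, lapply(spines, `[[`, "truth"))
  noiseless <- study_set("truth", "truth", lapply(spines, `[[`, "set"))
  make_trial <- function(rater, trial_label, sigma) {
    sets <- lapply(spines, function(sp) {
      perturb(sp$set, noise,
              seed = substream_seed(cfg$seed,
                                    paste(rater, trial_label,
                                          sp$set$image_id, sep = "/")),
              sigma = sigma)
    })
    study_set(trial_label, rater, sets)
  }
  trials <- list(US1 = make_trial("US", "trial1", noise$sigma),
                 US2 = make_trial("US", "trial2", noise$sigma),
                 CV = make_trial("CV", "fixed", noise$cv_sigma))
  list(truth = truth, noiseless = noiseless, trials = trials)
}
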