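# Independent geometric oracles used to cross-check the mensuration kernels.
# These deliberately take a different route (polar angles / cross products)
# than the implementation's signed-angle kernel.

wrap180 <- function(a) ((a + 180) %% 360) - 180

polar_deg <- function(v) atan2(v[2], v[1]) * 180 / pi

oracle_tangent_angle <- function(quad) {
  polar_deg(unname(quad$ps) - unname(quad$pi))
}

oracle_endplate_angle <- function(quad, which) {
  if (which == "superior") polar_deg(unname(quad$as) - unname(quad$ps))
  else polar_deg(unname(quad$ai) - unname(quad$pi))
}

oracle_rra <- function(upper, lower) {
  wrap180(oracle_tangent_angle(upper) - oracle_tangent_angle(lower))
}

oracle_ka <- function(upper, lower) {
  wrap180(oracle_endplate_angle(upper, "inferior") -
            oracle_endplate_angle(lower, "superior"))
}

# Signed point-to-line distance via the cross product; positive on the
# anterior side (direction rotated -90 degrees).
oracle_point_line_dist <- function(p, anchor, dir) {
  d <- unname(dir) / sqrt(sum(dir^2))
  q <- unname(p) - unname(anchor)
  -(d[1] * q[2] - d[2] * q[1])
}

oracle_st <- function(upper, lower) {
  dir <- unname(lower$ps) - unname(lower$pi)
  oracle_point_line_dist(unname(upper$pi), unname(lower$pi), dir)
}

# Random valid landmark set: generator geometry with randomized population
# parameters plus heavy landmark jitter, so quads are generic (wedged,
# tilted, translated) rather than idealized.
random_landmark_set <- function(seed, atlas = TRUE, jitter = 1.0) {
  cfg <- generator_config(
    n_images = 1, seed = seed,
    ara_mean = 15, ara_sd = 15,
    segment_weights = local({
      w <- with_seed_helper(seed + 1, stats::runif(5, 0.5, 1.5))
      w / sum(w)
    }),
    base_tilt_sd = 8, listhesis_sd = 1, wedge_sd = 2,
    atlas = atlas, atlas_angle_sd = 8,
    global_rotation_sd = 10, global_translation_sd = 25)
  params <- with_seed_helper(seed, draw_spine_params(cfg))
  set <- generate_spine(cfg, sprintf("rnd%06d", seed), params)$set
  if (jitter > 0) {
    set <- perturb(set, noise_model(sigma = jitter), seed = seed + 2)
  }
  set
}

# Local seeded evaluation that restores the caller's RNG state.
with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Small hand-built quad: axis-aligned 16 x 11 mm body at a given offset.
box_quad <- function(label, x0 = 0, y0 = 0, depth = 16, height = 11) {
  vertebra_quad(label,
                as = c(x0 + depth, y0 + height),
                ps = c(x0, y0 + height),
                ai = c(x0 + depth, y0),
                pi = c(x0, y0))
}

# Straight stacked test spine: C7 at origin, bodies 11 mm high with 5 mm
# gaps; optional per-level anterior shifts (named by pair, e.g. c("45" = 2)).
stacked_spine <- function(shifts = c(), atlas = NULL, image_id = "stack") {
  levels <- c("C2", "C3", "C4", "C5", "C6", "C7")
  pairs <- c("23", "34", "45", "56", "67")
  quads <- list()
  y <- 0
  x <- 0
  for (i in 6:1) {
    quads[[levels[i]]] <- box_quad(levels[i], x0 = x, y0 = y)
    if (i > 1) {
      y <- y + 11 + 5
      pair <- pairs[i - 1]
      if (pair %in% names(shifts)) x <- x + shifts[[pair]]
    }
  }
  landmark_set(image_id, quads, atlas = atlas)
}
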