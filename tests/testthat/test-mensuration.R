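test_that("signed_angle is the CCW rotation in (-180, 180]", {
  expect_equal(signed_angle(c(0, 1), c(0, 1)), 0)
  expect_equal(signed_angle(c(1, 0), c(0, 1)), 90)
  th <- 10 * pi / 180
  expect_equal(signed_angle(c(0, 1), c(-sin(th), cos(th))), 10,
               tolerance = 1e-12)
  expect_error(signed_angle(c(0, 0), c(1, 0)),
               class = "cervimetrics_degenerate_geometry")

  # antisymmetry on random directions
  for (i in 1:50) {
    a <- with_seed_helper(i, stats::runif(2, -1, 1))
    b <- with_seed_helper(i + 999, stats::runif(2, -1, 1))
    if (sqrt(sum(a^2)) < 1e-6 || sqrt(sum(b^2)) < 1e-6) next
    expect_equal(signed_angle(a, b), -signed_angle(b, a), tolerance = 1e-12)
    expect_lte(signed_angle(a, b), 180)
    expect_gt(signed_angle(a, b), -180)
  }
})

test_that("posterior tangent and endplate lines follow the corner scheme", {
  v <- vertebra_quad("C4", as = c(15, 10), ps = c(0, 10),
                     ai = c(15, 0), pi = c(0, 0))
  pt <- posterior_tangent(v)
  expect_equal(pt$direction, c(0, 1))
  expect_equal(unname(pt$anchor), c(0, 0))
  expect_equal(endplate_line(v, "superior")$direction, c(1, 0))
  expect_equal(endplate_line(v, "inferior")$direction, c(1, 0))

  slanted <- vertebra_quad("C4", as = c(15, 12), ps = c(0, 10),
                           ai = c(15, 0), pi = c(0, 0))
  expect_equal(endplate_line(slanted, "superior")$direction,
               c(15, 2) / sqrt(15^2 + 2^2))
  tilted <- vertebra_quad("C4", as = c(14, 10), ps = c(-1, 10),
                          ai = c(15, 0), pi = c(0, 0))
  expect_equal(posterior_tangent(tilted)$direction,
               c(-1, 10) / sqrt(101))

  # unit length on random non-degenerate quads
  for (i in 1:100) {
    set <- random_landmark_set(3000 + i)
    for (v in set$vertebrae) {
      expect_equal(sqrt(sum(posterior_tangent(v)$direction^2)), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("atlas plane angle matches the hand atan oracle and is rotation-equivariant", {
  horiz <- atlas_landmarks(c(40, 0), c(20, 2), c(0, 0))
  expect_equal(compute_c1h(horiz), 0)

  a <- atlas_landmarks(c(40, 1), c(20, 2), c(0, 0))
  expect_equal(compute_c1h(a), atan(1 / 40) * 180 / pi, tolerance = 1e-9)
  expect_equal(compute_c1h(a), 1.432, tolerance = 1e-3)

  set <- random_landmark_set(42, atlas = TRUE)
  rotated <- apply_rigid_transform(set, rotation_deg = 3)
  expect_equal(compute_c1h(rotated$atlas), compute_c1h(set$atlas) + 3,
               tolerance = 1e-9)

  expect_true(is.na(compute_c1h(NULL)))
})

test_that("segmental and global variables on hand-built spines", {
  straight <- stacked_spine()
  m <- measure_all(straight)
  expect_equal(m$ARA, 0)
  expect_equal(m$TR, 0)
  for (pair in c("23", "34", "45", "56", "67")) {
    expect_equal(m[[paste0("RRA", pair)]], 0)
    expect_equal(m[[paste0("KA", pair)]], 0)
    expect_equal(m[[paste0("ST", pair)]], 0)
  }

  # +2 mm anterior shift of everything above C4/C5
  shifted <- stacked_spine(shifts = c("45" = 2))
  ms <- measure_all(shifted)
  expect_equal(ms$ST45, 2)
  expect_equal(ms$ST23, 0)
  expect_equal(ms$TR, 2)

  # TR is the plain x-offset of C2.ps from C7.pi
  set <- stacked_spine()
  set$vertebrae$C2 <- box_quad("C2", x0 = 15, y0 = 80)
  expect_equal(compute_tr(set), 15)
})

test_that("KA equals RRA on parallelogram bodies and splits with wedging", {
  cfg <- generator_config(n_images = 1, wedge_sd = 0, listhesis_sd = 0)
  for (i in 1:25) {
    params <- with_seed_helper(7000 + i, draw_spine_params(cfg))
    set <- generate_spine(cfg, "pgram", params)$set
    m <- measure_all(set)
    for (pair in c("23", "34", "45", "56", "67")) {
      expect_equal(m[[paste0("KA", pair)]], m[[paste0("RRA", pair)]],
                   tolerance = 1e-9)
    }
  }

  # inferior endplate of the upper body tilted +5 degrees by construction
  wedges <- matrix(0, 6, 2, dimnames = list(c("C2", "C3", "C4", "C5", "C6",
                                              "C7"), c("sup", "inf")))
  wedges["C4", "inf"] <- 5
  p <- spine_params(ara_total = 0, wedges = wedges)
  set <- generate_spine(generator_config(n_images = 1), "wedge", p)$set
  m <- measure_all(set)
  expect_equal(m$KA45, 5, tolerance = 1e-9)
  expect_equal(m$RRA45, 0, tolerance = 1e-9)
})

test_that("angles and distances agree with independent polar/cross oracles", {
  for (i in 1:200) {
    set <- random_landmark_set(5000 + i)
    m <- measure_all(set)
    levels <- c("C2", "C3", "C4", "C5", "C6", "C7")
    pairs <- c("23", "34", "45", "56", "67")
    for (j in 1:5) {
      up <- set$vertebrae[[levels[j]]]
      lo <- set$vertebrae[[levels[j + 1]]]
      expect_equal(m[[paste0("RRA", pairs[j])]], oracle_rra(up, lo),
                   tolerance = 1e-9)
      expect_equal(m[[paste0("KA", pairs[j])]], oracle_ka(up, lo),
                   tolerance = 1e-9)
      expect_equal(m[[paste0("ST", pairs[j])]], oracle_st(up, lo),
                   tolerance = 1e-9)
    }
    expect_equal(m$ARA, oracle_rra(set$vertebrae$C2, set$vertebrae$C7),
                 tolerance = 1e-9)
  }
})

test_that("ARA telescopes over the segmental rotation angles", {
  for (i in 1:200) {
    m <- measure_all(random_landmark_set(6000 + i))
    expect_equal(m$ARA, m$RRA23 + m$RRA34 + m$RRA45 + m$RRA56 + m$RRA67,
                 tolerance = 1e-9)
  }
})

test_that("alignment variables are invariant under rigid motion, equivariant in scale", {
  rigid_vars <- c("ARA", paste0("RRA", c("23", "34", "45", "56", "67")),
                  paste0("KA", c("23", "34", "45", "56", "67")),
                  paste0("ST", c("23", "34", "45", "56", "67")))
  for (i in 1:60) {
    set <- random_landmark_set(8000 + i)
    rot <- with_seed_helper(i, stats::runif(1, -30, 30))
    tr <- with_seed_helper(i + 500, stats::runif(2, -50, 50))
    moved <- apply_rigid_transform(set, rotation_deg = rot, translation = tr)
    m0 <- measure_all(set)
    m1 <- measure_all(moved)
    for (v in rigid_vars) expect_equal(m1[[v]], m0[[v]], tolerance = 1e-9)
    expect_equal(m1$C1H, m0$C1H + rot, tolerance = 1e-9)

    # pure translation leaves C1H and TR alone
    slid <- apply_rigid_transform(set, translation = tr)
    ms <- measure_all(slid)
    expect_equal(ms$C1H, m0$C1H, tolerance = 1e-9)
    expect_equal(ms$TR, m0$TR, tolerance = 1e-9)

    # uniform scale multiplies distances, leaves angles
    sc <- with_seed_helper(i + 900, stats::runif(1, 0.5, 2))
    scaled <- measure_all(apply_rigid_transform(set, scale = sc))
    expect_equal(scaled$ARA, m0$ARA, tolerance = 1e-9)
    expect_equal(scaled$ST45, m0$ST45 * sc, tolerance = 1e-9)
    expect_equal(scaled$TR, m0$TR * sc, tolerance = 1e-9)
  }
})

test_that("measure_all reports 18 variables, missing markers, and is pure", {
  set <- random_landmark_set(99)
  m <- measure_all(set)
  vars <- setdiff(names(m), "image_id")
  expect_length(vars, 18)
  expect_true(all(is.finite(unlist(m[vars]))))

  # bit-identical on repeated application
  expect_identical(measure_all(set), measure_all(set))

  # no atlas: C1H missing, everything else finite
  no_c1 <- stacked_spine()
  m2 <- measure_all(no_c1)
  expect_true(is.na(m2$C1H))
  expect_equal(sum(is.finite(unlist(m2[vars]))), 17)

  # missing C7: global and C6/C7 variables missing, others computable
  partial <- landmark_set("p", lapply(c("C2", "C3", "C4", "C5", "C6"),
                                      function(l, i = match(l, c("C2", "C3", "C4", "C5", "C6"))) {
                                        box_quad(l, y0 = (5 - i) * 16)
                                      }))
  m3 <- measure_all(partial)
  expect_true(is.na(m3$ARA))
  expect_true(is.na(m3$TR))
  expect_true(is.na(m3$RRA67))
  expect_false(is.na(m3$RRA23))
})
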