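test_that("screw operator has the closed-form rotation and composes as powers", {
  p <- helical_params(134.6, 5.6)
  # twist 0 (mod 360) is a pure translation
  t0 <- screw_from_params(helical_params(360, 5.6))
  expect_equal(t0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(t0$translation, c(0, 0, 5.6), tolerance = 1e-12)
  tf <- screw_from_params(p)
  expect_equal(sum(diag(tf$rotation)), 1 + 2 * cos(134.6 * pi / 180),
               tolerance = 1e-12)
  # n applications equal the closed-form n-th power
  acc <- tf
  for (k in 2:7) acc <- compose_transforms(tf, acc)
  pow <- screw_from_params(p, power = 7)
  expect_equal(acc$rotation, pow$rotation, tolerance = 1e-9)
  expect_equal(acc$translation, pow$translation, tolerance = 1e-9)
  expect_error(screw_from_params(p, axis_direction = c(0, 0, 0)),
               class = "helicomb_error_degenerate_axis")
})

test_that("screw decomposition inverts construction for 1000 random screws", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    ang <- runif(1, 5, 180)
    ri <- runif(1, 1, 20)
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    org <- rnorm(3, sd = 10)
    d <- screw_decompose(screw_from_params(helical_params(ang, ri), org, ax))
    worst <- max(worst, abs(d$twist_deg - ang), abs(d$rise_A - ri),
                 1 - abs(sum(d$axis_direction * ax)))
    # recovered axis passes through the line: origin component off-axis
    rel <- d$axis_origin - org
    off <- rel - sum(rel * ax) * ax
    worst <- max(worst, sqrt(sum(off^2)))
  }
  expect_lt(worst, 1e-6)
  expect_error(screw_decompose(rigid_transform(diag(3), c(0, 0, 3))),
               class = "helicomb_error_undefined_axis")
})

test_that("filament construction preserves internal geometry and ring symmetry", {
  prot <- toy_prot()
  p <- helical_params(134.6, 5.6)
  f <- build_filament(prot, p, 12)
  d0 <- dist(tidy(prot)[, c("x", "y", "z")])
  d7 <- dist(tidy(f$protomers[[7]])[, c("x", "y", "z")])
  expect_equal(as.numeric(d7), as.numeric(d0), tolerance = 1e-9)
  # consecutive-subunit axial spacing equals the rise
  td <- tidy(f)
  expect_equal(diff(td$axial), rep(5.6, 11), tolerance = 1e-9)
  # single-subunit build returns the protomer unchanged
  f1 <- build_filament(prot, p, 1)
  expect_equal(tidy(f1$protomers[[1]])$x, tidy(prot)$x)
  # a cn = 3 ring with one level: members related by 120 deg, zero rise
  ring <- build_filament(prot, helical_params(60, 8, cn = 3), 3)
  tr <- tidy(ring)
  expect_equal(tr$axial, rep(tr$axial[1], 3), tolerance = 1e-9)
  R120 <- rotation_about_axis(c(0, 0, 1), 120)
  expect_equal(unname(apply_transform(rigid_transform(R120),
                                      as.matrix(tidy(ring$protomers[[1]])[, c("x", "y", "z")]))),
               unname(as.matrix(tidy(ring$protomers[[2]])[, c("x", "y", "z")])),
               tolerance = 1e-9)
  expect_error(build_filament(prot, helical_params(60, 8, cn = 3), 7),
               class = "helicomb_error_precondition")
})

test_that("estimate_params inverts build_filament over a twist/rise/cn grid", {
  prot <- toy_prot()
  for (tw in c(20, 80, 134.6, 170)) {
    for (ri in c(3, 8, 20)) {
      for (cn in 1:3) {
        f <- build_filament(prot, helical_params(tw, ri, cn), 8 * cn)
        est <- estimate_params(f)
        expect_equal(est$twist_deg, tw, tolerance = 1e-3)
        expect_equal(est$rise_A, ri, tolerance = 1e-3)
        expect_identical(est$cn, as.integer(cn))
      }
    }
  }
})

test_that("estimate_params reports the descriptive strand count of the lattice", {
  prot <- toy_prot()
  est <- estimate_params(build_filament(prot, helical_params(134.6, 5.6), 12))
  expect_identical(est$n_start, 3L)
})

test_that("parameter recovery tolerates coordinate noise", {
  hits <- 0
  for (s in 1:20) {
    fx <- make_filament_fixture(n = 18, noise_sigma = 0.3, seed = s)
    est <- estimate_params(fx$filament)
    if (abs(est$twist_deg - 134.6) < 0.5 && abs(est$rise_A - 5.6) < 0.2) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("non-helical assemblies and short inputs are rejected", {
  prot <- toy_prot()
  f <- build_filament(prot, helical_params(134.6, 5.6), 8)
  # scramble: replace protomers with randomly placed copies
  set.seed(5)
  f$protomers <- lapply(f$protomers, function(p) {
    transform_protomer(p, random_rigid_transform())
  })
  expect_error(estimate_params(f), class = "helicomb_error_non_helical")
  f2 <- build_filament(prot, helical_params(134.6, 5.6), 2)
  expect_error(estimate_params(f2), class = "helicomb_error_precondition")
})
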