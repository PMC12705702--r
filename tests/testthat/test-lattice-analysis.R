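test_that("hashed contact graph equals the O(N^2) oracle", {
  for (cutoff in c(4.5, 6)) {
    fx <- ifi16_fixture(n = 8)
    got <- contact_graph(fx$filament, cutoff)
    want <- brute_contact_graph(fx$filament, cutoff)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$i, want$i)
    expect_identical(got$j, want$j)
    expect_identical(got$n_contacts, as.integer(want$n_contacts))
    expect_equal(got$min_dist, want$min_dist, tolerance = 1e-9)
  }
  # two isolated protomers: empty edge set
  prot <- toy_prot()
  far <- filament(list(prot, transform_protomer(
    prot, rigid_transform(diag(3), c(200, 0, 0)))))
  expect_identical(nrow(contact_graph(far)), 0L)
})

test_that("interior subunits of the calibrated lattice have contact degree 6", {
  fx <- ifi16_fixture(n = 24)
  cg <- contact_graph(fx$filament)
  deg <- table(factor(c(cg$i, cg$j), levels = 1:24))
  expect_true(all(deg[6:19] == 6))
  expect_setequal(unique(cg$offset), c(2, 3, 5))
})

test_that("honeycomb extraction yields a six-member typed shell, stable across centers and lengths", {
  fx <- ifi16_fixture(n = 24)
  hc <- extract_honeycomb(fx$filament, 12)
  expect_s3_class(hc, "honeycomb")
  expect_identical(nrow(hc$shell), 6L)
  expect_setequal(hc$shell$offset, c(-5, -3, -2, 2, 3, 5))
  expect_setequal(unique(hc$shell$half), c("top", "bottom"))
  expect_identical(sum(hc$shell$half == "top"), 3L)
  expect_false(any(duplicated(hc$shell$partner)))
  expect_true(all(hc$shell$n_contacts >= 1))
  # shell composition is invariant to the center index and filament length
  hc2 <- extract_honeycomb(fx$filament, 14)
  expect_identical(hc2$shell$offset, hc$shell$offset)
  fx30 <- ifi16_fixture(n = 30)
  hc3 <- extract_honeycomb(fx30$filament, 15)
  expect_identical(hc3$shell$offset, hc$shell$offset)
  # terminal subunit: incomplete shell, missing offsets listed
  err <- expect_error(extract_honeycomb(fx$filament, 2),
                      class = "helicomb_error_incomplete_shell")
  expect_match(conditionMessage(err), "-5")
})

test_that("interface typing follows the dominant center segment", {
  prot <- toy_prot()
  hc3 <- classify_interfaces(probe_honeycomb(prot, segment_residues(prot, "h3")))
  expect_identical(hc3$shell$surface, "3a")
  expect_identical(hc3$shell$type, 3L)
  hc2 <- classify_interfaces(probe_honeycomb(prot,
                                             segment_residues(prot, "loop_h5h6")))
  expect_identical(hc2$shell$type, 2L)
  hc1 <- classify_interfaces(probe_honeycomb(prot,
                                             segment_residues(prot, c("h1", "h2"))))
  expect_identical(hc1$shell$type, 1L)
  expect_identical(hc1$shell$type_label, "1a:1b")
  expect_true(all(c("type", "side", "ambiguous", "residue_pairs") %in%
                    names(hc1$shell)))
  # residue pairs are recorded for every classified contact
  expect_gt(nrow(hc3$shell$residue_pairs[[1]]), 0)
})

test_that("base-layer count is 5 for the IFI16-preset fixture and survives rigid motion", {
  fx <- ifi16_fixture(n = 24)
  expect_identical(base_layer_count(fx$filament), 5L)
  expect_identical(base_layer_count(fx$filament, end = "top"), 5L)
  fx30 <- ifi16_fixture(n = 30)
  expect_identical(base_layer_count(fx30$filament), 5L)
  set.seed(9)
  moved <- transform_filament(fx$filament, random_rigid_transform())
  expect_identical(base_layer_count(moved), 5L)
  short <- build_filament(toy_prot(), helical_params(134.6, 5.6), 6)
  expect_error(base_layer_count(short), class = "helicomb_error_precondition")
})

test_that("base-layer count matches a brute-force azimuth cover on a cn = 3 lattice", {
  # wide-protomer C3 lattice: 3 subunits per ring, rings every 14 A
  prot <- toy_prot()
  f <- build_filament(prot, helical_params(25, 14, cn = 3), 21)
  got <- base_layer_count(f)
  # oracle: minimal subset of slab protomers whose padded azimuth intervals
  # cover the circle, found by direct enumeration on a 0.5-degree grid
  s <- vapply(f$protomers, function(p) {
    mean(helicomb:::axial_coord(f, cbind(tidy(p)$x, tidy(p)$y, tidy(p)$z)))
  }, 0)
  thick <- median(vapply(f$protomers, function(p) {
    diff(range(helicomb:::axial_coord(f, cbind(tidy(p)$x, tidy(p)$y, tidy(p)$z))))
  }, 0))
  cand <- which(s <= min(s) + thick)
  grid <- seq(0.25, 360, by = 0.5)
  covers <- lapply(cand, function(k) {
    at <- f$protomers[[k]]$atoms
    xyz <- cbind(at$x, at$y, at$z)[at$is_heavy, ]
    az <- helicomb:::azimuth_deg(f, xyz)
    rad <- helicomb:::radial_coord(f, xyz)
    w <- asin(pmin(1, 1.7 / pmax(rad, 1.7))) * 180 / pi
    sapply(grid, function(g) {
      any(pmin(abs(g - az), 360 - abs(g - az)) <= w)
    })
  })
  oracle <- NA
  for (k in seq_along(cand)) {
    for (sub in utils::combn(seq_along(cand), k, simplify = FALSE)) {
      if (all(Reduce(`|`, covers[sub]))) {
        oracle <- k
        break
      }
    }
    if (!is.na(oracle)) break
  }
  expect_identical(got, as.integer(oracle))
})

test_that("rim diameters: analytic ring, rigid-motion invariance, linear scaling", {
  # a ring of point atoms at radius r has outer = inner = 2r
  r <- 17
  ang <- seq(0, 350, by = 10)
  at <- atom_table("C", "CA", seq_along(ang), "ALA", "A",
                   x = r * cos(ang * pi / 180), y = r * sin(ang * pi / 180),
                   z = 0)
  ring_prots <- lapply(0:5, function(k) {
    transform_protomer(protomer(at), rigid_transform(diag(3), c(0, 0, 4 * k)))
  })
  ring <- filament(ring_prots)
  d <- rim_diameters(ring)
  expect_equal(d$outer_A, 2 * r)
  expect_equal(d$inner_A, 2 * r)

  fx <- ifi16_fixture(n = 24)
  d0 <- rim_diameters(fx$filament)
  set.seed(11)
  moved <- transform_filament(fx$filament, random_rigid_transform())
  expect_equal(rim_diameters(moved), d0, tolerance = 1e-6)
  # uniform coordinate scaling scales both diameters linearly
  scaled <- fx$filament
  scaled$protomers <- lapply(scaled$protomers, function(p) {
    p$atoms$x <- 2 * p$atoms$x
    p$atoms$y <- 2 * p$atoms$y
    p$atoms$z <- 2 * p$atoms$z
    p
  })
  d2 <- rim_diameters(scaled)
  expect_equal(d2$outer_A / d0$outer_A, 2, tolerance = 0.02)
  expect_equal(d2$inner_A / d0$inner_A, 2, tolerance = 0.05)
})

test_that("residue annotation maps interface residues and leaves buried ones empty", {
  fx <- ifi16_fixture(n = 24)
  f <- fx$filament
  hc <- extract_honeycomb(f, 12)
  iface_res <- sort(unique(unlist(lapply(hc$shell$residue_pairs,
                                         function(p) p$resno_a))))
  buried <- setdiff(protomer_residues(f$protomers[[1]]), iface_res)
  ann <- annotate_residues(f, c(iface_res[1], buried[1]), center = 12)
  expect_gt(ann$n_interfaces[1], 0)
  expect_identical(ann$n_interfaces[2], 0L)
  expect_error(annotate_residues(f, 9999), class = "helicomb_error_lookup")
})
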