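test_that("residue correspondence: identity for same sequence, NW alignment otherwise", {
  a <- toy_prot()
  m <- residue_mapping(a, a)
  expect_identical(m$resno_a, m$resno_b)
  b <- toy_prot(seed = 9)
  m2 <- residue_mapping(a, b)
  expect_gt(nrow(m2), 30)
  expect_true(all(diff(m2$resno_a) > 0))
  expect_true(all(diff(m2$resno_b) > 0))
})

test_that("self-alignment is exact and trimming converges deterministically", {
  a <- toy_prot()
  al <- align_monomers(a, a)
  expect_lt(al$rmsd, 1e-9)
  # perturb a minority of residues strongly: trimming recovers the core
  b <- a
  set.seed(3)
  idx <- sample(nrow(b$atoms), 8)
  b$atoms$x[idx] <- b$atoms$x[idx] + 9
  al_full <- align_monomers(a, b)
  al_trim <- align_monomers(a, b, trim = TRUE)
  expect_lt(al_trim$rmsd, al_full$rmsd)
  expect_lt(al_trim$retained_fraction, 1)
  expect_gte(al_trim$n_used, 30)
  again <- align_monomers(a, b, trim = TRUE)
  expect_identical(al_trim$n_used, again$n_used)
  expect_equal(al_trim$rmsd, again$rmsd, tolerance = 1e-12)
  # too-small mappings are rejected
  m <- residue_mapping(a, a)[1:10, ]
  expect_error(align_monomers(a, a, mapping = m),
               class = "helicomb_error_correspondence")
})

test_that("threading onto a honeycomb is rigid and exact for the native center", {
  fx <- ifi16_fixture(n = 16)
  hc <- extract_honeycomb(fx$filament, 8)
  thr <- thread_monomer(toy_prot(), hc)
  expect_lt(max(abs(as.matrix(tidy(thr)[, c("x", "y", "z")]) -
                      as.matrix(tidy(hc$center)[, c("x", "y", "z")]))), 1e-9)
  # internal geometry untouched (rigid threading)
  expect_equal(as.numeric(dist(tidy(thr)[, c("x", "y", "z")])),
               as.numeric(dist(tidy(toy_prot())[, c("x", "y", "z")])),
               tolerance = 1e-9)
  # insufficient correspondence coverage
  m <- residue_mapping(toy_prot(), hc$center)
  expect_error(thread_monomer(toy_prot(), hc, mapping = m[1:20, ]),
               class = "helicomb_error_correspondence")
  expect_error(thread_monomer(toy_prot(), hc, mapping = m[0, ]),
               class = "helicomb_error_correspondence")
})

test_that("the native center re-scored in its own shell has zero clashes everywhere", {
  fx <- ifi16_fixture(n = 16)
  hc <- extract_honeycomb(fx$filament, 8)
  rep <- score_shell(thread_monomer(toy_prot(), hc), hc)
  expect_identical(rep$total_clashes, 0L)
  expect_true(all(rep$per_interface$clash_count == 0))
  expect_lt(rep$total, 0)  # native packing is net favorable
})

test_that("half sums partition the total exactly and the report tidies", {
  fx <- ifi16_fixture(n = 16)
  hc <- extract_honeycomb(fx$filament, 8)
  for (src in c("template", "threaded")) {
    rep <- score_shell(toy_prot(seed = 9), hc, shell_source = src)
    expect_identical(rep$half_sums[["top"]] + rep$half_sums[["bottom"]],
                     rep$total)
    expect_identical(sum(rep$per_interface$score), rep$total)
    expect_true(all(rep$per_interface$clash_count >= 0))
    expect_identical(nrow(tidy(rep)), 6L)
    expect_identical(nrow(glance(rep)), 1L)
  }
})

test_that("scores are invariant to a global rigid motion of template and monomer", {
  fx <- ifi16_fixture(n = 16)
  f <- fx$filament
  hc <- extract_honeycomb(f, 8)
  rep0 <- score_shell(hc$center, hc)
  set.seed(21)
  tf <- random_rigid_transform()
  f2 <- transform_filament(f, tf)
  hc2 <- extract_honeycomb(f2, 8)
  rep2 <- score_shell(hc2$center, hc2)
  expect_equal(rep2$per_interface$score, rep0$per_interface$score)
  expect_equal(rep2$total, rep0$total)
})

test_that("clash count grows monotonically through the lattice-mismatch onset window", {
  p <- make_toy_protomer(toy_protomer_spec(pseudo_atoms_per_helix = 25))
  counts <- vapply(c(0, 10, 15, 20), function(dt) {
    hcB <- model_honeycomb(p, helical_params(134.6 + dt, 5.6))
    score_shell(p, hcB, shell_source = "template")$total_clashes
  }, 0L)
  expect_true(all(diff(counts) > 0))
})

test_that("center-subunit swap prefers the native adapter", {
  fx <- ifi16_fixture(n = 16)
  hc <- extract_honeycomb(fx$filament, 8)
  native <- swap_center_analysis(toy_prot(), hc)
  foreign <- swap_center_analysis(toy_prot(seed = 9), hc)
  expect_lte(native$total, foreign$total)
  expect_identical(native$total_clashes, 0L)
})

test_that("honeycomb self-comparison reports zero displacement at every position", {
  fx <- ifi16_fixture(n = 16)
  hc <- extract_honeycomb(fx$filament, 8)
  cmp <- compare_honeycombs(hc, hc)
  expect_identical(nrow(cmp), 6L)
  expect_true(all(cmp$matched))
  expect_lt(max(cmp$displacement_A), 1e-6)
  expect_lt(max(cmp$rotation_deg), 1e-3)
  # a mismatched-architecture honeycomb deviates at some position
  hcB <- model_honeycomb(toy_prot(), helical_params(120, 8),
                         offsets = c(-5, -3, -2, 2, 3, 5))
  cmpB <- compare_honeycombs(hc, hcB)
  expect_gt(max(cmpB$displacement_A, na.rm = TRUE), 5)
})
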