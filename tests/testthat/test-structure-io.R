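test_that("PDB write -> read round-trips atoms, names, numbering and coordinates", {
  fx <- ifi16_fixture(n = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fx$filament, path)
  chains <- read_structure(path)
  expect_length(chains, 6)
  for (k in c(1, 4)) {
    a <- chains[[k]]$atoms
    b <- fx$filament$protomers[[k]]$atoms
    expect_identical(nrow(a), nrow(b))
    expect_identical(a$name, b$name)
    expect_identical(a$resno, b$resno)
    expect_identical(a$resname, b$resname)
    # PDB fixed-width coordinates carry 3 decimals
    expect_lt(max(abs(a$x - b$x)), 1e-3 + 1e-9)
    expect_lt(max(abs(a$z - b$z)), 1e-3 + 1e-9)
  }
  # second round trip is exact (idempotence after quantization)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(chains, path2)
  again <- read_structure(path2)
  expect_equal(again[[2]]$atoms$x, chains[[2]]$atoms$x, tolerance = 1e-9)
})

test_that("single-chain files, waters-only files and missing files behave", {
  prot <- toy_prot()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(prot, path)
  chains <- read_structure(path)
  expect_length(chains, 1)
  expect_identical(nrow(chains[[1]]$atoms), nrow(prot$atoms))

  waters <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), waters)
  expect_error(read_structure(waters), class = "helicomb_error_empty_input")
  expect_error(read_structure("no/such/file.pdb"), class = "helicomb_error_io")
})

test_that("hydrogens are kept but flagged as non-heavy", {
  at <- atom_table(element = c("N", "C", "H"), name = c("N", "CA", "H"),
                   resno = c(1, 1, 1), resname = "GLY",
                   x = c(0, 1.5, -0.5), y = 0, z = 0)
  expect_identical(at$is_heavy, c(TRUE, TRUE, FALSE))
  p <- protomer(at)
  expect_identical(sum(p$atoms$is_heavy), 2L)
})

test_that("order_protomers recovers the generating order up to shift and reflection", {
  fx <- ifi16_fixture(n = 12)
  labels_in_order <- vapply(fx$filament$protomers, function(p) p$label, "")
  for (s in 1:5) {
    set.seed(s)
    shuffled <- sample(fx$filament$protomers)
    f2 <- order_protomers(shuffled)
    got <- vapply(f2$protomers, function(p) p$label, "")
    expect_true(identical(got, labels_in_order) ||
                  identical(got, rev(labels_in_order)))
    est <- estimate_params(f2)
    expect_equal(est$twist_deg, 134.6, tolerance = 1e-6)
    expect_equal(est$rise_A, 5.6, tolerance = 1e-6)
  }
})

test_that("order_protomers rejects short or mismatched chain sets and lines", {
  fx <- ifi16_fixture(n = 12)
  expect_error(order_protomers(fx$filament$protomers[1:2]),
               class = "helicomb_error_precondition")
  other <- make_toy_protomer(toy_protomer_spec(pseudo_atoms_per_helix = 5))
  expect_error(order_protomers(c(fx$filament$protomers[1:3], list(other))),
               class = "helicomb_error_composition")
  # collinear centroids: protomers stacked along a line
  prot <- toy_prot()
  stack <- lapply(0:4, function(k) {
    transform_protomer(prot, rigid_transform(diag(3), c(0, 0, 30 * k)))
  })
  expect_error(order_protomers(stack),
               class = "helicomb_error_degenerate_geometry")
})

test_that("segment annotations load from the packaged config and validate", {
  ss <- ss_segment_table("IFI16")
  expect_true(all(c("h1", "h3", "loop_h5h6", "h6") %in% ss$segment))
  expect_true(all(ss$start <= ss$end))
  # the short helix 3 of the pyrin fold and the proline-shifted h5/h6 loop
  expect_lte(diff(unlist(ss[ss$segment == "h3", c("start", "end")])), 6)
  expect_true(73 >= ss$start[ss$segment == "loop_h5h6"] &&
                73 <= ss$end[ss$segment == "loop_h5h6"])
  expect_error(ss_segment_table("NOPE"), class = "helicomb_error_lookup")
  # segments outside the residue span are rejected at construction
  expect_error(protomer(toy_prot()$atoms,
                        ss_segments = tibble::tibble(segment = "h1",
                                                     start = 1, end = 999)),
               class = "helicomb_error_segments")
})
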