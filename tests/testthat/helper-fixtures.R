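# Shared fixtures, memoized so each is built once per test run.
.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- force(expr)
  .fx_cache[[key]]
}

toy_prot <- function(seed = 42L, ...) {
  cached(paste0("prot_", seed, "_", paste(c(...), collapse = "_")),
         make_toy_protomer(toy_protomer_spec(seed = seed, ...)))
}

ifi16_fixture <- function(n = 24, noise = 0, seed = 1L) {
  cached(sprintf("fx_%d_%g_%d", n, noise, seed),
         make_filament_fixture(n = n, noise_sigma = noise, seed = seed))
}

# Independent O(N^2) contact-graph oracle: plain double loop over protomer
# pairs and full distance matrices.
brute_contact_graph <- function(f, cutoff = 4.5) {
  n <- length(f$protomers)
  rows <- list()
  xyz <- lapply(f$protomers, function(p) {
    a <- p$atoms[p$atoms$is_heavy, ]
    cbind(a$x, a$y, a$z)
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      A <- xyz[[i]]
      B <- xyz[[j]]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      hits <- d2 < cutoff^2
      if (any(hits)) {
        rows[[length(rows) + 1]] <- data.frame(
          i = i, j = j, offset = j - i, n_contacts = sum(hits),
          min_dist = sqrt(max(0, min(d2))))
      }
    }
  }
  do.call(rbind, rows)
}

# Build a one-contact honeycomb whose single shell member is a probe atom
# placed near the given residues of the center; used to unit-test the
# interface-typing rule with a known dominant segment.
probe_honeycomb <- function(center, target_res, half = "top") {
  at <- tidy(center)
  sel <- at[at$resno %in% target_res, ]
  cen <- colMeans(cbind(sel$x, sel$y, sel$z))
  probe <- protomer(atom_table("C", "CA", 1, "ALA", "B",
                               cen[1] + 2.5, cen[2], cen[3]),
                    label = "probe")
  structure(list(center_index = 1L, center = center,
                 shell = tibble::tibble(partner = 2L, offset = 3L,
                                        half = half, n_contacts = NA_integer_,
                                        min_dist = NA_real_,
                                        structure = list(probe)),
                 axis_origin = c(0, 0, 0), axis_direction = c(0, 0, 1),
                 cutoff = 4.5),
            class = "honeycomb")
}

random_rigid_transform <- function() {
  ax <- rnorm(3)
  rigid_transform(rotation_about_axis(ax, runif(1, 10, 350)),
                  rnorm(3, sd = 25))
}
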