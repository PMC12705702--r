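# Run code under a fixed RNG seed without disturbing the session RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a coarse-grained toy protomer
#'
#' Describes a pseudo-atomic stand-in for a death-fold domain: a bundle of
#' six short pseudo-helices (one C-alpha-like pseudo-atom per residue, ideal
#' helical trace) connected by two-residue loops, anisotropically scaled to
#' `bundle_dimensions` and placed with its centroid at `centroid_radius`
#' from the filament axis. A small seeded jitter breaks the bundle's internal
#' symmetry so rigid-body superpositions are uniquely determined.
#'
#' The defaults are calibrated so that filaments built with the IFI16
#' pyrin-domain lattice preset have interior contact degree 6 (the canonical
#' death-fold honeycomb shell) with no native steric clashes.
#'
#' @param n_pseudo_helices Number of pseudo-helices (default 6, the
#'   death-fold bundle).
#' @param pseudo_atoms_per_helix Residues per pseudo-helix.
#' @param bundle_dimensions Length-3 extents in Angstrom.
#' @param centroid_radius Radial placement of the protomer centroid
#'   (Angstrom).
#' @param jitter_A Seeded coordinate jitter (Angstrom).
#' @param seed Integer seed making the protomer deterministic.
#' @return A list of class `toy_protomer_spec`.
#' @export
toy_protomer_spec <- function(n_pseudo_helices = 6L,
                              pseudo_atoms_per_helix = 9L,
                              bundle_dimensions = c(33.2, 25.4, 20.7),
                              centroid_radius = 22.8,
                              jitter_A = 0.25,
                              seed = 42L) {
  stopifnot(n_pseudo_helices >= 2, pseudo_atoms_per_helix >= 3,
            all(bundle_dimensions > 0), centroid_radius >= 0)
  structure(list(n_pseudo_helices = as.integer(n_pseudo_helices),
                 pseudo_atoms_per_helix = as.integer(pseudo_atoms_per_helix),
                 bundle_dimensions = as.numeric(bundle_dimensions),
                 centroid_radius = centroid_radius,
                 jitter_A = jitter_A,
                 seed = as.integer(seed)),
            class = "toy_protomer_spec")
}

#' Generate a coarse-grained toy protomer
#'
#' @param spec A [toy_protomer_spec()].
#' @return A [protomer()] with pseudo-atoms named `"CA"`, a deterministic
#'   pseudo-sequence, and `ss_segments` naming the pseudo-helices
#'   `h1`...`h6` and loops `loop_h1h2`...`loop_h5h6`.
#' @export
make_toy_protomer <- function(spec = toy_protomer_spec()) {
  stopifnot(inherits(spec, "toy_protomer_spec"))
  nh <- spec$n_pseudo_helices
  app <- spec$pseudo_atoms_per_helix
  with_seed(spec$seed, {
    # helix axes at hexagon vertices in the local xy plane, alternating
    # up/down direction as in an antiparallel bundle
    hex_r <- 1
    coords <- list()
    segs <- list()
    resno <- 0L
    helix_trace <- function(n, up) {
      t <- seq_len(n) - 1
      z <- 1.5 * t * if (up) 1 else -1
      cbind(2.3 * cos(100 * t * pi / 180), 2.3 * sin(100 * t * pi / 180), z)
    }
    for (h in seq_len(nh)) {
      ang <- 2 * pi * (h - 1) / nh
      up <- h %% 2 == 1
      tr <- helix_trace(app, up)
      tr[, 1] <- tr[, 1] + 9 * cos(ang)
      tr[, 2] <- tr[, 2] + 9 * sin(ang)
      tr[, 3] <- tr[, 3] - if (up) 1.5 * (app - 1) / 2 else -1.5 * (app - 1) / 2
      segs[[paste0("h", h)]] <- c(resno + 1L, resno + app)
      resno <- resno + app
      coords[[length(coords) + 1]] <- tr
      if (h < nh) {
        # two-residue loop bridging to the next helix
        a <- tr[app, ]
        ang2 <- 2 * pi * h / nh
        up2 <- (h + 1) %% 2 == 1
        nxt <- helix_trace(app, up2)
        nxt[, 1] <- nxt[, 1] + 9 * cos(ang2)
        nxt[, 2] <- nxt[, 2] + 9 * sin(ang2)
        nxt[, 3] <- nxt[, 3] - if (up2) 1.5 * (app - 1) / 2 else -1.5 * (app - 1) / 2
        b <- nxt[1, ]
        loop <- rbind(a + (b - a) / 3, a + 2 * (b - a) / 3)
        segs[[paste0("loop_h", h, "h", h + 1)]] <- c(resno + 1L, resno + 2L)
        resno <- resno + 2L
        coords[[length(coords) + 1]] <- loop
      }
    }
    xyz <- do.call(rbind, coords)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$jitter_A), ncol = 3)
    # anisotropic scale to the requested bundle dimensions
    ext <- apply(xyz, 2, function(v) diff(range(v)))
    xyz <- sweep(xyz, 2, spec$bundle_dimensions / ext, "*")
    xyz <- sweep(xyz, 2, colMeans(xyz))
    # fixed bundle orientation (part of the degree-6 calibration), then
    # radial placement
    R0 <- rotation_about_axis(c(0, 0, 1), 56) %*%
      rotation_about_axis(c(0, 1, 0), 63) %*%
      rotation_about_axis(c(1, 0, 0), 139) %*%
      rotation_about_axis(c(0, 1, 0), 55) %*%
      rotation_about_axis(c(1, 0, 0), 25)
    xyz <- xyz %*% t(R0)
    xyz[, 1] <- xyz[, 1] + spec$centroid_radius
    n_res <- nrow(xyz)
    seq1 <- paste(sample(c("A", "D", "E", "F", "I", "K", "L", "N", "Q", "R",
                           "S", "T", "V", "Y"), n_res, replace = TRUE),
                  collapse = "")
    aa1to3 <- setNames(c("ALA", "ASP", "GLU", "PHE", "ILE", "LYS", "LEU",
                         "ASN", "GLN", "ARG", "SER", "THR", "VAL", "TYR"),
                       c("A", "D", "E", "F", "I", "K", "L", "N", "Q", "R",
                         "S", "T", "V", "Y"))
    resnames <- aa1to3[strsplit(seq1, "")[[1]]]
    atoms <- atom_table(element = "C", name = "CA", resno = seq_len(n_res),
                        resname = resnames, chain = "A",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    ss <- tibble(segment = names(segs),
                 start = vapply(segs, `[`, 0L, 1),
                 end = vapply(segs, `[`, 0L, 2))
    protomer(atoms, label = "toy", sequence = seq1, ss_segments = ss)
  })
}

# Immutable named lattice presets. The IFI16 pyrin-domain preset carries the
# refined symmetry operator of that filament (twist 134.6 deg, rise 5.6 A,
# C1, three-start). Comparator presets are not shipped: they are derived
# from local coordinate files with derive_preset().
.preset_registry <- new.env(parent = emptyenv())

#' Named helical lattice presets
#'
#' @param name Preset name; `"IFI16"` is built in. Presets registered by
#'   [derive_preset()] in the running session are also available.
#' @return A list of class `lattice_preset` with `name`, `params`
#'   (a [helical_params()]) and `provenance` (`"literature"`, `"derived"`,
#'   or `"user"`).
#' @export
lattice_preset <- function(name = "IFI16") {
  if (name == "IFI16") {
    return(structure(list(name = "IFI16",
                          params = helical_params(134.6, 5.6, cn = 1L,
                                                  n_start = 3L),
                          provenance = "literature"),
                     class = "lattice_preset"))
  }
  if (!is.null(.preset_registry[[name]])) return(.preset_registry[[name]])
  abort(sprintf("Unknown lattice preset '%s'.", name),
        class = "helicomb_error_lookup")
}

#' Derive a lattice preset from a deposited coordinate file
#'
#' Reads a multi-chain filament model, orders its chains along the 1-start
#' helix and estimates the helical parameters; the result is registered as a
#' preset with provenance `"derived"` and, optionally, cached to a JSON file
#' with a provenance stamp so later sessions can reload it without the
#' coordinate file.
#'
#' @param path Coordinate file (PDB or mmCIF) of the filament model, or a
#'   JSON cache written by a previous call.
#' @param name Preset name to register.
#' @param cache Optional JSON path to write the derived preset to.
#' @return The `lattice_preset`, invisibly.
#' @export
derive_preset <- function(path, name, cache = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    preset <- structure(list(name = rec$name,
                             params = helical_params(rec$twist_deg,
                                                     rec$rise_A, rec$cn),
                             provenance = "derived"),
                        class = "lattice_preset")
  } else {
    chains <- read_structure(path)
    fil <- order_protomers(chains)
    params <- estimate_params(fil)
    preset <- structure(list(name = name, params = params,
                             provenance = "derived"),
                        class = "lattice_preset")
  }
  .preset_registry[[name]] <- preset
  if (!is.null(cache)) {
    jsonlite::write_json(list(name = preset$name,
                              twist_deg = preset$params$twist_deg,
                              rise_A = preset$params$rise_A,
                              cn = preset$params$cn,
                              provenance = "derived",
                              source = basename(path)),
                         cache, auto_unbox = TRUE, digits = NA)
  }
  invisible(preset)
}

#' Generate an idealized filament fixture with known ground truth
#'
#' Builds a filament from a toy protomer and a lattice preset, optionally
#' perturbs every coordinate with i.i.d. Gaussian noise, and returns the
#' filament together with the exact generating parameters so estimator
#' recovery can be checked.
#'
#' @param preset A [lattice_preset()] (or [helical_params()], wrapped as a
#'   user preset).
#' @param spec A [toy_protomer_spec()].
#' @param n Number of subunits (>= 6; divisible by the preset's cn).
#' @param noise_sigma Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed Seed for the noise (the protomer has its own seed in `spec`).
#' @return A list with `filament` and `truth` (`params`, `axis_origin`,
#'   `axis_direction`, `spec`, `n`, `noise_sigma`, `seed`).
#' @export
make_filament_fixture <- function(preset = lattice_preset("IFI16"),
                                  spec = toy_protomer_spec(),
                                  n = 24, noise_sigma = 0, seed = 1L) {
  if (inherits(preset, "helical_params")) {
    preset <- structure(list(name = "user", params = preset,
                             provenance = "user"),
                        class = "lattice_preset")
  }
  stopifnot(inherits(preset, "lattice_preset"))
  if (n < 6) {
    abort("Fixture filaments need n >= 6 subunits.",
          class = "helicomb_error_precondition")
  }
  prot <- make_toy_protomer(spec)
  fil <- build_filament(prot, preset$params, n)
  if (noise_sigma > 0) {
    fil$protomers <- with_seed(seed, purrr::map(fil$protomers, function(p) {
      xyz <- atom_xyz(p$atoms)
      p$atoms <- set_atom_xyz(
        p$atoms, xyz + matrix(rnorm(length(xyz), sd = noise_sigma), ncol = 3))
      p
    }))
  }
  list(filament = fil,
       truth = list(params = preset$params, axis_origin = fil$axis_origin,
                    axis_direction = fil$axis_direction, spec = spec,
                    n = n, noise_sigma = noise_sigma, seed = seed))
}
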