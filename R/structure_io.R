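#' Read a coordinate file into protomers
#'
#' Reads a PDB v3.3 or PDBx/mmCIF coordinate file and returns one [protomer()]
#' per polymer (protein) chain. Hydrogens are retained but flagged
#' (`is_heavy = FALSE`); waters and ligands are dropped; alternate locations
#' are resolved to the highest-occupancy conformer; author residue numbering
#' is kept and insertion codes are preserved in the residue ordering.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param ss_segments Optional segment table applied to every chain (see
#'   [protomer()]), e.g. from [ss_segment_table()].
#' @return A list of [protomer()] objects, one per polymer chain.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           ss_segments = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "helicomb_error_io")
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) {
      abort(sprintf("Could not parse %s as %s: %s", path, format,
                    conditionMessage(e)),
            class = "helicomb_error_format")
    })
  at <- as_tibble(parsed$atom)
  aa3 <- names(bio3d::aa.table$aa1)
  at <- at[at$resid %in% bio3d::aa.table$aa3 |
             toupper(at$resid) %in% c("MSE"), , drop = FALSE]
  if (nrow(at) == 0) {
    abort("No polymer (protein) chains in file.",
          class = "helicomb_error_empty_input")
  }
  # resolve altloc to highest occupancy, keeping the first on ties
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    at$o[is.na(at$o)] <- 1
    at <- at |>
      group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
      arrange(dplyr::desc(.data$o), .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  }
  at$insert[is.na(at$insert)] <- ""
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem))) {
    elem <- substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  }
  elem[is.na(elem) | elem == ""] <-
    substr(at$elety[is.na(elem) | elem == ""], 1, 1)
  atoms <- atom_table(element = elem, name = at$elety, resno = at$resno,
                      resname = at$resid, chain = at$chain,
                      x = at$x, y = at$y, z = at$z)
  # fold insertion codes into ordering while keeping author numbers
  ins_rank <- match(at$insert, c("", LETTERS))
  ord <- order(atoms$chain, atoms$resno, ins_rank)
  atoms <- atoms[ord, , drop = FALSE]
  split(atoms, atoms$chain) |>
    purrr::imap(function(a, ch) protomer(a, label = ch,
                                         ss_segments = ss_segments)) |>
    unname()
}

#' Write protomers or a filament to a PDB file
#'
#' Chains are written in order; filament subunits beyond the 26 one-letter
#' chain ids reuse ids cyclically with distinct segment numbering via resno
#' untouched (chain id collisions only matter for files with > 62 chains).
#'
#' @param x A [protomer()], list of protomers, or [filament()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  prots <- if (inherits(x, "protomer")) list(x)
  else if (inherits(x, "filament")) x$protomers
  else x
  ids <- c(LETTERS, letters, 0:9)
  all_atoms <- purrr::imap(prots, function(p, i) {
    a <- p$atoms
    a$chain <- ids[((i - 1) %% length(ids)) + 1]
    a
  }) |> bind_rows()
  n <- nrow(all_atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(atom_xyz(all_atoms))),
    resno = all_atoms$resno,
    resid = all_atoms$resname,
    eleno = seq_len(n),
    elety = all_atoms$name,
    chain = all_atoms$chain,
    elesy = all_atoms$element)
  invisible(path)
}

#' Filament assemblies
#'
#' A filament is an ordered list of protomers indexed along the 1-start
#' helix, together with the filament axis (origin + unit direction) as the
#' reference frame and, when known, the helical parameters.
#'
#' @param protomers List of [protomer()] objects in 1-start order.
#' @param axis_origin,axis_direction Filament axis; the direction is
#'   normalized and chosen so the rise from index k to k+1 is positive.
#' @param params Optional [helical_params()].
#' @return An object of class `filament`.
#' @export
filament <- function(protomers, axis_origin = c(0, 0, 0),
                     axis_direction = c(0, 0, 1), params = NULL) {
  stopifnot(length(protomers) >= 2,
            all(vapply(protomers, inherits, TRUE, "protomer")))
  keys <- vapply(protomers, residue_composition_key, "")
  if (length(unique(keys)) != 1) {
    abort("All protomers must share an identical residue composition.",
          class = "helicomb_error_composition")
  }
  d <- axis_direction / sqrt(sum(axis_direction^2))
  structure(list(protomers = protomers, axis_origin = as.numeric(axis_origin),
                 axis_direction = d, params = params),
            class = "filament")
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf("<filament> %d protomers, axis [%.2f %.2f %.2f]\n",
              length(x$protomers), x$axis_direction[1], x$axis_direction[2],
              x$axis_direction[3]))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' @rdname filament
#' @param x A `filament`.
#' @param ... Unused.
#' @return For `tidy.filament`: a tibble with one row per protomer giving its
#'   index, label, centroid, axial coordinate and radius in the filament frame.
#' @export
tidy.filament <- function(x, ...) {
  cen <- t(vapply(x$protomers, protomer_centroid, numeric(3)))
  rel <- sweep(cen, 2, x$axis_origin)
  s <- as.numeric(rel %*% x$axis_direction)
  rad <- sqrt(rowSums((rel - outer(s, x$axis_direction))^2))
  tibble(index = seq_along(x$protomers),
         label = vapply(x$protomers, function(p) p$label, ""),
         x = cen[, 1], y = cen[, 2], z = cen[, 3],
         axial = s, radius = rad)
}

n_protomers <- function(f) length(f$protomers)

filament_centroids <- function(f) {
  t(vapply(f$protomers, protomer_centroid, numeric(3)))
}

axial_coord <- function(f, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
  as.numeric(sweep(xyz, 2, f$axis_origin) %*% f$axis_direction)
}

radial_coord <- function(f, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
  rel <- sweep(xyz, 2, f$axis_origin)
  s <- as.numeric(rel %*% f$axis_direction)
  sqrt(pmax(0, rowSums(rel^2) - s^2))
}

azimuth_deg <- function(f, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, 1, 3)
  b <- axis_basis(f$axis_direction)
  rel <- sweep(xyz, 2, f$axis_origin)
  (atan2(rel %*% b$e2, rel %*% b$e1) * 180 / pi) %% 360
}

axis_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Fit the filament axis from protomer centroids
#'
#' The axis is the line minimizing the variance of the centroid radial
#' distances (principal axis of the centroid cloud, refined by cylindrical
#' least squares); its origin is the mean centroid projected onto the line.
#'
#' @param centroids n x 3 matrix of protomer centroids (n >= 3).
#' @return List with `origin`, `direction` (unit), and `radius_spread`
#'   (standard deviation of centroid radii about the fitted axis).
#' @export
fit_filament_axis <- function(centroids) {
  C <- as.matrix(centroids)
  stopifnot(ncol(C) == 3)
  if (nrow(C) < 3) {
    abort("Need at least 3 centroids to fit an axis.",
          class = "helicomb_error_precondition")
  }
  m <- colMeans(C)
  Cc <- sweep(C, 2, m)
  pc <- svd(Cc)$v[, 1]
  radii_about <- function(d, o) {
    rel <- sweep(C, 2, o)
    s <- as.numeric(rel %*% d)
    sqrt(pmax(0, rowSums(rel^2) - s^2))
  }
  obj <- function(par) {
    d <- sph_dir(par[1], par[2])
    b <- axis_basis(d)
    o <- m + par[3] * b$e1 + par[4] * b$e2
    var(radii_about(d, o))
  }
  init <- dir_to_sph(pc)
  fit <- optim(c(init, 0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  d <- sph_dir(fit$par[1], fit$par[2])
  b <- axis_basis(d)
  o <- m + fit$par[3] * b$e1 + fit$par[4] * b$e2
  r <- radii_about(d, o)
  if (median(r) < 1e-3) {
    abort("Centroids are collinear with the axis; no helical arrangement.",
          class = "helicomb_error_degenerate_geometry")
  }
  o <- o + sum((m - o) * d) * d  # put origin at the mean centroid's level
  list(origin = o, direction = d, radius_spread = sd(r))
}

sph_dir <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

dir_to_sph <- function(d) {
  d <- d / sqrt(sum(d^2))
  c(acos(pmin(1, pmax(-1, d[3]))), atan2(d[2], d[1]))
}

#' Order chains into a filament along the 1-start helix
#'
#' Fits the filament axis to the chain centroids, then indexes the chains so
#' that consecutive indices are related by the smallest consistent screw
#' displacement: chains are sorted by axial coordinate (ties, as in lattices
#' with axial point-group symmetry, broken by azimuth). The axis direction is
#' chosen so the rise from index k to k+1 is positive; positive twist then
#' means a right-handed screw.
#'
#' @param chains List of [protomer()] objects (>= 3) with identical residue
#'   composition, in any order.
#' @return A [filament()] with ordered protomers and fitted axis.
#' @export
order_protomers <- function(chains) {
  if (length(chains) < 3) {
    abort("Need at least 3 chains to order a filament.",
          class = "helicomb_error_precondition")
  }
  keys <- vapply(chains, residue_composition_key, "")
  if (length(unique(keys)) != 1) {
    abort("Chains have mismatched residue composition.",
          class = "helicomb_error_composition")
  }
  cen <- t(vapply(chains, protomer_centroid, numeric(3)))
  ax <- fit_filament_axis(cen)
  f0 <- structure(list(axis_origin = ax$origin, axis_direction = ax$direction),
                  class = "filament")
  s <- axial_coord(f0, cen)
  az <- azimuth_deg(f0, cen)
  ord <- order(round(s, 3), az)
  filament(chains[ord], axis_origin = ax$origin, axis_direction = ax$direction)
}

#' Packaged secondary-structure segment annotations
#'
#' Loads the editable per-protein segment table shipped with the package
#' (or a user-supplied JSON with the same shape) and returns the segment
#' ranges for one protein as a tibble usable by [protomer()].
#'
#' @param protein Entry name, e.g. `"IFI16"`.
#' @param path Optional path to a custom annotation JSON.
#' @return A tibble with columns `segment`, `start`, `end`.
#' @export
ss_segment_table <- function(protein = "IFI16", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ss_segments.json", package = "helicomb")
  }
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tab[names(tab) != "_comment"]
  if (!protein %in% names(tab)) {
    abort(sprintf("No segment annotation for '%s'.", protein),
          class = "helicomb_error_lookup")
  }
  entry <- tab[[protein]]
  tibble(segment = names(entry),
         start = vapply(entry, function(v) as.integer(v[1]), 0L),
         end = vapply(entry, function(v) as.integer(v[2]), 0L))
}
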