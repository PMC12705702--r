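#' Transform a whole filament rigidly
#'
#' Applies a rigid transform to every protomer and to the stored axis, so
#' that frame-dependent measurements (base-layer count, rim diameters) are
#' invariant to the motion.
#'
#' @param f A [filament()].
#' @param tf A [rigid_transform()].
#' @return The transformed filament.
#' @export
transform_filament <- function(f, tf) {
  f$protomers <- purrr::map(f$protomers, transform_protomer, tf = tf)
  f$axis_origin <- apply_transform(tf, f$axis_origin)
  f$axis_direction <- as.numeric(tf$rotation %*% f$axis_direction)
  f
}

# All heavy atoms of the filament with their protomer index.
filament_heavy_atoms <- function(f) {
  purrr::imap(f$protomers, function(p, i) {
    a <- p$atoms[p$atoms$is_heavy, c("resno", "name", "x", "y", "z")]
    a$protomer <- i
    a
  }) |> bind_rows()
}

# Spatial-hash neighbor search: all atom pairs within `cutoff`, cell grid of
# edge `cutoff` so only the 27 surrounding cells need scanning (13 offsets +
# the in-cell half to visit each unordered pair once).
hashed_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  cx <- floor(xyz[, 1] / cutoff)
  cy <- floor(xyz[, 2] / cutoff)
  cz <- floor(xyz[, 3] / cutoff)
  cx <- cx - min(cx); cy <- cy - min(cy); cz <- cz - min(cz)
  nx <- max(cx) + 2L
  ny <- max(cy) + 2L
  key <- cx + nx * (cy + ny * cz)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs$code <- offs$dx + nx * (offs$dy + ny * offs$dz)
  offs <- offs[offs$code > 0, , drop = FALSE]  # half the neighbors + exclude self cell
  A <- tibble(key = key, id = seq_len(n))
  res <- vector("list", nrow(offs) + 1)
  # in-cell pairs
  incell <- A |> group_by(.data$key) |> filter(n() > 1) |> ungroup()
  if (nrow(incell) > 0) {
    res[[1]] <- incell |>
      group_by(.data$key) |>
      summarise(pair = list({
        p <- combn(.data$id, 2)
        tibble(id1 = p[1, ], id2 = p[2, ])
      }), .groups = "drop") |>
      tidyr::unnest("pair") |>
      select("id1", "id2")
  }
  for (k in seq_len(nrow(offs))) {
    B <- tibble(key = key - offs$code[k], id2 = seq_len(n))
    res[[k + 1]] <- inner_join(A, B, by = "key",
                               relationship = "many-to-many") |>
      select(id1 = "id", "id2")
  }
  pairs <- bind_rows(res)
  if (nrow(pairs) == 0) return(tibble(id1 = integer(), id2 = integer(),
                                      dist = numeric()))
  d2 <- (xyz[pairs$id1, 1] - xyz[pairs$id2, 1])^2 +
    (xyz[pairs$id1, 2] - xyz[pairs$id2, 2])^2 +
    (xyz[pairs$id1, 3] - xyz[pairs$id2, 3])^2
  keep <- d2 < cutoff^2
  tibble(id1 = pairs$id1[keep], id2 = pairs$id2[keep],
         dist = sqrt(d2[keep]))
}

#' Contact graph of a filament
#'
#' An edge joins protomers i and j when at least one heavy-atom pair lies
#' within `cutoff`; the heavy-atom contact count and minimum interatomic
#' distance are recorded per edge. Atom pairs are found with a spatial hash
#' (cell grid of edge `cutoff`), so the cost is near-linear in the number of
#' atoms.
#'
#' @param f A [filament()] with >= 2 protomers.
#' @param cutoff Heavy-atom contact cutoff in Angstrom (default 4.5, the
#'   standard interface-contact convention).
#' @return A tibble of class `contact_graph` with columns `i`, `j` (i < j),
#'   `offset` (j - i), `n_contacts`, `min_dist`.
#' @export
contact_graph <- function(f, cutoff = 4.5) {
  stopifnot(inherits(f, "filament"))
  if (n_protomers(f) < 2) {
    abort("Need >= 2 protomers.", class = "helicomb_error_precondition")
  }
  at <- filament_heavy_atoms(f)
  pr <- hashed_pairs(cbind(at$x, at$y, at$z), cutoff)
  pi_ <- at$protomer[pr$id1]
  pj_ <- at$protomer[pr$id2]
  keep <- pi_ != pj_
  if (!any(keep)) {
    edges <- tibble(i = integer(), j = integer(), offset = integer(),
                    n_contacts = integer(), min_dist = numeric())
    class(edges) <- c("contact_graph", class(edges))
    attr(edges, "cutoff") <- cutoff
    attr(edges, "n_protomers") <- n_protomers(f)
    return(edges)
  }
  edges <- tibble(i = pmin(pi_[keep], pj_[keep]),
                  j = pmax(pi_[keep], pj_[keep]),
                  dist = pr$dist[keep]) |>
    group_by(.data$i, .data$j) |>
    summarise(n_contacts = n(), min_dist = min(.data$dist),
              .groups = "drop") |>
    mutate(offset = .data$j - .data$i) |>
    select("i", "j", "offset", "n_contacts", "min_dist") |>
    arrange(.data$i, .data$j)
  class(edges) <- c("contact_graph", class(edges))
  attr(edges, "cutoff") <- cutoff
  attr(edges, "n_protomers") <- n_protomers(f)
  edges
}

# Brute-force O(N^2) heavy-atom pairs between two protomers.
contact_pairs <- function(pa, pb, cutoff = 4.5) {
  a <- pa$atoms[pa$atoms$is_heavy, , drop = FALSE]
  b <- pb$atoms[pb$atoms$is_heavy, , drop = FALSE]
  A <- atom_xyz(a)
  B <- atom_xyz(b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  tibble(resno_a = a$resno[hit[, 1]], name_a = a$name[hit[, 1]],
         resno_b = b$resno[hit[, 2]], name_b = b$name[hit[, 2]],
         dist = sqrt(pmax(0, d2[hit])))
}

# Offsets |o| that occur for essentially every eligible subunit pair are the
# lattice's canonical neighbor offsets.
canonical_offsets <- function(edges, n) {
  tab <- edges |> group_by(.data$offset) |> summarise(cnt = n())
  tab$eligible <- n - tab$offset
  sort(tab$offset[tab$cnt >= 0.8 * tab$eligible])
}

#' Extract the honeycomb neighborhood of a protomer
#'
#' The honeycomb of a center subunit is its full shell of lattice contacts
#' (six for canonical death-fold filaments), each labeled with its signed
#' index offset and axial half (top/bottom by the sign of the partner's
#' axial displacement). Interface types are assigned by
#' [classify_interfaces()].
#'
#' @param f A [filament()].
#' @param center Index of the center protomer; must be interior (all
#'   canonical lattice neighbors present).
#' @param cutoff Heavy-atom contact cutoff (Angstrom).
#' @param classify Assign interface types when the protomer carries
#'   `ss_segments` (default `TRUE`).
#' @return An object of class `honeycomb`: the center protomer plus a shell
#'   tibble (one row per contact) carrying the partner structures.
#' @export
extract_honeycomb <- function(f, center, cutoff = 4.5, classify = TRUE) {
  stopifnot(inherits(f, "filament"))
  n <- n_protomers(f)
  edges <- contact_graph(f, cutoff)
  canon <- canonical_offsets(edges, n)
  canon_signed <- sort(unique(c(canon, -canon)))
  nb <- edges |>
    filter(.data$i == center | .data$j == center) |>
    mutate(partner = ifelse(.data$i == center, .data$j, .data$i))
  missing <- setdiff(canon_signed, nb$partner - center)
  if (length(missing) > 0) {
    abort(sprintf("Center %d is not interior; missing neighbor offsets: %s",
                  center, paste(missing, collapse = ", ")),
          class = "helicomb_error_incomplete_shell")
  }
  cen_s <- axial_coord(f, protomer_centroid(f$protomers[[center]]))
  shell <- nb |>
    mutate(offset = .data$partner - center) |>
    filter(.data$offset %in% canon_signed)
  part_s <- vapply(shell$partner, function(k) {
    axial_coord(f, protomer_centroid(f$protomers[[k]]))
  }, 0)
  shell <- tibble(
    partner = shell$partner,
    offset = shell$offset,
    half = ifelse(part_s > cen_s, "top", "bottom"),
    n_contacts = shell$n_contacts,
    min_dist = shell$min_dist,
    structure = purrr::map(shell$partner, function(k) f$protomers[[k]])) |>
    arrange(.data$half == "bottom", .data$offset)
  hc <- structure(list(center_index = center,
                       center = f$protomers[[center]],
                       shell = shell,
                       axis_origin = f$axis_origin,
                       axis_direction = f$axis_direction,
                       cutoff = cutoff),
                  class = "honeycomb")
  if (classify && !is.null(hc$center$ss_segments)) {
    hc <- classify_interfaces(hc)
  }
  hc
}

#' @export
print.honeycomb <- function(x, ...) {
  cat(sprintf("<honeycomb> center %d with %d shell contacts\n",
              x$center_index, nrow(x$shell)))
  print(tidy(x))
  invisible(x)
}

#' @rdname extract_honeycomb
#' @param x A `honeycomb`.
#' @param ... Unused.
#' @return For `tidy.honeycomb`: the shell table without the structure
#'   list-column.
#' @export
tidy.honeycomb <- function(x, ...) {
  select(x$shell, -dplyr::any_of(c("structure", "residue_pairs")))
}

#' Interface surface definitions
#'
#' Maps each of the six conserved death-fold interface surfaces (Type 1a/1b,
#' 2a/2b, 3a/3b) to the secondary-structure segments of the six-helix bundle
#' that form it: the Type 1 faces are the h1+h2 and h3+h4 faces, Type 2 the
#' h4/h5 corner against the h5-h6 loop, and Type 3 the short helix 3 against
#' the h1-h2 loop.
#'
#' @return Named list of segment-name vectors, one per surface label.
#' @export
interface_surfaces <- function() {
  list(`1a` = c("h1", "h2"),
       `1b` = c("h3", "h4"),
       `2a` = c("h4", "loop_h4h5", "h5"),
       `2b` = c("h5", "loop_h5h6", "h6"),
       `3a` = c("h3"),
       `3b` = c("loop_h1h2"))
}

#' Classify honeycomb contacts into interface types
#'
#' Each shell contact is assigned a Type 1/2/3 label and an 'a'/'b' side by
#' which secondary-structure segments of the center subunit dominate the
#' contact: per surface, the heavy-atom contacts whose center residue lies
#' in the surface's segments are summed and the argmax surface wins. A
#' runner-up surface of a different type within `tie_tol` of the winner
#' flags the contact as ambiguous (never an error); an 'a'/'b' tie within
#' `tie_tol` is resolved to 'a' for the +axis (top) half.
#'
#' @param hc A `honeycomb` whose center protomer carries `ss_segments`.
#' @param surfaces Surface definitions, see [interface_surfaces()].
#' @param tie_tol Relative tie tolerance (default 0.1).
#' @return The honeycomb with `type`, `side`, `type_label`, `ambiguous` and
#'   `residue_pairs` filled in on the shell table.
#' @export
classify_interfaces <- function(hc, surfaces = interface_surfaces(),
                                tie_tol = 0.1) {
  stopifnot(inherits(hc, "honeycomb"))
  if (is.null(hc$center$ss_segments)) {
    abort("Center protomer has no ss_segments annotation.",
          class = "helicomb_error_segments")
  }
  surf_res <- purrr::map(surfaces, segment_residues, p = hc$center)
  n_segs <- lengths(surfaces)
  rows <- purrr::map(seq_len(nrow(hc$shell)), function(k) {
    partner <- hc$shell$structure[[k]]
    pairs <- contact_pairs(hc$center, partner, hc$cutoff)
    scores <- vapply(surf_res, function(res) {
      sum(pairs$resno_a %in% res)
    }, 0)
    # ties broken toward the more specific (fewer-segment) surface, so a
    # contact carried purely by h3 reads Type 3a, not the broader h3+h4 face
    ord <- order(-scores, n_segs)
    best <- names(scores)[ord[1]]
    type <- substr(best, 1, 1)
    side <- substr(best, 2, 2)
    ambiguous <- FALSE
    if (scores[[best]] > 0) {
      for (cand in names(scores)[ord[-1]]) {
        if (substr(cand, 1, 1) == type) next
        overlap <- length(intersect(surfaces[[best]], surfaces[[cand]])) > 0
        if (!overlap &&
            (scores[[best]] - scores[[cand]]) / scores[[best]] < tie_tol) {
          ambiguous <- TRUE
        }
        break
      }
    }
    # a/b tie within the winning type: resolve to 'a' on the top half
    other_side <- paste0(type, setdiff(c("a", "b"), side))
    if (other_side %in% names(scores) && scores[[best]] > 0 &&
        (scores[[best]] - scores[[other_side]]) / scores[[best]] < tie_tol) {
      side <- if (hc$shell$half[k] == "top") "a" else "b"
    }
    tibble(type = as.integer(type), side = side,
           type_label = paste0(type, "a:", type, "b"),
           surface = paste0(type, side),
           ambiguous = ambiguous, residue_pairs = list(pairs))
  }) |> bind_rows()
  hc$shell <- bind_cols(
    select(hc$shell, -dplyr::any_of(c("type", "side", "type_label",
                                      "surface", "ambiguous",
                                      "residue_pairs"))),
    rows)
  hc
}

protomer_axial_extent <- function(f, p) {
  s <- axial_coord(f, atom_xyz(p$atoms, heavy_only = TRUE))
  diff(range(s))
}

# 1-degree azimuthal footprint of a protomer's heavy atoms. Each atom is
# given its van der Waals angular half-width asin(r_vdw / radius) (r_vdw =
# 1.7 A), so the footprint is the surface a caliper would see, not a set of
# zero-width points; this also bridges sparse pseudo-atomic sampling.
azimuth_mask <- function(f, p, r_vdw = 1.7) {
  xyz <- atom_xyz(p$atoms, heavy_only = TRUE)
  az <- azimuth_deg(f, xyz)
  rad <- radial_coord(f, xyz)
  w <- asin(pmin(1, r_vdw / pmax(rad, r_vdw))) * 180 / pi
  mask <- rep(FALSE, 360)
  bins <- 0:359 + 0.5
  for (i in seq_along(az)) {
    lo <- (az[i] - w[i]) %% 360
    hi <- (az[i] + w[i]) %% 360
    mask <- mask | if (lo <= hi) bins >= lo & bins <= hi
    else bins >= lo | bins <= hi
  }
  mask
}

#' Number of protomers forming the filament base layer
#'
#' Counts the protomers whose centroids lie in the terminal axial slab
#' (thickness = the median protomer axial extent) and that together span the
#' full 360 degrees of azimuth; the size of the minimal such set is returned
#' (found by exhaustive search over slab subsets). This is the subunit count
#' of the polygon seen end-on at the filament base: six for canonical
#' inflammasome pyrin-domain filaments, five for the IFI16 pyrin-domain
#' filament.
#'
#' @param f A [filament()] whose axial span is at least three slab
#'   thicknesses.
#' @param end Which end to measure: `"bottom"` (minimal axial coordinate,
#'   default) or `"top"`.
#' @return Integer count.
#' @export
base_layer_count <- function(f, end = c("bottom", "top")) {
  stopifnot(inherits(f, "filament"))
  end <- match.arg(end)
  cen <- filament_centroids(f)
  s <- axial_coord(f, cen)
  thick <- median(vapply(f$protomers, protomer_axial_extent, 0, f = f))
  span <- diff(range(s))
  if (span < 3 * thick) {
    abort(sprintf(
      "Filament too short for a base-layer count: axial span %.1f A < 3 x slab thickness %.1f A.",
      span, thick), class = "helicomb_error_precondition")
  }
  sel <- if (end == "bottom") s <= min(s) + thick else s >= max(s) - thick
  cand <- which(sel)
  masks <- purrr::map(cand, function(k) azimuth_mask(f, f$protomers[[k]]))
  full <- Reduce(`|`, masks)
  if (!all(full)) {
    abort("Terminal slab does not span the full azimuth.",
          class = "helicomb_error_degenerate_geometry")
  }
  if (length(cand) <= 14) {
    for (k in seq_along(cand)) {
      subsets <- combn(seq_along(cand), k, simplify = FALSE)
      for (sub in subsets) {
        if (all(Reduce(`|`, masks[sub]))) return(k)
      }
    }
    return(length(cand))
  }
  # very wide slabs: greedy set cover (exact search is exponential)
  covered <- rep(FALSE, 360)
  left <- seq_along(cand)
  count <- 0
  while (!all(covered) && length(left) > 0) {
    gain <- vapply(left, function(k) sum(masks[[k]] & !covered), 0)
    pick <- left[which.max(gain)]
    covered <- covered | masks[[pick]]
    left <- setdiff(left, pick)
    count <- count + 1
  }
  count
}

#' Outer-rim and inner-cavity diameters
#'
#' The outer diameter is twice the maximum heavy-atom radial distance over
#' interior subunits, and the inner-cavity diameter twice the minimum radial
#' distance (a plain caliper reading of the solvent channel: no probe radius
#' is subtracted). Interior subunits are those at least one slab thickness
#' away from either filament end, to avoid end effects. Both diameters are
#' reported to 1 Angstrom.
#'
#' @param f A [filament()] with a defined axis.
#' @return A tibble with columns `outer_A` and `inner_A`.
#' @export
rim_diameters <- function(f) {
  stopifnot(inherits(f, "filament"))
  cen <- filament_centroids(f)
  s <- axial_coord(f, cen)
  thick <- median(vapply(f$protomers, protomer_axial_extent, 0, f = f))
  interior <- which(s >= min(s) + thick & s <= max(s) - thick)
  if (length(interior) == 0) interior <- seq_along(f$protomers)
  rad <- unlist(purrr::map(interior, function(k) {
    radial_coord(f, atom_xyz(f$protomers[[k]]$atoms, heavy_only = TRUE))
  }))
  tibble(outer_A = round(2 * max(rad)), inner_A = round(2 * min(rad)))
}

#' Map residues to the filament interfaces they participate in
#'
#' For each requested residue, reports the set of interface surfaces of the
#' center subunit (e.g. `"2b"`, `"3a"`) whose contact residue pairs contain
#' it; an empty set means the residue is buried (not interfacial).
#'
#' @param f A [filament()] whose protomers carry `ss_segments`.
#' @param residues Integer author residue numbers present in the protomer.
#' @param center Interior center index; chosen automatically when `NULL`.
#' @param cutoff Heavy-atom contact cutoff (Angstrom).
#' @return A tibble with columns `resno`, `interfaces` (list of surface
#'   labels), `n_interfaces`.
#' @export
annotate_residues <- function(f, residues, center = NULL, cutoff = 4.5) {
  stopifnot(inherits(f, "filament"))
  known <- protomer_residues(f$protomers[[1]])
  bad <- setdiff(residues, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue number(s): %s",
                  paste(bad, collapse = ", ")),
          class = "helicomb_error_lookup")
  }
  if (is.null(center)) center <- pick_interior_center(f, cutoff)
  hc <- extract_honeycomb(f, center, cutoff, classify = TRUE)
  res <- purrr::map(as.integer(residues), function(r) {
    hit <- purrr::map2_lgl(hc$shell$residue_pairs, seq_len(nrow(hc$shell)),
                           function(pr, k) r %in% pr$resno_a)
    tibble(resno = r,
           interfaces = list(sort(unique(hc$shell$surface[hit]))),
           n_interfaces = sum(hit))
  }) |> bind_rows()
  res$n_interfaces <- lengths(res$interfaces)
  res
}

# First center for which the full canonical shell is present.
pick_interior_center <- function(f, cutoff = 4.5) {
  n <- n_protomers(f)
  for (k in order(abs(seq_len(n) - (n + 1) / 2))) {
    ok <- tryCatch({
      extract_honeycomb(f, k, cutoff, classify = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(k)
  }
  abort("No interior protomer with a complete shell.",
        class = "helicomb_error_incomplete_shell")
}

#' Construct an idealized honeycomb from lattice parameters
#'
#' Builds the center-plus-shell neighborhood directly from a protomer and a
#' screw operator: shell member at offset k is the center transformed by the
#' k-th power of the screw (plus ring rotations when `cn > 1` offsets are
#' requested on a Cn lattice). This is the "modeling one domain on another
#' architecture" construction: the interface set is chosen (typically the
#' canonical shell offsets of a reference lattice) and the geometry comes
#' from the parameters under study.
#'
#' @param p A [protomer()] positioned relative to the axis.
#' @param params A [helical_params()].
#' @param offsets Signed shell offsets (default the death-fold shell of the
#'   IFI16-calibrated toy lattice, `c(-5, -3, -2, 2, 3, 5)`).
#' @param axis_origin,axis_direction The lattice axis.
#' @param cutoff Contact cutoff carried into scoring (Angstrom).
#' @return A `honeycomb` (unclassified; pass through [classify_interfaces()]
#'   if the protomer has `ss_segments`).
#' @export
model_honeycomb <- function(p, params, offsets = c(-5, -3, -2, 2, 3, 5),
                            axis_origin = c(0, 0, 0),
                            axis_direction = c(0, 0, 1), cutoff = 4.5) {
  stopifnot(inherits(p, "protomer"), inherits(params, "helical_params"))
  members <- purrr::map(offsets, function(k) {
    transform_protomer(p, screw_from_params(params, axis_origin,
                                            axis_direction, power = k))
  })
  shell <- tibble(partner = NA_integer_, offset = offsets,
                  half = ifelse(offsets > 0, "top", "bottom"),
                  n_contacts = NA_integer_, min_dist = NA_real_,
                  structure = members) |>
    arrange(.data$half == "bottom", .data$offset)
  structure(list(center_index = 0L, center = p, shell = shell,
                 axis_origin = axis_origin,
                 axis_direction = axis_direction / sqrt(sum(axis_direction^2)),
                 cutoff = cutoff),
            class = "honeycomb")
}
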