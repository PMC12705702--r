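#' Helical lattice parameters
#'
#' Describes a filament lattice by its 1-start screw operator: `twist_deg`
#' (degrees of azimuthal rotation per subunit, reported in (0, 360]; values
#' above 180 describe a left-handed screw about the axis direction along
#' which the rise is positive), `rise_A` (Angstrom per subunit), `cn` (axial
#' point-group order; 1 = no rotational symmetry) and `n_start` (descriptive
#' strand count).
#'
#' @param twist_deg Twist per subunit in degrees, 0 < |twist| <= 360.
#' @param rise_A Rise per subunit in Angstrom, > 0.
#' @param cn Axial point-group order (integer >= 1).
#' @param n_start Descriptive strand count (integer >= 1); when `NULL` it is
#'   derived as `cn * round(360 / min(twist, 360 - twist))`, the number of
#'   near-co-level strands.
#' @return An object of class `helical_params`.
#' @examples
#' ifi16 <- helical_params(134.6, 5.6)  # IFI16 pyrin-domain filament operator
#' ifi16
#' @export
helical_params <- function(twist_deg, rise_A, cn = 1L, n_start = NULL) {
  twist_deg <- as.numeric(twist_deg) %% 360
  if (twist_deg == 0) twist_deg <- 360
  if (!is.finite(rise_A) || rise_A <= 0) {
    abort("rise_A must be > 0.", class = "helicomb_error_params")
  }
  cn <- as.integer(cn)
  if (cn < 1) abort("cn must be >= 1.", class = "helicomb_error_params")
  if (is.null(n_start)) {
    t_eff <- min(twist_deg, 360 - twist_deg)
    n_start <- if (t_eff < 1e-9) cn else max(1L, cn * as.integer(round(360 / t_eff)))
  }
  structure(list(twist_deg = twist_deg, rise_A = rise_A, cn = cn,
                 n_start = as.integer(n_start),
                 handedness = if (twist_deg <= 180) "right" else "left"),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "<helical_params> twist %.4g deg (%s-handed), rise %.4g A, C%d, %d-start\n",
    x$twist_deg, x$handedness, x$rise_A, x$cn, x$n_start))
  invisible(x)
}

#' @rdname helical_params
#' @param x A `helical_params`.
#' @param ... Unused.
#' @export
tidy.helical_params <- function(x, ...) {
  tibble(twist_deg = x$twist_deg, rise_A = x$rise_A, cn = x$cn,
         n_start = x$n_start, handedness = x$handedness)
}

#' Screw operator from helical parameters
#'
#' Builds the rigid transform relating subunit k to subunit k+1: rotation by
#' `twist_deg` about the axis composed with translation `rise_A` along it.
#'
#' @param params A [helical_params()].
#' @param axis_origin Point on the axis.
#' @param axis_direction Axis direction (normalized internally; must be
#'   non-zero).
#' @param power Integer: return the `power`-th application of the screw
#'   (rotation by `power * twist`, translation `power * rise`), computed in
#'   closed form.
#' @return A [rigid_transform()].
#' @export
screw_from_params <- function(params, axis_origin = c(0, 0, 0),
                              axis_direction = c(0, 0, 1), power = 1) {
  stopifnot(inherits(params, "helical_params"))
  n <- sqrt(sum(axis_direction^2))
  if (n < 1e-12) {
    abort("Axis direction has zero length.",
          class = "helicomb_error_degenerate_axis")
  }
  d <- axis_direction / n
  R <- rotation_about_axis(d, power * params$twist_deg)
  t <- axis_origin - as.numeric(R %*% axis_origin) + power * params$rise_A * d
  rigid_transform(R, t)
}

#' Decompose a rigid transform into its screw parameters
#'
#' Inverse of [screw_from_params()]: recovers the rotation angle (twist), the
#' translation along the rotation axis (rise) and the positioned screw axis
#' (the line about which the off-axis translation vanishes). The axis
#' direction is chosen so the rise is positive (for zero rise, so the twist
#' is in (0, 180]); twist is reported in (0, 360].
#'
#' @param transform A [rigid_transform()].
#' @param tol Rotation angle (degrees) below which the screw axis is
#'   considered undefined (a pure translation has no unique axis).
#' @return List with `twist_deg`, `rise_A`, `axis_origin` (point on the axis
#'   closest to the coordinate origin), and `axis_direction`.
#' @export
screw_decompose <- function(transform, tol = 1e-4) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- transform$rotation
  t <- transform$translation
  ang <- rotation_angle(R)
  if (ang < tol) {
    abort("Rotation angle below tolerance: pure translation has no unique screw axis.",
          class = "helicomb_error_undefined_axis")
  }
  if (ang > 180 - 1e-7) {
    # axis from the dominant column of R + I
    M <- R + diag(3)
    u <- M[, which.max(colSums(M^2))]
    u <- u / sqrt(sum(u^2))
    theta <- 180
  } else {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    u <- v / sqrt(sum(v^2))
    theta <- ang
  }
  rise <- sum(t * u)
  if (rise < 0 || (abs(rise) < 1e-9 && theta > 180)) {
    u <- -u
    theta <- -theta
    rise <- -rise
  }
  twist <- theta %% 360
  if (twist == 0) twist <- 360
  # axis point: (I - R) p = t_perp, rank-2 system with null space along u
  A <- diag(3) - R
  b <- t - rise * u
  s <- svd(A)
  inv <- ifelse(s$d > 1e-9, 1 / pmax(s$d, 1e-12), 0)
  p <- s$v %*% (inv * crossprod(s$u, b))
  p <- as.numeric(p)
  p <- p - sum(p * u) * u
  list(twist_deg = twist, rise_A = rise, axis_origin = p, axis_direction = u)
}

#' Build an ideal filament from a protomer and helical parameters
#'
#' Subunit k (k = 0, ..) is the protomer transformed by the k-th power of the
#' screw operator; for `cn > 1` each level is additionally replicated by
#' rotations of 360/cn degrees about the axis (ring-major subunit order:
#' all cn copies of level 0, then level 1, ...).
#'
#' @param protomer A [protomer()] positioned relative to the axis.
#' @param params A [helical_params()].
#' @param n_subunits Total number of subunits (>= 1; divisible by `cn`).
#' @param axis_origin,axis_direction The filament axis.
#' @return A [filament()] carrying `params` and the axis. For `n_subunits = 1`
#'   (and cn = 1) the single untransformed protomer is returned as a
#'   one-subunit object of class `filament` (the >= 2 protomer invariant is
#'   relaxed for this trivial case).
#' @export
build_filament <- function(protomer, params, n_subunits,
                           axis_origin = c(0, 0, 0),
                           axis_direction = c(0, 0, 1)) {
  stopifnot(inherits(protomer, "protomer"), inherits(params, "helical_params"))
  n_subunits <- as.integer(n_subunits)
  if (n_subunits < 1 || n_subunits %% params$cn != 0) {
    abort("n_subunits must be >= 1 and divisible by cn.",
          class = "helicomb_error_precondition")
  }
  d <- axis_direction / sqrt(sum(axis_direction^2))
  n_levels <- n_subunits %/% params$cn
  prots <- vector("list", n_subunits)
  i <- 1
  for (l in seq_len(n_levels) - 1L) {
    S <- screw_from_params(params, axis_origin, d, power = l)
    for (cc in seq_len(params$cn) - 1L) {
      tf <- if (cc == 0) S else {
        Rc <- rotation_about_axis(d, cc * 360 / params$cn)
        compose_transforms(
          rigid_transform(Rc, axis_origin - as.numeric(Rc %*% axis_origin)), S)
      }
      p <- transform_protomer(protomer, tf)
      p$label <- sprintf("%s_%03d", protomer$label, i)
      prots[[i]] <- p
      i <- i + 1
    }
  }
  if (n_subunits == 1) {
    return(structure(list(protomers = prots, axis_origin = axis_origin,
                          axis_direction = d, params = params),
                     class = "filament"))
  }
  filament(prots, axis_origin = axis_origin, axis_direction = d,
           params = params)
}

#' Estimate helical parameters from an ordered filament
#'
#' Superposes each subunit onto its successor along the 1-start helix
#' (Kabsch over matched C-alpha atoms when present, otherwise all heavy
#' atoms), screw-decomposes each consecutive transform, and returns the
#' median twist and rise. The axial point-group order `cn` is detected from
#' co-level rings (subunits at the same axial level related by 360/cn
#' rotations); when `cn > 1` the consecutive transforms are taken between
#' subunits k and k+cn, which pairs matching ring copies of adjacent levels.
#'
#' For a Cn lattice the 1-start operator is only defined modulo 360/cn once
#' subunit identity is forgotten; the index order of the assembly is what
#' resolves the ambiguity here.
#'
#' @param filament A [filament()] with >= 3 ordered protomers.
#' @param spread_tol Consistency tolerance: median absolute deviation of the
#'   consecutive twists (degrees) or rises (Angstrom) above which the
#'   assembly is rejected as non-helical.
#' @return A [helical_params()] with an `estimate` attribute carrying the
#'   per-pair twists/rises and the fitted axis.
#' @export
estimate_params <- function(filament, spread_tol = 3) {
  stopifnot(inherits(filament, "filament"))
  n <- n_protomers(filament)
  if (n < 3) {
    abort("Need >= 3 ordered protomers.", class = "helicomb_error_precondition")
  }
  cen <- filament_centroids(filament)
  s <- axial_coord(filament, cen)
  cn <- detect_cn(filament, s)
  pairs <- seq_len(n - cn)
  dec <- purrr::map(pairs, function(k) {
    fit <- kabsch(match_xyz(filament$protomers[[k]]),
                  match_xyz(filament$protomers[[k + cn]]))
    screw_decompose(fit$transform)
  })
  tw <- vapply(dec, function(d) d$twist_deg, 0)
  ri <- vapply(dec, function(d) d$rise_A, 0)
  # align signs: a screw (t, r) can decompose as (360 - t, -r) flipped; the
  # positive-rise convention already handles this. Unwrap twists about the
  # first value so the median is not split across the 0/360 seam.
  tw_u <- tw[1] + ((tw - tw[1] + 180) %% 360) - 180
  if (mad(tw_u, constant = 1) > spread_tol || mad(ri, constant = 1) > spread_tol) {
    abort("Consecutive subunit transforms are inconsistent: not a helical assembly.",
          class = "helicomb_error_non_helical")
  }
  twist <- median(tw_u) %% 360
  if (twist == 0) twist <- 360
  rise <- median(ri)
  out <- helical_params(twist, rise, cn = cn)
  attr(out, "estimate") <- list(twists = tw_u, rises = ri,
                                axis_origin = filament$axis_origin,
                                axis_direction = filament$axis_direction)
  out
}

# Detect the axial point-group order: cluster subunits into co-level groups
# (gaps in axial coordinate larger than a fraction of the typical level
# spacing) and accept the modal group size as cn only when every level has
# that size and co-level partners sit at ~360/cn azimuthal spacings.
detect_cn <- function(f, s) {
  n <- length(s)
  span <- diff(range(s))
  if (span < 1e-6) return(1L)
  ord <- order(s)
  gaps <- diff(s[ord])
  lvl_tol <- 0.25 * max(gaps)
  lev <- cumsum(c(TRUE, gaps > lvl_tol))
  sizes <- tabulate(lev)
  cn <- as.integer(names(sort(table(sizes), decreasing = TRUE))[1])
  if (is.na(cn) || cn < 2 || n %% cn != 0 || !all(sizes == cn)) return(1L)
  az <- azimuth_deg(f, filament_centroids(f))[ord]
  for (l in unique(lev)) {
    a <- sort(az[lev == l])
    ring_gaps <- diff(c(a, a[1] + 360))
    if (any(abs(ring_gaps - 360 / cn) > 5)) return(1L)
  }
  cn
}

match_xyz <- function(p) {
  ca <- p$atoms[p$atoms$name == "CA" & p$atoms$is_heavy, , drop = FALSE]
  if (nrow(ca) >= 3) atom_xyz(ca) else atom_xyz(p$atoms, heavy_only = TRUE)
}
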