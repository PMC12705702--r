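#' Residue correspondence between two protomers
#'
#' Identical sequences map position-by-position; otherwise a global
#' Needleman-Wunsch alignment (BLOSUM62, gap open 10, gap extend 1) pairs
#' the residues. A hand-curated mapping can be passed to the downstream
#' operations instead.
#'
#' @param a,b [protomer()] objects.
#' @return A tibble with columns `resno_a`, `resno_b` (author numbering of
#'   aligned, non-gap positions).
#' @export
residue_mapping <- function(a, b) {
  res_a <- protomer_residues(a)
  res_b <- protomer_residues(b)
  if (identical(a$sequence, b$sequence) && length(res_a) == length(res_b)) {
    return(tibble(resno_a = res_a, resno_b = res_b))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(ps != "-")
  keep <- pa != "-" & ps != "-"
  tibble(resno_a = res_a[ia[keep]], resno_b = res_b[ib[keep]])
}

mapped_ca_xyz <- function(a, b, mapping) {
  pick <- function(p, resnos) {
    at <- p$atoms
    ca <- at[at$name == "CA" & at$is_heavy, , drop = FALSE]
    if (nrow(ca) < 3) ca <- at[at$is_heavy, , drop = FALSE]
    ca[match(resnos, ca$resno), , drop = FALSE]
  }
  aa <- pick(a, mapping$resno_a)
  bb <- pick(b, mapping$resno_b)
  ok <- !is.na(aa$resno) & !is.na(bb$resno)
  list(a = atom_xyz(aa[ok, , drop = FALSE]),
       b = atom_xyz(bb[ok, , drop = FALSE]),
       resno_a = aa$resno[ok], resno_b = bb$resno[ok])
}

#' Superpose two monomers and report the (core-trimmed) RMSD
#'
#' Kabsch superposition of `a` onto `b` over mapped C-alpha atoms. With
#' `trim = TRUE`, pairs with residuals above twice the current RMSD are
#' discarded iteratively (at most 5 rounds, stopping when the retained set
#' is unchanged or would drop below 30 pairs), giving the core RMSD over
#' the structurally conserved residues.
#'
#' @param a,b [protomer()] objects.
#' @param mapping Residue correspondence (see [residue_mapping()]); computed
#'   from the sequences when `NULL`. At least 30 pairs are required.
#' @param trim Iteratively trim to the conserved core (default `FALSE`).
#' @return An object of class `monomer_alignment`: list with `rmsd`
#'   (Angstrom), `transform` (mapping `a` onto `b`), `n_pairs`, `n_used`,
#'   `retained_fraction`, and the per-pair `residuals`.
#' @export
align_monomers <- function(a, b, mapping = NULL, trim = FALSE) {
  if (is.null(mapping)) mapping <- residue_mapping(a, b)
  m <- mapped_ca_xyz(a, b, mapping)
  n0 <- nrow(m$a)
  if (n0 < 30) {
    abort(sprintf("Only %d mapped residue pairs; need >= 30.", n0),
          class = "helicomb_error_correspondence")
  }
  keep <- seq_len(n0)
  fit <- kabsch(m$a, m$b)
  if (trim) {
    for (round in 1:5) {
      thr <- 2 * fit$rmsd
      new_keep <- keep[fit$residuals <= thr]
      if (length(new_keep) < 30 || length(new_keep) == length(keep)) break
      keep <- new_keep
      fit <- kabsch(m$a[keep, , drop = FALSE], m$b[keep, , drop = FALSE])
    }
  }
  structure(list(rmsd = fit$rmsd, transform = fit$transform, n_pairs = n0,
                 n_used = length(keep), retained_fraction = length(keep) / n0,
                 residuals = fit$residuals,
                 resno_a = m$resno_a[keep], resno_b = m$resno_b[keep]),
            class = "monomer_alignment")
}

#' @export
print.monomer_alignment <- function(x, ...) {
  cat(sprintf("<monomer_alignment> RMSD %.2f A over %d/%d pairs\n",
              x$rmsd, x$n_used, x$n_pairs))
  invisible(x)
}

#' @rdname align_monomers
#' @param x A `monomer_alignment`.
#' @param ... Unused.
#' @export
glance.monomer_alignment <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs, n_used = x$n_used,
         retained_fraction = x$retained_fraction)
}

#' Rigidly thread a monomer onto the center of a honeycomb
#'
#' The monomer is superposed onto the template's center subunit over mapped
#' C-alpha atoms and returned in the template frame. No backbone remodeling
#' or side-chain repacking is performed: the threading is strictly
#' rigid-body, so the score of the threaded monomer is a property of the two
#' architectures alone.
#'
#' @param monomer A [protomer()] to place.
#' @param template A `honeycomb` (see [extract_honeycomb()]).
#' @param mapping Residue correspondence monomer -> template center; derived
#'   from the sequences when `NULL`. Must cover at least `min_coverage` of
#'   the template-center residues.
#' @param min_coverage Minimum alignable-core fraction (default 0.6).
#' @return The transformed [protomer()], with attribute `alignment` (the
#'   [align_monomers()] fit used for placement).
#' @export
thread_monomer <- function(monomer, template, mapping = NULL,
                           min_coverage = 0.6) {
  stopifnot(inherits(template, "honeycomb"))
  if (is.null(mapping)) mapping <- residue_mapping(monomer, template$center)
  n_center <- length(protomer_residues(template$center))
  if (nrow(mapping) < min_coverage * n_center) {
    abort(sprintf(
      "Residue correspondence covers %d of %d template-center residues (< %.0f%%).",
      nrow(mapping), n_center, 100 * min_coverage),
      class = "helicomb_error_correspondence")
  }
  fit <- align_monomers(monomer, template$center, mapping = mapping)
  out <- transform_protomer(monomer, fit$transform)
  attr(out, "alignment") <- fit
  out
}

#' Score a threaded monomer against a honeycomb shell
#'
#' For each shell contact, counts heavy-atom pairs between the threaded
#' center and the shell member closer than `clash_cutoff` (steric clashes)
#' and non-clashing pairs within `contact_cutoff` (favorable contacts), and
#' scores the interface as `w_clash * clashes - w_contact * contacts`
#' (dimensionless; lower is more favorable). Top- and bottom-half sums
#' partition the total exactly. This is a transparent stand-in for
#' physics-based interface energies: only its signs and orderings are
#' meaningful, not its magnitudes.
#'
#' @param threaded A [protomer()] positioned by [thread_monomer()] (or the
#'   native center for a self-score).
#' @param template A `honeycomb` providing the shell.
#' @param shell_source `"template"` scores against the template's own shell
#'   protomers (center-subunit swap); `"threaded"` rebuilds each shell
#'   member from the threaded monomer using the template's lattice
#'   operators (modeling a homo-assembly of the threaded species on the
#'   template architecture).
#' @param clash_cutoff,contact_cutoff Heavy-atom cutoffs in Angstrom
#'   (defaults 2.6 and 4.5).
#' @param w_clash,w_contact Score weights (defaults 10 and 1).
#' @param threaded_label,template_label Labels carried into the report.
#' @return An object of class `compat_report`.
#' @export
score_shell <- function(threaded, template,
                        shell_source = c("template", "threaded"),
                        clash_cutoff = 2.6, contact_cutoff = 4.5,
                        w_clash = 10, w_contact = 1,
                        threaded_label = threaded$label,
                        template_label = template$center$label) {
  stopifnot(inherits(template, "honeycomb"))
  shell_source <- match.arg(shell_source)
  shell <- template$shell
  if (nrow(shell) == 0) {
    abort("Template shell is empty.", class = "helicomb_error_incomplete_shell")
  }
  members <- shell$structure
  if (shell_source == "threaded") {
    members <- purrr::map(members, function(mem) {
      tf <- kabsch(match_xyz(template$center), match_xyz(mem))$transform
      transform_protomer(threaded, tf)
    })
  }
  per <- purrr::map(seq_len(nrow(shell)), function(k) {
    pairs <- contact_pairs(threaded, members[[k]], contact_cutoff)
    clash <- sum(pairs$dist < clash_cutoff)
    contact <- sum(pairs$dist >= clash_cutoff)
    tibble(offset = shell$offset[k], half = shell$half[k],
           surface = if ("surface" %in% names(shell)) shell$surface[k]
                     else NA_character_,
           type_label = if ("type_label" %in% names(shell))
             shell$type_label[k] else NA_character_,
           clash_count = clash, contact_count = contact,
           score = w_clash * clash - w_contact * contact)
  }) |> bind_rows()
  half_sums <- per |>
    group_by(.data$half) |>
    summarise(score = sum(.data$score), .groups = "drop")
  top <- sum(half_sums$score[half_sums$half == "top"])
  bottom <- sum(half_sums$score[half_sums$half == "bottom"])
  structure(list(per_interface = per,
                 half_sums = c(top = top, bottom = bottom),
                 total = top + bottom,
                 total_clashes = sum(per$clash_count),
                 threaded_monomer = threaded_label,
                 template = template_label,
                 shell_source = shell_source,
                 weights = c(w_clash = w_clash, w_contact = w_contact),
                 cutoffs = c(clash = clash_cutoff, contact = contact_cutoff)),
            class = "compat_report")
}

#' @export
print.compat_report <- function(x, ...) {
  cat(sprintf("<compat_report> %s threaded into %s shell (%s)\n",
              x$threaded_monomer, x$template, x$shell_source))
  cat(sprintf("  total %g (top %g + bottom %g), %d clashes\n",
              x$total, x$half_sums[["top"]], x$half_sums[["bottom"]],
              x$total_clashes))
  print(x$per_interface)
  invisible(x)
}

#' @rdname score_shell
#' @param x A `compat_report`.
#' @param ... Unused.
#' @export
tidy.compat_report <- function(x, ...) x$per_interface

#' @rdname score_shell
#' @export
glance.compat_report <- function(x, ...) {
  tibble(threaded = x$threaded_monomer, template = x$template,
         shell_source = x$shell_source, total = x$total,
         top = x$half_sums[["top"]], bottom = x$half_sums[["bottom"]],
         clashes = x$total_clashes)
}

#' Swap the center subunit of a receptor honeycomb for an adapter
#'
#' Threads the adapter monomer onto the receptor honeycomb's center and
#' scores it against the receptor's own shell: the center-subunit
#' replacement used to ask how well an adapter domain fits the lattice of an
#' upstream receptor filament.
#'
#' @param adapter A [protomer()] (e.g. an adapter pyrin domain).
#' @param receptor_honeycomb A `honeycomb` from the receptor filament.
#' @param mapping Optional residue correspondence adapter -> receptor center.
#' @param ... Passed to [score_shell()].
#' @return A `compat_report`.
#' @export
swap_center_analysis <- function(adapter, receptor_honeycomb, mapping = NULL,
                                 ...) {
  threaded <- thread_monomer(adapter, receptor_honeycomb, mapping)
  score_shell(threaded, receptor_honeycomb, shell_source = "template", ...)
}

#' Compare two honeycombs position by position
#'
#' Superposes the center of `b` onto the center of `a` (over mapped C-alpha
#' atoms), carries the whole of `b` along, and reports, for every matched
#' shell position (same signed offset and half), the centroid displacement
#' and orientation difference between the two shell members. Unmatched
#' positions are reported with `matched = FALSE`, never as an error.
#'
#' @param a,b `honeycomb` objects.
#' @param mapping Optional residue correspondence b-center -> a-center.
#' @return A tibble with one row per shell position: `offset`, `half`,
#'   `displacement_A`, `rotation_deg`, `matched`.
#' @export
compare_honeycombs <- function(a, b, mapping = NULL) {
  stopifnot(inherits(a, "honeycomb"), inherits(b, "honeycomb"))
  if (is.null(mapping)) mapping <- residue_mapping(b$center, a$center)
  fit <- align_monomers(b$center, a$center, mapping = mapping)
  b_shell <- purrr::map(b$shell$structure, transform_protomer,
                        tf = fit$transform)
  key_a <- paste(a$shell$offset, a$shell$half)
  key_b <- paste(b$shell$offset, b$shell$half)
  purrr::map(seq_len(nrow(a$shell)), function(k) {
    j <- match(key_a[k], key_b)
    if (is.na(j)) {
      return(tibble(offset = a$shell$offset[k], half = a$shell$half[k],
                    displacement_A = NA_real_, rotation_deg = NA_real_,
                    matched = FALSE))
    }
    pa <- a$shell$structure[[k]]
    pb <- b_shell[[j]]
    disp <- sqrt(sum((protomer_centroid(pa) - protomer_centroid(pb))^2))
    mb <- mapped_ca_xyz(pb, pa, mapping)
    rot <- rotation_angle(kabsch(mb$a, mb$b)$transform$rotation)
    tibble(offset = a$shell$offset[k], half = a$shell$half[k],
           displacement_A = disp, rotation_deg = rot, matched = TRUE)
  }) |> bind_rows()
}
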