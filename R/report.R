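#' Analysis configuration
#'
#' Collects every tunable cutoff and weight of the pipeline in one object
#' that round-trips through JSON, so a report records exactly the
#' conventions it was produced under.
#'
#' @param contact_cutoff Heavy-atom contact cutoff, Angstrom (> 0).
#' @param clash_cutoff Heavy-atom clash threshold, Angstrom (> 0).
#' @param w_clash,w_contact Compatibility score weights.
#' @param tie_tol Interface-typing tie tolerance (relative).
#' @param seed Integer seed for any seeded component.
#' @return A list of class `filament_config`.
#' @export
filament_config <- function(contact_cutoff = 4.5, clash_cutoff = 2.6,
                            w_clash = 10, w_contact = 1, tie_tol = 0.1,
                            seed = 1L) {
  if (contact_cutoff <= 0 || clash_cutoff <= 0) {
    abort("Cutoffs must be > 0.", class = "helicomb_error_config")
  }
  structure(list(contact_cutoff = as.numeric(contact_cutoff),
                 clash_cutoff = as.numeric(clash_cutoff),
                 w_clash = as.numeric(w_clash),
                 w_contact = as.numeric(w_contact),
                 tie_tol = as.numeric(tie_tol),
                 seed = as.integer(seed)),
            class = "filament_config")
}

#' @rdname filament_config
#' @param config A `filament_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname filament_config
#' @export
read_config <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(filament_config, rec)
}

#' End-to-end architecture analysis of one filament
#'
#' Orders the chains of a filament model (when given a file or chain list),
#' estimates its helical parameters, counts the base-layer protomers,
#' measures the rim diameters, and extracts and classifies an interior
#' honeycomb neighborhood. Optionally writes the report to `output_dir` as
#' `report.json` plus `interfaces.csv` (byte-identical for identical inputs
#' and config).
#'
#' @param x A coordinate file path, a list of [protomer()] chains, or a
#'   [filament()].
#' @param config A [filament_config()].
#' @param output_dir Optional directory to write the report bundle into.
#' @param ss_segments Optional segment table applied when reading from file.
#' @return A list of class `filament_report` with elements `params`,
#'   `base_count`, `diameters`, `honeycomb`, `interfaces`, `config`.
#' @export
analyze_filament <- function(x, config = filament_config(),
                             output_dir = NULL, ss_segments = NULL) {
  fil <- if (inherits(x, "filament")) x
  else if (is.character(x)) order_protomers(read_structure(x, ss_segments = ss_segments))
  else order_protomers(x)
  params <- estimate_params(fil)
  base <- base_layer_count(fil)
  dia <- rim_diameters(fil)
  center <- pick_interior_center(fil, config$contact_cutoff)
  hc <- extract_honeycomb(fil, center, config$contact_cutoff)
  interfaces <- tidy(hc)
  out <- structure(list(params = params, base_count = base, diameters = dia,
                        honeycomb = hc, interfaces = interfaces,
                        config = config, filament = fil),
                   class = "filament_report")
  if (!is.null(output_dir)) write_report_bundle(out, output_dir)
  out
}

#' @export
print.filament_report <- function(x, ...) {
  cat("<filament_report>\n")
  print(x$params)
  cat(sprintf("  base layer: %d protomers; rim diameters: outer %g A, inner %g A\n",
              x$base_count, x$diameters$outer_A, x$diameters$inner_A))
  cat(sprintf("  honeycomb shell: %d contacts around subunit %d\n",
              nrow(x$interfaces), x$honeycomb$center_index))
  invisible(x)
}

#' @rdname analyze_filament
#' @param x A `filament_report`.
#' @param ... Unused.
#' @export
glance.filament_report <- function(x, ...) {
  dplyr::bind_cols(tidy(x$params),
                   tibble(base_count = x$base_count,
                          outer_A = x$diameters$outer_A,
                          inner_A = x$diameters$inner_A,
                          shell_size = nrow(x$interfaces)))
}

#' @rdname analyze_filament
#' @param report A `filament_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- list(params = as.list(tidy(report$params)),
              base_count = report$base_count,
              diameters = as.list(report$diameters),
              shell = lapply(split(report$interfaces,
                                   seq_len(nrow(report$interfaces))),
                             as.list) |> unname(),
              config = unclass(report$config))
  jsonlite::write_json(rec, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$interfaces, file.path(dir, "interfaces.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Thread a monomer into a template filament and report compatibility
#'
#' Composes [extract_honeycomb()], [thread_monomer()] and [score_shell()]:
#' the cross-threading experiment asking whether a monomer fits a given
#' filament architecture. Optionally writes `compat.json` and `compat.csv`.
#'
#' @param monomer A [protomer()] or coordinate file path (first chain used).
#' @param template A [filament()], `honeycomb`, or coordinate file path.
#' @param config A [filament_config()].
#' @param shell_source Passed to [score_shell()].
#' @param mapping Optional residue correspondence.
#' @param output_dir Optional directory for the report files.
#' @return A `compat_report`.
#' @export
thread_report <- function(monomer, template, config = filament_config(),
                          shell_source = "template", mapping = NULL,
                          output_dir = NULL) {
  if (is.character(monomer)) monomer <- read_structure(monomer)[[1]]
  hc <- if (inherits(template, "honeycomb")) template else {
    fil <- if (inherits(template, "filament")) template
    else order_protomers(read_structure(template))
    extract_honeycomb(fil, pick_interior_center(fil, config$contact_cutoff),
                      config$contact_cutoff)
  }
  threaded <- thread_monomer(monomer, hc, mapping)
  rep <- score_shell(threaded, hc, shell_source = shell_source,
                     clash_cutoff = config$clash_cutoff,
                     contact_cutoff = config$contact_cutoff,
                     w_clash = config$w_clash, w_contact = config$w_contact)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(threaded = rep$threaded_monomer, template = rep$template,
           shell_source = rep$shell_source, total = rep$total,
           top = rep$half_sums[["top"]], bottom = rep$half_sums[["bottom"]],
           clashes = rep$total_clashes,
           per_interface = lapply(split(rep$per_interface,
                                        seq_len(nrow(rep$per_interface))),
                                  as.list) |> unname()),
      file.path(output_dir, "compat.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(rep$per_interface, file.path(output_dir, "compat.csv"),
                     row.names = FALSE)
  }
  rep
}
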