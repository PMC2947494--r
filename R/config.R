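run_config_keys <- c(
  "calculation_type", "pqr_file_1", "pqr_file_2",
  "grid_dimensions", "coarse_grid_lengths", "medium_grid_lengths",
  "fine_grid_lengths", "counter_ion", "protein_dielectric",
  "solvent_dielectric", "membrane_dielectric", "headgroup_dielectric",
  "solution_method", "boundary_condition", "srad", "sdens", "temperature",
  "membrane_bottom", "membrane_thickness", "headgroup_thickness",
  "upper_exclusion_radius", "lower_exclusion_radius", "membrane_potential")

#' Workflow run configuration
#'
#' The full parameter surface of a calculation: type, structure files, grid
#' ladder, electrolyte, dielectrics, surface parameters and membrane
#' geometry, mirroring the standard parameter tables of membrane PB
#' calculations.
#'
#' @param calculation_type one of `"protein_solvation"`, `"ion_solvation"`,
#'   `"gating_charge"`.
#' @param pqr_file_1 path of the first PQR file (protein / open state).
#' @param pqr_file_2 path of the second PQR file (ion / closed state);
#'   required for ion-solvation and gating runs.
#' @param grid_dimensions node counts per axis.
#' @param coarse_grid_lengths,medium_grid_lengths,fine_grid_lengths side
#'   lengths of the focusing ladder (Angstrom); medium/fine may be `NULL`
#'   for fewer focusing levels.
#' @param counter_ions numeric matrix with columns (valence, molar
#'   concentration, radius), one row per species.
#' @param protein_dielectric,solvent_dielectric,membrane_dielectric,headgroup_dielectric
#'   relative permittivities.
#' @param solution_method only `"lpbe"` is supported.
#' @param boundary_condition `"focus"`, `"zero"`, `"sdh"`, `"mdh"` or
#'   `"membrane_potential"`.
#' @param srad solvent probe radius (Angstrom).
#' @param sdens surface sphere density (points/Angstrom^2).
#' @param temperature Kelvin.
#' @param membrane_bottom z of the membrane bottom face (Angstrom).
#' @param membrane_thickness total slab thickness (Angstrom).
#' @param headgroup_thickness per-leaflet head-group thickness (Angstrom).
#' @param upper_exclusion_radius,lower_exclusion_radius exclusion radii
#'   (Angstrom).
#' @param membrane_potential sweep endpoint |V| in mV (gating runs).
#' @return a validated object of class `run_config`.
#' @export
run_config <- function(calculation_type, pqr_file_1, pqr_file_2 = NULL,
                       grid_dimensions = c(65, 65, 65),
                       coarse_grid_lengths = c(200, 200, 200),
                       medium_grid_lengths = NULL,
                       fine_grid_lengths = NULL,
                       counter_ions = rbind(c(1, 0.1, 2), c(-1, 0.1, 2)),
                       protein_dielectric = 5, solvent_dielectric = 80,
                       membrane_dielectric = 2, headgroup_dielectric = 80,
                       solution_method = "lpbe",
                       boundary_condition = "focus",
                       srad = 1.4, sdens = 10, temperature = 298.15,
                       membrane_bottom = -21, membrane_thickness = 42,
                       headgroup_thickness = 0,
                       upper_exclusion_radius = 0,
                       lower_exclusion_radius = 0,
                       membrane_potential = 50) {
  cfg <- structure(list(
    calculation_type = calculation_type, pqr_file_1 = pqr_file_1,
    pqr_file_2 = pqr_file_2,
    grid_dimensions = rep_len(as.integer(grid_dimensions), 3),
    coarse_grid_lengths = rep_len(as.numeric(coarse_grid_lengths), 3),
    medium_grid_lengths = if (is.null(medium_grid_lengths)) NULL else
      rep_len(as.numeric(medium_grid_lengths), 3),
    fine_grid_lengths = if (is.null(fine_grid_lengths)) NULL else
      rep_len(as.numeric(fine_grid_lengths), 3),
    counter_ions = rbind(counter_ions),
    protein_dielectric = protein_dielectric,
    solvent_dielectric = solvent_dielectric,
    membrane_dielectric = membrane_dielectric,
    headgroup_dielectric = headgroup_dielectric,
    solution_method = solution_method,
    boundary_condition = boundary_condition,
    srad = srad, sdens = sdens, temperature = temperature,
    membrane_bottom = membrane_bottom,
    membrane_thickness = membrane_thickness,
    headgroup_thickness = headgroup_thickness,
    upper_exclusion_radius = upper_exclusion_radius,
    lower_exclusion_radius = lower_exclusion_radius,
    membrane_potential = membrane_potential), class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  types <- c("protein_solvation", "ion_solvation", "gating_charge")
  if (!cfg$calculation_type %in% types)
    stop("calculation_type must be one of: ", paste(types, collapse = ", "))
  if (cfg$calculation_type %in% c("ion_solvation", "gating_charge") &&
      is.null(cfg$pqr_file_2))
    stop(cfg$calculation_type, " requires two PQR files")
  if (cfg$solution_method != "lpbe")
    stop("only the linearized PB equation ('lpbe') is supported")
  bcs <- c("focus", "zero", "sdh", "mdh", "membrane_potential")
  if (!cfg$boundary_condition %in% bcs)
    stop("boundary_condition must be one of: ", paste(bcs, collapse = ", "))
  if (cfg$membrane_thickness <= 0)
    stop("membrane_thickness must be positive")
  if (2 * cfg$headgroup_thickness >= cfg$membrane_thickness)
    stop("head-group layers cannot fill the whole membrane")
  if (ncol(cfg$counter_ions) != 3)
    stop("counter_ions must have columns (valence, concentration, radius)")
  if (any(cfg$counter_ions[, 2] < 0))
    stop("ion concentrations must be non-negative")
  stopifnot(cfg$srad >= 0, cfg$sdens > 0, cfg$temperature > 0,
            all(cfg$grid_dimensions >= 3),
            cfg$upper_exclusion_radius >= 0,
            cfg$lower_exclusion_radius >= 0)
  cfg
}

fmt_cfg_val <- function(v) {
  if (is.numeric(v)) paste(format(v, trim = TRUE, scientific = FALSE),
                           collapse = ", ")
  else as.character(v)
}

#' Write a run configuration to a flat key/value file
#'
#' One `key = value` line per parameter (vectors comma-separated; one
#' `counter_ion` line per species), diffable against the standard parameter
#' tables.  [read_run_config()] restores an identical configuration.
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- character(0)
  for (key in names(cfg)) {
    v <- cfg[[key]]
    if (is.null(v)) next
    if (key == "counter_ions") {
      for (r in seq_len(nrow(v)))
        lines <- c(lines, sprintf("counter_ion = %s", fmt_cfg_val(v[r, ])))
    } else {
      lines <- c(lines, sprintf("%s = %s", key, fmt_cfg_val(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' Parses the flat `key = value` format of [write_run_config()].  Unknown
#' keys are rejected.  `#` starts a comment.
#'
#' @param path path to a configuration file.
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3
  if (any(bad)) stop("unparseable config line: ", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  unknown <- setdiff(unique(keys), run_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  numeric_keys <- setdiff(run_config_keys,
                          c("calculation_type", "pqr_file_1", "pqr_file_2",
                            "solution_method", "boundary_condition",
                            "counter_ion"))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k == "counter_ion") next
    v <- trimws(vals[i])
    if (k %in% numeric_keys)
      v <- as.numeric(strsplit(v, "\\s*,\\s*")[[1]])
    args[[k]] <- v
  }
  ci <- which(keys == "counter_ion")
  if (length(ci))
    args$counter_ions <- do.call(rbind, lapply(vals[ci], function(v)
      as.numeric(strsplit(trimws(v), "\\s*,\\s*")[[1]])))
  do.call(run_config, args)
}

cfg_ions <- function(cfg) {
  lapply(seq_len(nrow(cfg$counter_ions)), function(r)
    ion_species(cfg$counter_ions[r, 1], cfg$counter_ions[r, 2],
                cfg$counter_ions[r, 3]))
}

cfg_membrane <- function(cfg) {
  membrane_geometry(
    z_bottom = cfg$membrane_bottom, thickness = cfg$membrane_thickness,
    headgroup_thickness = cfg$headgroup_thickness,
    eps_membrane = cfg$membrane_dielectric,
    eps_headgroup = cfg$headgroup_dielectric,
    upper_exclusion_radius = cfg$upper_exclusion_radius,
    lower_exclusion_radius = cfg$lower_exclusion_radius)
}

cfg_lengths <- function(cfg) {
  L <- list(cfg$coarse_grid_lengths)
  if (!is.null(cfg$medium_grid_lengths))
    L <- c(L, list(cfg$medium_grid_lengths))
  if (!is.null(cfg$fine_grid_lengths)) L <- c(L, list(cfg$fine_grid_lengths))
  L
}

resolve_pqr <- function(path, base_dir) {
  p <- if (!is.null(base_dir) && !file.exists(path))
    file.path(base_dir, path) else path
  if (!file.exists(p)) stop("PQR file not found: ", path)
  read_pqr(p)
}

#' Run the workflow described by a configuration
#'
#' Dispatches to [protein_solvation()], [ion_solvation()] or
#' [gating_charge()] with the parameters of `cfg`.
#'
#' @param cfg a [run_config()].
#' @param base_dir directory against which relative PQR paths are resolved.
#' @param tol solver tolerance.
#' @return the workflow result (`solvation_result` or `gating_result`).
#' @export
run_workflow <- function(cfg, base_dir = NULL, tol = 1e-6) {
  stopifnot(inherits(cfg, "run_config"))
  s1 <- resolve_pqr(cfg$pqr_file_1, base_dir)
  ions <- cfg_ions(cfg)
  consts <- physical_constants(cfg$temperature)
  surf <- surface_spec(cfg$srad, cfg$sdens)
  mem <- cfg_membrane(cfg)
  lengths <- cfg_lengths(cfg)
  counts <- cfg$grid_dimensions
  bc0 <- if (cfg$boundary_condition %in% c("focus", "membrane_potential"))
    "mdh" else cfg$boundary_condition
  switch(cfg$calculation_type,
    protein_solvation = protein_solvation(
      s1, mem, lengths, counts, cfg$protein_dielectric,
      cfg$solvent_dielectric, ions, surf, consts, bc0, tol),
    ion_solvation = {
      s2 <- resolve_pqr(cfg$pqr_file_2, base_dir)
      ion_solvation(s1, s2, mem, lengths, counts, cfg$protein_dielectric,
                    cfg$solvent_dielectric, ions, surf, consts, bc0, tol)
    },
    gating_charge = {
      s2 <- resolve_pqr(cfg$pqr_file_2, base_dir)
      gating_charge(s1, s2, mem, lengths, counts, cfg$protein_dielectric,
                    cfg$solvent_dielectric, ions, surf, consts,
                    V_max = abs(cfg$membrane_potential), tol = tol)
    })
}

#' Preview the membrane-modified dielectric map
#'
#' Performs the quick "dummy" pass: builds only the dielectric map of the
#' coarsest grid at a reduced node count and inserts the membrane, so the
#' slab, head-group and exclusion geometry can be inspected before any
#' solve.
#'
#' @param cfg a [run_config()].
#' @param counts node count per axis of the preview grid (default 33).
#' @param base_dir directory against which relative PQR paths are resolved.
#' @return the membrane-modified dielectric [scalar_grid()].
#' @export
preview_membrane <- function(cfg, counts = 33, base_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  s <- resolve_pqr(cfg$pqr_file_1, base_dir)
  gs <- grid_spec(c(0, 0, 0), cfg$coarse_grid_lengths, counts)
  surf <- surface_spec(cfg$srad, cfg$sdens)
  diel <- build_dielectric_map(s, gs, cfg$protein_dielectric,
                               cfg$solvent_dielectric, surf)
  kappa <- build_kappa_map(s, gs, cfg_ions(cfg),
                           physical_constants(cfg$temperature))
  add_membrane(diel, kappa, cfg_membrane(cfg), cfg$protein_dielectric)$diel
}

#' Serialize a workflow result to JSON
#'
#' @param res a `solvation_result` or `gating_result`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(res, path = NULL) {
  obj <- if (inherits(res, "gating_result"))
    list(type = "gating_charge", valence_e = res$valence_e,
         sweep = res$sweep, max_fit_residual_kT = res$fit_residual_kT)
  else
    list(type = "solvation", delta_kcal_mol = res$delta$kcal_mol,
         delta_kJ_mol = res$delta$kJ_mol, delta_kT = res$delta$kT)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
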