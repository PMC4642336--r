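#' Experiment threshold profiles
#'
#' Named presets bundling the experiment-specific threshold fractions and
#' evaluation points used in published RNAP titrations of transcription
#' factors: `"nusg-ntd"` (55 %/75 % of the mean at 1:1), `"nuse"`
#' (60 %/80 % at 1:2) and `"nusa-ntd"` (65 %/85 % at 1:1).
#'
#' @format Named list of lists with `f_strong`, `f_slight`, `point`.
#' @export
threshold_profiles <- list(
  "nusg-ntd" = list(f_strong = 0.55, f_slight = 0.75, point = "1:1"),
  "nuse"     = list(f_strong = 0.60, f_slight = 0.80, point = "1:2"),
  "nusa-ntd" = list(f_strong = 0.65, f_slight = 0.85, point = "1:1")
)

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override [binding_scenario()] and
#'   classification defaults (`profile`, `f_strong`, `f_slight`, `point`,
#'   `sasa_cutoff`, `neighbor_cutoff`, `patch_cutoff`, `seed`, plus any
#'   scenario field).
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (is.null(path)) return(list())
  yaml::read_yaml(path)
}

resolve_thresholds <- function(config) {
  prof <- threshold_profiles[[config$profile %||% "nusg-ntd"]]
  if (is.null(prof)) {
    abort(sprintf("unknown profile '%s'", config$profile),
          class = "methylmap_config_error")
  }
  list(
    f_strong = config$f_strong %||% prof$f_strong,
    f_slight = config$f_slight %||% prof$f_slight,
    point = config$point %||% prof$point
  )
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, digits = NA, pretty = TRUE, auto_unbox = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

write_provenance <- function(dir, command, config, seed) {
  write_json_atomic(
    list(command = command,
         package = "methylmap",
         version = as.character(utils::packageVersion("methylmap")),
         r_version = R.version.string,
         seed = seed,
         config = config,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "provenance.json")
  )
}

#' Generate a synthetic scenario on disk
#'
#' Writes the ligand and partner structures, the simulated peak tables, the
#' ground-truth interface and a provenance record into `out_dir`.
#'
#' @param out_dir Output directory (created).
#' @param seed Random seed.
#' @param config Named list of [binding_scenario()] overrides (or a YAML
#'   path via [read_run_config()]).
#' @return The `synthetic_titration` object, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- config[intersect(names(config), names(formals(binding_scenario)))]
  args$seed <- seed
  scenario <- do.call(binding_scenario, args)
  sim <- simulate_titration(scenario)
  write_pdb(scenario$structure, file.path(out_dir, "structure.pdb"))
  write_pdb(scenario$partner, file.path(out_dir, "partner.pdb"))
  write_titration(sim$series, out_dir)
  write_json_atomic(list(interface = sim$truth,
                         kd = scenario$kd, conc = scenario$conc,
                         lambda = scenario$lambda,
                         attenuation = scenario$attenuation,
                         sigma = scenario$sigma),
                    file.path(out_dir, "truth.json"))
  write_provenance(out_dir, "simulate", config, seed)
  invisible(sim)
}

#' Map a binding surface from titration data
#'
#' The core pipeline: normalize intensities, form relative intensities
#' against the free state, classify methyls by mean-based thresholds,
#' aggregate to residues, apply the +/-2 sequence extension, cluster
#' spatial patches, and write the classification (JSON), the annotated
#' structure (class codes in the B-factor column) and the patch report.
#' When a ground-truth file is present (synthetic runs) a recovery score is
#' computed.
#'
#' @param input_dir Directory holding `structure.pdb`, `peaks.tsv`,
#'   `points.tsv` (e.g. from [run_simulate()]).
#' @param out_dir Output directory (default: `input_dir`).
#' @param config Named list: `profile` or explicit `f_strong` / `f_slight`
#'   / `point`, `patch_cutoff` (default 5).
#' @return List with `classification` (`methyl_classification`),
#'   `residues`, `patches` (`patch_report`) and optionally `recovery`.
#' @export
run_map_surface <- function(input_dir, out_dir = input_dir,
                            config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- resolve_thresholds(config)
  atoms <- read_pdb(file.path(input_dir, "structure.pdb"))
  series <- read_titration(input_dir)
  mc <- classify_methyls(relative_intensities(series),
                         f_strong = thr$f_strong, f_slight = thr$f_slight,
                         point = thr$point)
  rc <- aggregate_residues(mc, structure_residues(atoms)) |>
    extend_classification()
  patches <- cluster_patches(rc, atoms,
                             cutoff = config$patch_cutoff %||% 5.0)
  write_json_atomic(
    list(thresholds = c(thr, list(mu = mc$mu, t_strong = mc$t_strong,
                                  t_slight = mc$t_slight)),
         summary = glance(mc), residues = rc),
    file.path(out_dir, "classification.json"))
  annotate_classification(atoms, rc, file.path(out_dir, "annotated.pdb"))
  write_patch_report(patches, file.path(out_dir, "patches.json"))

  out <- list(classification = mc, residues = rc, patches = patches)
  truth_file <- file.path(input_dir, "truth.json")
  if (file.exists(truth_file)) {
    truth <- jsonlite::read_json(truth_file, simplifyVector = TRUE)$interface
    out$recovery <- score_recovery(rc, truth)
    write_json_atomic(out$recovery, file.path(out_dir, "recovery.json"))
  }
  write_provenance(out_dir, "map-surface", config,
                   config$seed %||% NA_integer_)
  invisible(out)
}

#' Prepare docking restraints from a mapped surface
#'
#' Computes solvent accessibility, selects active (affected and exposed)
#' and passive (exposed neighbors) residues, and writes the
#' ambiguous-interaction-restraint table plus JSON selections.
#'
#' @param input_dir Directory with `structure.pdb` and a prior
#'   [run_map_surface()] output (`classification.json`).
#' @param out_dir Output directory (default: `input_dir`).
#' @param config Named list: `sasa_cutoff` (0.40), `neighbor_cutoff` (6.5),
#'   `air_bound` (2.0), `active_override` (residue numbers), and partner
#'   selections `partner_active` / `partner_passive` (residue-number
#'   vectors on `partner_chain`, default "B").
#' @return The [docking_restraint_set()], invisibly.
#' @export
run_prep_docking <- function(input_dir, out_dir = input_dir,
                             config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- read_pdb(file.path(input_dir, "structure.pdb"))
  cls <- jsonlite::read_json(file.path(input_dir, "classification.json"),
                             simplifyVector = TRUE)
  rc <- as_tibble(cls$residues)
  access <- relative_accessibility(atoms)
  sasa_cutoff <- config$sasa_cutoff %||% 0.40
  active <- select_active(rc, access, sasa_cutoff = sasa_cutoff,
                          override = config$active_override)
  passive <- select_passive(atoms, active, access,
                            neighbor_cutoff = config$neighbor_cutoff %||% 6.5,
                            sasa_cutoff = sasa_cutoff)
  pchain <- config$partner_chain %||% "B"
  as_partner <- function(x) {
    if (is.null(x)) NULL else tibble(chain = pchain, resno = as.integer(x))
  }
  set <- docking_restraint_set(
    active, passive,
    partner_active = as_partner(config$partner_active),
    partner_passive = as_partner(config$partner_passive),
    bound = config$air_bound %||% 2.0
  )
  write_docking_json(set, file.path(out_dir, "docking.json"))
  if (nrow(set$active) > 0 &&
      nrow(set$partner_active) + nrow(set$partner_passive) > 0) {
    write_air_table(set, file.path(out_dir, "air.tbl"))
  }
  write_provenance(out_dir, "prep-docking", config,
                   config$seed %||% NA_integer_)
  invisible(set)
}

#' Generate NOE restraints from a structure
#'
#' Simulates classified NOE cross peaks from the structure's own distances
#' and converts them to distance restraints (satisfied by construction on
#' the source structure); writes the `.tbl` file and a tally report.
#'
#' @param structure_file Path to the source PDB file.
#' @param out_dir Output directory.
#' @param config Named list: `cutoff` (5.5), `lower` (1.8).
#' @return List with `restraints` and `tally`, invisibly.
#' @export
run_gen_restraints <- function(structure_file, out_dir, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- read_pdb(structure_file)
  peaks <- simulate_noe_peaks(atoms, cutoff = config$cutoff %||% 5.5)
  restraints <- noe_restraints(peaks, lower = config$lower %||% 1.8)
  write_tbl(restraints, file.path(out_dir, "restraints.tbl"))
  tally <- restraint_tally(restraints)
  write_json_atomic(tally, file.path(out_dir, "tally.json"))
  write_provenance(out_dir, "gen-restraints", config,
                   config$seed %||% NA_integer_)
  invisible(list(restraints = restraints, tally = tally))
}

#' Validate an ensemble against restraints
#'
#' Runs [violation_stats()] and [ensemble_precision()] on a multi-model
#' structure and writes the combined report.
#'
#' @param ensemble_file Path to a multi-model PDB file.
#' @param restraints_file Path to a `.tbl` restraint file.
#' @param out_dir Output directory.
#' @param config Named list: `resno_range` (c(first, last)), `atom_set`
#'   ("backbone" or "heavy").
#' @return List with `violations` (`restraint_validation`) and `precision`,
#'   invisibly.
#' @export
run_validate_ensemble <- function(ensemble_file, restraints_file, out_dir,
                                  config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- read_pdb(ensemble_file)
  restraints <- read_tbl(restraints_file)
  violations <- violation_stats(atoms, restraints)
  range <- if (is.null(config$resno_range)) NULL else
    as.integer(config$resno_range)
  precision <- if (length(unique(atoms$model)) >= 2) {
    ensemble_precision(atoms, resno_range = range,
                       atom_set = config$atom_set %||% "backbone")
  } else {
    NULL
  }
  write_json_atomic(list(violations = glance(violations),
                         precision = precision),
                    file.path(out_dir, "validation.json"))
  write_provenance(out_dir, "validate-ensemble", config,
                   config$seed %||% NA_integer_)
  invisible(list(violations = violations, precision = precision))
}
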