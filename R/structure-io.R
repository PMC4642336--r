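#' Read a macromolecular structure from PDB format
#'
#' Parses PDB-format coordinates (single model or MODEL/ENDMDL ensemble) into
#' a tidy atom table with one row per atom per model. HETATM records,
#' hydrogens and alternate locations are retained but flagged; for alternate
#' locations only the highest-occupancy conformer of each atom is kept.
#'
#' @param file Path to a PDB file, or a character vector of PDB-format lines
#'   (anything containing a newline or more than one element is treated as
#'   raw text).
#' @return A `pdb_atoms` tibble with columns `model`, `chain`, `resno`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`, `b`, `het`,
#'   `hydrogen`.
#' @details All models of an ensemble must contain the identical set of
#'   (chain, residue number, atom name) keys; a mismatch raises an
#'   ensemble-consistency error. Malformed coordinate fields raise a parse
#'   error naming the offending line. Blank chain identifiers are assigned
#'   chain "A".
#' @examples
#' pdb <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
#'   "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
#'   "END")
#' read_pdb(pdb)
#' @export
read_pdb <- function(file) {
  lines <- if (length(file) > 1L || grepl("\n", file[1], fixed = TRUE)) {
    unlist(strsplit(file, "\n", fixed = TRUE))
  } else {
    readLines(file, warn = FALSE)
  }
  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_coord)) {
    abort("no ATOM/HETATM records found", class = "methylmap_parse_error")
  }
  check_coordinate_fields(lines, which(is_coord))

  blocks <- split_models(lines)
  models <- purrr::imap(blocks, function(block, i) {
    parse_model_block(block) |> mutate(model = as.integer(i), .before = 1)
  })
  atoms <- bind_rows(models)
  check_ensemble_consistency(atoms)
  check_residue_order(atoms)
  new_pdb_atoms(atoms)
}

# Malformed x/y/z fields (columns 31-54) fail early with the line number.
check_coordinate_fields <- function(lines, idx) {
  for (i in idx) {
    for (start in c(31L, 39L, 47L)) {
      field <- substr(lines[i], start, start + 7L)
      if (is.na(suppressWarnings(as.numeric(field)))) {
        abort(
          sprintf("malformed coordinate field at line %d: '%s'", i, lines[i]),
          class = "methylmap_parse_error"
        )
      }
    }
  }
  invisible(NULL)
}

split_models <- function(lines) {
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) == 0L) return(list(lines))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    abort("unbalanced MODEL/ENDMDL records", class = "methylmap_parse_error")
  }
  purrr::map2(model_starts, model_ends, function(s, e) lines[seq(s + 1L, e - 1L)])
}

# One MODEL block -> atom tibble; record-level parsing delegated to bio3d.
parse_model_block <- function(block) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(block, "END"), tf)
  pdb <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- guess_element(at$elety[missing_el])
  out <- tibble(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    resname = at$resid,
    atom = at$elety,
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    het = at$type == "HETATM",
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("non-finite coordinates after parsing", class = "methylmap_parse_error")
  }
  # Alternate locations: keep the highest-occupancy conformer per atom key,
  # preserving the original record order.
  out |>
    mutate(rec_order = row_number()) |>
    group_by(.data$chain, .data$resno, .data$atom) |>
    mutate(best_alt = .data$rec_order ==
             .data$rec_order[order(-.data$occ, .data$altloc)][1]) |>
    ungroup() |>
    filter(.data$best_alt) |>
    arrange(.data$rec_order) |>
    mutate(
      hydrogen = .data$element %in% c("H", "D"),
      altloc = NULL, rec_order = NULL, best_alt = NULL
    )
}

# Element from the atom-name column when the element column is absent:
# first alphabetic character, except the H of 2-character digit-led names
# (e.g. "1HB2") and standard heteroatom-led names.
guess_element <- function(elety) {
  nm <- gsub("[0-9']", "", elety)
  toupper(substr(nm, 1, 1))
}

check_ensemble_consistency <- function(atoms) {
  keys <- atoms |>
    group_by(.data$model) |>
    summarise(key = paste(sort(paste(.data$chain, .data$resno, .data$atom)),
                          collapse = ";"))
  if (length(unique(keys$key)) != 1L) {
    abort(
      "models do not share an identical (chain, residue, atom) set",
      class = "methylmap_ensemble_error"
    )
  }
  invisible(NULL)
}

check_residue_order <- function(atoms) {
  bad <- atoms |>
    filter(!.data$het, .data$model == .data$model[1]) |>
    group_by(.data$chain) |>
    summarise(ok = all(diff(rle(.data$resno)$values) > 0))
  if (!all(bad$ok)) {
    abort(
      sprintf("residue numbers not strictly increasing in chain(s): %s",
              paste(bad$chain[!bad$ok], collapse = ", ")),
      class = "methylmap_parse_error"
    )
  }
  invisible(NULL)
}

new_pdb_atoms <- function(x) {
  stopifnot(is.data.frame(x))
  class(x) <- unique(c("pdb_atoms", class(as_tibble(x))))
  x
}

#' Coerce an atom table to `pdb_atoms`
#'
#' Validates the column contract of [read_pdb()] on a plain data frame
#' (useful for programmatically built structures).
#'
#' @param x Data frame with at least `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z`; missing `model`, `occ`, `b`, `het`, `hydrogen`, `element`
#'   columns are filled with defaults.
#' @return A `pdb_atoms` tibble.
#' @export
as_pdb_atoms <- function(x) {
  x <- as_tibble(x)
  required <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (!"model" %in% names(x)) x$model <- 1L
  if (!"element" %in% names(x)) x$element <- guess_element(x$atom)
  if (!"occ" %in% names(x)) x$occ <- 1
  if (!"b" %in% names(x)) x$b <- 0
  if (!"het" %in% names(x)) x$het <- FALSE
  if (!"hydrogen" %in% names(x)) x$hydrogen <- x$element %in% c("H", "D")
  x$resno <- as.integer(x$resno)
  x$model <- as.integer(x$model)
  if (any(!is.finite(x$x) | !is.finite(x$y) | !is.finite(x$z))) {
    abort("non-finite coordinates", class = "methylmap_parse_error")
  }
  new_pdb_atoms(x[c("model", "chain", "resno", "resname", "atom", "element",
                    "x", "y", "z", "occ", "b", "het", "hydrogen")])
}

#' Write a structure to PDB format
#'
#' Inverse of [read_pdb()]: coordinates survive a write/read cycle to the
#' fixed-format precision (3 decimals). Multi-model tables are written as
#' MODEL/ENDMDL blocks.
#'
#' @param atoms A `pdb_atoms` tibble (or data frame coercible via
#'   [as_pdb_atoms()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(atoms, file) {
  atoms <- as_pdb_atoms(atoms)
  m1 <- atoms |> filter(.data$model == .data$model[1])
  xyz <- atoms |>
    arrange(.data$model) |>
    group_by(.data$model) |>
    summarise(xyz = list(as.vector(rbind(.data$x, .data$y, .data$z)))) |>
    pull(.data$xyz)
  xyz <- do.call(rbind, xyz)
  bio3d::write.pdb(
    file = file, xyz = xyz,
    type = ifelse(m1$het, "HETATM", "ATOM"),
    resno = m1$resno, resid = m1$resname, eleno = seq_len(nrow(m1)),
    elety = m1$atom, chain = m1$chain, o = m1$occ, b = m1$b,
    elesy = m1$element, verbose = FALSE
  )
  invisible(file)
}

#' Unique residues of a structure
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param model Model number to take residues from (default: first).
#' @param het Include HETATM residues? Default `FALSE`.
#' @return Tibble with `chain`, `resno`, `resname`, ordered by chain and
#'   residue number.
#' @export
structure_residues <- function(atoms, model = NULL, het = FALSE) {
  atoms <- as_pdb_atoms(atoms)
  model <- model %||% min(atoms$model)
  keep_het <- het
  atoms |>
    filter(.data$model == !!model, keep_het | !.data$het) |>
    distinct(.data$chain, .data$resno, .data$resname) |>
    arrange(.data$chain, .data$resno)
}

#' Encode a residue classification in the B-factor column
#'
#' Writes the structure with the per-atom B-factor replaced by a class code,
#' realizing the colored-surface view of a titration analysis as a PDB file
#' loadable in any viewer: strong = 4, slight = 3, extension = 2,
#' unaffected = 1, no-data = 0.
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param classification A residue classification tibble (see
#'   [aggregate_residues()]), with optional logical `extension` column.
#' @param file Optional output path; when `NULL` the annotated PDB text is
#'   returned as a character vector.
#' @return The PDB text (invisibly when `file` is given).
#' @export
annotate_classification <- function(atoms, classification, file = NULL) {
  atoms <- as_pdb_atoms(atoms)
  cls <- as_tibble(classification)
  res <- structure_residues(atoms, het = TRUE)
  orphan <- anti_join(cls, res, by = c("chain", "resno"))
  if (nrow(orphan) > 0) {
    abort(
      sprintf("classification references residues absent from structure: %s",
              paste(paste0(orphan$chain, orphan$resno), collapse = ", ")),
      class = "methylmap_annotation_error"
    )
  }
  if (!"extension" %in% names(cls)) cls$extension <- FALSE
  cls$code <- dplyr::case_when(
    cls$class == "strong" ~ 4,
    cls$class == "slight" ~ 3,
    cls$extension ~ 2,
    cls$class == "unaffected" ~ 1,
    .default = 0
  )
  out <- atoms |>
    left_join(cls |> select("chain", "resno", "code"),
              by = c("chain", "resno")) |>
    mutate(b = ifelse(is.na(.data$code), 0, .data$code), code = NULL)
  tf <- file %||% tempfile(fileext = ".pdb")
  write_pdb(out, tf)
  if (is.null(file)) {
    txt <- readLines(tf)
    unlink(tf)
    txt
  } else {
    invisible(readLines(tf))
  }
}
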