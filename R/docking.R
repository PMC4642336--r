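#' Select active residues for data-driven docking
#'
#' Active residues are those experimentally affected by partner binding
#' (class strong or slight; extension-flagged residues do not qualify) that
#' are also solvent exposed (relative SASA at or above the cutoff). An
#' explicit residue list overrides the automatic selection, mirroring the
#' common practice of naming actives directly.
#'
#' @param rc Residue classification tibble.
#' @param access Accessibility tibble from [relative_accessibility()].
#' @param sasa_cutoff Relative-SASA exposure cutoff (default 0.40).
#' @param override Optional tibble (`chain`, `resno`) or integer vector of
#'   residue numbers (chain taken from `rc`) emitted verbatim as actives.
#' @return Tibble `chain`, `resno`, ordered by residue number; may be empty
#'   (with a warning).
#' @export
select_active <- function(rc, access, sasa_cutoff = 0.40, override = NULL) {
  if (!is.null(override)) {
    if (is.numeric(override)) {
      override <- tibble(chain = unique(as_tibble(rc)$chain)[1],
                         resno = as.integer(override))
    }
    return(as_tibble(override)[, c("chain", "resno")] |>
             arrange(.data$chain, .data$resno))
  }
  rc <- as_tibble(rc)
  out <- rc |>
    filter(.data$class %in% c("strong", "slight")) |>
    inner_join(as_tibble(access) |> select("chain", "resno", "rel_sasa"),
               by = c("chain", "resno")) |>
    filter(!is.na(.data$rel_sasa), .data$rel_sasa >= sasa_cutoff) |>
    select("chain", "resno") |>
    arrange(.data$chain, .data$resno)
  if (nrow(out) == 0) warn("no active residues selected")
  out
}

#' Select passive residues around the actives
#'
#' Reimplements the automatic passive selection used by data-driven docking
#' servers: solvent-exposed residues with any heavy atom within
#' `neighbor_cutoff` of any active residue's heavy atoms, excluding the
#' actives themselves.
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param actives Active residue tibble (`chain`, `resno`).
#' @param access Accessibility tibble from [relative_accessibility()].
#' @param neighbor_cutoff Heavy-atom distance cutoff in Angstroms
#'   (default 6.5).
#' @param sasa_cutoff Relative-SASA exposure cutoff (default 0.40).
#' @param model Model used for coordinates (default: first).
#' @return Tibble `chain`, `resno`; disjoint from `actives`.
#' @export
select_passive <- function(atoms, actives, access, neighbor_cutoff = 6.5,
                           sasa_cutoff = 0.40, model = NULL) {
  atoms <- as_pdb_atoms(atoms)
  actives <- as_tibble(actives)
  model <- model %||% min(atoms$model)
  heavy <- atoms |> filter(.data$model == !!model, !.data$hydrogen, !.data$het)
  axyz <- heavy |> semi_join(actives, by = c("chain", "resno"))
  if (nrow(axyz) == 0) return(tibble(chain = character(), resno = integer()))
  A <- as.matrix(axyz[, c("x", "y", "z")])
  cand <- heavy |>
    anti_join(actives, by = c("chain", "resno")) |>
    inner_join(as_tibble(access) |> select("chain", "resno", "rel_sasa"),
               by = c("chain", "resno")) |>
    filter(!is.na(.data$rel_sasa), .data$rel_sasa >= sasa_cutoff)
  if (nrow(cand) == 0) return(tibble(chain = character(), resno = integer()))
  B <- as.matrix(cand[, c("x", "y", "z")])
  d2 <- outer(rowSums(B^2), rowSums(A^2), "+") - 2 * B %*% t(A)
  near <- apply(d2, 1, min) <= neighbor_cutoff^2
  cand[near, ] |>
    distinct(.data$chain, .data$resno) |>
    arrange(.data$chain, .data$resno)
}

#' Bundle active/passive selections into a docking restraint set
#'
#' @param active,passive Ligand-side residue tibbles (`chain`, `resno`).
#' @param partner_active,partner_passive Partner-side residue tibbles.
#' @param bound Effective-distance upper bound for the ambiguous restraints
#'   in Angstroms (default 2.0).
#' @return A `docking_restraint_set` (validated list).
#' @export
docking_restraint_set <- function(active, passive = NULL,
                                  partner_active = NULL,
                                  partner_passive = NULL, bound = 2.0) {
  norm <- function(x) {
    if (is.null(x)) return(tibble(chain = character(), resno = integer()))
    as_tibble(x)[, c("chain", "resno")] |>
      mutate(resno = as.integer(.data$resno)) |>
      distinct()
  }
  set <- list(active = norm(active), passive = norm(passive),
              partner_active = norm(partner_active),
              partner_passive = norm(partner_passive), bound = bound)
  if (nrow(inner_join(set$active, set$passive, by = c("chain", "resno")))) {
    abort("active and passive residue sets must be disjoint")
  }
  if (nrow(inner_join(set$partner_active, set$partner_passive,
                      by = c("chain", "resno")))) {
    abort("partner active and passive residue sets must be disjoint")
  }
  structure(set, class = "docking_restraint_set")
}

#' @export
print.docking_restraint_set <- function(x, ...) {
  cat(sprintf(
    "<docking_restraint_set> %d active / %d passive vs partner %d active / %d passive, bound %.1f A\n",
    nrow(x$active), nrow(x$passive), nrow(x$partner_active),
    nrow(x$partner_passive), x$bound))
  invisible(x)
}

#' Write an ambiguous-interaction-restraint table
#'
#' One ambiguous restraint per ligand active residue against the union of
#' the partner's active and passive residues: any atom of the active
#' residue is restrained to an r^-6 effective distance of at most `bound`
#' from any atom of the partner set, written as CNS-dialect assign
#' statements with an OR group.
#'
#' @param set A [docking_restraint_set()] with at least one active residue
#'   and a non-empty partner selection.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_air_table <- function(set, file) {
  stopifnot(inherits(set, "docking_restraint_set"))
  if (nrow(set$active) == 0) {
    abort("at least one active residue is required",
          class = "methylmap_config_error")
  }
  partner <- bind_rows(set$partner_active, set$partner_passive) |> distinct()
  if (nrow(partner) == 0) {
    abort("partner active/passive selection is empty",
          class = "methylmap_config_error")
  }
  or_group <- paste0(
    "(",
    paste(sprintf("(resid %d and segid %s)", partner$resno, partner$chain),
          collapse = " or "),
    ")"
  )
  lines <- sprintf("assign (resid %d and segid %s) %s %.1f %.1f %.1f",
                   set$active$resno, set$active$chain, or_group,
                   set$bound, set$bound, 0)
  writeLines(lines, file)
  invisible(file)
}

#' Read an ambiguous-interaction-restraint table
#'
#' Inverse of [write_air_table()].
#'
#' @param file Path to the `.tbl` file.
#' @return List with `$active` (one row per top-level restraint: `chain`,
#'   `resno`, `lower`, `upper`) and `$partners` (per restraint `id`, the
#'   alternative residues of the OR group).
#' @export
read_air_table <- function(file) {
  stmts <- split_assigns(readLines(file, warn = FALSE))
  active <- list()
  partners <- list()
  for (i in seq_along(stmts)) {
    parsed <- top_level_groups(stmts[i])
    s1 <- parse_selection_group(parsed$groups[1])
    s2 <- parse_selection_group(parsed$groups[2])
    d <- parsed$numbers
    active[[i]] <- tibble(id = i, chain = s1$chain, resno = s1$resno,
                          lower = d[1] - d[2], upper = d[1] + d[3])
    partners[[i]] <- s2 |> mutate(id = i, .before = 1) |> select(-"atom")
  }
  list(active = bind_rows(active), partners = bind_rows(partners))
}

#' Serialize active/passive selections as JSON
#'
#' @param set A [docking_restraint_set()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_docking_json <- function(set, file) {
  stopifnot(inherits(set, "docking_restraint_set"))
  jsonlite::write_json(unclass(set), file, digits = NA, pretty = TRUE)
  invisible(file)
}
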