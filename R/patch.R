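#' Extend affected residues along the sequence (the +/-2 rule)
#'
#' Methyl mapping only reports on Ile/Leu/Val residues, so the displayed
#' interaction surface is extended by the two residues preceding and
#' following each affected Ile/Leu/Val residue - unless a neighbor is
#' itself an Ile/Leu/Val classified unaffected, in which case it stays
#' unflagged. Extension residues never seed further extension, and an
#' extension never downgrades a residue already classified strong or
#' slight.
#'
#' @param rc Residue classification tibble from [aggregate_residues()].
#' @param include_no_data_ilv Should Ile/Leu/Val neighbors without data
#'   (unassigned/excluded probes) receive the extension flag? Default
#'   `TRUE`: only *unaffected* ILV neighbors are excluded.
#' @return `rc` with the `extension` flag set and `provenance` recording the
#'   seeding residue for pure extensions.
#' @export
extend_classification <- function(rc, include_no_data_ilv = TRUE) {
  rc <- as_tibble(rc) |> arrange(.data$chain, .data$resno)
  rc$extension <- FALSE
  ext_origin <- rep(NA_integer_, nrow(rc))
  ilv <- c("ILE", "LEU", "VAL")
  affected <- which(rc$class %in% c("strong", "slight"))
  for (i in affected) {
    for (off in c(-2L, -1L, 1L, 2L)) {
      j <- which(rc$chain == rc$chain[i] & rc$resno == rc$resno[i] + off)
      if (length(j) != 1L) next             # outside the chain
      if (rc$class[j] %in% c("strong", "slight")) next
      is_ilv <- rc$resname[j] %in% ilv
      if (is_ilv && rc$class[j] == "unaffected") next
      if (is_ilv && rc$class[j] == "no-data" && !include_no_data_ilv) next
      rc$extension[j] <- TRUE
      if (is.na(ext_origin[j])) ext_origin[j] <- rc$resno[i]
    }
  }
  rc |>
    mutate(provenance = ifelse(.data$extension & .data$provenance == "",
                               paste0("ext:", ext_origin), .data$provenance))
}

#' Cluster affected residues into spatial patches
#'
#' Groups the flagged residues (strong, slight or extension) into patches by
#' single-linkage clustering on the minimal heavy-atom distance between
#' residues: two residues join the same patch when any of their heavy atoms
#' are within `cutoff` of each other, directly or through a chain of such
#' contacts. Patches are numbered by decreasing size.
#'
#' @param rc Residue classification tibble (after
#'   [extend_classification()]; plain classifications work too).
#' @param atoms A `pdb_atoms` tibble providing coordinates.
#' @param cutoff Single-linkage distance cutoff in Angstroms (default 5.0).
#' @param model Model used for coordinates (default: first).
#' @return A `patch_report`: list with `$residues` (flagged residues plus
#'   `patch` id) and `$patches` (per-patch size and centroid).
#' @export
cluster_patches <- function(rc, atoms, cutoff = 5.0, model = NULL) {
  rc <- as_tibble(rc)
  atoms <- as_pdb_atoms(atoms)
  model <- model %||% min(atoms$model)
  flagged <- rc |>
    filter(.data$class %in% c("strong", "slight") | .data$extension)
  empty <- list(
    residues = flagged[0, ] |> mutate(patch = integer(0)),
    patches = tibble(patch = integer(0), n_residues = integer(0),
                     x = double(0), y = double(0), z = double(0))
  )
  if (nrow(flagged) == 0) return(structure(empty, class = "patch_report"))

  heavy <- atoms |>
    filter(.data$model == !!model, !.data$hydrogen, !.data$het) |>
    semi_join(flagged, by = c("chain", "resno"))
  have_coords <- heavy |> distinct(.data$chain, .data$resno)
  dropped <- anti_join(flagged, have_coords, by = c("chain", "resno"))
  if (nrow(dropped) > 0) {
    warn(sprintf("flagged residues without coordinates excluded: %s",
                 paste(paste0(dropped$chain, dropped$resno), collapse = ", ")))
    flagged <- semi_join(flagged, have_coords, by = c("chain", "resno"))
  }
  if (nrow(flagged) == 0) return(structure(empty, class = "patch_report"))

  key <- paste(flagged$chain, flagged$resno)
  akey <- paste(heavy$chain, heavy$resno)
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  n <- nrow(flagged)
  dmin <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    pa <- xyz[akey == key[a], , drop = FALSE]
    pb <- xyz[akey == key[b], , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    dmin[a, b] <- dmin[b, a] <- sqrt(max(0, min(d2)))
  }
  membership <- if (n == 1L) {
    1L
  } else {
    cutree(hclust(as.dist(dmin), method = "single"), h = cutoff)
  }
  # renumber patches by decreasing size, ties by first residue
  sizes <- sort(table(membership), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  flagged$patch <- unname(relabel[as.character(membership)])

  centroids <- heavy |>
    left_join(flagged |> select("chain", "resno", "patch"),
              by = c("chain", "resno")) |>
    group_by(.data$patch) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
  patches <- flagged |>
    count(.data$patch, name = "n_residues") |>
    left_join(centroids, by = "patch") |>
    arrange(.data$patch)
  structure(list(residues = flagged |> arrange(.data$patch, .data$resno),
                 patches = patches),
            class = "patch_report")
}

#' @export
print.patch_report <- function(x, ...) {
  cat("<patch_report>", nrow(x$patches), "patch(es),",
      nrow(x$residues), "flagged residues\n")
  print(x$patches)
  invisible(x)
}

#' @describeIn cluster_patches Flagged residues with patch membership.
#' @param x A `patch_report`.
#' @param ... Unused.
#' @export
tidy.patch_report <- function(x, ...) x$residues

#' @describeIn cluster_patches One row per patch (size, centroid).
#' @export
glance.patch_report <- function(x, ...) x$patches

#' Serialize a patch report to JSON
#'
#' @param report A `patch_report`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_patch_report <- function(report, file) {
  stopifnot(inherits(report, "patch_report"))
  jsonlite::write_json(
    list(residues = report$residues, patches = report$patches),
    file, digits = NA, pretty = TRUE
  )
  invisible(file)
}
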