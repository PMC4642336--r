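#' Assemble a methyl titration series
#'
#' Bundles the per-point methyl peak tables with the titration metadata
#' (molar ratio of unlabeled partner to labeled protein, labeled-protein
#' concentration, number of scans). The free state is the point with molar
#' ratio 0.
#'
#' @param peaks Tibble with columns `point` (label, e.g. "free", "1:1"),
#'   `chain`, `resno`, `resname`, `site`, `assignment` (one of
#'   "unambiguous", "ambiguous", "unassigned") and `intensity` (raw
#'   spectrometer units, >= 0).
#' @param points Tibble with columns `point`, `ratio` (partner:labeled,
#'   dimensionless), `conc` (labeled-protein concentration, micromolar) and
#'   `scans` (integer >= 1).
#' @return A `titration_series` object (list of the two validated tibbles).
#' @export
titration_series <- function(peaks, points) {
  peaks <- as_tibble(peaks)
  points <- as_tibble(points)
  need_peaks <- c("point", "chain", "resno", "resname", "site",
                  "assignment", "intensity")
  need_points <- c("point", "ratio", "conc", "scans")
  if (length(miss <- setdiff(need_peaks, names(peaks)))) {
    abort(paste("peaks missing columns:", paste(miss, collapse = ", ")))
  }
  if (length(miss <- setdiff(need_points, names(points)))) {
    abort(paste("points missing columns:", paste(miss, collapse = ", ")))
  }
  if (any(peaks$intensity < 0, na.rm = TRUE)) {
    abort("raw intensities must be >= 0")
  }
  if (!all(peaks$assignment %in% c("unambiguous", "ambiguous", "unassigned"))) {
    abort("assignment must be unambiguous, ambiguous or unassigned")
  }
  if (!all(peaks$point %in% points$point)) {
    abort("every peak must belong to a declared titration point")
  }
  if (any(points$conc <= 0) || any(points$scans < 1)) {
    abort("concentration must be > 0 and scans >= 1",
          class = "methylmap_config_error")
  }
  if (!any(points$ratio == 0)) {
    abort("a free point (ratio 0) is required")
  }
  structure(list(peaks = peaks, points = points), class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series>", nrow(x$points), "points,",
      nrow(x$peaks), "peak records\n")
  print(x$points)
  invisible(x)
}

free_point_label <- function(series) {
  series$points$point[series$points$ratio == 0][1]
}

#' Normalize peak intensities by concentration and scan number
#'
#' Divides each raw intensity by (labeled-protein concentration x number of
#' scans) of its titration point, making intensities comparable across
#' points recorded with different sample concentrations or scan counts.
#'
#' @param series A [titration_series()].
#' @return The series with a `norm` column added to `$peaks`; record order
#'   is preserved.
#' @export
normalize_intensities <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  series$peaks <- series$peaks |>
    left_join(series$points |> select("point", "conc", "scans"),
              by = "point") |>
    mutate(norm = .data$intensity / (.data$conc * .data$scans),
           conc = NULL, scans = NULL)
  series
}

#' Relative intensities against the free state
#'
#' For every non-free titration point, forms r_i = I_norm(point) /
#' I_norm(free) per methyl probe, matching probes by (chain, residue, site).
#' Probes that are not unambiguously assigned, are missing in either
#' spectrum, or have zero/missing free-state intensity are marked excluded
#' with a reason; they never enter downstream means.
#'
#' @param series A normalized [titration_series()] (see
#'   [normalize_intensities()]; normalization is applied on the fly if the
#'   `norm` column is absent).
#' @return Tibble with `point`, `chain`, `resno`, `resname`, `site`,
#'   `assignment`, `r`, `excluded`, `reason`.
#' @export
relative_intensities <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (!"norm" %in% names(series$peaks)) series <- normalize_intensities(series)
  free_label <- free_point_label(series)
  key <- c("chain", "resno", "resname", "site")
  free <- series$peaks |>
    filter(.data$point == free_label) |>
    select(dplyr::all_of(key), free_norm = "norm",
           free_assignment = "assignment")
  series$peaks |>
    filter(.data$point != free_label) |>
    left_join(free, by = key) |>
    mutate(
      r = ifelse(!is.na(.data$free_norm) & .data$free_norm > 0,
                 .data$norm / .data$free_norm, NA_real_),
      reason = dplyr::case_when(
        .data$assignment != "unambiguous" ~ "not unambiguously assigned",
        is.na(.data$free_norm) ~ "missing in free spectrum",
        .data$free_norm <= 0 ~ "zero free-state intensity",
        is.na(.data$norm) ~ "missing at titration point",
        .default = NA_character_
      ),
      excluded = !is.na(.data$reason)
    ) |>
    select("point", dplyr::all_of(key), "assignment", "r",
           "excluded", "reason")
}

#' Classify methyl groups by mean-based intensity thresholds
#'
#' At one evaluation point, computes the mean mu of the relative intensities
#' of all included (unambiguous, finite) probes and classifies each included
#' probe against experiment-specific fractions of that mean:
#' strong if r < f_strong * mu, slight if f_strong * mu <= r < f_slight * mu,
#' unaffected otherwise. Ties at a threshold fall into the milder class.
#' Excluded probes keep class "excluded" and never contribute to mu.
#'
#' @param rel Relative-intensity tibble from [relative_intensities()], or a
#'   [titration_series()] (converted on the fly).
#' @param f_strong,f_slight Threshold fractions of the mean relative
#'   intensity, 0 < f_strong < f_slight < 1 (e.g. 0.55 / 0.75).
#' @param point Evaluation point label; defaults to the only non-free point,
#'   otherwise must be given.
#' @return A `methyl_classification` object; see [tidy.methyl_classification()]
#'   and [glance.methyl_classification()].
#' @examples
#' rel <- tibble::tibble(
#'   point = "1:1", chain = "A", resno = 1:4, resname = "ILE", site = "CD1",
#'   assignment = "unambiguous", r = c(1, 1, 1, 0.4),
#'   excluded = FALSE, reason = NA_character_)
#' classify_methyls(rel, 0.55, 0.75)
#' @export
classify_methyls <- function(rel, f_strong = 0.55, f_slight = 0.75,
                             point = NULL) {
  if (inherits(rel, "titration_series")) rel <- relative_intensities(rel)
  if (!(f_strong > 0 && f_strong < f_slight && f_slight < 1)) {
    abort("need 0 < f_strong < f_slight < 1",
          class = "methylmap_config_error")
  }
  pts <- unique(rel$point)
  if (is.null(point)) {
    if (length(pts) != 1L) {
      abort("several titration points present; specify `point`",
            class = "methylmap_config_error")
    }
    point <- pts
  }
  if (!point %in% pts) {
    abort(sprintf("point '%s' not found in relative intensities", point),
          class = "methylmap_config_error")
  }
  probes <- rel |>
    filter(.data$point == !!point) |>
    mutate(included = !.data$excluded & is.finite(.data$r))
  n_inc <- sum(probes$included)
  if (n_inc < 3) {
    abort(sprintf(
      "only %d included probes at point '%s'; need >= 3 for a stable mean",
      n_inc, point), class = "methylmap_analysis_error")
  }
  mu <- mean(probes$r[probes$included])
  t_strong <- f_strong * mu
  t_slight <- f_slight * mu
  probes <- probes |>
    mutate(class = dplyr::case_when(
      !.data$included ~ "excluded",
      .data$r < t_strong ~ "strong",
      .data$r < t_slight ~ "slight",
      .default = "unaffected"
    ), included = NULL)
  structure(
    list(probes = probes, mu = mu, t_strong = t_strong, t_slight = t_slight,
         f_strong = f_strong, f_slight = f_slight, point = point),
    class = "methyl_classification"
  )
}

#' @export
print.methyl_classification <- function(x, ...) {
  cat(sprintf(
    "<methyl_classification> point %s: mean r = %.3f, thresholds %.3f (strong) / %.3f (slight)\n",
    x$point, x$mu, x$t_strong, x$t_slight))
  print(table(x$probes$class))
  invisible(x)
}

#' @describeIn classify_methyls Per-probe tibble with the assigned class.
#' @param x A `methyl_classification` object.
#' @param ... Unused.
#' @export
tidy.methyl_classification <- function(x, ...) {
  x$probes
}

#' @describeIn classify_methyls One-row summary (mean, thresholds, class
#'   counts).
#' @export
glance.methyl_classification <- function(x, ...) {
  cl <- x$probes$class
  tibble(
    point = x$point, n_probes = length(cl),
    n_included = sum(cl != "excluded"), n_excluded = sum(cl == "excluded"),
    mu = x$mu, t_strong = x$t_strong, t_slight = x$t_slight,
    n_strong = sum(cl == "strong"), n_slight = sum(cl == "slight"),
    n_unaffected = sum(cl == "unaffected")
  )
}

residue_class_levels <- c("strong", "slight", "unaffected", "no-data")

#' Aggregate methyl classes to residue level
#'
#' A residue takes the most severe class among its methyl probes (strong >
#' slight > unaffected), so a Leu or Val counts as affected when at least
#' one of its two signals shows a significant decrease. Residues whose
#' probes are all excluded, and residues without probes (non-Ile/Leu/Val),
#' are "no-data".
#'
#' @param mc A `methyl_classification` from [classify_methyls()].
#' @param residues Residue tibble (`chain`, `resno`, `resname`) covering the
#'   full sequence, e.g. from [structure_residues()].
#' @return Residue classification tibble: `chain`, `resno`, `resname`,
#'   `class` (factor strong/slight/unaffected/no-data), `extension`
#'   (all `FALSE`; set by [extend_classification()]) and `provenance`
#'   (probe sites that determined the class).
#' @export
aggregate_residues <- function(mc, residues) {
  stopifnot(inherits(mc, "methyl_classification"))
  residues <- as_tibble(residues)[, c("chain", "resno", "resname")]
  severity <- c(strong = 1, slight = 2, unaffected = 3)
  per_res <- mc$probes |>
    filter(.data$class != "excluded") |>
    group_by(.data$chain, .data$resno) |>
    summarise(
      class = names(severity)[min(severity[.data$class])],
      provenance = paste(.data$site[severity[.data$class] ==
                                      min(severity[.data$class])],
                         collapse = ","),
      .groups = "drop"
    )
  residues |>
    left_join(per_res, by = c("chain", "resno")) |>
    mutate(
      class = factor(ifelse(is.na(.data$class), "no-data", .data$class),
                     levels = residue_class_levels),
      extension = FALSE,
      provenance = ifelse(is.na(.data$provenance), "", .data$provenance)
    ) |>
    arrange(.data$chain, .data$resno)
}

#' Read and write the native peak-table format
#'
#' The native on-disk form of a titration series is a pair of tab-separated
#' tables: `peaks.tsv` (one row per peak per point) and `points.tsv`
#' (titration metadata).
#'
#' @param series A [titration_series()].
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_titration()` returns `dir` invisibly; `read_titration()`
#'   returns a [titration_series()].
#' @export
write_titration <- function(series, dir) {
  stopifnot(inherits(series, "titration_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(series$peaks, file.path(dir, "peaks.tsv"))
  readr::write_tsv(series$points, file.path(dir, "points.tsv"))
  invisible(dir)
}

#' @rdname write_titration
#' @export
read_titration <- function(dir) {
  peaks <- readr::read_tsv(file.path(dir, "peaks.tsv"),
                           show_col_types = FALSE)
  points <- readr::read_tsv(file.path(dir, "points.tsv"),
                            show_col_types = FALSE)
  titration_series(peaks, points)
}
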