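#' NOE intensity class to upper distance bound
#'
#' Converts NOESY cross-peak intensity classes to the upper distance limits
#' used for structure calculation: strong 3.0 A, medium 4.0 A, weak 5.0 A,
#' very weak 6.0 A.
#'
#' @param class Character vector of class labels ("strong", "medium",
#'   "weak", "very weak").
#' @return Numeric vector of upper bounds in Angstroms.
#' @export
noe_upper_bound <- function(class) {
  bounds <- c("strong" = 3.0, "medium" = 4.0, "weak" = 5.0, "very weak" = 6.0)
  bad <- setdiff(unique(class), names(bounds))
  if (length(bad)) {
    abort(sprintf("unknown NOE class label(s): %s", paste(bad, collapse = ", ")))
  }
  unname(bounds[class])
}

#' NOE distance restraints from classified cross peaks
#'
#' Turns a table of classified NOE cross peaks into distance restraints with
#' class-dependent upper bounds ([noe_upper_bound()]) and a fixed lower
#' bound at van der Waals contact.
#'
#' @param peaks Tibble with `chain1`, `resno1`, `atom1`, `chain2`, `resno2`,
#'   `atom2`, `class`. Atom names may contain a trailing wildcard (`#` or
#'   `*`) denoting a pseudo-atom group.
#' @param lower Lower bound in Angstroms (default 1.8, van der Waals
#'   contact).
#' @return Restraint tibble with `lower`, `upper`, `origin = "noe"` and a
#'   sequence-separation `category` (see [categorize_restraints()]).
#' @export
noe_restraints <- function(peaks, lower = 1.8) {
  peaks <- as_tibble(peaks)
  out <- peaks |>
    mutate(lower = lower, upper = noe_upper_bound(.data$class),
           origin = "noe") |>
    select("chain1", "resno1", "atom1", "chain2", "resno2", "atom2",
           "lower", "upper", "origin")
  categorize_restraints(out)
}

#' Hydrogen-bond distance restraints
#'
#' For each hydrogen bond, restrains the amide proton to less than 2.3 A
#' from the acceptor and the amide nitrogen to less than 3.1 A from the
#' acceptor (two restraints per bond).
#'
#' @param hbonds Tibble with one row per hydrogen bond: donor residue
#'   (`chain1`, `resno1`), donor atom names `h_atom` and `n_atom` (defaults
#'   "H" and "N" if absent), and acceptor (`chain2`, `resno2`, `atom2`).
#' @param lower Lower bound in Angstroms (default 1.8).
#' @return Restraint tibble (2 rows per input bond), origin
#'   `"hydrogen-bond"`, categorized by sequence separation.
#' @export
hbond_restraints <- function(hbonds, lower = 1.8) {
  hbonds <- as_tibble(hbonds)
  if (!"h_atom" %in% names(hbonds)) hbonds$h_atom <- "H"
  if (!"n_atom" %in% names(hbonds)) hbonds$n_atom <- "N"
  if (any(hbonds$h_atom == hbonds$n_atom)) {
    abort("donor H and N atoms must be distinct")
  }
  # the proton and nitrogen of one amide must be in the same residue;
  # optional n_chain/n_resno columns allow stating (and checking) this
  if (all(c("n_chain", "n_resno") %in% names(hbonds)) &&
      any(hbonds$n_chain != hbonds$chain1 | hbonds$n_resno != hbonds$resno1)) {
    abort("donor H and N must belong to the same residue")
  }
  out <- hbonds |>
    tidyr::pivot_longer(c("h_atom", "n_atom"), names_to = "donor_kind",
                        values_to = "atom1") |>
    mutate(
      upper = ifelse(.data$donor_kind == "h_atom", 2.3, 3.1),
      lower = lower, origin = "hydrogen-bond"
    ) |>
    select("chain1", "resno1", "atom1", "chain2", "resno2", "atom2",
           "lower", "upper", "origin")
  categorize_restraints(out)
}

restraint_categories <- c("intraresidual", "sequential", "medium-range",
                          "long-range")

#' Categorize restraints by sequence separation
#'
#' Standard NMR bookkeeping categories from the residue separation
#' |i - j|: 0 intraresidual, 1 sequential, 2-4 medium-range, >= 5
#' long-range. Restraints between different chains are counted as
#' long-range (with a warning).
#'
#' @param restraints Restraint tibble (`chain1`, `resno1`, `chain2`,
#'   `resno2`, ...).
#' @return The tibble with a `category` factor column.
#' @export
categorize_restraints <- function(restraints) {
  restraints <- as_tibble(restraints)
  inter <- !is.na(restraints$chain1) & !is.na(restraints$chain2) &
    restraints$chain1 != restraints$chain2
  if (any(inter)) {
    warn(sprintf("%d inter-chain restraint(s) categorized as long-range",
                 sum(inter)))
  }
  sep <- abs(restraints$resno1 - restraints$resno2)
  restraints$category <- factor(
    dplyr::case_when(
      inter ~ "long-range",
      sep == 0 ~ "intraresidual",
      sep == 1 ~ "sequential",
      sep <= 4 ~ "medium-range",
      .default = "long-range"
    ),
    levels = restraint_categories
  )
  restraints
}

#' Tally distance restraints
#'
#' Per-category counts plus the two headline totals: the NOE total (sum of
#' the four sequence-separation categories) and the combined
#' distance-restraint total (NOE total + hydrogen-bond restraints, the
#' number quoted when hydrogen bonds are counted as distance restraints).
#' Dihedral restraints are carried as a count-only bookkeeping field.
#'
#' @param restraints Restraint tibble with `category` and `origin` columns,
#'   or `NULL` when `counts` is given.
#' @param counts Alternatively, a named vector/list of per-category NOE
#'   counts (`intraresidual`, `sequential`, `medium-range` or
#'   `medium_range`, `long-range` or `long_range`).
#' @param n_hbond Number of hydrogen-bond restraints (counted from
#'   `restraints` when omitted; note each hydrogen bond contributes two).
#' @param n_dihedral Dihedral restraint count (bookkeeping only; default 0).
#' @return One-row tibble: the four category counts, `noe_total`, `hbond`,
#'   `distance_total`, `dihedral`.
#' @examples
#' restraint_tally(counts = c(intraresidual = 329, sequential = 386,
#'                            medium_range = 321, long_range = 471),
#'                 n_hbond = 58)
#' @export
restraint_tally <- function(restraints = NULL, counts = NULL, n_hbond = NULL,
                            n_dihedral = 0) {
  if (is.null(restraints) && is.null(counts)) {
    abort("provide either a restraint table or per-category counts")
  }
  if (!is.null(counts)) {
    counts <- unlist(counts)
    names(counts) <- gsub("_", "-", names(counts))
    cat_counts <- setNames(rep(0L, 4), restraint_categories)
    cat_counts[names(counts)] <- counts
    n_hbond <- n_hbond %||% 0L
  } else {
    restraints <- as_tibble(restraints)
    if (!"category" %in% names(restraints)) {
      restraints <- categorize_restraints(restraints)
    }
    noe <- restraints |> filter(.data$origin != "hydrogen-bond")
    cat_counts <- table(factor(noe$category, levels = restraint_categories))
    n_hbond <- n_hbond %||% sum(restraints$origin == "hydrogen-bond")
  }
  noe_total <- sum(cat_counts)
  tibble(
    intraresidual = as.integer(cat_counts[["intraresidual"]]),
    sequential = as.integer(cat_counts[["sequential"]]),
    medium_range = as.integer(cat_counts[["medium-range"]]),
    long_range = as.integer(cat_counts[["long-range"]]),
    noe_total = as.integer(noe_total),
    hbond = as.integer(n_hbond),
    distance_total = as.integer(noe_total + n_hbond),
    dihedral = as.integer(n_dihedral)
  )
}

# --- selection resolution -------------------------------------------------

# Wildcards: trailing "#" or "*" expands over protons of a pseudo-atom
# group. If a proton selection matches nothing (e.g. proton-less synthetic
# structures), fall back to the corresponding methyl/methylene carbon.
resolve_selection <- function(keys, chain, resno, atom) {
  base <- sub("[#*]$", "", atom)
  wild <- grepl("[#*]$", atom)
  pat <- if (wild) paste0("^", base) else paste0("^", base, "$")
  in_res <- keys$chain == chain & keys$resno == resno
  hit <- which(in_res & grepl(pat, keys$atom))
  if (length(hit) == 0 && grepl("^[HMQ]", base)) {
    carbon <- sub("^[HMQ]", "C", base)
    hit <- which(in_res & keys$atom == carbon)
  }
  hit
}

# r^-6 summed effective distance between two atom groups (x1, x2 are
# coordinate matrices); equals the plain distance for single atoms and is
# always <= the minimum pair distance.
effective_distance <- function(x1, x2) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  d2[d2 < 0] <- 0
  sum(d2^-3)^(-1 / 6)
}

#' Validate distance restraints against a structure ensemble
#'
#' Measures every restraint in every model, using the r^-6 summed effective
#' distance for pseudo-atom groups, and reports violation statistics in the
#' convention of structure-calculation software: the per-model rms is taken
#' over *all* restraints (violated or not), the headline rms is the mean
#' over models (with sd), and the maximum is the largest single violation
#' anywhere in the ensemble.
#'
#' @param atoms A `pdb_atoms` tibble (1 or more models).
#' @param restraints Restraint tibble (`chain1`, `resno1`, `atom1`, ...,
#'   `lower`, `upper`).
#' @return A `restraint_validation` object; `glance()` gives the one-row
#'   summary (`rms`, `rms_sd`, `max_violation`), `tidy()` the per-model,
#'   per-restraint distances and violations.
#' @export
violation_stats <- function(atoms, restraints) {
  atoms <- as_pdb_atoms(atoms)
  restraints <- as_tibble(restraints)
  models <- sort(unique(atoms$model))
  m1 <- atoms |> filter(.data$model == models[1])
  keys <- m1[, c("chain", "resno", "atom")]

  sel1 <- sel2 <- vector("list", nrow(restraints))
  for (i in seq_len(nrow(restraints))) {
    sel1[[i]] <- resolve_selection(keys, restraints$chain1[i],
                                   restraints$resno1[i], restraints$atom1[i])
    sel2[[i]] <- resolve_selection(keys, restraints$chain2[i],
                                   restraints$resno2[i], restraints$atom2[i])
    if (length(sel1[[i]]) == 0 || length(sel2[[i]]) == 0) {
      abort(sprintf(
        "restraint %d (%s%d %s <-> %s%d %s) does not resolve to any atoms",
        i, restraints$chain1[i], restraints$resno1[i], restraints$atom1[i],
        restraints$chain2[i], restraints$resno2[i], restraints$atom2[i]),
        class = "methylmap_selection_error")
    }
  }

  key_str <- function(df) paste(df$chain, df$resno, df$atom)
  ref_key <- key_str(m1)
  per <- purrr::map(models, function(m) {
    am <- atoms |> filter(.data$model == m)
    am <- am[match(ref_key, key_str(am)), ]
    xyz <- as.matrix(am[, c("x", "y", "z")])
    d <- vapply(seq_len(nrow(restraints)), function(i) {
      effective_distance(xyz[sel1[[i]], , drop = FALSE],
                         xyz[sel2[[i]], , drop = FALSE])
    }, numeric(1))
    v <- pmax(0, d - restraints$upper, restraints$lower - d)
    tibble(model = m, restraint = seq_len(nrow(restraints)),
           distance = d, violation = v)
  }) |> bind_rows()

  per_model <- per |>
    group_by(.data$model) |>
    summarise(rms = sqrt(mean(.data$violation^2)),
              max_violation = max(.data$violation), .groups = "drop")
  structure(
    list(per_restraint = per, per_model = per_model,
         rms = mean(per_model$rms),
         rms_sd = if (nrow(per_model) > 1) sd(per_model$rms) else 0,
         max_violation = max(per_model$max_violation),
         n_restraints = nrow(restraints), n_models = length(models)),
    class = "restraint_validation"
  )
}

#' @export
print.restraint_validation <- function(x, ...) {
  cat(sprintf(
    "<restraint_validation> %d restraints x %d models: rms %.4f (+/- %.4f) A, max %.3f A\n",
    x$n_restraints, x$n_models, x$rms, x$rms_sd, x$max_violation))
  invisible(x)
}

#' @describeIn violation_stats Per-model, per-restraint distances and
#'   violations.
#' @param x A `restraint_validation`.
#' @param ... Unused.
#' @export
tidy.restraint_validation <- function(x, ...) x$per_restraint

#' @describeIn violation_stats One-row violation summary.
#' @export
glance.restraint_validation <- function(x, ...) {
  tibble(n_restraints = x$n_restraints, n_models = x$n_models,
         rms = x$rms, rms_sd = x$rms_sd, max_violation = x$max_violation)
}

#' Ensemble coordinate precision
#'
#' Mean rmsd of ensemble models to their mean coordinates after iterative
#' least-squares superposition: models are fitted onto the current mean,
#' the mean is recomputed, and the cycle repeats until the precision
#' changes by less than `tol`.
#'
#' @param atoms A multi-model `pdb_atoms` tibble (>= 2 models).
#' @param resno_range Optional `c(first, last)` residue-number range.
#' @param atom_set `"backbone"` (N, CA, C) or `"heavy"` (all heavy atoms).
#' @param chain Optional chain filter.
#' @param tol Convergence tolerance on the precision (default 1e-6 A).
#' @return One-row tibble: `atom_set`, `n_models`, `n_atoms`, `precision`
#'   (A, mean over models of rmsd to the mean), `precision_sd`.
#' @export
ensemble_precision <- function(atoms, resno_range = NULL,
                               atom_set = c("backbone", "heavy"),
                               chain = NULL, tol = 1e-6) {
  atoms <- as_pdb_atoms(atoms)
  atom_set <- match.arg(atom_set)
  models <- sort(unique(atoms$model))
  if (length(models) < 2) {
    abort("ensemble precision needs at least 2 models",
          class = "methylmap_analysis_error")
  }
  sel <- atoms |> filter(!.data$het, !.data$hydrogen)
  if (atom_set == "backbone") {
    sel <- sel |> filter(.data$atom %in% c("N", "CA", "C"))
  }
  if (!is.null(chain)) sel <- sel |> filter(.data$chain %in% !!chain)
  if (!is.null(resno_range)) {
    sel <- sel |> filter(.data$resno >= resno_range[1],
                         .data$resno <= resno_range[2])
  }
  key_str <- function(df) paste(df$chain, df$resno, df$atom)
  ref <- sel |> filter(.data$model == models[1])
  X <- t(vapply(models, function(m) {
    am <- sel |> filter(.data$model == m)
    am <- am[match(key_str(ref), key_str(am)), ]
    as.vector(t(as.matrix(am[, c("x", "y", "z")])))
  }, numeric(3 * nrow(ref))))

  prec <- function(X) {
    mu <- colMeans(X)
    dev <- sweep(X, 2, mu)
    rmsds <- sqrt(rowSums(dev^2) / (ncol(X) / 3))
    list(mean = mean(rmsds), sd = sd(rmsds), rmsds = rmsds)
  }
  last <- Inf
  for (iter in 1:100) {
    X <- bio3d::fit.xyz(fixed = colMeans(X), mobile = X,
                        fixed.inds = seq_len(ncol(X)),
                        mobile.inds = seq_len(ncol(X)))
    p <- prec(X)
    if (abs(last - p$mean) < tol) break
    last <- p$mean
  }
  tibble(atom_set = atom_set, n_models = length(models),
         n_atoms = nrow(ref), precision = p$mean, precision_sd = p$sd)
}
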