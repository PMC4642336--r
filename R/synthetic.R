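#' Fraction of labeled protein bound (two-state binding)
#'
#' Physical root of the two-state binding quadratic
#' L * p^2 - (L + P + K) * p + P = 0, where L and P are the total labeled
#' and partner concentrations and K the dissociation constant (all in the
#' same units, conventionally micromolar).
#'
#' @param kd Dissociation constant (>= 0).
#' @param ligand_total Total labeled-protein concentration (> 0).
#' @param partner_total Total partner concentration (>= 0).
#' @return Fraction bound in \[0, 1\] (vectorized over any argument).
#' @examples
#' fraction_bound(50, 20, 20)
#' @export
fraction_bound <- function(kd, ligand_total, partner_total) {
  if (any(kd < 0) || any(partner_total < 0) || any(ligand_total <= 0)) {
    abort("concentrations must be >= 0 and ligand_total > 0")
  }
  s <- ligand_total + partner_total + kd
  disc <- pmax(0, s^2 - 4 * ligand_total * partner_total)
  pmin(1, pmax(0, (s - sqrt(disc)) / (2 * ligand_total)))
}

# Amino-acid pool for the toy fold; ILV frequencies chosen high enough
# that a ~100-residue fold carries >= 25 methyl-bearing residues.
toy_fold_sequence <- function(n_res, min_ilv = 25) {
  ilv <- c("ILE", "LEU", "VAL")
  others <- c("ALA", "GLY", "SER", "THR", "ASP", "GLU", "LYS", "ARG",
              "PHE", "TYR", "ASN", "GLN")
  prob <- c(rep(0.30 / 3, 3), rep(0.70 / length(others), length(others)))
  seq <- sample(c(ilv, others), n_res, replace = TRUE, prob = prob)
  short <- max(0, ceiling(min_ilv * n_res / 100) - sum(seq %in% ilv))
  if (short > 0) {
    idx <- sample(which(!seq %in% ilv), short)
    seq[idx] <- sample(ilv, short, replace = TRUE)
  }
  seq
}

#' Generate a synthetic toy protein fold
#'
#' A parametric four-helix bundle of 60-130 residues with backbone
#' (N, CA, C, O), CB, and side-chain methyl carbons for Ile/Leu/Val
#' residues, used as the labeled protein of a [binding_scenario()]. The
#' geometry is idealized (3.8 A CA spacing, 100 deg/1.5 A helical rise,
#' side chains pointing away from the helix axes); it is a stand-in for a
#' real fold, not a physically refined structure.
#'
#' @param n_res Number of residues (default 100).
#' @param seed Random seed controlling the sequence.
#' @return A `pdb_atoms` tibble (single model, chain "A").
#' @export
toy_fold <- function(n_res = 100, seed = 1) {
  stopifnot(n_res >= 60, n_res <= 130)
  set.seed(seed)
  seqaa <- toy_fold_sequence(n_res)

  n_loop <- 4L
  n_helix <- 4L
  n_hres <- floor((n_res - (n_helix - 1) * n_loop) / n_helix)
  extra <- n_res - (n_helix * n_hres + (n_helix - 1) * n_loop)
  helix_len <- rep(n_hres, n_helix)
  helix_len[1] <- helix_len[1] + extra
  axes <- list(c(5.5, 5.5), c(5.5, -5.5), c(-5.5, -5.5), c(-5.5, 5.5))

  ca <- matrix(NA_real_, n_res, 3)
  outward <- matrix(NA_real_, n_res, 3)
  i <- 1L
  z_end <- 0
  for (h in seq_len(n_helix)) {
    dir <- if (h %% 2 == 1) 1 else -1
    len <- helix_len[h]
    z0 <- if (h == 1) 0 else z_end
    for (j in seq_len(len)) {
      theta <- (i * 100) * pi / 180
      radial <- c(cos(theta), sin(theta))
      ca[i, ] <- c(axes[[h]][1] + 2.3 * radial[1],
                   axes[[h]][2] + 2.3 * radial[2],
                   z0 + dir * 1.5 * (j - 1))
      outward[i, ] <- c(radial, 0)
      i <- i + 1L
    }
    z_end <- ca[i - 1L, 3]
    if (h < n_helix) {
      # loop: straight interpolation toward the next helix start
      theta_next <- ((i + n_loop) * 100) * pi / 180
      nxt <- c(axes[[h + 1]][1] + 2.3 * cos(theta_next),
               axes[[h + 1]][2] + 2.3 * sin(theta_next),
               z_end)
      from <- ca[i - 1L, ]
      for (j in seq_len(n_loop)) {
        frac <- j / (n_loop + 1)
        ca[i, ] <- from + frac * (nxt - from) + c(0, 0, 2.5 * sin(pi * frac))
        v <- ca[i, ] - c(0, 0, ca[i, 3])
        outward[i, ] <- v / sqrt(sum(v^2))
        i <- i + 1L
      }
    }
  }

  rows <- vector("list", n_res)
  unit <- function(v) v / sqrt(sum(v^2))
  for (k in seq_len(n_res)) {
    u <- outward[k, ]
    prev <- if (k > 1) ca[k - 1, ] else ca[k, ] - c(1.5, 0, 0)
    nxt <- if (k < n_res) ca[k + 1, ] else ca[k, ] + c(1.5, 0, 0)
    t1 <- unit(c(-u[2], u[1], 0.3))
    at <- list(
      N = ca[k, ] + 0.38 * (prev - ca[k, ]),
      CA = ca[k, ],
      C = ca[k, ] + 0.38 * (nxt - ca[k, ]),
      O = ca[k, ] + 0.38 * (nxt - ca[k, ]) + 1.23 * u
    )
    if (seqaa[k] != "GLY") at$CB <- ca[k, ] + 1.53 * u
    if (seqaa[k] == "ILE") {
      at$CG1 <- ca[k, ] + 2.6 * u + 0.5 * t1
      at$CD1 <- ca[k, ] + 3.9 * u
    } else if (seqaa[k] == "LEU") {
      at$CG <- ca[k, ] + 2.5 * u
      at$CD1 <- ca[k, ] + 3.3 * u + 0.9 * t1
      at$CD2 <- ca[k, ] + 3.3 * u - 0.9 * t1
    } else if (seqaa[k] == "VAL") {
      at$CG1 <- ca[k, ] + 2.6 * u + 0.8 * t1
      at$CG2 <- ca[k, ] + 2.6 * u - 0.8 * t1
    }
    xyz <- unname(do.call(rbind, at))
    rows[[k]] <- tibble(
      chain = "A", resno = k, resname = seqaa[k], atom = names(at),
      x = round(xyz[, 1], 3), y = round(xyz[, 2], 3), z = round(xyz[, 3], 3)
    )
  }
  as_pdb_atoms(bind_rows(rows))
}

#' Place a partner atom cloud against one face of a structure
#'
#' A planar slab of carbon atoms (chain "B") just beyond the +x face of the
#' ligand, standing in for the surface of a large binding partner.
#'
#' @param atoms Ligand `pdb_atoms`.
#' @param offset Gap between the ligand's +x extreme and the wall (default
#'   2.0 A, close enough that the wall contacts the face, not just the
#'   single most protruding side chain).
#' @param spacing Grid spacing of wall atoms (default 2.5 A).
#' @param margin How far the wall extends laterally beyond the central part
#'   of the ligand's bounding box (default 2 A).
#' @return A `pdb_atoms` tibble for the partner cloud.
#' @export
partner_wall <- function(atoms, offset = 2.0, spacing = 2.5, margin = 2) {
  atoms <- as_pdb_atoms(atoms)
  heavy <- atoms |> filter(!.data$hydrogen, !.data$het)
  x0 <- max(heavy$x) + offset
  ys <- seq(min(heavy$y) - margin, max(heavy$y) + margin, by = spacing)
  zs <- seq(min(heavy$z) - margin, max(heavy$z) + margin, by = spacing)
  grid <- expand.grid(y = ys, z = zs)
  as_pdb_atoms(tibble(
    chain = "B", resno = seq_len(nrow(grid)), resname = "UNK", atom = "C",
    x = x0, y = grid$y, z = grid$z
  ))
}

#' Place a partner shell molded against one face of a structure
#'
#' Emulates the surface of a much larger binding partner enveloping one
#' face of the ligand: every heavy atom in the +x face band receives a
#' partner carbon at `clearance` further along +x, and the resulting cloud
#' is thinned on a grid. Unlike the flat [partner_wall()], the shell
#' follows the surface relief, so an entire face - side chains and
#' backbone - sits within contact distance, as it would against a
#' complementary macromolecular surface.
#'
#' @param atoms Ligand `pdb_atoms`.
#' @param clearance Gap between each face atom and its partner atom
#'   (default 3.0 A, roughly van der Waals contact).
#' @param face_frac Fraction of heavy atoms (by x coordinate, from the top)
#'   considered part of the contacted face (default 0.30).
#' @param grid Thinning grid spacing (default 1.5 A).
#' @return A `pdb_atoms` tibble for the partner cloud (chain "B").
#' @export
partner_shell <- function(atoms, clearance = 3.0, face_frac = 0.30,
                          grid = 1.5) {
  atoms <- as_pdb_atoms(atoms)
  heavy <- atoms |> filter(!.data$hydrogen, !.data$het)
  x_cut <- stats::quantile(heavy$x, 1 - face_frac)
  face <- heavy |> filter(.data$x >= x_cut)
  pts <- tibble(x = face$x + clearance, y = face$y, z = face$z) |>
    mutate(cell = paste(round(.data$x / grid), round(.data$y / grid),
                        round(.data$z / grid))) |>
    distinct(.data$cell, .keep_all = TRUE) |>
    select(-"cell")
  as_pdb_atoms(tibble(
    chain = "B", resno = seq_len(nrow(pts)), resname = "UNK", atom = "C",
    x = pts$x, y = pts$y, z = pts$z
  ))
}

#' Define a synthetic binding scenario (ground truth)
#'
#' Assembles the ligand structure, partner atom cloud, binding constants
#' and noise model that drive [simulate_titration()]. The ground-truth
#' interface is the set of ligand residues with any heavy atom within 5 A
#' of the partner; each methyl probe carries a contact score
#' s_i = sum over partner atoms within `contact_cutoff` of (r0 / r)^6,
#' measured from the methyl carbon, which controls the
#' interface-proximity-dependent extra line broadening.
#'
#' @param structure Ligand `pdb_atoms`; default [toy_fold()].
#' @param partner Partner `pdb_atoms`; default [partner_shell()] molded
#'   against the ligand's +x face.
#' @param kd Dissociation constant, micromolar (default 2: tight
#'   association, so that at 20 uM / 1:1 interface probes lose roughly
#'   40-80 % of their intensity).
#' @param conc Labeled-protein concentration, micromolar (default 20).
#' @param ratios Partner:labeled molar ratios including the free state 0
#'   (default `c(0, 1, 2)`).
#' @param scans Number of scans per spectrum (default 128).
#' @param lambda Broadening amplitude per unit contact score (default 1).
#' @param attenuation Uniform intensity attenuation A of the bound state,
#'   in (0, 1\] (default 0.5; models the overall size-dependent signal loss
#'   on complex formation).
#' @param r0 Contact radius of the broadening kernel, Angstroms (default 4).
#' @param contact_cutoff Partner atoms beyond this distance are ignored in
#'   the contact score (default 10 A).
#' @param sigma Multiplicative log-normal intensity noise sd (default 0.05).
#' @param gain_sd Per-peak gain spread, log-normal sd (default 0.1).
#' @param ambiguous_frac Fraction of probes marked as ambiguously assigned
#'   (default 0.1).
#' @param interface_cutoff Heavy-atom distance defining the ground-truth
#'   interface (default 5 A).
#' @param seed Random seed governing all randomness of the scenario.
#' @return A `binding_scenario` object.
#' @export
binding_scenario <- function(structure = NULL, partner = NULL, kd = 2,
                             conc = 20, ratios = c(0, 1, 2), scans = 128,
                             lambda = 1, attenuation = 0.5, r0 = 4,
                             contact_cutoff = 10, sigma = 0.05,
                             gain_sd = 0.1, ambiguous_frac = 0.1,
                             interface_cutoff = 5, seed = 1) {
  if (conc <= 0 || any(ratios < 0)) abort("concentrations must be positive")
  if (sigma < 0) abort("sigma must be >= 0")
  if (attenuation <= 0 || attenuation > 1) abort("attenuation must be in (0, 1]")
  structure <- if (is.null(structure)) toy_fold(seed = seed) else
    as_pdb_atoms(structure)
  partner <- if (is.null(partner)) partner_shell(structure) else
    as_pdb_atoms(partner)

  heavy <- structure |> filter(!.data$hydrogen, !.data$het,
                               .data$model == min(.data$model))
  P <- as.matrix(partner[, c("x", "y", "z")])
  L <- as.matrix(heavy[, c("x", "y", "z")])
  d2 <- outer(rowSums(L^2), rowSums(P^2), "+") - 2 * L %*% t(P)
  d2[d2 < 0] <- 0
  near <- sqrt(apply(d2, 1, min))
  interface <- heavy |>
    mutate(near = near) |>
    group_by(.data$chain, .data$resno) |>
    summarise(dmin = min(.data$near), .groups = "drop") |>
    filter(.data$dmin <= interface_cutoff) |>
    select("chain", "resno")
  if (nrow(interface) == 0) abort("scenario has an empty interface")

  probes <- enumerate_methyl_probes(structure)
  pxyz <- probes |>
    left_join(heavy |> select("chain", "resno", "atom", "x", "y", "z"),
              by = c("chain", "resno", site = "atom"))
  D2 <- outer(rowSums(as.matrix(pxyz[, c("x", "y", "z")])^2),
              rowSums(P^2), "+") -
    2 * as.matrix(pxyz[, c("x", "y", "z")]) %*% t(P)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  contact <- (r0 / D)^6
  contact[D > contact_cutoff] <- 0
  probes$s <- rowSums(contact)

  structure(
    list(structure = structure, partner = partner, probes = probes,
         interface = interface, kd = kd, conc = conc, ratios = ratios,
         scans = scans, lambda = lambda, attenuation = attenuation,
         r0 = r0, contact_cutoff = contact_cutoff, sigma = sigma,
         gain_sd = gain_sd, ambiguous_frac = ambiguous_frac,
         interface_cutoff = interface_cutoff, seed = seed),
    class = "binding_scenario"
  )
}

#' @export
print.binding_scenario <- function(x, ...) {
  cat(sprintf(
    "<binding_scenario> %d residues, %d methyl probes, %d interface residues\n",
    nrow(structure_residues(x$structure)), nrow(x$probes), nrow(x$interface)))
  cat(sprintf(
    "  Kd %g uM, %g uM labeled, ratios %s, lambda %g, A %g, sigma %g, seed %d\n",
    x$kd, x$conc, paste(x$ratios, collapse = "/"), x$lambda,
    x$attenuation, x$sigma, x$seed))
  invisible(x)
}

ratio_label <- function(ratio) {
  ifelse(ratio == 0, "free", paste0("1:", format(ratio, trim = TRUE)))
}

#' Simulate a methyl titration from a binding scenario
#'
#' Per methyl probe i, the true relative intensity at a titration point
#' with bound fraction p_b is r_i = (1 - p_b) + p_b * A * exp(-lambda *
#' s_i), i.e. a fast-exchange population average of the free signal and a
#' bound signal uniformly attenuated by A and additionally broadened for
#' interface probes through the contact score s_i. Observed raw intensities
#' add a per-peak gain (log-normal, fixed across points) and multiplicative
#' noise (log-normal, redrawn per point), then scale with concentration and
#' scan count; the free point has p_b = 0. A fixed fraction of probes is
#' marked ambiguous. All randomness derives from the scenario seed.
#'
#' @param scenario A [binding_scenario()].
#' @return A `synthetic_titration` list: `$series` (a [titration_series()]),
#'   `$truth` (interface residues), `$r_true` (noise-free relative
#'   intensities per probe and point), `$scenario`.
#' @export
simulate_titration <- function(scenario) {
  stopifnot(inherits(scenario, "binding_scenario"))
  set.seed(scenario$seed)
  probes <- scenario$probes
  n <- nrow(probes)
  gains <- rlnorm(n, 0, scenario$gain_sd)
  n_amb <- round(scenario$ambiguous_frac * n)
  ambiguous <- sample(n, n_amb)
  assignment <- rep("unambiguous", n)
  assignment[ambiguous] <- "ambiguous"

  points <- tibble(
    point = ratio_label(scenario$ratios),
    ratio = scenario$ratios,
    conc = scenario$conc,
    scans = scenario$scans
  )
  peak_list <- vector("list", nrow(points))
  r_list <- vector("list", nrow(points))
  for (p in seq_len(nrow(points))) {
    p_b <- if (points$ratio[p] == 0) 0 else
      fraction_bound(scenario$kd, scenario$conc,
                     scenario$conc * points$ratio[p])
    r_true <- (1 - p_b) +
      p_b * scenario$attenuation * exp(-scenario$lambda * probes$s)
    eps <- if (scenario$sigma > 0) rnorm(n, 0, scenario$sigma) else numeric(n)
    raw <- gains * r_true * points$conc[p] * points$scans[p] * exp(eps)
    peak_list[[p]] <- probes |>
      select("chain", "resno", "resname", "site") |>
      mutate(point = points$point[p], .before = 1) |>
      mutate(assignment = assignment, intensity = raw)
    r_list[[p]] <- probes |>
      select("chain", "resno", "resname", "site") |>
      mutate(point = points$point[p], r_true = r_true, p_b = p_b)
  }
  structure(
    list(series = titration_series(bind_rows(peak_list), points),
         truth = scenario$interface,
         r_true = bind_rows(r_list),
         scenario = scenario),
    class = "synthetic_titration"
  )
}

#' @export
print.synthetic_titration <- function(x, ...) {
  print(x$series)
  cat("ground truth:", nrow(x$truth), "interface residues\n")
  invisible(x)
}

#' Simulate classified NOE cross peaks from a structure
#'
#' Emits one cross peak per atom pair closer than `cutoff`, classified by
#' distance bins chosen so that the class's standard upper bound always
#' strictly exceeds the true distance (strong < 2.7 A < 3.0; medium < 3.3
#' < 4.0; weak < 4.2 < 5.0; very weak < `cutoff` < 6.0). Protons are used
#' when the structure has any; otherwise methyl carbons serve as
#' pseudo-atom proxies.
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param model Model to measure (default: first).
#' @param cutoff Maximum distance for an observable cross peak (default
#'   5.5 A).
#' @param bins Upper edges of the strong/medium/weak classes (default
#'   2.7, 3.3, 4.2 A).
#' @param min_dist No peak is emitted below this distance (default 1.8 A,
#'   the van der Waals lower bound of the generated restraints, so that
#'   restraints derived from the peaks are satisfied by construction).
#' @return Tibble `chain1`, `resno1`, `atom1`, `chain2`, `resno2`, `atom2`,
#'   `distance`, `class`.
#' @export
simulate_noe_peaks <- function(atoms, model = NULL, cutoff = 5.5,
                               bins = c(2.7, 3.3, 4.2), min_dist = 1.8) {
  atoms <- as_pdb_atoms(atoms)
  model <- model %||% min(atoms$model)
  m <- atoms |> filter(.data$model == !!model, !.data$het)
  sel <- if (any(m$hydrogen)) {
    m |> filter(.data$hydrogen)
  } else {
    m |> filter(.data$atom %in% c("CD1", "CD2", "CG1", "CG2"),
                .data$resname %in% c("ILE", "LEU", "VAL"))
  }
  xyz <- as.matrix(sel[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  idx <- which(upper.tri(d2) & sqrt(d2) < cutoff & sqrt(d2) > min_dist,
               arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(chain1 = character(), resno1 = integer(),
                  atom1 = character(), chain2 = character(),
                  resno2 = integer(), atom2 = character(),
                  distance = double(), class = character()))
  }
  d <- sqrt(d2[idx])
  tibble(
    chain1 = sel$chain[idx[, 1]], resno1 = sel$resno[idx[, 1]],
    atom1 = sel$atom[idx[, 1]],
    chain2 = sel$chain[idx[, 2]], resno2 = sel$resno[idx[, 2]],
    atom2 = sel$atom[idx[, 2]],
    distance = d,
    class = dplyr::case_when(
      d < bins[1] ~ "strong",
      d < bins[2] ~ "medium",
      d < bins[3] ~ "weak",
      .default = "very weak"
    )
  ) |>
    arrange(.data$resno1, .data$resno2)
}

#' Jitter a structure into a synthetic ensemble
#'
#' Copies model 1 `n_models` times, displaces every atom by i.i.d. Gaussian
#' noise of sd `sigma_coord`, then applies an independent random rigid
#' rotation and translation to each model (so superposition is actually
#' exercised by consumers).
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param sigma_coord Per-coordinate jitter sd in Angstroms (>= 0).
#' @param n_models Number of models (>= 2).
#' @param seed Random seed.
#' @return A multi-model `pdb_atoms` tibble.
#' @export
jitter_ensemble <- function(atoms, sigma_coord, n_models, seed = 1) {
  stopifnot(sigma_coord >= 0, n_models >= 2)
  atoms <- as_pdb_atoms(atoms)
  base <- atoms |> filter(.data$model == min(.data$model))
  set.seed(seed)
  models <- purrr::map(seq_len(n_models), function(m) {
    xyz <- as.matrix(base[, c("x", "y", "z")])
    xyz <- xyz + matrix(rnorm(length(xyz), 0, sigma_coord), ncol = 3)
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    xyz <- xyz %*% rot + matrix(runif(3, -10, 10), nrow(xyz), 3, byrow = TRUE)
    base |> mutate(model = as.integer(m), x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3])
  })
  as_pdb_atoms(bind_rows(models))
}

#' Score interface recovery against the ground truth
#'
#' Residue-level precision, recall and F1 of a predicted binding surface
#' (affected plus extension residues) against the ground-truth interface.
#' An empty prediction against a non-empty truth scores 0/0/0.
#'
#' @param predicted Residue classification tibble (strong/slight/extension
#'   residues are taken as the prediction), or a tibble/vector of residue
#'   numbers.
#' @param truth Ground-truth interface: tibble (`chain`, `resno`) or vector
#'   of residue numbers.
#' @return One-row tibble `precision`, `recall`, `f1`, `n_predicted`,
#'   `n_truth`.
#' @export
score_recovery <- function(predicted, truth) {
  as_set <- function(x) {
    if (is.data.frame(x)) {
      x <- as_tibble(x)
      if ("class" %in% names(x)) {
        ext <- if ("extension" %in% names(x)) x$extension else FALSE
        x <- x[x$class %in% c("strong", "slight") | ext, ]
      }
      paste(x$chain %||% "A", x$resno)
    } else {
      paste("A", x)
    }
  }
  p <- unique(as_set(predicted))
  t <- unique(as_set(truth))
  tp <- length(intersect(p, t))
  precision <- if (length(p) == 0) 0 else tp / length(p)
  recall <- if (length(t) == 0) 0 else tp / length(t)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         n_predicted = length(p), n_truth = length(t))
}
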