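test_that("NOE classes map to the standard upper limits", {
  expect_equal(noe_upper_bound("strong"), 3.0)
  expect_equal(noe_upper_bound("medium"), 4.0)
  expect_equal(noe_upper_bound("weak"), 5.0)
  expect_equal(noe_upper_bound("very weak"), 6.0)
  all4 <- noe_upper_bound(c("strong", "medium", "weak", "very weak"))
  expect_equal(length(unique(all4)), 4L)   # total and injective
  expect_error(noe_upper_bound("faint"), "unknown")
})

test_that("each hydrogen bond yields the H and N acceptor restraints", {
  hb <- tibble::tibble(chain1 = "A", resno1 = 10L,
                       chain2 = "A", resno2 = 6L, atom2 = "O")
  r <- hbond_restraints(hb)
  expect_equal(nrow(r), 2L)
  expect_setequal(r$upper, c(2.3, 3.1))
  expect_equal(r$atom1[r$upper == 2.3], "H")
  expect_equal(r$atom1[r$upper == 3.1], "N")
  expect_equal(unique(r$origin), "hydrogen-bond")

  many <- hbond_restraints(dplyr::bind_rows(hb, hb, hb))
  expect_equal(nrow(many), 6L)

  split_donor <- hb |> dplyr::mutate(n_chain = "A", n_resno = 11L)
  expect_error(hbond_restraints(split_donor), "same residue")
})

test_that("restraints on satisfying geometry show zero violation", {
  # H...A = 2.0, N...A = 3.0 by construction
  atoms <- atoms_from(
    list(6, "ALA", "O", 0, 0, 0),
    list(10, "ALA", "H", 2.0, 0, 0),
    list(10, "ALA", "N", 3.0, 0, 0)
  )
  hb <- tibble::tibble(chain1 = "A", resno1 = 10L,
                       chain2 = "A", resno2 = 6L, atom2 = "O")
  v <- glance(violation_stats(atoms, hbond_restraints(hb)))
  expect_equal(v$rms, 0)
  expect_equal(v$max_violation, 0)
})

test_that("sequence-separation categories follow the NMR convention", {
  mk <- function(r1, r2, ch2 = "A") {
    tibble::tibble(chain1 = "A", resno1 = r1, atom1 = "CA",
                   chain2 = ch2, resno2 = r2, atom2 = "CA",
                   lower = 1.8, upper = 5, origin = "noe")
  }
  expect_equal(as.character(categorize_restraints(mk(7, 7))$category),
               "intraresidual")
  expect_equal(as.character(categorize_restraints(mk(7, 8))$category),
               "sequential")
  expect_equal(as.character(categorize_restraints(mk(7, 9))$category),
               "medium-range")
  expect_equal(as.character(categorize_restraints(mk(7, 11))$category),
               "medium-range")
  expect_equal(as.character(categorize_restraints(mk(7, 12))$category),
               "long-range")
  expect_warning(inter <- categorize_restraints(mk(7, 7, ch2 = "B")),
                 "inter-chain")
  expect_equal(as.character(inter$category), "long-range")
})

test_that("random restraint sets partition across categories", {
  set.seed(12)
  r <- tibble::tibble(
    chain1 = "A", resno1 = sample(1:50, 200, TRUE), atom1 = "CA",
    chain2 = "A", resno2 = sample(1:50, 200, TRUE), atom2 = "CB",
    lower = 1.8, upper = 5, origin = "noe"
  ) |> categorize_restraints()
  expect_false(any(is.na(r$category)))
  tl <- restraint_tally(r)
  expect_equal(tl$noe_total, 200L)
  expect_equal(tl$intraresidual + tl$sequential + tl$medium_range +
                 tl$long_range, 200L)
})

test_that("tallies reproduce published bookkeeping totals", {
  tl <- restraint_tally(
    counts = c(intraresidual = 329, sequential = 386,
               medium_range = 321, long_range = 471),
    n_hbond = 58, n_dihedral = 193
  )
  expect_equal(tl$noe_total, 1507L)
  expect_equal(tl$distance_total, 1565L)
  expect_equal(tl$dihedral, 193L)

  empty <- restraint_tally(tibble::tibble(
    chain1 = character(), resno1 = integer(), atom1 = character(),
    chain2 = character(), resno2 = integer(), atom2 = character(),
    lower = double(), upper = double(), origin = character()))
  expect_equal(empty$noe_total, 0L)
  expect_equal(empty$distance_total, 0L)
})

test_that("a single over-long restraint gives its violation directly", {
  atoms <- atoms_from(
    list(1, "ALA", "CA", 0, 0, 0),
    list(9, "ALA", "CA", 3.5, 0, 0)
  )
  r <- tibble::tibble(chain1 = "A", resno1 = 1L, atom1 = "CA",
                      chain2 = "A", resno2 = 9L, atom2 = "CA",
                      lower = 1.8, upper = 3.0)
  v <- glance(violation_stats(atoms, r))
  expect_equal(v$rms, 0.5)
  expect_equal(v$max_violation, 0.5)
})

test_that("pseudo-atom groups use the r^-6 effective distance", {
  # two equivalent protons at 4 and 6 A: (4^-6 + 6^-6)^(-1/6) ~ 3.93 A
  atoms <- atoms_from(
    list(1, "ALA", "HB1", 4, 0, 0),
    list(1, "ALA", "HB2", 6, 0, 0),
    list(5, "ALA", "H", 0, 0, 0)
  )
  r <- tibble::tibble(chain1 = "A", resno1 = 5L, atom1 = "H",
                      chain2 = "A", resno2 = 1L, atom2 = "HB#",
                      lower = 1.8, upper = 6)
  d <- tidy(violation_stats(atoms, r))$distance
  expect_equal(d, (4^-6 + 6^-6)^(-1 / 6), tolerance = 1e-12)
  expect_lt(d, 4)   # effective distance never exceeds the closest pair
})

test_that("proton selections fall back to methyl carbons", {
  f <- toy_fold(n_res = 60, seed = 2)
  ile <- structure_residues(f) |> dplyr::filter(resname == "ILE")
  r <- tibble::tibble(chain1 = "A", resno1 = ile$resno[1], atom1 = "HD1#",
                      chain2 = "A", resno2 = ile$resno[2], atom2 = "HD1#",
                      lower = 1.8, upper = 60)
  v <- violation_stats(f, r)
  expect_equal(nrow(tidy(v)), 1L)
  expect_true(is.finite(tidy(v)$distance))

  missing <- r |> dplyr::mutate(atom2 = "XQ9")
  expect_error(violation_stats(f, missing),
               class = "methylmap_selection_error")
})

test_that("violations are invariant under per-model rigid motion", {
  f <- toy_fold(n_res = 60, seed = 3)
  rst <- noe_restraints(simulate_noe_peaks(f))
  ens <- jitter_ensemble(f, 0.4, 3, seed = 5)      # jitter + rigid motion
  v1 <- glance(violation_stats(ens, rst))
  rot <- qr.Q(qr(matrix(c(0, 1, 1, 1, 0, 2, 2, 2, 1), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  moved <- ens |>
    dplyr::group_by(model) |>
    dplyr::group_modify(function(d, g) {
      xyz <- as.matrix(d[, c("x", "y", "z")]) %*% rot
      d |> dplyr::mutate(x = xyz[, 1] + 3, y = xyz[, 2] - 8, z = xyz[, 3])
    }) |>
    dplyr::ungroup() |> as_pdb_atoms()
  v2 <- glance(violation_stats(moved, rst))
  expect_equal(v2$rms, v1$rms, tolerance = 1e-8)
  expect_equal(v2$max_violation, v1$max_violation, tolerance = 1e-8)
})

test_that("identical models have zero precision; rotation is removed", {
  f <- toy_fold(n_res = 60, seed = 2)
  two <- dplyr::bind_rows(f, f |> dplyr::mutate(model = 2L)) |> as_pdb_atoms()
  expect_equal(ensemble_precision(two)$precision, 0, tolerance = 1e-9)

  rot <- qr.Q(qr(matrix(c(2, 0, 1, 1, 1, 0, 0, 2, 1), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  xyz <- as.matrix(f[, c("x", "y", "z")]) %*% rot
  m2 <- f |> dplyr::mutate(model = 2L, x = xyz[, 1] + 6, y = xyz[, 2],
                           z = xyz[, 3] - 2)
  pair <- dplyr::bind_rows(f, m2) |> as_pdb_atoms()
  expect_lt(ensemble_precision(pair)$precision, 1e-4)
  expect_error(ensemble_precision(f), class = "methylmap_analysis_error")
})

test_that("precision respects the residue range and atom set", {
  f <- toy_fold(n_res = 60, seed = 2)
  ens <- jitter_ensemble(f, 0.5, 4, seed = 8)
  pb <- ensemble_precision(ens, resno_range = c(1, 30))
  expect_lt(pb$n_atoms, 3 * 60)
  ph <- ensemble_precision(ens, atom_set = "heavy")
  expect_gt(ph$n_atoms, pb$n_atoms)
  expect_gt(ph$precision, 0)
})

test_that("tbl files round-trip restraints", {
  f <- toy_fold(n_res = 60, seed = 1)
  rst <- noe_restraints(simulate_noe_peaks(f))
  tf <- withr::local_tempfile(fileext = ".tbl")
  write_tbl(rst, tf)
  back <- read_tbl(tf)
  expect_equal(nrow(back), nrow(rst))
  expect_equal(back$resno1, rst$resno1)
  expect_equal(back$atom1, rst$atom1)
  expect_equal(back$lower, rst$lower, tolerance = 1e-3)
  expect_equal(back$upper, rst$upper, tolerance = 1e-3)
  expect_equal(as.character(back$category), as.character(rst$category))
  expect_equal(unique(back$origin), "noe")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_restraints_tsv(rst, tsv)
  back2 <- read_restraints_tsv(tsv)
  expect_equal(back2$upper, rst$upper)
})
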