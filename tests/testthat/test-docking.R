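access_for <- function(resno, rel, chain = "A") {
  tibble::tibble(chain = chain, resno = as.integer(resno), resname = "ALA",
                 sasa = rel * 100, rel_sasa = rel)
}

test_that("buried residues never become active", {
  rc <- rc_from(1:4, c("LEU", "ILE", "VAL", "ALA"),
                c("strong", "slight", "unaffected", "no-data"))
  acc <- access_for(1:4, c(0.1, 0.2, 0.9, 0.9))
  expect_warning(act <- select_active(rc, acc), "no active")
  expect_equal(nrow(act), 0L)
})

test_that("affected and exposed residues become active; extensions do not", {
  rc <- rc_from(1:5, c("LEU", "ILE", "VAL", "ALA", "ILE"),
                c("strong", "slight", "unaffected", "no-data", "no-data"))
  rc$extension[4] <- TRUE
  acc <- access_for(1:5, c(0.9, 0.41, 0.9, 0.9, 0.9))
  act <- select_active(rc, acc, sasa_cutoff = 0.40)
  expect_equal(act$resno, c(1L, 2L))
})

test_that("an explicit override emits exactly the named residues", {
  rc <- rc_from(1:50, rep("ALA", 50), rep("no-data", 50))
  act <- select_active(rc, access_for(1:50, 0), override = c(27, 31, 43, 45))
  expect_equal(act$resno, c(27L, 31L, 43L, 45L))
})

test_that("raising the exposure cutoff shrinks active and passive sets", {
  sim <- simulate_titration(small_scenario(seed = 2))
  sc <- sim$scenario
  mc <- classify_methyls(relative_intensities(sim$series), point = "1:1")
  rc <- aggregate_residues(mc, structure_residues(sc$structure))
  acc <- relative_accessibility(sc$structure)
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.7), function(cut) {
    nrow(select_active(rc, acc, sasa_cutoff = cut))
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("actives stay within the true interface neighborhood", {
  sim <- simulate_titration(small_scenario(seed = 6))
  sc <- sim$scenario
  mc <- classify_methyls(relative_intensities(sim$series), point = "1:1")
  rc <- aggregate_residues(mc, structure_residues(sc$structure))
  acc <- relative_accessibility(sc$structure)
  act <- select_active(rc, acc, sasa_cutoff = 0.2)
  # ground-truth interface widened by 5 A (single-linkage on heavy atoms)
  heavy <- sc$structure |> dplyr::filter(!hydrogen, !het)
  txyz <- as.matrix(heavy[heavy$resno %in% sim$truth$resno,
                          c("x", "y", "z")])
  near5 <- vapply(act$resno, function(rn) {
    a <- as.matrix(heavy[heavy$resno == rn, c("x", "y", "z")])
    d2 <- outer(rowSums(a^2), rowSums(txyz^2), "+") - 2 * a %*% t(txyz)
    sqrt(max(0, min(d2))) <= 5
  }, TRUE)
  expect_true(all(near5))
})

test_that("passive selection finds exposed neighbors of actives", {
  # isolated single-residue protein: nothing around the active
  lone <- atoms_from(list(1, "ALA", "CA", 0, 0, 0))
  acc1 <- access_for(1, 1.0)
  act1 <- tibble::tibble(chain = "A", resno = 1L)
  expect_equal(nrow(select_passive(lone, act1, acc1)), 0L)

  # two exposed residues 4 A apart, one active -> the other is passive
  two <- atoms_from(list(1, "ALA", "CA", 0, 0, 0),
                    list(2, "ALA", "CA", 4, 0, 0))
  acc2 <- access_for(1:2, 1.0)
  pas <- select_passive(two, act1, acc2)
  expect_equal(pas$resno, 2L)
})

test_that("passive selection matches a brute-force scan on a toy fold", {
  f <- toy_fold(n_res = 60, seed = 9) |> dplyr::filter(resno <= 30) |>
    as_pdb_atoms()
  acc <- relative_accessibility(f)
  act <- tibble::tibble(chain = "A", resno = c(5L, 12L))
  got <- select_passive(f, act, acc, neighbor_cutoff = 6.5,
                        sasa_cutoff = 0.3)
  heavy <- f |> dplyr::filter(!hydrogen, !het)
  axyz <- as.matrix(heavy[heavy$resno %in% act$resno, c("x", "y", "z")])
  want <- c()
  for (rn in setdiff(unique(heavy$resno), act$resno)) {
    rel <- acc$rel_sasa[acc$resno == rn]
    if (is.na(rel) || rel < 0.3) next
    b <- as.matrix(heavy[heavy$resno == rn, c("x", "y", "z")])
    d2 <- outer(rowSums(b^2), rowSums(axyz^2), "+") - 2 * b %*% t(axyz)
    if (sqrt(max(0, min(d2))) <= 6.5) want <- c(want, rn)
  }
  expect_setequal(got$resno, want)
  expect_equal(nrow(dplyr::inner_join(got, act, by = c("chain", "resno"))),
               0L)
})

test_that("active and passive sets must be disjoint", {
  a <- tibble::tibble(chain = "A", resno = 1:3)
  expect_error(docking_restraint_set(a, a), "disjoint")
})

test_that("AIR tables have one restraint per active with an OR group", {
  set <- docking_restraint_set(
    active = tibble::tibble(chain = "A", resno = 10L),
    partner_active = tibble::tibble(chain = "B", resno = c(772L, 773L)),
    bound = 2.0
  )
  tf <- withr::local_tempfile(fileext = ".tbl")
  write_air_table(set, tf)
  txt <- readLines(tf)
  expect_equal(length(txt), 1L)
  expect_equal(lengths(regmatches(txt, gregexpr(" or ", txt))), 1L)

  back <- read_air_table(tf)
  expect_equal(back$active$resno, 10L)
  expect_equal(back$active$upper, 2.0)
  expect_equal(back$active$lower, 0.0)
  expect_setequal(back$partners$resno, c(772L, 773L))
})

test_that("the four worked actives give four top-level restraints", {
  set <- docking_restraint_set(
    active = tibble::tibble(chain = "A", resno = c(27L, 31L, 43L, 45L)),
    partner_active = tibble::tibble(chain = "C",
                                    resno = c(772L, 773L, 776L, 777L))
  )
  tf <- withr::local_tempfile(fileext = ".tbl")
  write_air_table(set, tf)
  back <- read_air_table(tf)
  expect_equal(nrow(back$active), 4L)
  expect_equal(back$active$resno, c(27L, 31L, 43L, 45L))
  expect_equal(unique(table(back$partners$id)), 4L)

  empty <- docking_restraint_set(
    active = tibble::tibble(chain = character(), resno = integer()),
    partner_active = tibble::tibble(chain = "C", resno = 1L))
  expect_error(write_air_table(empty, tf), class = "methylmap_config_error")
})
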