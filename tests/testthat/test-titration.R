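peaks_for <- function(point, resno, r, assignment = "unambiguous",
                      resname = "ILE", site = "CD1") {
  tibble::tibble(point = point, chain = "A", resno = as.integer(resno),
                 resname = resname, site = site, assignment = assignment,
                 intensity = r)
}

series_two_points <- function(free_int, bound_int, conc = c(20, 20),
                              scans = c(128, 128),
                              assignment = "unambiguous") {
  n <- length(free_int)
  titration_series(
    dplyr::bind_rows(
      peaks_for("free", seq_len(n), free_int, assignment),
      peaks_for("1:1", seq_len(n), bound_int, assignment)
    ),
    tibble::tibble(point = c("free", "1:1"), ratio = c(0, 1),
                   conc = conc, scans = scans)
  )
}

test_that("normalization divides by concentration times scans", {
  s <- series_two_points(c(100, 200, 300), c(100, 200, 300),
                         conc = c(1, 1), scans = c(1, 1))
  ns <- normalize_intensities(s)
  expect_equal(ns$peaks$norm, ns$peaks$intensity)

  # 20 uM x 64 scans and 10 uM x 128 scans share the normalization constant
  s2 <- series_two_points(c(1280, 640), c(1280, 640),
                          conc = c(20, 10), scans = c(64, 128))
  n2 <- normalize_intensities(s2)$peaks
  expect_equal(n2$norm[n2$point == "free"], n2$norm[n2$point == "1:1"])

  s3 <- series_two_points(1280, 1280, conc = c(20, 20), scans = c(32, 32))
  expect_equal(normalize_intensities(s3)$peaks$norm, c(2, 2))
})

test_that("invalid titration metadata is rejected", {
  expect_error(
    series_two_points(1, 1, conc = c(0, 20)),
    class = "methylmap_config_error"
  )
  expect_error(
    series_two_points(1, 1, scans = c(0, 1)),
    class = "methylmap_config_error"
  )
})

test_that("relative intensities ratio against the free state", {
  s <- series_two_points(c(10, 10, 10), c(10, 10, 10))
  expect_equal(relative_intensities(s)$r, c(1, 1, 1))

  s <- series_two_points(2.0 * 20 * 128, rep(0.5 * 20 * 128, 1))
  expect_equal(relative_intensities(s)$r, 0.25)
})

test_that("probes missing from a spectrum are excluded with a reason", {
  peaks <- dplyr::bind_rows(
    peaks_for("free", 1:3, c(10, 10, 10)),
    peaks_for("1:1", 1:2, c(5, 5))
  )
  extra_free <- titration_series(
    peaks, tibble::tibble(point = c("free", "1:1"), ratio = c(0, 1),
                          conc = 20, scans = 128))
  rel <- relative_intensities(extra_free)
  expect_equal(sum(rel$excluded), 0L)
  expect_equal(nrow(rel), 2L)

  # probe 3 present only at the titration point -> excluded, reason recorded
  peaks2 <- dplyr::bind_rows(
    peaks_for("free", 1:2, c(10, 10)),
    peaks_for("1:1", 1:3, c(5, 5, 5))
  )
  rel2 <- relative_intensities(titration_series(
    peaks2, tibble::tibble(point = c("free", "1:1"), ratio = c(0, 1),
                           conc = 20, scans = 128)))
  expect_equal(sum(rel2$excluded), 1L)
  expect_match(rel2$reason[rel2$resno == 3], "free")

  # zero free-state intensity is guarded, not divided
  rel3 <- relative_intensities(series_two_points(c(0, 10, 10), c(5, 5, 5)))
  expect_true(rel3$excluded[rel3$resno == 1])
  expect_true(is.na(rel3$r[rel3$resno == 1]))
})

test_that("classification matches the worked threshold example", {
  # r = {1, 1, 1, 0.4} at 55 %/75 %: mean 0.85, thresholds 0.4675/0.6375
  s <- series_two_points(rep(10, 4), c(10, 10, 10, 4))
  mc <- classify_methyls(relative_intensities(s), 0.55, 0.75)
  expect_equal(mc$mu, 0.85)
  expect_equal(mc$t_strong, 0.4675)
  expect_equal(mc$t_slight, 0.6375)
  expect_equal(tidy(mc)$class, c("unaffected", "unaffected", "unaffected",
                                 "strong"))
  g <- glance(mc)
  expect_equal(g$n_strong, 1L)
  expect_equal(g$n_unaffected, 3L)
})

test_that("classification is scale invariant", {
  base <- series_two_points(rep(10, 5), c(10, 9, 8, 3, 6))
  cls0 <- tidy(classify_methyls(relative_intensities(base), 0.55, 0.75))$class
  for (k in c(10, 0.01)) {
    scaled <- series_two_points(rep(10, 5) * k, c(10, 9, 8, 3, 6) * k)
    cls <- tidy(classify_methyls(relative_intensities(scaled),
                                 0.55, 0.75))$class
    expect_equal(cls, cls0)
  }
  # rescaling concentration and scans together also cancels
  resc <- series_two_points(rep(10, 5), c(10, 9, 8, 3, 6),
                            conc = c(200, 200), scans = c(16, 16))
  expect_equal(tidy(classify_methyls(relative_intensities(resc),
                                     0.55, 0.75))$class, cls0)
})

test_that("all-equal relative intensities classify as unaffected", {
  s <- series_two_points(rep(10, 4), rep(7, 4))
  mc <- classify_methyls(relative_intensities(s), 0.55, 0.75)
  expect_equal(unique(tidy(mc)$class), "unaffected")
  expect_equal(mc$mu, 0.7)
})

test_that("a probe exactly at a threshold takes the milder class", {
  # r = {1, 1, 1.5, 0.5}: mean 1 exactly, T_strong = 0.5 at f_strong = 0.5
  s <- series_two_points(rep(10, 4), c(10, 10, 15, 5))
  mc <- classify_methyls(relative_intensities(s), 0.5, 0.75)
  expect_identical(mc$t_strong, 0.5)
  expect_equal(tidy(mc)$class[4], "slight")

  # r = {1, 1.25, 1, 0.75}: mean 1 exactly, T_slight = 0.75
  s2 <- series_two_points(rep(10, 4), c(10, 12.5, 10, 7.5))
  mc2 <- classify_methyls(relative_intensities(s2), 0.5, 0.75)
  expect_identical(mc2$t_slight, 0.75)
  expect_equal(tidy(mc2)$class[4], "unaffected")
})

test_that("degenerate configurations are refused", {
  s <- series_two_points(rep(10, 4), c(10, 10, 10, 4))
  rel <- relative_intensities(s)
  expect_error(classify_methyls(rel, 0.75, 0.55),
               class = "methylmap_config_error")
  expect_error(classify_methyls(rel, 0.55, 0.75, point = "1:9"),
               class = "methylmap_config_error")
  few <- series_two_points(rep(10, 4), c(10, 10, 10, 4),
                           assignment = "ambiguous")
  expect_error(classify_methyls(relative_intensities(few), 0.55, 0.75),
               class = "methylmap_analysis_error")
})

test_that("probe classes are conserved and exclusion is monotone", {
  set.seed(42)
  n <- 12
  r_free <- rep(10, n)
  r_bound <- runif(n, 2, 12)
  asn <- rep("unambiguous", n)
  s <- series_two_points(r_free, r_bound)
  mc <- classify_methyls(relative_intensities(s), 0.55, 0.75)
  counts <- table(tidy(mc)$class)
  expect_equal(sum(counts), n)

  # flipping one probe to ambiguous can move thresholds but never
  # resurrects an already excluded probe
  asn[3] <- "ambiguous"
  peaks <- dplyr::bind_rows(
    peaks_for("free", 1:n, r_free, asn),
    peaks_for("1:1", 1:n, r_bound, asn)
  )
  s2 <- titration_series(
    peaks, tibble::tibble(point = c("free", "1:1"), ratio = c(0, 1),
                          conc = 20, scans = 128))
  mc2 <- classify_methyls(relative_intensities(s2), 0.55, 0.75)
  excl1 <- tidy(mc)$resno[tidy(mc)$class == "excluded"]
  excl2 <- tidy(mc2)$resno[tidy(mc2)$class == "excluded"]
  expect_true(all(excl1 %in% excl2))
  expect_true(3 %in% excl2)
})

test_that("residue aggregation takes the most severe probe class", {
  rel <- tibble::tibble(
    point = "1:1", chain = "A",
    resno = c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L),
    resname = c("LEU", "LEU", "VAL", "VAL", "ILE", "VAL", "VAL", "ILE"),
    site = c("CD1", "CD2", "CG1", "CG2", "CD1", "CG1", "CG2", "CD1"),
    assignment = c(rep("unambiguous", 5), "ambiguous", "ambiguous",
                   "unambiguous"),
    r = c(0.2, 1.0, 0.5, 1.0, 0.5, NA, NA, 1.0),
    excluded = c(rep(FALSE, 5), TRUE, TRUE, FALSE),
    reason = c(rep(NA_character_, 5), "not unambiguously assigned",
               "not unambiguously assigned", NA)
  )
  mc <- classify_methyls(rel, 0.55, 0.80)
  residues <- tibble::tibble(
    chain = "A", resno = 1:6,
    resname = c("LEU", "VAL", "ILE", "VAL", "ILE", "ALA"))
  rc <- aggregate_residues(mc, residues)
  expect_equal(as.character(rc$class),
               c("strong",      # Leu: one strong + one unaffected probe
                 "slight",      # Val: one slight probe suffices
                 "slight",      # Ile: its single probe's class
                 "no-data",     # Val: both probes excluded
                 "unaffected",  # Ile: unaffected probe
                 "no-data"))    # Ala: never probed
})

test_that("titration series round-trips through the TSV format", {
  sim <- simulate_titration(small_scenario(seed = 3))
  dir <- withr::local_tempdir()
  write_titration(sim$series, dir)
  back <- read_titration(dir)
  expect_equal(back$peaks$intensity, sim$series$peaks$intensity)
  expect_equal(back$points, sim$series$points,  ignore_attr = TRUE)
})
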