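# Hand-written 1-model, 3-residue PDB text (Ala-Leu-Gly backbone + CB/CD).
mini_pdb_text <- function() {
  c(
    "HEADER    TEST STRUCTURE",
    "ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   1.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.000   1.420  1.00 10.00           C",
    "ATOM      4  CB  ALA A   1       1.988   2.232  -0.705  1.00 10.00           C",
    "ATOM      5  N   LEU A   2       3.332   1.092   1.512  1.00 10.00           N",
    "ATOM      6  CA  LEU A   2       3.988   1.110   2.810  1.00 10.00           C",
    "ATOM      7  C   LEU A   2       5.480   1.250   2.620  1.00 10.00           C",
    "ATOM      8  CB  LEU A   2       3.690  -0.160   3.610  1.00 10.00           C",
    "ATOM      9  CD1 LEU A   2       4.200  -0.300   5.050  1.00 10.00           C",
    "ATOM     10  CD2 LEU A   2       2.300  -0.700   3.560  1.00 10.00           C",
    "ATOM     11  N   GLY A   3       6.110   1.290   3.790  1.00 10.00           N",
    "ATOM     12  CA  GLY A   3       7.550   1.420   3.820  1.00 10.00           C",
    "ATOM     13  C   GLY A   3       8.150   1.480   5.220  1.00 10.00           C",
    "END"
  )
}

# A lone alanine with all heavy atoms at idealized geometry.
ala_atoms <- function() {
  as_pdb_atoms(tibble::tibble(
    chain = "A", resno = 1L, resname = "ALA",
    atom = c("N", "CA", "C", "O", "CB"),
    x = c(0.000, 1.458, 2.009, 1.383, 1.988),
    y = c(1.000, 1.000, 1.000, 1.000, 2.232),
    z = c(0.000, 0.000, 1.420, 2.390, -0.705)
  ))
}

# Quick atom-table builder: one row per atom spec c(resno, resname, atom,
# x, y, z), all on chain `chain`.
atoms_from <- function(..., chain = "A") {
  rows <- list(...)
  tibble::tibble(
    chain = chain,
    resno = as.integer(vapply(rows, function(r) as.integer(r[[1]]), 1L)),
    resname = vapply(rows, function(r) r[[2]], ""),
    atom = vapply(rows, function(r) r[[3]], ""),
    x = vapply(rows, function(r) as.numeric(r[[4]]), 1),
    y = vapply(rows, function(r) as.numeric(r[[5]]), 1),
    z = vapply(rows, function(r) as.numeric(r[[6]]), 1)
  ) |> as_pdb_atoms()
}

# Minimal residue classification tibble.
rc_from <- function(resno, resname, class, chain = "A") {
  tibble::tibble(
    chain = chain, resno = as.integer(resno), resname = resname,
    class = factor(class,
                   levels = c("strong", "slight", "unaffected", "no-data")),
    extension = FALSE, provenance = ""
  )
}

# Independent brute-force implementation of the +/-2 sequence extension.
brute_force_extension <- function(rc, include_no_data_ilv = TRUE) {
  ilv <- c("ILE", "LEU", "VAL")
  ext <- rep(FALSE, nrow(rc))
  for (i in seq_len(nrow(rc))) {
    if (!(rc$class[i] %in% c("strong", "slight"))) next
    for (off in c(-2, -1, 1, 2)) {
      j <- which(rc$chain == rc$chain[i] & rc$resno == rc$resno[i] + off)
      if (length(j) != 1) next
      if (rc$class[j] %in% c("strong", "slight")) next
      if (rc$resname[j] %in% ilv &&
          (rc$class[j] == "unaffected" ||
           (!include_no_data_ilv && rc$class[j] == "no-data"))) next
      ext[j] <- TRUE
    }
  }
  ext
}

# Random residue classification on a 50-residue chain; affected classes
# are only ever assigned to Ile/Leu/Val residues (the only probed types).
random_classification <- function(n = 50) {
  resname <- sample(c("ILE", "LEU", "VAL", "ALA", "GLY", "SER", "ARG"),
                    n, replace = TRUE)
  class <- ifelse(
    resname %in% c("ILE", "LEU", "VAL"),
    sample(c("strong", "slight", "unaffected", "no-data"), n, replace = TRUE),
    "no-data"
  )
  rc_from(seq_len(n), resname, class)
}

# Small scenario used where full-size simulations would be wasteful.
small_scenario <- function(seed = 1, ...) {
  binding_scenario(structure = toy_fold(n_res = 80, seed = seed),
                   seed = seed, ...)
}
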