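#' Enumerate [I,L,V] methyl probes
#'
#' Lists the methyl groups observable under Ile-d1 / Leu-d1,d2 / Val-g1,g2
#' labeling: one probe per Ile (CD1), two per Leu (CD1, CD2) and two per Val
#' (CG1, CG2); other residue types contribute nothing. Probes are identified
#' by the methyl carbon atom name, and assignments are non-stereospecific by
#' default.
#'
#' @param x A `pdb_atoms` tibble, a residue tibble (`chain`, `resno`,
#'   `resname`), or a character vector of 3-letter residue codes (a bare
#'   sequence; numbered 1..n on chain "A").
#' @return Tibble with `chain`, `resno`, `resname`, `site` (methyl carbon
#'   atom name) and `stereospecific` (all `FALSE`); unique on
#'   (chain, resno, site).
#' @examples
#' enumerate_methyl_probes(c("ALA", "LEU", "GLY"))
#' @export
enumerate_methyl_probes <- function(x) {
  res <- if (is.character(x)) {
    tibble(chain = "A", resno = seq_along(x), resname = toupper(x))
  } else if (inherits(x, "pdb_atoms") ||
             all(c("atom", "x") %in% names(x))) {
    structure_residues(x)
  } else {
    as_tibble(x)[, c("chain", "resno", "resname")]
  }
  sites <- tibble(
    resname = c("ILE", "LEU", "LEU", "VAL", "VAL"),
    site = c("CD1", "CD1", "CD2", "CG1", "CG2")
  )
  res |>
    inner_join(sites, by = "resname", relationship = "many-to-many") |>
    mutate(stereospecific = FALSE) |>
    arrange(.data$chain, .data$resno, .data$site) |>
    select("chain", "resno", "resname", "site", "stereospecific")
}
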