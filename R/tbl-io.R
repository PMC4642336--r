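#' Write distance restraints as CNS/XPLOR assign statements
#'
#' One `assign (sel) (sel) d dminus dplus` line per restraint, with
#' `d = upper`, `dminus = upper - lower`, `dplus = 0`, so the bounds are
#' `[d - dminus, d + dplus]`. Selections are written as
#' `(segid <chain> and resid <resno> and name <atom>)`; the origin is kept
#' as a trailing comment.
#'
#' @param restraints Restraint tibble (see [noe_restraints()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tbl <- function(restraints, file) {
  restraints <- as_tibble(restraints)
  sel <- function(chain, resno, atom) {
    sprintf("(segid %s and resid %d and name %s)", chain, resno, atom)
  }
  lines <- sprintf(
    "assign %s %s %6.3f %6.3f %6.3f ! %s",
    sel(restraints$chain1, restraints$resno1, restraints$atom1),
    sel(restraints$chain2, restraints$resno2, restraints$atom2),
    restraints$upper, restraints$upper - restraints$lower, 0,
    restraints$origin %||% "noe"
  )
  writeLines(lines, file)
  invisible(file)
}

# Split text into assign statements; returns character vector, comments
# stripped.
split_assigns <- function(lines) {
  txt <- paste(gsub("!.*$", "", lines), collapse = " ")
  parts <- strsplit(txt, "(?i)\\bassign\\b", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# Extract top-level balanced-parenthesis groups and the trailing numbers.
top_level_groups <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  groups <- character()
  buf <- character()
  for (ch in chars) {
    if (ch == "(") {
      depth <- depth + 1L
      if (depth == 1L) {
        buf <- character()
        next
      }
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth == 0L) {
        groups <- c(groups, paste(buf, collapse = ""))
        next
      }
    }
    if (depth >= 1L) buf <- c(buf, ch)
  }
  tail <- sub(".*\\)", "", s)
  nums <- as.numeric(strsplit(trimws(tail), "\\s+")[[1]])
  list(groups = groups, numbers = nums)
}

# A selection group is either a simple "key value and ..." conjunction or a
# top-level OR of parenthesized simple selections.
parse_selection_group <- function(g) {
  inner <- top_level_groups(paste0("(", g, ")"))$groups[1]
  if (grepl("\\(", inner)) {
    subs <- top_level_groups(inner)$groups
    purrr::map(subs, parse_simple_selection) |> bind_rows()
  } else {
    parse_simple_selection(inner)
  }
}

parse_simple_selection <- function(s) {
  grab <- function(key) {
    m <- stringr::str_match(s, paste0("(?i)\\b", key, "\\s+(\\S+)"))[, 2]
    m
  }
  tibble(
    chain = grab("segid") %||% NA_character_,
    resno = as.integer(grab("resid")),
    atom = grab("name")
  )
}

#' Read CNS-dialect distance restraints
#'
#' Parses `assign (sel) (sel) d dminus dplus` statements written by
#' [write_tbl()] (and plain single-selection statements from other tools).
#' Statements whose selections contain OR groups are ambiguous restraints;
#' use [read_air_table()] for those.
#'
#' @param file Path to a `.tbl` file.
#' @return Restraint tibble with bounds recovered as
#'   `lower = d - dminus`, `upper = d + dplus`, categorized by sequence
#'   separation. Atom names absent from a selection are returned as `NA`
#'   (whole-residue selection).
#' @export
read_tbl <- function(file) {
  stmts <- split_assigns(readLines(file, warn = FALSE))
  rows <- purrr::map(stmts, function(s) {
    parsed <- top_level_groups(s)
    if (length(parsed$groups) < 2 || length(parsed$numbers) < 3) {
      abort(sprintf("cannot parse assign statement: %s", s),
            class = "methylmap_parse_error")
    }
    s1 <- parse_selection_group(parsed$groups[1])
    s2 <- parse_selection_group(parsed$groups[2])
    if (nrow(s1) > 1 || nrow(s2) > 1) {
      abort("ambiguous (OR) selection found; use read_air_table()",
            class = "methylmap_parse_error")
    }
    d <- parsed$numbers
    tibble(chain1 = s1$chain, resno1 = s1$resno, atom1 = s1$atom,
           chain2 = s2$chain, resno2 = s2$resno, atom2 = s2$atom,
           lower = d[1] - d[2], upper = d[1] + d[3])
  })
  out <- bind_rows(rows)
  out$origin <- read_tbl_origins(file, nrow(out))
  categorize_restraints(out)
}

read_tbl_origins <- function(file, n) {
  lines <- readLines(file, warn = FALSE)
  tags <- stringr::str_match(lines[grepl("(?i)\\bassign\\b", lines, perl = TRUE)],
                             "!\\s*(\\S+)")[, 2]
  if (length(tags) == n) ifelse(is.na(tags), "noe", tags) else rep("noe", n)
}

#' Restraints as a flat tab-separated table
#'
#' The package's flat dialect: one row per restraint with explicit columns,
#' lossless for everything [write_tbl()] writes.
#'
#' @param restraints Restraint tibble.
#' @param file Path.
#' @return `write_restraints_tsv()`: `file`, invisibly;
#'   `read_restraints_tsv()`: the categorized restraint tibble.
#' @export
write_restraints_tsv <- function(restraints, file) {
  readr::write_tsv(as_tibble(restraints), file)
  invisible(file)
}

#' @rdname write_restraints_tsv
#' @export
read_restraints_tsv <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE)
  categorize_restraints(out)
}
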