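AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

MAX_GROUPS <- 32L
MAX_DIST <- 150L
MAX_DIST_PER_PAIR <- 31L

#' Construct a motif specification
#'
#' A motif specification has three parts.  Each *group* stands for one motif
#' residue and restricts the residue types (a string of one-letter codes read
#' as a disjunction, e.g. `"DN"` = Asp or Asn) and the secondary structure
#' (any subset of `h`/`s`/`c`; `"*"` means unrestricted) that a matching
#' residue may have.  Each *distance constraint* bounds the distance between
#' one named atom of one group and one named atom of another, holding the
#' least, measured and greatest admissible distance in Angstrom.  Each
#' *separation constraint* bounds the signed sequence separation (difference
#' of within-chain ordinal positions) between two groups.
#'
#' Specifications are limited to 32 groups, 150 distance constraints in total
#' and 31 distance constraints per unordered group pair.
#'
#' @param groups data.frame with columns `label` (integer), `types` (string of
#'   one-letter codes), `ss` (string over `h`,`s`,`c`, or `"*"`).
#' @param distances data.frame with columns `group_a`, `atom_a`, `group_b`,
#'   `atom_b`, `d_min`, `d_meas`, `d_max`; may be empty.
#' @param separations data.frame with columns `group_a`, `group_b`, `sep_min`,
#'   `sep_max`; may be empty.
#' @param provenance Character vector of free-text header lines.
#' @return An object of class `motif_spec`.
#' @seealso [parse_motif()], [write_motif()], [validate_motif()],
#'   [build_motif()]
#' @export
motif_spec <- function(groups,
                       distances = empty_distances(),
                       separations = empty_separations(),
                       provenance = character()) {
  groups$ss[groups$ss == "*"] <- "hsc"
  spec <- structure(
    list(groups = as.data.frame(groups),
         distances = as.data.frame(distances),
         separations = as.data.frame(separations),
         provenance = as.character(provenance)),
    class = "motif_spec"
  )
  issues <- validate_motif(spec)
  if (length(issues)) {
    stop("invalid motif specification:\n  ", paste(issues, collapse = "\n  "))
  }
  spec
}

empty_distances <- function() {
  data.frame(group_a = integer(), atom_a = character(),
             group_b = integer(), atom_b = character(),
             d_min = numeric(), d_meas = numeric(), d_max = numeric(),
             stringsAsFactors = FALSE)
}

empty_separations <- function() {
  data.frame(group_a = integer(), group_b = integer(),
             sep_min = integer(), sep_max = integer(),
             stringsAsFactors = FALSE)
}

#' Validate a motif specification
#'
#' Checks every structural invariant of the format and returns a description
#' of each violation; it reports rather than raises, so it can be used on
#' specs under construction.
#'
#' @param spec A `motif_spec` (or a bare list with the same fields).
#' @return Character vector of issues; empty when the specification is valid.
#' @export
validate_motif <- function(spec) {
  issues <- character()
  g <- spec$groups
  d <- spec$distances
  s <- spec$separations

  if (nrow(g) == 0) issues <- c(issues, "no groups defined")
  if (nrow(g) > MAX_GROUPS) {
    issues <- c(issues, sprintf("%d groups exceed the maximum of %d",
                                nrow(g), MAX_GROUPS))
  }
  if (anyDuplicated(g$label)) {
    issues <- c(issues, sprintf("duplicate group label %s",
                                g$label[duplicated(g$label)][1]))
  }
  for (i in seq_len(nrow(g))) {
    tys <- strsplit(g$types[i], "")[[1]]
    if (length(tys) == 0) {
      issues <- c(issues, sprintf("group %s: empty residue-type set", g$label[i]))
    } else if (!all(tys %in% AA1)) {
      issues <- c(issues, sprintf("group %s: unknown residue-type letter '%s'",
                                  g$label[i], setdiff(tys, AA1)[1]))
    }
    ssl <- strsplit(g$ss[i], "")[[1]]
    if (length(ssl) == 0 || !all(ssl %in% c("h", "s", "c"))) {
      issues <- c(issues, sprintf("group %s: secondary-structure set must be over h/s/c or '*'",
                                  g$label[i]))
    }
  }

  if (nrow(d) > MAX_DIST) {
    issues <- c(issues, sprintf("%d distance constraints exceed the maximum of %d",
                                nrow(d), MAX_DIST))
  }
  if (nrow(d)) {
    pair <- paste(pmin(d$group_a, d$group_b), pmax(d$group_a, d$group_b))
    over <- table(pair)
    over <- over[over > MAX_DIST_PER_PAIR]
    if (length(over)) {
      issues <- c(issues, sprintf(
        "group pair (%s) carries %d distance constraints (maximum %d per pair)",
        names(over)[1], over[1], MAX_DIST_PER_PAIR))
    }
  }
  for (i in seq_len(nrow(d))) {
    for (glab in c(d$group_a[i], d$group_b[i])) {
      if (!(glab %in% g$label)) {
        issues <- c(issues, sprintf("distance constraint %d references undeclared group %s", i, glab))
      }
    }
    if (d$group_a[i] == d$group_b[i] && d$atom_a[i] == d$atom_b[i]) {
      issues <- c(issues, sprintf("distance constraint %d relates an atom to itself", i))
    }
    if (is.na(d$d_min[i]) || is.na(d$d_max[i]) || is.na(d$d_meas[i])) {
      issues <- c(issues, sprintf("distance constraint %d has a non-numeric bound", i))
    } else {
      if (d$d_min[i] < 0) {
        issues <- c(issues, sprintf("distance constraint %d: negative lower bound", i))
      }
      if (d$d_min[i] > d$d_max[i]) {
        issues <- c(issues, sprintf("distance constraint %d: d_min %g > d_max %g",
                                    i, d$d_min[i], d$d_max[i]))
      } else if (d$d_meas[i] < d$d_min[i] || d$d_meas[i] > d$d_max[i]) {
        issues <- c(issues, sprintf("distance constraint %d: measured %g outside [%g, %g]",
                                    i, d$d_meas[i], d$d_min[i], d$d_max[i]))
      }
    }
  }

  for (i in seq_len(nrow(s))) {
    for (glab in c(s$group_a[i], s$group_b[i])) {
      if (!(glab %in% g$label)) {
        issues <- c(issues, sprintf("separation constraint %d references undeclared group %s", i, glab))
      }
    }
    if (!is.na(s$sep_min[i]) && !is.na(s$sep_max[i]) && s$sep_min[i] > s$sep_max[i]) {
      issues <- c(issues, sprintf("separation constraint %d: sep_min %d > sep_max %d",
                                  i, s$sep_min[i], s$sep_max[i]))
    }
  }

  issues
}

#' Parse the motif-specification text format
#'
#' The format consists of whitespace-delimited lines starting with one of
#' three case-insensitive keywords.  `GROUP <label> <types> <ss>` declares a
#' motif residue; `<types>` is a string of one-letter residue codes read as a
#' disjunction and `<ss>` is a combination of `h`/`s`/`c` or `*` for no
#' restriction.  `DIST <label_a> <atom_a> <label_b> <atom_b> <min> <measured>
#' <max>` bounds an inter-atomic distance in Angstrom.  `DELTA <label_a>
#' <label_b> <min> <max>` bounds the signed sequence separation between two
#' groups (DELTA lines are optional).  Lines starting with any other token are
#' retained verbatim as provenance comments; a trailing `#` comment on a
#' constraint line is dropped.
#'
#' @param text Path to a motif file, or a character vector of lines (a single
#'   string containing newlines is accepted).
#' @return A `motif_spec`.  Errors name the offending line.
#' @export
parse_motif <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- sub("\r$", "", lines)

  groups <- list()
  dists <- list()
  seps <- list()
  prov <- character()

  num <- function(tok, what, ln) {
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) stop("line ", ln, ": non-numeric ", what, " '", tok, "'")
    v
  }
  int <- function(tok, what, ln) {
    v <- num(tok, what, ln)
    if (v != round(v)) stop("line ", ln, ": non-integer ", what, " '", tok, "'")
    as.integer(v)
  }

  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) {
      if (grepl("^\\s*#", lines[ln])) prov <- c(prov, lines[ln])
      next
    }
    kw <- toupper(toks[1])
    if (kw == "GROUP") {
      if (length(toks) != 4) stop("line ", ln, ": GROUP needs <label> <types> <ss>")
      groups[[length(groups) + 1]] <- data.frame(
        label = int(toks[2], "group label", ln),
        types = toupper(toks[3]),
        ss = if (toks[4] == "*") "hsc" else tolower(toks[4]),
        stringsAsFactors = FALSE)
    } else if (kw == "DIST") {
      if (length(toks) != 8) {
        stop("line ", ln, ": DIST needs <label> <atom> <label> <atom> <min> <measured> <max>")
      }
      dists[[length(dists) + 1]] <- data.frame(
        group_a = int(toks[2], "group label", ln), atom_a = toupper(toks[3]),
        group_b = int(toks[4], "group label", ln), atom_b = toupper(toks[5]),
        d_min = num(toks[6], "distance", ln),
        d_meas = num(toks[7], "distance", ln),
        d_max = num(toks[8], "distance", ln),
        stringsAsFactors = FALSE)
    } else if (kw == "DELTA") {
      if (length(toks) != 5) stop("line ", ln, ": DELTA needs <label> <label> <min> <max>")
      seps[[length(seps) + 1]] <- data.frame(
        group_a = int(toks[2], "group label", ln),
        group_b = int(toks[3], "group label", ln),
        sep_min = int(toks[4], "separation", ln),
        sep_max = int(toks[5], "separation", ln),
        stringsAsFactors = FALSE)
    } else {
      prov <- c(prov, lines[ln])
    }
  }

  if (length(groups) == 0) stop("no GROUP lines found")
  motif_spec(
    groups = do.call(rbind, groups),
    distances = if (length(dists)) do.call(rbind, dists) else empty_distances(),
    separations = if (length(seps)) do.call(rbind, seps) else empty_separations(),
    provenance = prov
  )
}

#' Write a motif specification as text
#'
#' Emits the provenance header, then the GROUP block, the DIST block and
#' (when present) the DELTA block.  `parse_motif(write_motif(spec))` is the
#' identity, field for field.
#'
#' @param spec A valid `motif_spec`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_motif <- function(spec, path = NULL) {
  issues <- validate_motif(spec)
  if (length(issues)) {
    stop("refusing to write invalid motif specification:\n  ",
         paste(issues, collapse = "\n  "))
  }
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  g <- spec$groups
  d <- spec$distances
  s <- spec$separations
  lines <- c(
    spec$provenance,
    sprintf("GROUP %d %s %s", g$label, g$types,
            ifelse(g$ss == "hsc" | g$ss == "*", "*", g$ss)),
    if (nrow(d)) sprintf("DIST %d %s %d %s %s %s %s",
                         d$group_a, d$atom_a, d$group_b, d$atom_b,
                         fmt(d$d_min), fmt(d$d_meas), fmt(d$d_max)),
    if (nrow(s)) sprintf("DELTA %d %d %d %d",
                         s$group_a, s$group_b, s$sep_min, s$sep_max)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("motif_spec: %d groups, %d distance constraints, %d separation constraints\n",
              nrow(x$groups), nrow(x$distances), nrow(x$separations)))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  group %d: types {%s}, ss %s\n", x$groups$label[i],
                x$groups$types[i],
                if (x$groups$ss[i] == "hsc") "*" else x$groups$ss[i]))
  }
  invisible(x)
}
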