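#' Test whether one residue assignment satisfies a motif specification
#'
#' The core match predicate: an assignment of structure residues to motif
#' groups is an instance of the motif iff every group's residue passes its
#' type and secondary-structure filters, every distance constraint holds with
#' inclusive bounds (`d_min <= d <= d_max`), and every separation constraint
#' holds on the signed within-chain ordinal separation.  A named atom missing
#' from an assigned residue makes the assignment fail (it is not an error:
#' truncated side chains are routine).  Any finite separation constraint
#' between groups assigned to different chains fails.
#'
#' @param spec A `motif_spec`.
#' @param model A `structure_model`.
#' @param assignment Character vector of residue keys, either named by group
#'   label or unnamed in group order; must cover all groups injectively.
#' @param abs_delta Use `|separation|` instead of the signed separation.
#' @return `TRUE` or `FALSE`.
#' @export
match_satisfies <- function(spec, model, assignment, abs_delta = FALSE) {
  keys <- .assignment_keys(spec, assignment)
  if (anyNA(keys)) stop("assignment must cover every group")
  ri <- match(keys, model$residues$key)
  if (anyNA(ri)) return(FALSE)
  if (anyDuplicated(ri)) return(FALSE)

  g <- spec$groups
  for (i in seq_len(nrow(g))) {
    if (!grepl(model$residues$res_type[ri[i]], g$types[i], fixed = TRUE)) return(FALSE)
    if (!grepl(model$residues$ss[ri[i]], g$ss[i], fixed = TRUE)) return(FALSE)
  }

  d <- spec$distances
  for (i in seq_len(nrow(d))) {
    a <- get_atom(model, keys[match(d$group_a[i], g$label)], d$atom_a[i])
    b <- get_atom(model, keys[match(d$group_b[i], g$label)], d$atom_b[i])
    if (is.null(a) || is.null(b)) return(FALSE)
    dd <- sqrt(sum((a - b)^2))
    if (dd < d$d_min[i] || dd > d$d_max[i]) return(FALSE)
  }

  s <- spec$separations
  for (i in seq_len(nrow(s))) {
    ka <- keys[match(s$group_a[i], g$label)]
    kb <- keys[match(s$group_b[i], g$label)]
    if (.res_chain(model, ka) != .res_chain(model, kb)) return(FALSE)
    sep <- .res_ordinal(model, kb) - .res_ordinal(model, ka)
    if (abs_delta) sep <- abs(sep)
    if (sep < s$sep_min[i] || sep > s$sep_max[i]) return(FALSE)
  }
  TRUE
}

.assignment_keys <- function(spec, assignment) {
  labs <- as.character(spec$groups$label)
  if (!is.null(names(assignment)) && all(nzchar(names(assignment)))) {
    unname(assignment[labs])
  } else if (length(assignment) == length(labs)) {
    unname(assignment)
  } else {
    stop("assignment length does not match the number of groups")
  }
}

#' Find all motif matches in one structure
#'
#' Enumerates every assignment of structure residues to motif groups that
#' satisfies all constraints.  Per-group candidate lists are prefiltered by
#' residue type and secondary structure; groups are expanded
#' most-constrained-first (smallest candidate list, ties broken by descending
#' number of incident constraints); a partial assignment is rejected at the
#' first violated constraint among those whose endpoints are both assigned.
#' With `prune = FALSE` the same result is computed by checking only complete
#' assignments (useful to verify pruning soundness).
#'
#' @param model A `structure_model`.
#' @param spec A valid `motif_spec`.
#' @param dedupe_sets Collapse matches that assign the same residue *set* (in
#'   permuted order, possible when groups share constraints) to a single
#'   match.  By default permuted assignments are distinct matches.
#' @param abs_delta Use `|separation|` for DELTA constraints.
#' @param prune Reject partial assignments early (default); `FALSE` disables
#'   pruning.
#' @return List of `motif_match` objects, each with `structure_id`,
#'   `assignment` (residue keys named by group label), `measured` (Angstrom,
#'   one per distance constraint) and `separations` (one per DELTA
#'   constraint), in deterministic order (sorted by assigned residue keys).
#' @seealso [brute_force_search()] for the exhaustive reference oracle,
#'   [search_many()] for batches.
#' @export
find_matches <- function(model, spec, dedupe_sets = FALSE, abs_delta = FALSE,
                         prune = TRUE) {
  issues <- validate_motif(spec)
  if (length(issues)) {
    stop("invalid motif specification:\n  ", paste(issues, collapse = "\n  "))
  }
  if (nrow(model$residues) == 0) return(list())

  g <- spec$groups
  k <- nrow(g)
  in_set <- function(letters, set) {
    vapply(letters, grepl, logical(1), x = set, fixed = TRUE)
  }
  cand <- lapply(seq_len(k), function(i) {
    which(in_set(model$residues$res_type, g$types[i]) &
          in_set(model$residues$ss, g$ss[i]))
  })
  if (any(lengths(cand) == 0)) return(list())

  # expansion order: most-constrained-first
  inc <- vapply(seq_len(k), function(i) {
    lab <- g$label[i]
    sum(spec$distances$group_a == lab) + sum(spec$distances$group_b == lab) +
      sum(spec$separations$group_a == lab) + sum(spec$separations$group_b == lab)
  }, integer(1))
  ord <- order(lengths(cand), -inc)

  pos_of <- match(seq_len(k), ord)  # group index -> position in expansion order

  # constraints checkable once the group at expansion position p is assigned
  gl <- g$label
  dist_at <- vector("list", k)
  sep_at <- vector("list", k)
  for (i in seq_len(nrow(spec$distances))) {
    pa <- pos_of[match(spec$distances$group_a[i], gl)]
    pb <- pos_of[match(spec$distances$group_b[i], gl)]
    p <- max(pa, pb)
    dist_at[[p]] <- c(dist_at[[p]], i)
  }
  for (i in seq_len(nrow(spec$separations))) {
    pa <- pos_of[match(spec$separations$group_a[i], gl)]
    pb <- pos_of[match(spec$separations$group_b[i], gl)]
    p <- max(pa, pb)
    sep_at[[p]] <- c(sep_at[[p]], i)
  }

  # coordinate cache: per constraint endpoint, coords across its group's candidates
  res_keys <- model$residues$key
  coord_cache <- new.env(parent = emptyenv())
  cache_get <- function(gidx, atom) {
    id <- paste0(gidx, "|", atom)
    if (!is.null(coord_cache[[id]])) return(coord_cache[[id]])
    m <- .atom_block(model, res_keys[cand[[gidx]]], atom)
    coord_cache[[id]] <- m
    m
  }

  d <- spec$distances
  s <- spec$separations
  ords <- model$residues$ordinal
  chains <- model$residues$chain

  assigned_res <- integer(k)   # residue row index per expansion position
  assigned_pos <- integer(k)   # candidate position per expansion position
  used <- rep(FALSE, nrow(model$residues))
  out <- list()

  check_at <- function(p) {
    for (ci in dist_at[[p]]) {
      ga <- match(d$group_a[ci], gl); gb <- match(d$group_b[ci], gl)
      pa <- pos_of[ga]; pb <- pos_of[gb]
      a <- cache_get(ga, d$atom_a[ci])[assigned_pos[pa], ]
      b <- cache_get(gb, d$atom_b[ci])[assigned_pos[pb], ]
      if (anyNA(a) || anyNA(b)) return(FALSE)
      dd <- sqrt(sum((a - b)^2))
      if (dd < d$d_min[ci] || dd > d$d_max[ci]) return(FALSE)
    }
    for (ci in sep_at[[p]]) {
      ra <- assigned_res[pos_of[match(s$group_a[ci], gl)]]
      rb <- assigned_res[pos_of[match(s$group_b[ci], gl)]]
      if (chains[ra] != chains[rb]) return(FALSE)
      sep <- ords[rb] - ords[ra]
      if (abs_delta) sep <- abs(sep)
      if (sep < s$sep_min[ci] || sep > s$sep_max[ci]) return(FALSE)
    }
    TRUE
  }

  descend <- function(p) {
    gidx <- ord[p]
    for (ci in seq_along(cand[[gidx]])) {
      r <- cand[[gidx]][ci]
      if (used[r]) next
      assigned_res[p] <<- r
      assigned_pos[p] <<- ci
      ok <- if (prune || p == k) check_at(p) else TRUE
      if (ok && !prune && p == k) {
        # re-verify the full assignment without relying on incremental checks
        for (q in seq_len(k - 1)) if (!check_at(q)) { ok <- FALSE; break }
      }
      if (ok) {
        if (p == k) {
          keys <- character(k)
          keys[ord] <- res_keys[assigned_res]
          out[[length(out) + 1]] <<- keys
        } else {
          used[r] <<- TRUE
          descend(p + 1)
          used[r] <<- FALSE
        }
      }
    }
  }
  descend(1)

  if (length(out) == 0) return(list())
  sig <- vapply(out, paste, character(1), collapse = " ")
  out <- out[order(sig)]
  if (dedupe_sets) {
    setsig <- vapply(out, function(kk) paste(sort(kk), collapse = " "), character(1))
    out <- out[!duplicated(setsig)]
  }
  lapply(out, function(kk) .make_match(model, spec, kk, abs_delta))
}

.make_match <- function(model, spec, keys, abs_delta = FALSE) {
  g <- spec$groups
  d <- spec$distances
  s <- spec$separations
  measured <- vapply(seq_len(nrow(d)), function(i) {
    measure_distance(model,
                     keys[match(d$group_a[i], g$label)], d$atom_a[i],
                     keys[match(d$group_b[i], g$label)], d$atom_b[i])
  }, numeric(1))
  seps <- vapply(seq_len(nrow(s)), function(i) {
    ka <- keys[match(s$group_a[i], g$label)]
    kb <- keys[match(s$group_b[i], g$label)]
    sep <- .res_ordinal(model, kb) - .res_ordinal(model, ka)
    if (abs_delta) abs(sep) else sep
  }, integer(1))
  structure(
    list(structure_id = model$structure_id,
         assignment = setNames(keys, as.character(g$label)),
         res_types = model$residues$res_type[match(keys, model$residues$key)],
         measured = measured, separations = seps),
    class = "motif_match"
  )
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("motif_match in %s: %s\n", x$structure_id,
              paste(sprintf("%s=%s", names(x$assignment), x$assignment),
                    collapse = " ")))
  invisible(x)
}

#' Search several structures for a motif
#'
#' Runs [find_matches()] over a collection of structures (models, file paths,
#' or a mix).  Unreadable files are reported as warnings and skipped, never
#' fatal: a batch scan must survive individual bad inputs.
#'
#' @param inputs List/vector of `structure_model` objects and/or PDB file
#'   paths (a directory path is expanded to its `*.pdb` / `*.ent` files).
#' @param spec A valid `motif_spec`.
#' @inheritParams find_matches
#' @return A `search_report`: list with `spec_provenance`, `matches` (flat
#'   list of `motif_match`), `structures_searched` and `structures_with_hits`.
#' @seealso [format_hits()], [write_report()]
#' @export
search_many <- function(inputs, spec, dedupe_sets = FALSE, abs_delta = FALSE) {
  if (is.character(inputs)) inputs <- as.list(inputs)
  expanded <- list()
  for (x in inputs) {
    if (is.character(x) && length(x) == 1 && dir.exists(x)) {
      expanded <- c(expanded, as.list(
        list.files(x, pattern = "\\.(pdb|ent)$", full.names = TRUE,
                   ignore.case = TRUE)))
    } else {
      expanded <- c(expanded, list(x))
    }
  }

  matches <- list()
  searched <- 0L
  with_hits <- 0L
  for (x in expanded) {
    model <- if (inherits(x, "structure_model")) x else {
      tryCatch(read_pdb(x), error = function(e) {
        warning("skipping unreadable input '", x, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    }
    if (is.null(model)) next
    searched <- searched + 1L
    hits <- find_matches(model, spec, dedupe_sets = dedupe_sets,
                         abs_delta = abs_delta)
    if (length(hits)) with_hits <- with_hits + 1L
    matches <- c(matches, hits)
  }

  structure(
    list(spec_provenance = paste(spec$provenance, collapse = "\n"),
         matches = matches,
         structures_searched = searched,
         structures_with_hits = with_hits),
    class = "search_report"
  )
}

#' One line of text per match
#'
#' Serializes each match as the structure id followed by one
#' `chain:resnum:type` token per group in label order.
#'
#' @param report A `search_report` (or a list of `motif_match`).
#' @param sep Field separator (default tab).
#' @return Character vector, one element per match.
#' @export
format_hits <- function(report, sep = "\t") {
  matches <- if (inherits(report, "search_report")) report$matches else report
  vapply(matches, function(m) {
    toks <- paste0(m$assignment, ":", m$res_types)
    paste(c(m$structure_id, toks), collapse = sep)
  }, character(1))
}

#' Write a search report as TSV
#'
#' Columns: `structure_id`, one `group_<label>` column per group
#' (`chain:resnum` keys), then one `dist_<i>` column per distance constraint
#' with the measured distance in Angstrom.  Lines starting with `#` echo the
#' specification provenance.
#'
#' @param report A `search_report`.
#' @param path Output path.
#' @param spec The `motif_spec` searched (used for column naming); optional.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, spec = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(report$spec_provenance)) {
    prov <- strsplit(report$spec_provenance, "\n")[[1]]
    bare <- !grepl("^\\s*#", prov)
    prov[bare] <- paste0("# ", prov[bare])
    writeLines(prov, con)
  }
  writeLines(sprintf("# structures_searched=%d structures_with_hits=%d matches=%d",
                     report$structures_searched, report$structures_with_hits,
                     length(report$matches)), con)
  if (length(report$matches)) {
    m1 <- report$matches[[1]]
    header <- c("structure_id",
                paste0("group_", names(m1$assignment)),
                if (length(m1$measured)) paste0("dist_", seq_along(m1$measured)))
    writeLines(paste(header, collapse = "\t"), con)
    for (m in report$matches) {
      writeLines(paste(c(m$structure_id, unname(m$assignment),
                         if (length(m$measured)) sprintf("%.3f", m$measured)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @export
print.search_report <- function(x, ...) {
  cat(sprintf("search_report: %d match(es) in %d of %d structure(s)\n",
              length(x$matches), x$structures_with_hits, x$structures_searched))
  for (line in head(format_hits(x, sep = " "), 10)) cat(" ", line, "\n")
  if (length(x$matches) > 10) cat("  ...\n")
  invisible(x)
}

#' Number of k-residue subsets of an m-residue structure
#'
#' The size of the raw combinatorial search space that constraint filtering
#' prunes: the binomial coefficient `choose(m, k)` (exact; `0` when `k > m`).
#' Reported alongside searches to contextualize pruning effectiveness.
#'
#' @param m Residue count of the structure.
#' @param k Motif size (group count).
#' @return Exact count as a double.
#' @export
count_candidate_subsets <- function(m, k) {
  stopifnot(m >= 0, k >= 0)
  if (k > m) return(0)
  round(choose(m, k))
}
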