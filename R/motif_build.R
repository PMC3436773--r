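#' Distance-bound tolerance rule
#'
#' When a motif is generated from a structure, each distance constraint's
#' bounds are set to the measured distance plus/minus a tolerance, either an
#' absolute amount in Angstrom or a percentage of the measured value.
#'
#' @param value Non-negative tolerance value.
#' @param unit `"A"` (Angstrom, default) or `"percent"`.
#' @return A `tolerance` object.
#' @export
tolerance <- function(value, unit = c("A", "percent")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value < 0) {
    stop("tolerance value must be a single non-negative number")
  }
  structure(list(value = value, unit = unit), class = "tolerance")
}

.tol_bounds <- function(d, tol) {
  x <- if (tol$unit == "percent") d * tol$value / 100 else tol$value
  c(max(0, d - x), d + x)
}

#' Measure an inter-atomic distance
#'
#' @param model A `structure_model`.
#' @param res_a,res_b Residue keys (e.g. `"A:57"`).
#' @param atom_a,atom_b PDB atom names.
#' @return Euclidean distance in Angstrom.  A missing residue or atom is a
#'   lookup error naming the offending key.
#' @export
measure_distance <- function(model, res_a, atom_a, res_b, atom_b) {
  a <- get_atom(model, res_a, atom_a)
  if (is.null(a)) stop("no atom '", atom_a, "' in residue ", normalize_res_key(res_a))
  b <- get_atom(model, res_b, atom_b)
  if (is.null(b)) stop("no atom '", atom_b, "' in residue ", normalize_res_key(res_b))
  sqrt(sum((a - b)^2))
}

#' Generate a motif specification from residues of a structure
#'
#' Re-creates, from an existing structure and an ordered residue selection,
#' the motif specification that the selection itself satisfies: one group per
#' residue carrying its observed type (and observed secondary structure, or a
#' wildcard), one distance constraint per measured atom pair with bounds at
#' the measured distance plus/minus the tolerance, and optionally one signed
#' sequence-separation constraint between each consecutive pair of groups.
#' Because every bound brackets a measured value, the source residues are
#' guaranteed to be recovered by [find_matches()] on the source structure.
#'
#' @param model A `structure_model`.
#' @param residues Ordered character vector of 2--32 residue keys.
#' @param pairs `"ca_only"` (default: one CA--CA constraint per unordered
#'   residue pair) or a list of explicit pairs, each
#'   `list(res_a, atom_a, res_b, atom_b)`.
#' @param tol A [tolerance()]; default 1.0 Angstrom absolute.
#' @param ss_policy `"observed"` records each residue's assigned label;
#'   `"wildcard"` leaves secondary structure unrestricted.
#' @param delta `"strict"` (default) emits, for each consecutive group pair in
#'   the order given, a separation constraint fixed at the observed signed
#'   within-chain ordinal separation; a single number `k` widens those bounds
#'   by plus/minus `k`; `"none"` emits no separation constraints.
#' @return A `motif_spec` whose provenance records the source structure and
#'   residues.
#' @examples
#' m <- make_chain(fixture_recipe(n_residues = 40, seed = 7))
#' keys <- residue_keys(m)[c(5, 12, 30)]
#' spec <- build_motif(m, keys, tol = tolerance(1.0), ss_policy = "wildcard")
#' length(find_matches(m, spec)) >= 1
#' @export
build_motif <- function(model, residues, pairs = "ca_only",
                        tol = tolerance(1.0),
                        ss_policy = c("observed", "wildcard"),
                        delta = "strict") {
  ss_policy <- match.arg(ss_policy)
  residues <- normalize_res_key(residues)
  k <- length(residues)
  if (k < 2 || k > MAX_GROUPS) {
    stop("a motif needs between 2 and ", MAX_GROUPS, " residues, got ", k)
  }
  ri <- match(residues, model$residues$key)
  if (anyNA(ri)) stop("unknown residue key: ", residues[which(is.na(ri))[1]])
  if (anyDuplicated(residues)) stop("duplicate residue in selection")

  groups <- data.frame(
    label = seq_len(k),
    types = model$residues$res_type[ri],
    ss = if (ss_policy == "wildcard") "hsc" else model$residues$ss[ri],
    stringsAsFactors = FALSE
  )

  if (identical(pairs, "ca_only")) {
    pr <- list()
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        pr[[length(pr) + 1]] <- list(i, "CA", j, "CA")
      }
    }
  } else {
    if (!is.list(pairs) || length(pairs) == 0) {
      stop("'pairs' must be \"ca_only\" or a non-empty list of atom pairs")
    }
    pr <- lapply(pairs, function(p) {
      ia <- match(normalize_res_key(p[[1]]), residues)
      ib <- match(normalize_res_key(p[[3]]), residues)
      if (is.na(ia) || is.na(ib)) {
        stop("explicit pair references a residue outside the selection: ",
             p[[1]], " / ", p[[3]])
      }
      list(ia, toupper(p[[2]]), ib, toupper(p[[4]]))
    })
  }
  if (length(pr) > MAX_DIST) {
    stop(length(pr), " distance constraints exceed the limit of ", MAX_DIST,
         "; use ca_only mode or fewer explicit pairs")
  }

  dists <- do.call(rbind, lapply(pr, function(p) {
    d <- measure_distance(model, residues[p[[1]]], p[[2]], residues[p[[3]]], p[[4]])
    b <- .tol_bounds(d, tol)
    data.frame(group_a = p[[1]], atom_a = p[[2]],
               group_b = p[[3]], atom_b = p[[4]],
               d_min = b[1], d_meas = d, d_max = b[2],
               stringsAsFactors = FALSE)
  }))

  seps <- empty_separations()
  if (!identical(delta, "none")) {
    slack <- if (identical(delta, "strict")) 0L else {
      if (!is.numeric(delta) || length(delta) != 1 || delta < 0) {
        stop("'delta' must be \"strict\", \"none\" or a non-negative slack")
      }
      as.integer(delta)
    }
    chains <- .res_chain(model, residues)
    ords <- .res_ordinal(model, residues)
    if (k > 1 && length(unique(chains)) > 1) {
      stop("sequence separation is undefined across chains; use delta = \"none\"")
    }
    seps <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
      sep <- ords[i + 1] - ords[i]
      data.frame(group_a = i, group_b = i + 1L,
                 sep_min = sep - slack, sep_max = sep + slack,
                 stringsAsFactors = FALSE)
    }))
  }

  motif_spec(
    groups = groups, distances = dists, separations = seps,
    provenance = c(
      sprintf("# motif generated from %s", model$structure_id),
      sprintf("# residues: %s", paste(residues, collapse = " ")),
      sprintf("# tolerance: %s %s", format(tol$value), tol$unit)
    )
  )
}

#' Widen every distance constraint of a specification
#'
#' Decreases each lower bound and increases each upper bound by the extra
#' tolerance (lower bounds floored at 0).  Groups and separation constraints
#' are untouched.  Widening can only grow the match set.
#'
#' @param spec A valid `motif_spec`.
#' @param extra A [tolerance()] (percent tolerances are taken relative to each
#'   constraint's measured distance).
#' @return The widened `motif_spec`.
#' @export
widen_spec <- function(spec, extra) {
  stopifnot(inherits(spec, "motif_spec"), inherits(extra, "tolerance"))
  d <- spec$distances
  if (nrow(d)) {
    x <- if (extra$unit == "percent") d$d_meas * extra$value / 100 else extra$value
    d$d_min <- pmax(0, d$d_min - x)
    d$d_max <- d$d_max + x
    spec$distances <- d
  }
  spec
}
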