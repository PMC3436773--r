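#' Read a PDB-format coordinate file into a structure model
#'
#' Parses ATOM/HETATM records into an in-memory model of chains, residues and
#' atoms, normalized for motif searching: only the first MODEL of a multi-model
#' file is kept, alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by file order), selenomethionine (MSE) HETATM records
#' are retained as methionine, and waters, hydrogens and all other HETATM
#' records are discarded.  Every residue receives a secondary-structure label
#' via [assign_secondary_structure()].
#'
#' Parsing of the fixed-column format itself is delegated to
#' [bio3d::read.pdb()]; this function adds the normalization above and the
#' residue/atom indexing used by the search engine.
#'
#' @param input Path to a PDB file, or a character vector of PDB-format lines
#'   (a single string containing newlines is also accepted).
#' @param structure_id Identifier stored in the model; defaults to the file
#'   base name (or `"structure"` for literal text input).
#' @param windows Secondary-structure torsion windows, see [ss_windows()].
#' @return An object of class `structure_model`: a list with elements
#'   `structure_id`, `source`, `residues` (one row per residue: `chain`,
#'   `resno`, `insert`, `key`, `ordinal`, `res3`, `res_type`, `ss`, `phi`,
#'   `psi`) and `atoms` (one row per atom), plus a coordinate lookup matrix.
#'   Residue keys have the form `"<chain>:<resno><insert>"`, e.g. `"A:57"`;
#'   `ordinal` is the 1-based position of the residue within its chain in file
#'   order (robust to author-numbering gaps), which is the quantity sequence
#'   separation (DELTA) constraints apply to.
#' @seealso [get_atom()], [write_pdb()], [build_motif()], [find_matches()]
#' @examples
#' pdb <- make_chain(fixture_recipe(n_residues = 20, seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(pdb, f)
#' m <- read_pdb(f)
#' head(m$residues)
#' @export
read_pdb <- function(input, structure_id = NULL, windows = ss_windows()) {
  is_path <- length(input) == 1 && !grepl("\n", input) && file.exists(input)
  if (is_path) {
    path <- input
    if (is.null(structure_id)) {
      structure_id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path),
                          ignore.case = TRUE)
    }
  } else {
    lines <- if (length(input) == 1) strsplit(input, "\n", fixed = TRUE)[[1]] else input
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(structure_id)) structure_id <- "structure"
  }

  .check_coordinate_fields(readLines(path, warn = FALSE))

  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  water <- c("HOH", "DOD", "WAT", "H2O")
  keep <- (at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")) &
    !(at$resid %in% water)
  at <- at[keep, , drop = FALSE]

  elesy <- trimws(ifelse(is.na(at$elesy), "", at$elesy))
  hydro <- elesy %in% c("H", "D") |
    (elesy == "" & grepl("^[0-9]*[HD]", trimws(at$elety)))
  at <- at[!hydro, , drop = FALSE]

  if (nrow(at) == 0) {
    stop("empty structure: no usable ATOM records in ", structure_id)
  }

  atoms <- data.frame(
    chain  = ifelse(is.na(at$chain), "", at$chain),
    resno  = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    res3   = at$resid,
    elety  = trimws(at$elety),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altloc(atoms)

  model_from_atoms(atoms, structure_id = structure_id,
                   source = if (is_path) path else "<text>", windows = windows)
}

# Reject ATOM/HETATM lines (first model only) whose x/y/z columns are not
# numeric, naming the offending line -- bio3d's own error carries no location.
.check_coordinate_fields <- function(lines) {
  rec <- substr(lines, 1, 6)
  endmdl <- which(trimws(rec) == "ENDMDL")
  last <- if (length(endmdl)) endmdl[1] else length(lines)
  for (i in seq_len(last)) {
    if (!(substr(lines[i], 1, 4) == "ATOM" || substr(lines[i], 1, 6) == "HETATM")) next
    for (col in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- trimws(substr(lines[i], col[1], col[2]))
      if (fld == "" || is.na(suppressWarnings(as.numeric(fld)))) {
        stop("parse error at line ", i, ": malformed coordinate field '",
             fld, "'")
      }
    }
  }
  invisible(TRUE)
}

# Keep, per (residue, atom name), the highest-occupancy altloc; ties -> first
# occurrence in the file.  Input and output are in file order.
.resolve_altloc <- function(atoms) {
  gid <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(match(gid, unique(gid)), -atoms$occ, seq_len(nrow(atoms)))
  sel <- ord[!duplicated(gid[ord])]
  atoms[sort(sel), , drop = FALSE]
}

#' @keywords internal
#' @noRd
model_from_atoms <- function(atoms, structure_id, source = "<memory>",
                             windows = ss_windows()) {
  key <- paste0(atoms$chain, ":", atoms$resno, atoms$insert)
  first <- !duplicated(key)
  residues <- data.frame(
    chain  = atoms$chain[first],
    resno  = atoms$resno[first],
    insert = atoms$insert[first],
    key    = key[first],
    res3   = atoms$res3[first],
    stringsAsFactors = FALSE
  )
  residues$ordinal <- stats::ave(seq_len(nrow(residues)), residues$chain,
                                 FUN = seq_along)
  residues$res_type <- suppressWarnings(bio3d::aa321(residues$res3))
  residues$res_type[is.na(residues$res_type)] <- "X"
  residues$ss <- "c"
  residues$phi <- NA_real_
  residues$psi <- NA_real_

  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rownames(xyz) <- paste0(key, "|", atoms$elety)
  if (anyDuplicated(rownames(xyz))) {
    dup <- rownames(xyz)[duplicated(rownames(xyz))][1]
    stop("duplicate atom after altloc resolution: ", dup)
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ", structure_id)

  model <- structure(
    list(structure_id = structure_id, source = source,
         residues = residues, atoms = atoms, xyz = xyz),
    class = "structure_model"
  )
  assign_secondary_structure(model, windows)
}

#' Torsion windows used for secondary-structure assignment
#'
#' Assignment is by backbone phi/psi windows: a residue is a helix candidate if
#' phi lies in `helix_phi` and psi in `helix_psi`, and a strand candidate if
#' phi lies in `strand_phi` and psi in either `strand_psi` interval (the second
#' interval catches the wrap-around near -180 degrees).  Candidate runs of at
#' least `helix_min_run` (resp. `strand_min_run`) consecutive residues are
#' labelled `h` (resp. `s`); everything else is coil `c`.  Two consecutive
#' residues are treated as peptide-bonded only if their C--N distance is at
#' most `peptide_bond_max` Angstrom, so chain breaks never contribute torsions.
#'
#' @param ... Named overrides of the defaults below.
#' @return A list of window parameters (degrees, Angstrom).
#' @export
ss_windows <- function(...) {
  w <- list(
    helix_phi = c(-100, -30), helix_psi = c(-80, -5), helix_min_run = 4,
    strand_phi = c(-180, -40), strand_psi = c(90, 180),
    strand_psi2 = c(-180, -170), strand_min_run = 3,
    peptide_bond_max = 2.0
  )
  modifyList(w, list(...))
}

#' Assign secondary-structure labels to every residue
#'
#' Labels each residue `h` (helix), `s` (strand) or `c` (coil) from its
#' backbone phi/psi torsions, using the windows of [ss_windows()].  Residues
#' for which the required backbone atoms (or a bonded neighbour) are missing
#' degrade to `c`; the operation never fails.  Assignment is deterministic:
#' identical coordinates always give identical labels.
#'
#' @param model A `structure_model`.
#' @param windows See [ss_windows()].
#' @return The model with updated `ss`, `phi` and `psi` residue columns.
#' @export
assign_secondary_structure <- function(model, windows = ss_windows()) {
  res <- model$residues
  n <- nrow(res)
  ncoord <- .atom_block(model, res$key, "N")
  cacoord <- .atom_block(model, res$key, "CA")
  ccoord <- .atom_block(model, res$key, "C")

  # peptide bond between residue i and i+1 (same chain, consecutive ordinal)
  bonded <- rep(FALSE, n)
  if (n > 1) {
    i <- seq_len(n - 1)
    d <- sqrt(rowSums((ccoord[i, , drop = FALSE] - ncoord[i + 1, , drop = FALSE])^2))
    bonded[i] <- res$chain[i] == res$chain[i + 1] &
      res$ordinal[i] + 1 == res$ordinal[i + 1] &
      !is.na(d) & d <= windows$peptide_bond_max
  }

  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && bonded[i - 1]) {
      quad <- rbind(ccoord[i - 1, ], ncoord[i, ], cacoord[i, ], ccoord[i, ])
      if (all(is.finite(quad))) {
        phi[i] <- bio3d::torsion.xyz(as.vector(t(quad)), atm.inc = 4)
      }
    }
    if (i < n && bonded[i]) {
      quad <- rbind(ncoord[i, ], cacoord[i, ], ccoord[i, ], ncoord[i + 1, ])
      if (all(is.finite(quad))) {
        psi[i] <- bio3d::torsion.xyz(as.vector(t(quad)), atm.inc = 4)
      }
    }
  }

  in_win <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  hcand <- in_win(phi, windows$helix_phi) & in_win(psi, windows$helix_psi)
  scand <- in_win(phi, windows$strand_phi) &
    (in_win(psi, windows$strand_psi) | in_win(psi, windows$strand_psi2))

  ss <- rep("c", n)
  ss[.runs_at_least(hcand, windows$helix_min_run)] <- "h"
  ss[.runs_at_least(scand, windows$strand_min_run)] <- "s"

  model$residues$ss <- ss
  model$residues$phi <- phi
  model$residues$psi <- psi
  model
}

# TRUE positions belonging to a run of >= k consecutive TRUEs
.runs_at_least <- function(mask, k) {
  r <- rle(mask)
  rep(r$values & r$lengths >= k, r$lengths)
}

# n x 3 matrix of the named atom for each residue key (NA rows when absent)
.atom_block <- function(model, keys, atom) {
  idx <- match(paste0(keys, "|", atom), rownames(model$xyz))
  out <- matrix(NA_real_, length(keys), 3)
  ok <- !is.na(idx)
  out[ok, ] <- model$xyz[idx[ok], , drop = FALSE]
  out
}

#' Look up one atom's coordinates
#'
#' Exact-name lookup of an atom within a residue.  An absent atom is a normal
#' value (`NULL`), not an error: truncated side chains are common in real
#' structures and must not abort a search.
#'
#' @param model A `structure_model`.
#' @param residue Residue key, e.g. `"A:57"` (the form `"A57"` is also
#'   accepted; an insertion code is appended, e.g. `"A:100A"`).
#' @param atom_name PDB atom name, e.g. `"CA"`, `"OD1"`.
#' @return Numeric length-3 coordinate vector in Angstrom, or `NULL`.
#' @export
get_atom <- function(model, residue, atom_name) {
  key <- normalize_res_key(residue)
  i <- match(paste0(key, "|", atom_name), rownames(model$xyz))
  if (is.na(i)) NULL else unname(model$xyz[i, ])
}

#' Canonical residue keys of a model
#'
#' @param model A `structure_model`.
#' @return Character vector of `"chain:resno[insert]"` keys in file order.
#' @export
residue_keys <- function(model) model$residues$key

#' @keywords internal
#' @noRd
normalize_res_key <- function(key) {
  key <- trimws(key)
  ifelse(grepl(":", key, fixed = TRUE), key,
         sub("^([A-Za-z0-9])(-?[0-9]+[A-Za-z]?)$", "\\1:\\2", key))
}

# ordinal (position within chain) for a vector of residue keys; NA if unknown
.res_ordinal <- function(model, keys) {
  model$residues$ordinal[match(keys, model$residues$key)]
}

# chain id for a vector of residue keys
.res_chain <- function(model, keys) {
  model$residues$chain[match(keys, model$residues$key)]
}

#' Write a structure model as a minimal PDB file
#'
#' Emits standard ATOM records (via [bio3d::write.pdb()]) such that
#' [read_pdb()] round-trips residue keys, atom names and coordinates to the
#' format's 3-decimal precision.
#'
#' @param model A `structure_model` with at least one residue.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  if (!inherits(model, "structure_model") || nrow(model$residues) == 0) {
    stop("cannot write an empty structure model")
  }
  a <- model$atoms
  xyz <- as.vector(t(cbind(a$x, a$y, a$z)))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$res3,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$insert == "", NA, a$insert),
    eleno = seq_len(nrow(a)), elety = a$elety,
    o = a$occ, b = rep(0, nrow(a)), verbose = FALSE
  )
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  nch <- length(unique(x$residues$chain))
  cat(sprintf("structure_model '%s': %d residues in %d chain%s, %d atoms\n",
              x$structure_id, nrow(x$residues), nch,
              if (nch == 1) "" else "s", nrow(x$atoms)))
  ssc <- table(factor(x$residues$ss, levels = c("h", "s", "c")))
  cat(sprintf("  secondary structure: h=%d s=%d c=%d\n",
              ssc[["h"]], ssc[["s"]], ssc[["c"]]))
  invisible(x)
}
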