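# Idealized backbone internal coordinates (Angstrom, degrees)
.GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  a_c_ca_cb = 110.5, t_cb = 122.6, omega = 180
)

# Torsion angles emitted per secondary-structure state.  Coil uses a small
# deterministic repertoire chosen to fall outside both the helix and strand
# torsion windows of ss_windows().
.SS_TORSIONS <- list(
  h = list(phi = -57, psi = -47),
  s = list(phi = -120, psi = 120),
  c = list(phi = c(-140, 60, -70), psi = c(70, 60, -150))
)

# NeRF internal-to-Cartesian placement: position d such that |c-d| = bond,
# angle(b,c,d) = angle_deg and torsion(a,b,c,d) = torsion_deg.
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi), bond * sin(th) * sin(chi))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m2, n)
  as.vector(rot %*% d2) + c
}

#' Recipe for a synthetic test structure
#'
#' Describes a single-chain structure of idealized residues (full backbone
#' N/CA/C/O plus CB except glycine, built from standard internal coordinates)
#' with optional planted motif copies.  The same recipe and seed always
#' produce a byte-identical structure.
#'
#' @param n_residues Chain length.
#' @param seed Integer seed controlling every random choice in the recipe.
#' @param ss Optional character vector (or single string) of per-residue
#'   `h`/`s`/`c` states; by default random segments (helix >= 5, strand >= 4,
#'   coil 2--6 residues) are drawn.
#' @param decoy_types Optional named probability vector over one-letter codes
#'   for the background residue types; default uniform over the 20 standard
#'   types.
#' @param planted List of planted-motif entries, each a list with elements
#'   `positions` (chain ordinals of the template residues), optional `types`
#'   (one-letter codes forced at those positions), `copies` (default 1),
#'   `copy_positions` (list of `copies - 1` ordinal vectors receiving
#'   rigid-motion images of the template geometry) and `sigma` (isotropic
#'   Gaussian coordinate noise in Angstrom applied per copy, default 0).
#' @param resno_gap_after Chain ordinals after which the author residue
#'   numbering jumps by 10 (to exercise numbering-gap handling).
#' @param chain_id,structure_id Identifiers for the generated model.
#' @return A `fixture_recipe` object.
#' @seealso [make_chain()]
#' @export
fixture_recipe <- function(n_residues, seed = 1, ss = NULL, decoy_types = NULL,
                           planted = list(), resno_gap_after = integer(0),
                           chain_id = "A", structure_id = NULL) {
  stopifnot(n_residues >= 1)
  if (!is.null(ss)) {
    if (length(ss) == 1 && nchar(ss) > 1) ss <- strsplit(ss, "")[[1]]
    if (length(ss) != n_residues || !all(ss %in% c("h", "s", "c"))) {
      stop("'ss' must give one of h/s/c for each residue")
    }
  }
  all_pos <- integer(0)
  for (p in planted) {
    if (is.null(p$positions)) stop("planted entry lacks 'positions'")
    copies <- if (is.null(p$copies)) 1L else p$copies
    cp <- if (is.null(p$copy_positions)) list() else p$copy_positions
    if (length(cp) != copies - 1) {
      stop("planted entry with ", copies, " copies needs ", copies - 1,
           " copy_positions vectors")
    }
    for (v in c(list(p$positions), cp)) {
      if (length(v) != length(p$positions)) {
        stop("copy_positions must match the template length")
      }
      if (any(v < 1 | v > n_residues)) {
        stop("planted motif position outside the chain (1..", n_residues, ")")
      }
      all_pos <- c(all_pos, v)
    }
  }
  if (anyDuplicated(all_pos)) stop("planted motif positions overlap")

  structure(
    list(n_residues = as.integer(n_residues), seed = as.integer(seed),
         ss = ss, decoy_types = decoy_types, planted = planted,
         resno_gap_after = as.integer(resno_gap_after),
         chain_id = chain_id,
         structure_id = structure_id %||%
           sprintf("fixture%d_%d", as.integer(n_residues), as.integer(seed))),
    class = "fixture_recipe"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic structure with planted motifs
#'
#' Builds the chain described by a [fixture_recipe()]: residues are placed
#' with idealized internal coordinates along the requested (or randomly
#' segmented) secondary-structure states; planted template positions get
#' their forced residue types; each additional copy receives a random
#' rigid-motion image of the template's atoms, recentred on the copy's
#' original CA centroid so the structure stays compact; per-copy Gaussian
#' coordinate noise is added last.  Because copies are rigid images, every
#' internal distance of the template is reproduced exactly in each copy
#' (before noise), so a motif built from one copy matches all of them.
#'
#' @param recipe A [fixture_recipe()].
#' @return A `structure_model` with an extra element `planted`: one entry per
#'   planted motif, a list of residue-key vectors (template first, then each
#'   copy) — the ground truth for search tests.
#' @examples
#' r <- fixture_recipe(60, seed = 3,
#'   planted = list(list(positions = c(10, 25, 40), types = c("H", "D", "S"))))
#' m <- make_chain(r)
#' m$planted
#' @export
make_chain <- function(recipe) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(recipe$seed)
  n <- recipe$n_residues

  ss <- recipe$ss %||% {
    out <- character(0)
    while (length(out) < n) {
      kind <- sample(c("h", "s", "c"), 1)
      len <- switch(kind, h = sample(5:9, 1), s = sample(4:6, 1),
                    c = sample(2:6, 1))
      out <- c(out, rep(kind, len))
    }
    out[seq_len(n)]
  }

  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    tt <- .SS_TORSIONS[[ss[i]]]
    j <- if (ss[i] == "c") sample(seq_along(tt$phi), 1) else 1L
    phi[i] <- tt$phi[j]
    psi[i] <- tt$psi[j]
  }

  aa20 <- setdiff(AA1, "X")
  prob <- recipe$decoy_types
  types <- if (is.null(prob)) {
    sample(aa20, n, replace = TRUE)
  } else {
    sample(names(prob), n, replace = TRUE, prob = as.numeric(prob))
  }
  for (p in recipe$planted) {
    if (!is.null(p$types)) types[p$positions] <- p$types
    copies <- p$copies %||% 1L
    for (j in seq_len(copies - 1)) {
      types[p$copy_positions[[j]]] <- types[p$positions]
    }
  }

  # backbone trace
  bb <- vector("list", n)
  g <- .GEOM
  for (i in seq_len(n)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(g$b_n_ca, 0, 0)
      th <- g$a_n_ca_c * pi / 180
      C <- CA + g$b_ca_c * c(-cos(th), sin(th), 0)
    } else {
      prev <- bb[[i - 1]]
      N <- .place_atom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA <- .place_atom(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- .place_atom(prev$C, N, CA, g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    bb[[i]] <- list(N = N, CA = CA, C = C)
  }
  res_atoms <- vector("list", n)
  for (i in seq_len(n)) {
    at <- bb[[i]]
    at$O <- .place_atom(at$N, at$CA, at$C, g$b_c_o, g$a_ca_c_o, psi[i] - 180)
    if (types[i] != "G") {
      at$CB <- .place_atom(at$N, at$C, at$CA, g$b_ca_cb, g$a_c_ca_cb, g$t_cb)
    }
    res_atoms[[i]] <- at
  }

  # transplant rigid-motion copies of each planted template, then add noise
  planted_keys <- list()
  resno <- seq_len(n)
  for (gap in recipe$resno_gap_after) {
    resno[resno > gap] <- resno[resno > gap] + 10L
  }
  key_of <- function(pos) paste0(recipe$chain_id, ":", resno[pos])

  for (p in recipe$planted) {
    copies <- p$copies %||% 1L
    sigma <- p$sigma %||% 0
    sets <- c(list(p$positions), if (copies > 1) p$copy_positions else list())
    for (j in seq_along(sets)) {
      if (j > 1) {
        rot <- .random_rotation()
        tmpl_ca <- do.call(rbind, lapply(p$positions, function(q) res_atoms[[q]]$CA))
        targ_ca <- do.call(rbind, lapply(sets[[j]], function(q) res_atoms[[q]]$CA))
        shift <- colMeans(targ_ca) - colMeans(tmpl_ca %*% rot)
        for (idx in seq_along(p$positions)) {
          src <- res_atoms[[p$positions[idx]]]
          res_atoms[[sets[[j]][idx]]] <- lapply(src, function(v) {
            as.vector(v %*% rot) + shift
          })
        }
      }
      if (sigma > 0) {
        for (q in sets[[j]]) {
          res_atoms[[q]] <- lapply(res_atoms[[q]], function(v) {
            v + rnorm(3, sd = sigma)
          })
        }
      }
    }
    planted_keys[[length(planted_keys) + 1]] <- lapply(sets, key_of)
  }

  rows <- list()
  for (i in seq_len(n)) {
    res3 <- bio3d::aa123(types[i])
    for (nm in names(res_atoms[[i]])) {
      v <- res_atoms[[i]][[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        chain = recipe$chain_id, resno = resno[i], insert = "", res3 = res3,
        elety = nm, x = round(v[1], 3), y = round(v[2], 3), z = round(v[3], 3),
        occ = 1, stringsAsFactors = FALSE)
    }
  }
  model <- model_from_atoms(do.call(rbind, rows),
                            structure_id = recipe$structure_id,
                            source = "<fixture>")
  model$planted <- planted_keys
  model$recipe <- recipe
  model
}

# uniform-ish random proper rotation (QR of a Gaussian matrix, det corrected)
.random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Exhaustive reference search (oracle)
#'
#' Enumerates *every* injective assignment of type/ss-compatible residues to
#' motif groups — with no constraint-ordering heuristics, no early pruning and
#' no shared search path with [find_matches()] — and keeps exactly those for
#' which [match_satisfies()] is true.  This is the ground-truth oracle that
#' the pruned search engine is validated against.
#'
#' @param model A `structure_model`.
#' @param spec A valid `motif_spec`.
#' @param max_assignments Refuse (with a size report) when the number of
#'   candidate assignments to enumerate exceeds this guard.
#' @inheritParams find_matches
#' @return List of `motif_match` in the same deterministic order as
#'   [find_matches()].
#' @export
brute_force_search <- function(model, spec, dedupe_sets = FALSE,
                               abs_delta = FALSE, max_assignments = 1e7) {
  issues <- validate_motif(spec)
  if (length(issues)) {
    stop("invalid motif specification:\n  ", paste(issues, collapse = "\n  "))
  }
  if (nrow(model$residues) == 0) return(list())
  g <- spec$groups
  k <- nrow(g)
  cand <- lapply(seq_len(k), function(i) {
    tset <- strsplit(g$types[i], "")[[1]]
    sset <- strsplit(g$ss[i], "")[[1]]
    which(model$residues$res_type %in% tset & model$residues$ss %in% sset)
  })
  if (any(lengths(cand) == 0)) return(list())
  total <- prod(lengths(cand))
  if (total > max_assignments) {
    stop("brute force refused: ", format(total, big.mark = ","),
         " candidate assignments exceed the guard of ",
         format(max_assignments, big.mark = ","))
  }

  grid <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  keep <- !apply(grid, 1, anyDuplicated)
  grid <- grid[keep, , drop = FALSE]

  out <- list()
  keys_all <- model$residues$key
  for (r in seq_len(nrow(grid))) {
    keys <- keys_all[grid[r, ]]
    if (match_satisfies(spec, model, keys, abs_delta = abs_delta)) {
      out[[length(out) + 1]] <- keys
    }
  }
  if (length(out) == 0) return(list())
  sig <- vapply(out, paste, character(1), collapse = " ")
  out <- out[order(sig)]
  if (dedupe_sets) {
    setsig <- vapply(out, function(kk) paste(sort(kk), collapse = " "), character(1))
    out <- out[!duplicated(setsig)]
  }
  lapply(out, function(kk) .make_match(model, spec, kk, abs_delta))
}
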