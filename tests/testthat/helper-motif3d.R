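# Shared fixtures: small PDB text builders and randomized search cases.

# One ATOM record in fixed-column PDB format.
pdb_line <- function(serial, name, res3, chain, resno, x, y, z,
                     occ = 1, alt = "", insert = "", type = "ATOM",
                     element = substr(trimws(name), 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          alt, res3, chain, resno, insert, x, y, z, occ, 0, element)
}

# PDB text for residues given as list(chain, resno, res3, atoms = named list
# of coordinate vectors).
pdb_text <- function(residues) {
  serial <- 0
  lines <- character(0)
  for (r in residues) {
    for (nm in names(r$atoms)) {
      serial <- serial + 1
      v <- r$atoms[[nm]]
      lines <- c(lines, pdb_line(serial, nm, r$res3, r$chain, r$resno,
                                 v[1], v[2], v[3],
                                 insert = r$insert %||% ""))
    }
  }
  c(lines, "END")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A residue with only a CA atom -- enough for CA-only motif machinery.
ca_res <- function(chain, resno, res3, xyz) {
  list(chain = chain, resno = resno, res3 = res3, atoms = list(CA = xyz))
}

# Random fixture + motif pair for oracle/property tests.  The motif is built
# from k residues of the structure so at least one match always exists.
# Chain length is coupled to motif size so that the oracle's exhaustive
# enumeration (product of per-group candidate-list sizes over a uniform
# 20-type background) stays at desk scale.
random_case <- function(seed, n_range = c(50, 140), k_range = c(3, 5),
                        sigma_choices = c(0, 0, 0.05)) {
  set.seed(seed)
  k <- sample(k_range[1]:k_range[2], 1)
  n <- sample(n_range[1]:n_range[2], 1)
  n <- min(n, switch(as.character(k), "2" = 200L, "3" = 200L, "4" = 140L, 80L))
  types <- sample(c("H", "D", "S", "L", "V", "A", "G", "Y"), k, replace = TRUE)
  pos <- sort(sample(seq_len(n), k))
  two_copies <- n >= 60 && runif(1) < 0.4
  copy_pos <- NULL
  if (two_copies) {
    avail <- setdiff(seq_len(n), pos)
    copy_pos <- list(sort(sample(avail, k)))
  }
  sigma <- sample(sigma_choices, 1)
  recipe <- fixture_recipe(
    n, seed = seed + 1L,
    planted = list(list(positions = pos, types = types,
                        copies = if (two_copies) 2L else 1L,
                        copy_positions = copy_pos, sigma = sigma)))
  model <- make_chain(recipe)
  tol <- sample(c(0.5, 1.0, 2.0), 1)
  ss_policy <- sample(c("wildcard", "wildcard", "observed"), 1)
  delta <- if (two_copies || runif(1) < 0.5) "none" else
    sample(list("strict", 5L), 1)[[1]]
  spec <- build_motif(model, unlist(model$planted[[1]][[1]]),
                      tol = tolerance(tol), ss_policy = ss_policy,
                      delta = delta)
  list(model = model, spec = spec, seed = seed)
}

assignments_of <- function(matches) {
  lapply(matches, function(m) unname(m$assignment))
}

has_assignment <- function(matches, keys) {
  any(vapply(assignments_of(matches), identical, logical(1), y = unname(keys)))
}
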