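planted_triad_model <- function(seed = 31, n = 60) {
  make_chain(fixture_recipe(n, seed = seed,
    planted = list(list(positions = c(10, 25, 40), types = c("H", "D", "S")))))
}

test_that("the match predicate is inclusive at both distance bounds", {
  m <- planted_triad_model()
  keys <- unlist(m$planted[[1]][[1]])
  spec <- build_motif(m, keys, ss_policy = "wildcard", delta = "none")
  expect_true(match_satisfies(spec, m, keys))

  # pin a bound exactly at the measured distance: still a match
  exact <- spec
  d1 <- measure_distance(m, keys[1], "CA", keys[2], "CA")
  exact$distances$d_max[1] <- d1
  exact$distances$d_min[1] <- d1
  expect_true(match_satisfies(exact, m, keys))

  # nudge the upper bound just below: no longer a match
  below <- spec
  below$distances$d_max[1] <- d1 - 0.01
  below$distances$d_min[1] <- 0
  expect_false(match_satisfies(below, m, keys))
})

test_that("type, ss and injectivity failures all reject an assignment", {
  m <- planted_triad_model()
  keys <- unlist(m$planted[[1]][[1]])
  spec <- build_motif(m, keys, ss_policy = "wildcard", delta = "none")

  wrong_type <- spec
  wrong_type$groups$types[1] <- "W"
  expect_false(match_satisfies(wrong_type, m, keys))

  wrong_ss <- spec
  real_ss <- m$residues$ss[match(keys[1], m$residues$key)]
  wrong_ss$groups$ss[1] <- setdiff(c("h", "s", "c"), real_ss)[1]
  expect_false(match_satisfies(wrong_ss, m, keys))

  expect_false(match_satisfies(spec, m, c(keys[1], keys[1], keys[3])))
})

test_that("a missing named atom fails the match instead of erroring", {
  m <- make_chain(fixture_recipe(20, seed = 33,
    planted = list(list(positions = c(5, 12), types = c("A", "G")))))
  keys <- unlist(m$planted[[1]][[1]])
  # constrains the CB of a glycine group: no residue can ever supply the atom
  spec <- parse_motif(c("GROUP 1 A *", "GROUP 2 G *",
                        "DIST 1 CB 2 CB 0 25 50"))
  expect_false(match_satisfies(spec, m, keys))
  expect_length(find_matches(m, spec), 0)
})

test_that("find_matches recovers planted motifs and nothing else at tight tolerance", {
  m <- planted_triad_model()
  keys <- unlist(m$planted[[1]][[1]])
  spec <- build_motif(m, keys, tol = tolerance(0.5), ss_policy = "wildcard",
                      delta = "none")
  hits <- find_matches(m, spec)
  expect_length(hits, 1)
  expect_equal(unname(hits[[1]]$assignment), keys)
  expect_true(all(hits[[1]]$measured >= spec$distances$d_min &
                  hits[[1]]$measured <= spec$distances$d_max))

  impossible <- spec
  impossible$groups$types <- c("W", "W", "W")
  expect_length(find_matches(m, impossible), 0)
})

test_that("two rigid planted copies give two matches, agreeing with the oracle", {
  m <- make_chain(fixture_recipe(80, seed = 35,
    planted = list(list(positions = c(10, 25, 40), types = c("H", "D", "S"),
                        copies = 2L, copy_positions = list(c(55, 62, 75))))))
  keys <- unlist(m$planted[[1]][[1]])
  spec <- build_motif(m, keys, tol = tolerance(1.0), ss_policy = "wildcard",
                      delta = "none")
  hits <- find_matches(m, spec)
  expect_length(hits, 2)
  expect_true(has_assignment(hits, unlist(m$planted[[1]][[2]])))
  bf <- brute_force_search(m, spec)
  expect_equal(assignments_of(hits), assignments_of(bf))
})

test_that("permuted assignments of symmetric specs are distinct unless deduped", {
  m <- read_pdb(pdb_text(list(
    ca_res("A", 1, "LEU", c(0, 0, 0)),
    ca_res("A", 5, "LEU", c(6, 0, 0)))))
  spec <- parse_motif(c("GROUP 1 L *", "GROUP 2 L *",
                        "DIST 1 CA 2 CA 5 6 7"))
  hits <- find_matches(m, spec)
  expect_length(hits, 2)    # (1,5) and (5,1)
  deduped <- find_matches(m, spec, dedupe_sets = TRUE)
  expect_length(deduped, 1)
})

test_that("DELTA is signed on within-chain ordinals; cross-chain always fails", {
  m <- read_pdb(pdb_text(list(
    ca_res("A", 3, "LEU", c(0, 0, 0)),
    ca_res("A", 9, "TYR", c(6, 0, 0)),
    ca_res("B", 1, "TYR", c(6, 6, 0)))))
  base <- c("GROUP 1 L *", "GROUP 2 Y *", "DIST 1 CA 2 CA 4 6 9")
  signed <- parse_motif(c(base, "DELTA 1 2 1 1"))
  # author numbering jumps 3 -> 9 but the ordinal separation is 1
  expect_length(find_matches(m, signed), 1)
  wrong_sign <- parse_motif(c(base, "DELTA 1 2 -1 -1"))
  expect_length(find_matches(m, wrong_sign), 0)
  # group order reversed: measured separation is -1, so the signed form fails
  # but the magnitude form matches
  reversed <- parse_motif(c(base, "DELTA 2 1 1 1"))
  expect_length(find_matches(m, reversed), 0)
  expect_length(find_matches(m, reversed, abs_delta = TRUE), 1)
  # B:1 is within distance range but on another chain: any finite DELTA fails
  expect_false(match_satisfies(signed, m, c("A:3", "B:1")))
})

test_that("pruning removes no valid assignment", {
  for (seed in c(41, 42, 43)) {
    case <- random_case(seed, n_range = c(40, 80), k_range = c(3, 4))
    pruned <- find_matches(case$model, case$spec, prune = TRUE)
    unpruned <- find_matches(case$model, case$spec, prune = FALSE)
    expect_equal(assignments_of(pruned), assignments_of(unpruned),
                 label = sprintf("pruning soundness, seed %d", seed))
  }
})

test_that("search_many aggregates, reports and survives unreadable files", {
  dir <- withr::local_tempdir()
  m1 <- planted_triad_model(seed = 51)
  m2 <- make_chain(fixture_recipe(40, seed = 52, structure_id = "plain40"))
  write_pdb(m1, file.path(dir, "hit.pdb"))
  write_pdb(m2, file.path(dir, "miss.pdb"))
  writeLines("this is not a pdb file", file.path(dir, "junk.pdb"))

  keys <- unlist(m1$planted[[1]][[1]])
  spec <- build_motif(m1, keys, ss_policy = "wildcard", delta = "none")
  expect_warning(report <- search_many(dir, spec), "skipping unreadable")
  expect_equal(report$structures_searched, 2)
  expect_equal(report$structures_with_hits, 1)
  expect_length(report$matches, 1)

  line <- format_hits(report)
  expect_match(line, "^hit\t")
  expect_match(line, "A:10:H\tA:25:D\tA:40:S$")

  empty <- search_many(list(), spec)
  expect_equal(empty$structures_searched, 0)
  expect_length(empty$matches, 0)
})

test_that("reports are byte-identical across repeated runs", {
  m <- planted_triad_model(seed = 61)
  spec <- build_motif(m, unlist(m$planted[[1]][[1]]), ss_policy = "wildcard",
                      delta = "none")
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_report(search_many(list(m), spec), f1, spec)
  write_report(search_many(list(m), spec), f2, spec)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("candidate subset counts follow the binomial coefficient exactly", {
  expect_equal(count_candidate_subsets(10, 3), 120)
  expect_equal(count_candidate_subsets(7, 0), 1)
  expect_equal(count_candidate_subsets(3, 5), 0)
  # against the direct falling-factorial product m(m-1)...(m-k+1)/k!
  expect_equal(count_candidate_subsets(250, 4), prod(250:247) / factorial(4))
  expect_equal(count_candidate_subsets(250, 4), 158882750)
})
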