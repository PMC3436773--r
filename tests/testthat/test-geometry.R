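random_rigid <- function(coords, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(coords %*% q, 2, rnorm(3, sd = 10), "+")
}

test_that("rmsd is the root mean square displacement, no fitting", {
  a <- matrix(rnorm(15), ncol = 3)
  expect_equal(rmsd(a, a), 0)

  # two points, each displaced by 1 A
  p <- rbind(c(0, 0, 0), c(5, 0, 0))
  q <- rbind(c(1, 0, 0), c(5, 1, 0))
  expect_equal(rmsd(p, q), 1.0)

  # independent sum-of-squares recomputation on a random pair
  set.seed(1)
  b <- a + matrix(rnorm(15, sd = 0.7), ncol = 3)
  direct <- sqrt(sum((a - b)^2) / nrow(a))
  expect_equal(rmsd(a, b), direct)
  expect_equal(rmsd(a, b), rmsd(b, a))
  expect_error(rmsd(a, b[1:3, ]), "length")
})

test_that("superpose recovers pure translations and rotations to rmsd ~ 0", {
  set.seed(2)
  a <- matrix(rnorm(24), ncol = 3)
  sp <- superpose(a, sweep(a, 2, c(1, 2, 3), "+"))
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 degrees about z
  sp2 <- superpose(a, a %*% rz)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal((a %*% rz) %*% sp2$rotation, a, tolerance = 1e-8,
               ignore_attr = TRUE)

  for (seed in 1:20) {
    b <- random_rigid(a, seed)
    sp3 <- superpose(a, b)
    expect_lt(sp3$rmsd, 1e-6)
    expect_equal(det(sp3$rotation), 1, tolerance = 1e-8)
    expect_equal(apply_transform(b, sp3), a, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("the fitted rmsd is optimal over sampled rigid transforms", {
  set.seed(3)
  a <- matrix(rnorm(18), ncol = 3)
  b <- a + matrix(rnorm(18, sd = 0.5), ncol = 3)
  fit <- superpose(a, b)$rmsd
  for (i in 1:1000) {
    expect_gte(rmsd(a, random_rigid(b)) + 1e-12, fit)
  }
})

test_that("reflections are excluded: a mirrored chiral set cannot reach rmsd 0", {
  chiral <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0.5, 0.5, 1.2))
  mirror <- chiral %*% diag(c(1, 1, -1))
  sp <- superpose(chiral, mirror)
  expect_gt(sp$rmsd, 0.1)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  # sampled proper rotations confirm the fit is the proper-rotation optimum
  set.seed(4)
  best <- min(vapply(1:500, function(i) rmsd(chiral, random_rigid(mirror)),
                     numeric(1)))
  expect_gte(best + 1e-12, sp$rmsd)
})

test_that("superposition agrees with the independent bio3d least-squares fit", {
  set.seed(5)
  for (i in 1:5) {
    a <- matrix(rnorm(30), ncol = 3)
    b <- a + matrix(rnorm(30, sd = 0.4), ncol = 3)
    ours <- superpose(a, b)$rmsd
    xyz_a <- as.vector(t(a))
    xyz_b <- as.vector(t(b))
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_a, mobile = xyz_b))
    theirs <- rmsd(a, matrix(fitted, ncol = 3, byrow = TRUE))
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("backbone_rmsd is 0 against itself and against a rigid copy", {
  m <- make_chain(fixture_recipe(50, seed = 71,
    planted = list(list(positions = c(8, 20, 35, 42),
                        types = c("D", "D", "N", "G"),
                        copies = 2L, copy_positions = list(c(12, 26, 30, 47))))))
  tmpl <- unlist(m$planted[[1]][[1]])
  copy <- unlist(m$planted[[1]][[2]])
  expect_equal(as.numeric(backbone_rmsd(m, tmpl, m, tmpl)), 0)
  r <- backbone_rmsd(m, tmpl, m, copy)
  expect_lt(as.numeric(r), 1e-3)   # write/transform precision only
  expect_equal(attr(r, "n_atoms"), 16)
  expect_error(backbone_rmsd(m, tmpl, m, copy[1:3]), "length")
})

test_that("backbone_rmsd drops pairs with missing atoms and counts them", {
  # glycine lacks CB: with atoms = N,CA,CB one pair per glycine is dropped
  m <- make_chain(fixture_recipe(30, seed = 72,
    planted = list(list(positions = c(5, 10, 15), types = c("A", "G", "L")))))
  keys <- unlist(m$planted[[1]][[1]])
  r <- backbone_rmsd(m, keys, m, keys, atoms = c("N", "CA", "CB"))
  expect_equal(attr(r, "dropped"), 1L)
  expect_equal(attr(r, "n_atoms"), 8L)
})

test_that("distance-matrix similarity is an elementwise absolute-difference sum", {
  a <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  da <- distance_matrix(a)
  expect_equal(diag(da), rep(0, 3), ignore_attr = TRUE)
  expect_equal(da[1, 2], 3)
  expect_equal(da[2, 3], 5)
  expect_true(isSymmetric(da))
  expect_equal(dm_similarity(da, da), 0)

  db <- da
  db[1, 2] <- db[2, 1] <- 4   # one off-diagonal pair differs by 1
  expect_equal(dm_similarity(da, db), 2)

  set.seed(6)
  m1 <- distance_matrix(matrix(rnorm(12), ncol = 3))
  m2 <- distance_matrix(matrix(rnorm(12), ncol = 3))
  expect_equal(dm_similarity(m1, m2), sum(abs(m1 - m2)))
  expect_equal(dm_similarity(m1, m2), dm_similarity(m2, m1))
  expect_gte(dm_similarity(m1, m2), 0)
  # blind to rigid motion
  p <- matrix(rnorm(12), ncol = 3)
  expect_equal(dm_similarity(distance_matrix(p),
                             distance_matrix(random_rigid(p))), 0,
               tolerance = 1e-8)
  expect_error(dm_similarity(m1, matrix(0, 2, 2)), "dimension")
})

test_that("degenerate superposition inputs are contract errors", {
  a <- matrix(rnorm(9), ncol = 3)
  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
  expect_error(superpose(a, a[1:2, ]), "length")
})
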