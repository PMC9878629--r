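test_that("Soergel distance matches bit-enumeration cases", {
  expect_equal(soergel(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(soergel(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(soergel(c(1, 1, 0, 0), c(0, 1, 1, 0)), 2 / 3)
  # all-zero pair: Tanimoto 0/0 is defined as identity, not maximal distance
  expect_equal(soergel(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_error(soergel(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("Soergel is a metric on random bit vectors", {
  set.seed(202)
  for (rep in 1:200) {
    x <- as.integer(runif(32) < 0.4)
    y <- as.integer(runif(32) < 0.4)
    z <- as.integer(runif(32) < 0.4)
    dxy <- soergel(x, y)
    expect_equal(dxy, soergel(y, x))
    expect_gte(dxy, 0)
    expect_lte(dxy, 1)
    expect_lte(dxy, soergel(x, z) + soergel(z, y) + 1e-12)
  }
  expect_equal(soergel(c(1, 0, 1), c(1, 0, 1)), 0)
})

test_that("inter-library means equal brute-force double loops", {
  set.seed(303)
  A <- random_fp_matrix(12)
  B <- random_fp_matrix(15)
  expect_equal(inter_library_distance(A, B, "soergel_maccs"),
               oracle_inter_mean(A, B, oracle_soergel), tolerance = 1e-12)
  # single-pair degenerate cases
  expect_equal(inter_library_distance(A[1, , drop = FALSE],
                                      A[1, , drop = FALSE], "soergel_maccs"), 0)
  expect_equal(inter_library_distance(A[1, , drop = FALSE],
                                      B[2, , drop = FALSE], "soergel_maccs"),
               soergel(A[1, ], B[2, ]))

  P <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(NULL, c("HBD", "HBA", "LogP", "MW", "TPSA", "RTB")))
  Q <- matrix(rnorm(8 * 6), 8, 6, dimnames = dimnames(P))
  sp <- list(center = colMeans(rbind(P, Q)),
             scale = apply(rbind(P, Q), 2, sd))
  Ps <- scale(P, sp$center, sp$scale)
  Qs <- scale(Q, sp$center, sp$scale)
  expect_equal(inter_library_distance(P, Q, "euclid_props"),
               oracle_inter_mean(Ps, Qs, oracle_euclid), tolerance = 1e-12)
})

test_that("intra-library means use unordered distinct pairs", {
  set.seed(404)
  A <- random_fp_matrix(12)
  expect_equal(intra_library_distance(A, "soergel_maccs"),
               oracle_intra_mean(A, oracle_soergel), tolerance = 1e-12)
  # identical molecules: zero diversity
  same <- A[rep(1, 5), ]
  expect_equal(intra_library_distance(same, "soergel_maccs"), 0)
  # two molecules: the single pair distance
  expect_equal(intra_library_distance(A[1:2, ], "soergel_maccs"),
               soergel(A[1, ], A[2, ]))
  expect_error(intra_library_distance(A[1, , drop = FALSE], "soergel_maccs"),
               ">= 2")
})

test_that("self inter-distance relates to intra-distance through the self-pair dilution", {
  set.seed(505)
  A <- random_fp_matrix(10)
  # inter(A, A) averages over all U^2 ordered pairs including the U zero
  # self-pairs, so it equals intra * (U-1)/U and never exceeds intra
  U <- nrow(A)
  intra <- intra_library_distance(A, "soergel_maccs")
  inter_self <- inter_library_distance(A, A, "soergel_maccs")
  expect_equal(inter_self, intra * (U - 1) / U, tolerance = 1e-12)
  expect_lte(inter_self, intra)
  # equality holds only when the library has a single distinct molecule
  same <- A[rep(3, 6), ]
  expect_equal(inter_library_distance(same, same, "soergel_maccs"),
               intra_library_distance(same, "soergel_maccs"))
})

test_that("property distances are invariant to affine rescaling of a column", {
  set.seed(606)
  P <- matrix(rnorm(9 * 6), 9, 6)
  Q <- matrix(rnorm(7 * 6), 7, 6)
  P2 <- P; Q2 <- Q
  P2[, 4] <- 1000 * P[, 4] - 3   # e.g. molecular weight in different units
  Q2[, 4] <- 1000 * Q[, 4] - 3
  expect_equal(inter_library_distance(P, Q, "euclid_props"),
               inter_library_distance(P2, Q2, "euclid_props"),
               tolerance = 1e-9)
  expect_equal(intra_library_distance(P, "euclid_props"),
               intra_library_distance(P2, "euclid_props"), tolerance = 1e-9)
})

test_that("distance matrices are symmetric with intra values on the diagonal", {
  set.seed(707)
  libs <- list(a = random_fp_matrix(8), b = random_fp_matrix(6),
               c = random_fp_matrix(7))
  dm <- distance_matrix(libs, "soergel_maccs")
  expect_true(isSymmetric(dm$matrix))
  expect_equal(diag(dm$matrix),
               vapply(libs, intra_library_distance, numeric(1),
                      metric = "soergel_maccs"),
               tolerance = 1e-12)
  expect_equal(dm$matrix["a", "b"],
               inter_library_distance(libs$a, libs$b, "soergel_maccs"),
               tolerance = 1e-12)
  # permuting library order permutes rows/columns consistently
  dm2 <- distance_matrix(libs[c(3, 1, 2)], "soergel_maccs")
  expect_equal(dm2$matrix[names(libs), names(libs)], dm$matrix,
               tolerance = 1e-12)
  expect_error(distance_matrix(libs[1], "soergel_maccs"), "at least 2")
})

test_that("subsampling caps library size deterministically", {
  set.seed(808)
  A <- random_fp_matrix(40)
  B <- random_fp_matrix(35)
  d1 <- inter_library_distance(A, B, "soergel_maccs", max_molecules = 10,
                               seed = 3)
  d2 <- inter_library_distance(A, B, "soergel_maccs", max_molecules = 10,
                               seed = 3)
  expect_identical(d1, d2)
  full <- inter_library_distance(A, B, "soergel_maccs")
  expect_lt(abs(d1 - full), 0.2)
})
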