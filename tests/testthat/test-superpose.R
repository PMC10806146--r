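test_that("kabsch recovers identity and known motions", {
  set.seed(11)
  m <- matrix(rnorm(30), 10, 3)
  r0 <- kabsch(m, m)
  expect_equal(r0$rmsd, 0, tolerance = 1e-12)
  expect_equal(r0$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(r0$transform$translation, c(0, 0, 0), tolerance = 1e-10)

  R <- rotation_about_axis(c(0, 0, 1), 90)
  fixed <- sweep(m %*% t(R), 2, c(1, 2, 3), `+`)
  r1 <- kabsch(m, fixed)
  expect_lt(r1$rmsd, 1e-10)
  expect_equal(r1$transform$rotation, R, tolerance = 1e-8)
  expect_equal(r1$transform$translation, c(1, 2, 3), tolerance = 1e-8)
})

test_that("kabsch beats brute-force rotation sampling", {
  set.seed(42)
  mobile <- matrix(rnorm(30), 10, 3)
  fixed <- matrix(rnorm(30), 10, 3)
  opt <- kabsch(mobile, fixed)
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  M <- sweep(mobile, 2, cm); F <- sweep(fixed, 2, cf)
  worst <- vapply(seq_len(1000), function(i) {
    R <- random_rotation()
    sqrt(mean(rowSums((M %*% t(R) - F)^2)))
  }, 0)
  expect_true(all(opt$rmsd <= worst + 1e-12))
})

test_that("rmsd is invariant under a common rigid motion", {
  set.seed(7)
  a <- matrix(rnorm(24), 8, 3); b <- matrix(rnorm(24), 8, 3)
  base <- kabsch(a, b)$rmsd
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    a2 <- sweep(a %*% t(R), 2, t, `+`)
    b2 <- sweep(b %*% t(R), 2, t, `+`)
    expect_equal(kabsch(a2, b2)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("forward and reverse superpositions compose to the identity", {
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  R <- random_rotation()
  b <- sweep(a %*% t(R), 2, c(4, -2, 9), `+`)
  fw <- kabsch(a, b)$transform
  bw <- kabsch(b, a)$transform
  comp <- compose_rigid(bw, fw)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-8)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-8)
})

test_that("degenerate inputs are handled explicitly", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "underdetermined")
  line <- cbind(seq_len(5), 0, 0)
  expect_warning(res <- kabsch(line, line), "degenerate")
  expect_equal(det(res$transform$rotation), 1, tolerance = 1e-8)
})

test_that("reflection is never returned even for mirrored targets", {
  set.seed(5)
  a <- matrix(rnorm(30), 10, 3)
  mirrored <- a %*% diag(c(-1, 1, 1))
  res <- kabsch(a, mirrored)
  expect_equal(det(res$transform$rotation), 1, tolerance = 1e-8)
  expect_gt(res$rmsd, 0)
})

test_that("sequence-guided correspondence handles identity and gaps", {
  dom <- fixture_domain()
  corr <- align_chains(dom, dom)
  expect_equal(nrow(corr), n_residues(dom))
  expect_equal(corr$query_resno, corr$template_resno)

  ## drop one internal residue from the query
  at <- dom$atoms[dom$atoms$resno != 40, , drop = FALSE]
  delq <- dd_structure(at)
  corr2 <- align_chains(delq, dom)
  expect_equal(nrow(corr2), n_residues(dom) - 1)
  expect_false(40 %in% corr2$template_resno[corr2$query_resno ==
                                              corr2$template_resno])
})

test_that("superposition placement is exact for constructed inputs", {
  dom <- fixture_domain()
  R <- rotation_about_axis(c(1, 1, 0), 65)
  moved <- transform_structure(dom, rigid_transform(R, c(10, -4, 2)))
  res <- superpose_homolog(moved, dom)
  expect_lt(res$result$rmsd, 1e-8)
  expect_lt(max(abs(structure_xyz(res$placed) - structure_xyz(dom))), 1e-6)
  ## the input is untouched
  expect_equal(unname(structure_xyz(moved)[1, ]),
               unname(apply_rigid(structure_xyz(dom),
                                  rigid_transform(R, c(10, -4, 2)))[1, ]))
})

test_that("kabsch agrees with an independent least-squares fit", {
  set.seed(19)
  a <- matrix(rnorm(60), 20, 3)
  b <- sweep(a %*% t(random_rotation()), 2, c(1, 1, 1), `+`) +
    matrix(rnorm(60, sd = 0.3), 20, 3)
  ours <- kabsch(a, b)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(b)), mobile = as.numeric(t(a))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("too few aligned pairs is an error naming the count", {
  dom <- fixture_domain()
  expect_error(superpose_homolog(dom, dom, min_pairs = 1000), "91")
})
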