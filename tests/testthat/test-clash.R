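mini_pair <- function(d, elety = "CA", resid = "ALA") {
  at <- data.frame(chain = c("A", "B"), resno = c(1, 50), insert = "",
                   resid = resid, elety = elety, element = "C",
                   x = c(0, d), y = 0, z = 0)
  dd_structure(at)
}

test_that("clash detection follows the radius arithmetic", {
  expect_equal(nrow(detect_clashes(mini_pair(10))), 0)
  cl <- detect_clashes(mini_pair(2.0))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$overlap, 2 * 1.70 - 2.0, tolerance = 1e-12)
  expect_equal(cl$distance, 2.0, tolerance = 1e-12)
  ## just below the reporting threshold
  expect_equal(nrow(detect_clashes(mini_pair(2 * 1.70 - 0.39))), 0)
})

test_that("bonded and 1-3 pairs are not reported as clashes", {
  dom <- fixture_domain()
  cl <- detect_clashes(dom)
  if (nrow(cl) > 0) {
    same <- cl$chain_i == cl$chain_j & cl$resno_i == cl$resno_j
    keys <- paste(pmin(cl$elety_i[same], cl$elety_j[same]),
                  pmax(cl$elety_i[same], cl$elety_j[same]), sep = "|")
    for (k in seq_along(keys)) {
      excl <- ddhelix:::residue_exclusions(cl$resid_i[same][k])
      expect_false(keys[k] %in% excl)
    }
    adj <- cl$chain_i == cl$chain_j & abs(cl$resno_i - cl$resno_j) == 1
    links <- paste(cl$elety_i[adj], cl$elety_j[adj])
    expect_false(any(links %in% ddhelix:::LINK_EXCLUSIONS))
  }
  succeed()
})

test_that("a deliberate subunit collision is detected and recomputable", {
  dom <- fixture_domain()
  bumped <- transform_structure(dom, rigid_transform(diag(3), c(4, 0, 0)))
  bumped$atoms$chain <- "B"
  a <- manual_assembly(list(dom, bumped), helix_indices = c(1, 2))
  cl <- detect_clashes(a)
  expect_gt(nrow(cl), 0)
  s <- heavy_atoms(assembly_structure(a))
  for (i in seq_len(min(5, nrow(cl)))) {
    pi_ <- atom_xyz(s, cl$resno_i[i], cl$elety_i[i], cl$chain_i[i])
    pj <- atom_xyz(s, cl$resno_j[i], cl$elety_j[i], cl$chain_j[i])
    expect_equal(sqrt(sum((pi_ - pj)^2)), cl$distance[i], tolerance = 1e-9)
  }
})

test_that("grid neighbour search matches brute force", {
  set.seed(31)
  xyz <- matrix(runif(300, 0, 15), 100, 3)
  for (cutoff in c(2, 4.5)) {
    got <- ddhelix:::neighbor_pairs(xyz, cutoff)
    got_keys <- sort(paste(got$i, got$j))
    d <- as.matrix(dist(xyz))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    want_keys <- sort(paste(idx[, 1], idx[, 2]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("clash-free input passes through relief unchanged", {
  s <- mini_pair(10)
  r <- relieve(s)
  expect_identical(structure_xyz(r$relieved), structure_xyz(s))
  expect_equal(r$report$n_moves, 0)
  expect_true(r$report$converged)
})

test_that("a constructed rotatable clash is relieved in one sweep", {
  pep <- build_peptide(c("ALA", "LYS", "ALA"), resnos = 1:3, chain = "A")
  ## park a blocking particle on the extended side chain tip
  nz <- atom_xyz(pep, 2, "NZ")
  block <- dd_structure(data.frame(chain = "B", resno = 50, insert = "",
                                   resid = "ALA", elety = "CA", element = "C",
                                   x = nz[1], y = nz[2], z = nz[3] + 1.5))
  a <- manual_assembly(list(pep, block), helix_indices = c(1, 5))
  before <- detect_clashes(a)
  expect_gt(nrow(before), 0)
  r <- relieve(a, max_iters = 5)
  expect_lt(r$report$final_overlap, r$report$initial_overlap)
  expect_true(r$report$converged)
  ## backbone is bit-identical
  for (nm in c("N", "CA", "C", "O", "CB")) {
    expect_identical(atom_xyz(r$relieved$subunits[[1]]$structure, 2, nm),
                     atom_xyz(pep, 2, nm))
  }
})

test_that("relief is monotone and deterministic", {
  dom <- fixture_domain()
  bumped <- transform_structure(dom, rigid_transform(
    rotation_about_axis(c(0, 0, 1), 30), c(6, 2, 1)))
  bumped$atoms$chain <- "B"
  a <- manual_assembly(list(dom, bumped), helix_indices = c(1, 2))
  r1 <- relieve(a, max_iters = 8)
  expect_true(all(diff(c(r1$report$initial_overlap,
                         r1$report$overlap_trace)) < 0))
  r2 <- relieve(a, max_iters = 8)
  expect_identical(structure_xyz(assembly_structure(r1$relieved)),
                   structure_xyz(assembly_structure(r2$relieved)))
  ## backbone untouched everywhere
  s0 <- assembly_structure(a); s1 <- assembly_structure(r1$relieved)
  bb <- s0$atoms$elety %in% c("N", "CA", "C", "O")
  expect_identical(structure_xyz(s0)[bb, ], structure_xyz(s1)[bb, ])
})
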