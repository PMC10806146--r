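test_that("contact map matches brute force on a two-subunit instance", {
  toy <- salt_bridge_toy()
  cm <- contact_map(toy, cutoff = 6)
  s <- heavy_atoms(assembly_structure(toy))
  at <- s$atoms
  xyz <- structure_xyz(s)
  ## brute force: min heavy-atom distance per residue pair across chains
  brute <- list()
  for (ri in unique(at$resno[at$chain == "A"])) {
    for (rj in unique(at$resno[at$chain == "B"])) {
      a <- xyz[at$chain == "A" & at$resno == ri, , drop = FALSE]
      b <- xyz[at$chain == "B" & at$resno == rj, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin <= 6) brute[[paste(ri, rj)]] <- dmin
    }
  }
  expect_equal(nrow(cm), length(brute))
  for (i in seq_len(nrow(cm))) {
    key <- paste(cm$resno_i[i], cm$resno_j[i])
    expect_equal(cm$dist[i], brute[[key]], tolerance = 1e-9)
  }
})

test_that("subunits beyond the cutoff produce an empty map", {
  dom <- fixture_domain()
  far <- transform_structure(dom, rigid_transform(diag(3), c(200, 0, 0)))
  far$atoms$chain <- "B"
  a <- manual_assembly(list(dom, far), helix_indices = c(1, 2))
  expect_equal(nrow(contact_map(a)), 0)
})

test_that("interface classification follows the offset rule", {
  expect_equal(classify_interface(-1), "Ia")
  expect_equal(classify_interface(1), "Ib")
  expect_equal(classify_interface(c(-3, -4)), c("IIa", "IIa"))
  expect_equal(classify_interface(4), "IIb")
  expect_equal(classify_interface(c(2, -2, 5, 0)),
               rep("unclassified", 4))
})

test_that("face offsets report contacts and nearest partners", {
  oct <- fixture_octamer()
  faces <- dd_faces()
  fo <- face_offsets(oct, faces$Ia)
  near <- fo[fo$kind == "nearest", ]
  ## mid-helix query copies: exclude the helix ends
  mid <- near[near$subunit %in% 12:17, ]
  expect_true(all(mid$offset == -1))
  ## antisymmetry of contact bookkeeping: a contact of subunit n at +k
  ## implies the partner record at -k
  cm <- contact_map(oct)
  expect_true(all(cm$offset > 0))   # canonical storage, lower index first
})

test_that("face offsets error on pivots missing from the model", {
  oct <- fixture_octamer()
  fake <- list(label = "Ia", pivots = 999, partners = integer(0),
               surround = integer(0))
  expect_error(face_offsets(oct, fake), "999.*15..105|absent")
})

test_that("a single-subunit assembly yields empty offset tables", {
  a <- manual_assembly(list(fixture_domain()), helix_indices = 1)
  fo <- face_offsets(a, dd_faces()$Ia)
  expect_equal(nrow(fo), 0)
})

test_that("the lowest-four aggregation rule is exact", {
  expect_equal(lowest_four_mean(c(-5, -4, -3, -2, -1, 0, 1, 2)), -3.5)
  expect_equal(lowest_four_mean(c(3, 1, 2)), 2)     # fewer than four: mean
  expect_equal(lowest_four_mean(5), 5)
  ## aggregated never exceeds the overall mean with >= 4 copies
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(4:10, 1))
    expect_lte(lowest_four_mean(x), mean(x) + 1e-12)
  }
})

test_that("a salt bridge scores as a negative electrostatic term", {
  toy <- salt_bridge_toy()
  params <- potential_params()
  en <- per_residue_energy(toy, params, scope = "all")
  k60 <- en$per_copy[en$per_copy$resno == 60, ]
  expect_equal(nrow(k60), 1)
  expect_lt(k60$elec, 0)
  ## closed-form oracle: only NZ(+1) and OD1/OD2(-0.5) carry charge
  s <- heavy_atoms(assembly_structure(toy))
  nz <- atom_xyz(s, 60, "NZ")
  expected <- 0
  for (od in c("OD1", "OD2")) {
    r <- sqrt(sum((atom_xyz(s, 33, od) - nz)^2))
    if (r <= params$cutoff)
      expected <- expected + params$coulomb_k * 1 * (-0.5) / (4 * r^2)
  }
  expect_equal(k60$elec, expected, tolerance = 1e-9)
})

test_that("energy decomposition conserves the total pair energy", {
  set.seed(21)
  for (rep in 1:3) {
    pieces <- lapply(1:3, function(i) {
      p <- build_peptide(sample(c("ALA", "LYS", "ASP", "SER"), 4, TRUE),
                         resnos = 1:4, chain = LETTERS[i])
      transform_structure(p, rigid_transform(random_rotation(),
                                             rnorm(3, sd = 4)))
    })
    a <- manual_assembly(pieces, helix_indices = 1:3)
    en <- per_residue_energy(a, scope = "all")
    expect_equal(sum(en$per_copy$energy), 2 * en$total_pair_energy,
                 tolerance = 1e-9)
  }
})

test_that("subunits beyond the cutoff have zero energies", {
  dom <- fixture_domain()
  far <- transform_structure(dom, rigid_transform(diag(3), c(300, 0, 0)))
  far$atoms$chain <- "B"
  a <- manual_assembly(list(dom, far), helix_indices = c(1, 2))
  en <- per_residue_energy(a, scope = "all")
  expect_true(all(en$per_copy$energy == 0))
  expect_equal(en$total_pair_energy, 0)
})

test_that("residue ranking is by energy then residue number", {
  agg <- data.frame(resno = c(10, 3, 7), resid = "ALA",
                    energy = c(0, 0, -2), n_copies = 4, flagged = FALSE)
  r <- rank_residues(agg)
  expect_equal(r$resno, c(7, 3, 10))
  ## an injected dominant salt bridge ranks first
  toy <- salt_bridge_toy()
  en <- per_residue_energy(toy, scope = "all")
  expect_equal(rank_residues(en)$resno[1:2] %in% c(33, 60), c(TRUE, TRUE))
})

test_that("missing potential parameters are reported by atom type", {
  at <- data.frame(chain = c("A", "B"), resno = c(1, 2), insert = "",
                   resid = "UNK", elety = "FE", element = "F",
                   x = c(0, 3), y = 0, z = 0)
  a <- manual_assembly(list(dd_structure(at[1, ]), dd_structure(at[2, ])),
                       helix_indices = 1:2)
  expect_error(per_residue_energy(a, scope = "all"), "F")
})
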