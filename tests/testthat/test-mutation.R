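test_that("the built-in panel lists the studied substitutions", {
  p <- mutation_panel()
  expect_true(all(c("W74A", "R97Q", "K60E", "Y105A", "F18A", "D19N",
                    "L20A", "P21A", "P22A", "A23S", "Q78A") %in% p$label))
  p2 <- mutation_panel(q78_to = "E")
  expect_true("Q78E" %in% p2$label)
})

test_that("self-mutations leave coordinates and scores untouched", {
  toy <- salt_bridge_toy()
  m <- mutation_spec(60, "K", "K")
  same <- apply_mutation(toy, m)
  expect_identical(structure_xyz(assembly_structure(same)),
                   structure_xyz(assembly_structure(toy)))
  d <- delta_score(toy, same, 60)
  expect_true(all(d$dE == 0))
})

test_that("mutation changes follow residue topology", {
  toy <- salt_bridge_toy()
  n0 <- nrow(assembly_structure(toy)$atoms)
  ## LYS and GLU both have 4 side-chain atoms beyond CB
  ke <- apply_mutation(toy, mutation_spec(60, "K", "E"), debump = FALSE)
  expect_equal(nrow(assembly_structure(ke)$atoms), n0)
  at <- assembly_structure(ke)$atoms
  expect_setequal(at$elety[at$resno == 60],
                  c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"))
  ## W74A drops the 9 tryptophan ring atoms in every query copy
  trp <- trp_contact_toy()
  wa <- apply_mutation(trp, mutation_spec(74, "W", "A"), debump = FALSE)
  expect_equal(nrow(assembly_structure(trp)$atoms) -
                 nrow(assembly_structure(wa)$atoms), 9)
})

test_that("a from-residue mismatch is rejected", {
  toy <- salt_bridge_toy()
  expect_error(apply_mutation(toy, mutation_spec(60, "R", "A")), "mismatch")
})

test_that("K60E flips the type Ia electrostatic term to repulsion", {
  toy <- salt_bridge_toy()
  mut <- apply_mutation(toy, mutation_spec(60, "K", "E"), debump = FALSE)
  d <- delta_score(toy, mut, 60)
  ia <- d[d$class == "Ia", ]
  expect_gt(ia$dE_elec, 0)        # attraction replaced by repulsion
  ## and the wild type really was attractive
  en <- per_residue_energy(toy, scope = "all")
  expect_lt(en$per_copy$elec[en$per_copy$resno == 60], 0)
  ## the charge-flip sign holds across bridge geometries
  for (gap in c(2.8, 3.5, 4.5)) {
    t2 <- salt_bridge_toy(gap = gap)
    m2 <- apply_mutation(t2, mutation_spec(60, "K", "E"), debump = FALSE)
    d2 <- delta_score(t2, m2, 60)
    expect_gt(d2$dE_elec[d2$class == "Ia"], 0)
  }
})

test_that("removing a buried tryptophan weakens the dispersion term", {
  trp <- trp_contact_toy()
  en <- per_residue_energy(trp, scope = "all")
  lj_wt <- en$per_copy$lj[en$per_copy$resno == 74]
  expect_lt(lj_wt, 0)             # the contact is attractive
  mut <- apply_mutation(trp, mutation_spec(74, "W", "A"), debump = FALSE)
  d <- delta_score(trp, mut, 74)
  iia <- d[d$class == "IIa", ]
  expect_gt(iia$dE_lj, 0)         # attraction magnitude decreases
})

test_that("positions without inter-subunit contacts score zero deltas", {
  toy <- salt_bridge_toy()
  ## residue 61 (terminal ALA) points away from the interface
  mut <- apply_mutation(toy, mutation_spec(61, "A", "S"), debump = FALSE)
  d <- delta_score(toy, mut, 61)
  far <- d[d$class %in% c("IIa", "IIb"), ]
  expect_true(all(far$dE == 0))
})

test_that("mutations are applied to every query copy", {
  oct <- fixture_octamer()
  mut <- apply_mutation(oct, mutation_spec(74, "W", "A"), debump = FALSE)
  tab <- assembly_table(mut)
  for (ch in tab$chain[tab$layer == "QUERY"]) {
    at <- assembly_structure(mut)$atoms
    expect_equal(at$resid[at$chain == ch & at$resno == 74][1], "ALA")
  }
  ## template layers untouched
  for (ch in tab$chain[tab$layer != "QUERY"]) {
    at <- assembly_structure(mut)$atoms
    expect_equal(at$resid[at$chain == ch & at$resno == 74][1], "TRP")
  }
})
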