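test_that("threading an identical sequence reproduces the template", {
  dom <- fixture_domain()
  thr <- thread_query(dom, chain_sequence(dom), chain_resnos(dom))
  expect_equal(nrow(thr$atoms), nrow(dom$atoms))
  expect_lt(max(abs(structure_xyz(thr) - structure_xyz(dom))), 1e-9)
  expect_length(attr(thr, "omitted"), 0)
})

test_that("a substitution changes exactly the side-chain atom complement", {
  tmpl <- build_peptide(rep("ALA", 12), resnos = 1:12, chain = "T")
  qseq <- "AAAAAWAAAAAA"   # A6W
  thr <- thread_query(tmpl, qseq, 1:12)
  ## TRP has 9 more side-chain heavy atoms than ALA
  expect_equal(nrow(thr$atoms), nrow(tmpl$atoms) + 9)
  bb <- c("N", "CA", "C", "O", "CB")
  for (a in bb) {
    expect_equal(atom_xyz(thr, 6, a), atom_xyz(tmpl, 6, a))
  }
  expect_equal(thr$atoms$resid[thr$atoms$resno == 6][1], "TRP")
})

test_that("glycine targets are threaded without a CB", {
  tmpl <- build_peptide(rep("ALA", 12), resnos = 1:12, chain = "T")
  thr <- thread_query(tmpl, "AAAAAGAAAAAA", 1:12)
  expect_false("CB" %in% thr$atoms$elety[thr$atoms$resno == 6])
  expect_equal(nrow(thr$atoms), nrow(tmpl$atoms) - 1)
})

test_that("insufficient threading coverage is an error", {
  tmpl <- build_peptide(rep("ALA", 12), resnos = 1:12, chain = "T")
  corr <- data.frame(query_resno = 1:5, template_resno = 1:5)
  expect_error(thread_query(tmpl, "AAAAAAAAAAAA", 1:12, correspondence = corr),
               "coverage")
})

test_that("the extension plan controls the number of placed query copies", {
  lat <- fixture_lattice()
  dom <- fixture_domain()
  mp <- myddosome_plan(lat$manifest)
  ## zero targets: only template layers
  plan0 <- layer_plan(mp$plan$carry, character(0), mp$plan$template_order)
  a0 <- build_extended_layer(dom, lat$structure, plan0)
  tab0 <- assembly_table(a0)
  expect_equal(sum(tab0$layer == "QUERY"), 0)
  expect_equal(nrow(tab0), 10)
  ## both IRAK layers targeted: one copy per target chain
  a8 <- build_extended_layer(dom, lat$structure, mp$plan)
  tab8 <- assembly_table(a8)
  expect_equal(sum(tab8$layer == "QUERY"), length(mp$plan$targets))
  expect_true(all(tab8$rmsd[tab8$layer == "QUERY"] < 1e-9))
})

test_that("re-anchoring applies one rigid motion to the whole query layer", {
  lat <- fixture_lattice()
  dom <- fixture_domain()
  mp <- myddosome_plan(lat$manifest)
  a <- build_extended_layer(dom, lat$structure, mp$plan)
  b <- reanchor(a, lat$structure, mp$anchor,
                template_order = mp$plan$template_order)
  qa <- Filter(function(s) s$layer == "QUERY", a$subunits)
  qb <- Filter(function(s) s$layer == "QUERY", b$subunits)
  ## indices shift to start at the anchor layer
  expect_equal(vapply(qb, `[[`, 0, "helix_index"), 11:18)
  ## subunits 5..8 move by the same transform as 1..4: all pairwise
  ## inter-subunit CA distances within the query layer are preserved
  ca_all_a <- do.call(rbind, lapply(qa, function(s) ca_coords(s$structure)))
  ca_all_b <- do.call(rbind, lapply(qb, function(s) ca_coords(s$structure)))
  i <- seq(1, nrow(ca_all_a), by = 37)
  da <- as.matrix(dist(ca_all_a[i, ]))
  db <- as.matrix(dist(ca_all_b[i, ]))
  expect_lt(max(abs(da - db)), 1e-9)
  ## the anchored tetramer achieves the joint Kabsch optimum
  mob <- do.call(rbind, lapply(qa[1:4], function(s) ca_coords(s$structure)))
  fix <- do.call(rbind, lapply(mp$anchor, function(ch)
    ca_coords(lat$structure, ch)))
  direct <- kabsch(mob, fix)
  moved <- do.call(rbind, lapply(qb[1:4], function(s) ca_coords(s$structure)))
  got_rmsd <- sqrt(mean(rowSums((moved - fix)^2)))
  expect_equal(got_rmsd, direct$rmsd, tolerance = 1e-9)
})

test_that("re-anchoring a layer already on the anchors is the identity", {
  lat <- fixture_lattice()
  dom <- fixture_domain()
  ch <- lat$manifest$chains
  bottom <- ch$chain[ch$layer == "IRAK2"]
  plan <- layer_plan(list(MYD88 = ch$chain[ch$layer == "MYD88"]),
                     bottom, ch$chain)
  a <- build_extended_layer(dom, lat$structure, plan)
  b <- reanchor(a, lat$structure, bottom, template_order = ch$chain)
  xa <- structure_xyz(assembly_structure(a))
  xb <- structure_xyz(assembly_structure(b))
  expect_lt(max(abs(xa - xb)), 1e-9)
})

test_that("construction is deterministic and preserves internal geometry", {
  lat <- fixture_lattice()
  dom <- fixture_domain()
  o1 <- build_octamer(dom, lat$structure, lat$manifest)
  o2 <- build_octamer(dom, lat$structure, lat$manifest)
  expect_identical(structure_xyz(assembly_structure(o1)),
                   structure_xyz(assembly_structure(o2)))
  ## each placed copy keeps its intra-subunit distances
  q <- Filter(function(s) s$layer == "QUERY", o1$subunits)[[5]]
  d_ref <- dist(structure_xyz(dom)[seq(1, 500, by = 29), ])
  d_got <- dist(structure_xyz(q$structure)[seq(1, 500, by = 29), ])
  expect_lt(max(abs(d_ref - d_got)), 1e-9)
})

test_that("the re-anchored query layer preserves the template screw", {
  oct <- fixture_octamer()
  lat <- fixture_lattice()
  qs <- Filter(function(s) s$layer == "QUERY", oct$subunits)
  merged <- assembly_structure(oct)
  est <- estimate_lattice(merged, vapply(qs, `[[`, "", "chain"))
  expect_equal(est$screw$twist, lat$manifest$twist, tolerance = 1e-6)
  expect_equal(est$screw$rise, lat$manifest$rise, tolerance = 1e-6)
})

test_that("placement failures name the offending chain", {
  lat <- fixture_lattice()
  short <- build_peptide(rep("ALA", 12), chain = "Q")
  mp <- myddosome_plan(lat$manifest)
  expect_error(build_extended_layer(short, lat$structure, mp$plan), "G")
})
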