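test_that("scaffolds are built with the requested torsions and sequence", {
  m <- build_scaffold(list(ss_type = "helix", sequence = "ACDKG"))
  rt <- residue_table(m)
  expect_equal(rt$resid, c("ALA", "CYS", "ASP", "LYS", "GLY"))
  expect_equal(rt$resno, 1:5)
  # backbone phi of interior residues matches the request
  bb <- function(i, a) atom_coord(get_residue(m, i), a)
  phi3 <- dihedral(bb(2, "C"), bb(3, "N"), bb(3, "CA"), bb(3, "C"))
  expect_equal(phi3, -57, tolerance = 0.5)
  psi3 <- dihedral(bb(3, "N"), bb(3, "CA"), bb(3, "C"), bb(4, "N"))
  expect_equal(psi3, -47, tolerance = 0.5)
  # side chains sit at the default minus rotamer
  expect_equal(chi1_and_rotamer(get_residue(m, 2))$rotamer, "m")
  expect_error(build_scaffold(list(ss_type = "helix", sequence = "AXA")),
               "unknown residue letter")
  expect_error(build_scaffold(list(ss_type = "helix", sequence = "AA",
                                   length = 3)), "length")
})

test_that("placed cysteine pairs read back their target geometry", {
  cases <- list(c(2.05, -90), c(3.5, 60), c(5.0, -90), c(9.0, 120))
  for (cs in cases) {
    m <- place_cys_pair(list(ss_type = "helix", sequence = "AAAALCAAA"),
                        list(ss_type = "helix", sequence = "AAAALCAAA"),
                        target_sg_sg = cs[1], target_dihedral = cs[2])
    pg <- pair_geometry(m, attr(m, "sno_resno"), attr(m, "proxy_resno"))
    expect_equal(pg$sg_sg_distance, cs[1], tolerance = 0.05)
    expect_equal(pg$cb_sg_sg_cb, cs[2], tolerance = 2)
  }
  # distance beyond 2.5 A never grades as a formed disulfide
  m5 <- place_cys_pair(list(ss_type = "helix", sequence = "AAAALCAAA"),
                       list(ss_type = "helix", sequence = "AAAALCAAA"),
                       target_sg_sg = 5.0, target_dihedral = -90)
  expect_equal(pair_geometry(m5, attr(m5, "sno_resno"),
                             attr(m5, "proxy_resno"))$grade, "none")
  expect_error(place_cys_pair(list(ss_type = "helix", sequence = "AAAA"),
                              list(ss_type = "helix", sequence = "AACAA"),
                              2.05, -90), "exactly one cysteine")
})

test_that("pair placement respects the contact cutoffs by construction", {
  m9 <- place_cys_pair(list(ss_type = "helix", sequence = "AAAALCAAA"),
                       list(ss_type = "helix", sequence = "AAAALCAAA"),
                       target_sg_sg = 9.5, target_dihedral = -90)
  sno <- attr(m9, "sno_resno")
  expect_false(attr(m9, "proxy_resno") %in%
                 find_partner_cys(m9, sno)$resno)
  expect_true(attr(m9, "proxy_resno") %in%
                find_partner_cys(m9, sno,
                                 params = list(com_cutoff = 11))$resno)
})

test_that("synthetic ensembles are seed-reproducible", {
  base <- helix_pair_base()
  e1 <- synth_ensemble(base, list(n_models = 5, seed = 42))
  e2 <- synth_ensemble(base, list(n_models = 5, seed = 42))
  expect_identical(e1, e2)
  e3 <- synth_ensemble(base, list(n_models = 5, seed = 43))
  expect_false(identical(e1, e3))
  # and byte-identical through the writer
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(e1, f1); write_structure(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("chi1 weights drive the sampled rotamer states", {
  base <- helix_pair_base()
  sno <- attr(base, "sno_resno")
  # small jitter: Cartesian noise feeds into chi1, so rotamer pinning is
  # only exact when the jitter is small relative to the bin width
  em <- synth_ensemble(base, list(n_models = 8, seed = 5,
                                  coordinate_jitter = 0.02, chi1_sd = 5,
                                  chi1_distribution = c(t = 0, m = 1,
                                                        p = 0)))
  rots <- vapply(em$models, function(m)
    chi1_and_rotamer(get_residue(m, sno))$rotamer, character(1))
  expect_true(all(rots == "m"))
  # a mixed weight vector recovers its fractions at binomial tolerance
  e2 <- synth_ensemble(base, list(n_models = 600, seed = 6,
                                  coordinate_jitter = 0.05,
                                  chi1_distribution = c(t = 0.5, m = 0.5,
                                                        p = 0)))
  rots2 <- vapply(e2$models, function(m)
    chi1_and_rotamer(get_residue(m, sno))$rotamer, character(1))
  frac_m <- mean(rots2 == "m")
  expect_equal(frac_m, 0.5, tolerance = 3 * sqrt(0.25 / 600) / 0.5)
  expect_error(synth_ensemble(base, list(chi1_distribution = c(t = 0.5,
                                                               m = 0.4,
                                                               p = 0.2))),
               "sum to 1")
})

test_that("fixture generation is self-validating through the readers", {
  st <- synth_sites_table(2, seed = 31)
  expect_true(file.exists(st$sites_path))
  for (acc in names(st$expected_category)) {
    ens <- read_structure(file.path(st$model_dir, paste0(acc, ".pdb")))
    expect_length(ens, 1)
    rt <- residue_table(ens$models[[1]])
    expect_gte(sum(rt$resid == "CYS"), 2)
  }
  expect_equal(unname(st$expected["n_input_sites"]), 2)
})
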