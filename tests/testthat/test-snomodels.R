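test_that("fraction_below uses a strict inequality", {
  expect_equal(fraction_below(c(3, 5, 7, 9), 6), 0.5)
  expect_equal(fraction_below(c(1, 2), 6), 1.0)
  expect_equal(fraction_below(c(6, 6, 3, 9), 6), 0.25)
  expect_error(fraction_below(numeric(0), 6), "empty")
})

test_that("ensemble summaries reproduce known per-model arithmetic", {
  ens <- synth_pair_ensemble(list(ss_type = "helix", sequence = "AAAALCAAA"),
                             list(ss_type = "helix", sequence = "AAAALCAAA"),
                             distances = c(3, 5, 7, 9))
  s <- analyze_ensemble(ens, attr(ens, "sno_resno"),
                        attr(ens, "proxy_resno"))
  expect_equal(s$n_models, 4)
  dist_row <- s$summary[s$summary$metric == "sg_sg_distance", ]
  expect_equal(dist_row$mean, 6.0, tolerance = 0.02)
  expect_equal(dist_row$sd, sqrt(5), tolerance = 0.02) # population sd
  expect_equal(s$fraction_below, 0.5)
  # an independent per-model loop gives the same means
  manual <- vapply(ens$models, function(m)
    pair_geometry(m, attr(ens, "sno_resno"),
                  attr(ens, "proxy_resno"))$sg_sg_distance, numeric(1))
  expect_equal(dist_row$mean, mean(manual), tolerance = 1e-9)
})

test_that("single-model ensembles have zero spread", {
  base <- helix_pair_base(d = 4.5)
  ens <- sno_ensemble(list(base))
  s <- analyze_ensemble(ens, attr(base, "sno_resno"),
                        attr(base, "proxy_resno"))
  expect_equal(s$n_models, 1)
  expect_true(all(s$summary$sd == 0, na.rm = TRUE))
  expect_equal(s$summary$mean[s$summary$metric == "sg_sg_distance"],
               s$per_model$sg_sg_distance)
})

test_that("sentinel pKa models are excluded from the pKa statistics", {
  per <- data.frame(model_id = 1:4, sg_sg_distance = c(3, 4, 5, 6),
                    pka_sno = c(9, 10, 99.99, 99.99),
                    pka_proxy = c(8, 8, 8, 8))
  s <- new_ensemble_summary(per)
  expect_equal(s$summary$mean[s$summary$metric == "pka_sno"], 9.5)
  # all-sentinel: undefined mean
  per2 <- per; per2$pka_sno <- 99.99
  s2 <- new_ensemble_summary(per2)
  expect_true(is.na(s2$summary$mean[s2$summary$metric == "pka_sno"]))
})

test_that("the pseudo-free-energy profile matches closed forms", {
  RT <- 1.9872e-3 * 298
  # two equally occupied bins: flat profile at zero
  p <- pmf_1d(c(rep(0.25, 500), rep(0.75, 500)), n_bins = 2)
  expect_equal(p$free_energy, c(0, 0))
  # e:1 occupancy: the offset is exactly RT
  n2 <- 1000; n1 <- round(exp(1) * n2)
  p2 <- pmf_1d(c(rep(0.25, n1), rep(0.75, n2)), n_bins = 2)
  expect_equal(p2$free_energy[1], 0)
  expect_equal(p2$free_energy[2], RT, tolerance = 0.001)
  # empty bins are undefined, not zero
  p3 <- pmf_1d(c(rep(0.1, 10), rep(0.9, 30)), n_bins = 4)
  expect_true(all(is.na(p3$free_energy[p3$count == 0])))
  expect_true(all(is.finite(p3$free_energy[p3$count > 0])))
  # scaling every count leaves the profile unchanged
  x <- c(rep(0.1, 5), rep(0.5, 10), rep(0.9, 25))
  expect_equal(pmf_1d(rep(x, 4), n_bins = 3)$free_energy,
               pmf_1d(x, n_bins = 3)$free_energy)
  # degenerate: all samples identical occupy a single bin at zero
  p4 <- pmf_1d(rep(2.5, 50), n_bins = 2)
  expect_equal(min(p4$free_energy, na.rm = TRUE), 0)
  expect_equal(sum(p4$count), 50)
})

test_that("the nine secondary-structure pair classes are a bijection", {
  labs <- c()
  for (a in c("H", "E", "C")) for (b in c("H", "E", "C"))
    labs <- c(labs, classify_pair_ss(a, b))
  expect_length(unique(labs), 9)
  expect_equal(classify_pair_ss("E", "E"), "strand-strand")
  expect_equal(classify_pair_ss("E", "H"), "strand-helix")
  expect_equal(classify_pair_ss("C", "H"), "loop-helix")
  expect_error(classify_pair_ss("X", "H"), "H, E or C")
})

test_that("cofactor proximity flags non-water HETATM within the cutoff", {
  at <- rbind(cys_residue_atoms(1, sg = c(3.2, 1.5, 0)),
              atom_row("ZN", "ZN", 101, 3.2, 4.5, 0, type = "HETATM"),
              atom_row("O", "HOH", 102, 3.2, 2.5, 0, type = "HETATM"))
  at$elesy[at$elety == "ZN"] <- "ZN"
  m <- sno_model(at)
  fl <- cofactor_proximity_flag(m, 1)
  expect_true(fl$flag)
  expect_equal(fl$nearest_ligand, "ZN")
  expect_equal(fl$nearest_distance, 3.0)
  # water alone never flags
  at2 <- at[at$resid != "ZN", ]
  expect_false(cofactor_proximity_flag(sno_model(at2), 1)$flag)
  # no HETATM at all
  expect_false(cofactor_proximity_flag(sno_model(cys_residue_atoms(1)),
                                       1)$flag)
})
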