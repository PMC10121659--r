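test_that("dihedral reproduces planar and orthogonal reference cases", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  # sign frozen against an independent torsion routine (bio3d::torsion.xyz)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, -1)),
               -90)
})

test_that("dihedral is rigid-motion invariant, reversal-invariant and
           mirror-antisymmetric", {
  set.seed(42)
  for (i in 1:25) {
    pts <- lapply(1:4, function(j) runif(3, -5, 5))
    ang <- tryCatch(do.call(dihedral, pts), error = function(e) NULL)
    if (is.null(ang)) next
    R <- rot3(runif(3, -1, 1), runif(1, 0, 360))
    t <- runif(3, -10, 10)
    moved <- lapply(pts, function(p) as.vector(R %*% p) + t)
    expect_equal(do.call(dihedral, moved), ang, tolerance = 1e-8)
    # a torsion does not depend on the viewing direction: traversing the
    # four points backwards yields the same signed angle
    expect_equal(do.call(dihedral, rev(pts)), ang, tolerance = 1e-8)
    # a mirror reflection flips the sign (chirality)
    mirrored <- lapply(pts, function(p) p * c(1, 1, -1))
    if (abs(abs(ang) - 180) > 1e-6)
      expect_equal(do.call(dihedral, mirrored), -ang, tolerance = 1e-8)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
})

test_that("rotamer bins partition the circle", {
  expect_equal(rotamer_state(-60), "m")
  expect_equal(rotamer_state(60), "p")
  expect_equal(rotamer_state(175), "t")
  # every angle maps to exactly one state; bin edges go to the closed side
  angs <- seq(-179.5, 180, by = 0.5)
  states <- rotamer_state(angs)
  expect_true(all(states %in% c("t", "m", "p")))
  # bins are left-open, right-closed: the boundary joins the bin it closes
  expect_equal(rotamer_state(120), "p")
  expect_equal(rotamer_state(0), "m")
  expect_equal(rotamer_state(-120), "t")
  expect_equal(rotamer_state(180), "t")
  expect_equal(rotamer_state(120.0001), "t")
})

test_that("chi1 is measured from N-CA-CB-gamma and binned", {
  for (chi in c(-60, 60, 175)) {
    m <- build_scaffold(list(ss_type = "strand", sequence = "GCG",
                             chi1 = chi))
    cr <- chi1_and_rotamer(get_residue(m, 2))
    expect_equal(cr$chi1, chi, tolerance = 0.1)
    expect_equal(cr$rotamer, rotamer_state(chi))
  }
  incomplete <- sno_model(cys_residue_atoms(1)[-4, ])
  expect_error(chi1_and_rotamer(get_residue(incomplete, 1)), "SG")
})

test_that("pair geometry reads back constructed targets", {
  m <- place_cys_pair(list(ss_type = "helix", sequence = "AAAALCAAA"),
                      list(ss_type = "helix", sequence = "AAAALCAAA"),
                      target_sg_sg = 2.05, target_dihedral = -87)
  pg <- pair_geometry(m, attr(m, "sno_resno"), attr(m, "proxy_resno"))
  expect_equal(nrow(pg), 1)
  expect_equal(pg$sg_sg_distance, 2.05, tolerance = 0.01)
  expect_equal(pg$cb_sg_sg_cb, -87, tolerance = 2)
  expect_equal(pg$grade, "A")
  expect_error(pair_geometry(m, 6, 6), "self-pair")
})

test_that("pair geometry enumerates altloc cross products", {
  # a proxy cysteine with two conformers, one near 2 A and one near 4 A
  # from the site - the two-alternative-conformation pattern seen in
  # experimental structures
  at <- rbind(cys_residue_atoms(1, sg = c(3.2, 1.5, 0)),
              shift_atoms(cys_residue_atoms(2, sg = c(3.2, 1.5, 0)),
                          dy = 5))
  sg2 <- which(at$elety == "SG" & at$resno == 2)
  a_row <- at[sg2, ]; a_row$alt <- "A"; a_row$o <- 0.6
  a_row[, c("x", "y", "z")] <- c(3.2, 3.4, 0)   # ~1.9 A from site SG
  b_row <- at[sg2, ]; b_row$alt <- "B"; b_row$o <- 0.4
  b_row[, c("x", "y", "z")] <- c(3.2, 5.5, 0)   # ~4 A from site SG
  at <- rbind(at[-sg2, ], a_row, b_row)
  m <- sno_model(at)
  pg <- pair_geometry(m, 1, 2)
  expect_equal(nrow(pg), 2)
  expect_setequal(pg$altloc_proxy, c("A", "B"))
  d <- sort(pg$sg_sg_distance)
  expect_lt(d[1], 2.5)
  expect_gt(d[2], 3.5)
})

test_that("pair distance and torsion magnitude are argument-symmetric", {
  m <- helix_pair_base(d = 4.2, dihedral = 75)
  s <- attr(m, "sno_resno"); p <- attr(m, "proxy_resno")
  ab <- pair_geometry(m, s, p)
  ba <- pair_geometry(m, p, s)
  expect_equal(ab$sg_sg_distance, ba$sg_sg_distance)
  expect_equal(abs(ab$cb_sg_sg_cb), abs(ba$cb_sg_sg_cb), tolerance = 1e-6)
})

test_that("disulfide grading follows the distance/torsion/rotamer rules", {
  row <- function(d, dih, rs = "m", rp = "m")
    list(sg_sg_distance = d, cb_sg_sg_cb = dih, rotamer_sno = rs,
         rotamer_proxy = rp)
  expect_equal(grade_disulfide(row(2.05, -87)), "A")
  expect_equal(grade_disulfide(row(2.05, 0)), "B")
  expect_equal(grade_disulfide(row(1.0, -90)), "C")
  expect_equal(grade_disulfide(row(2.05, -90, rp = "p")), "D")
  expect_equal(grade_disulfide(row(5.0, -90)), "none")
  # total over a sweep of inputs
  for (d in c(0.5, 1.8, 2.2, 2.5, 3, 8))
    for (dih in c(-170, -90, -50, 0, 60, 90, 180))
      for (r in c("t", "m", "p"))
        expect_true(grade_disulfide(row(d, dih, r, "m")) %in%
                      c("A", "B", "C", "D", "none"))
})
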