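# Three-state secondary structure from backbone hydrogen bonds
# (Kabsch-Sander electrostatic model, reduced to helix/strand/loop).

# place amide H: 1.01 Angstrom from N, anti to the carbonyl O of the
# preceding residue, in the peptide plane
.amide_h <- function(n_coord, c_prev, o_prev, bond = 1.01) {
  v <- c_prev - o_prev
  n_coord + bond * v / sqrt(sum(v^2))
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy between a backbone carbonyl (C=O) and an amide
#' (N-H): `E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol.
#' A hydrogen bond is assigned when `E < -0.5` kcal/mol.
#'
#' @param o_coord,c_coord acceptor-side O and C coordinates.
#' @param n_coord,h_coord donor-side N and H coordinates.
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(o_coord, c_coord, n_coord, h_coord) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  27.888 * (1 / d(o_coord, n_coord) + 1 / d(c_coord, h_coord) -
              1 / d(o_coord, h_coord) - 1 / d(c_coord, n_coord))
}

#' Three-state secondary structure assignment
#'
#' Backbone-hydrogen-bond based assignment in the Kabsch-Sander spirit,
#' reduced to three states: `H` helix (3/4/5-turn patterns on at least two
#' consecutive residues, covering the 3-10, alpha and pi classes), `E`
#' strand (parallel or antiparallel bridge ladders), `C` loop otherwise.
#' Amide hydrogens are reconstructed geometrically when absent; chains (and
#' chain breaks, detected as C-N peptide distances above 2.5 Angstrom) are
#' handled per contiguous segment, while bridge partners may lie in any
#' segment. Residues missing backbone atoms, and chains shorter than three
#' residues, are loops.
#'
#' @param model `sno_model`.
#' @param energy_cutoff hydrogen-bond energy threshold in kcal/mol
#'   (default -0.5).
#' @return data.frame `chain`, `resno`, `insert`, `resid`, `ss` with
#'   `ss` in `{"H","E","C"}`.
#' @export
assign_ss3 <- function(model, energy_cutoff = -0.5) {
  rt <- residue_table(model)
  n <- nrow(rt)
  rt$ss <- rep("C", n)
  if (n < 3) return(rt)
  # backbone coordinate matrices (first altloc when duplicated)
  bb <- array(NA_real_, dim = c(n, 4, 3),
              dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  for (i in seq_len(n)) {
    res <- get_residue(model, rt$resno[i], rt$chain[i], rt$insert[i])
    for (a in c("N", "CA", "C", "O")) {
      p <- atom_coord(res, a)
      if (!is.null(p)) bb[i, a, ] <- p
    }
  }
  ok <- apply(bb, 1, function(m) all(is.finite(m)))
  # contiguity: same chain and peptide C(i)-N(i+1) distance < 2.5 A
  linked <- rep(FALSE, n) # linked[i]: residue i bonded to i-1
  for (i in 2:n) {
    if (rt$chain[i] != rt$chain[i - 1]) next
    if (!all(is.finite(bb[i - 1, "C", ])) || !all(is.finite(bb[i, "N", ])))
      next
    linked[i] <- sqrt(sum((bb[i - 1, "C", ] - bb[i, "N", ])^2)) < 2.5
  }
  # amide H for every linked, non-proline residue with complete backbone
  hpos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!linked[i] || !ok[i] || rt$resid[i] == "PRO") next
    if (!all(is.finite(bb[i - 1, c("C", "O"), ]))) next
    hpos[i, ] <- .amide_h(bb[i, "N", ], bb[i - 1, "C", ], bb[i - 1, "O", ])
  }
  # hydrogen bonds: CO(i) -> NH(j), |i-j| >= 2, CA-CA < 9 A prefilter
  hb <- matrix(FALSE, n, n)
  ca <- bb[, "CA", ]
  for (i in seq_len(n)) {
    if (!ok[i]) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || !ok[j] || !is.finite(hpos[j, 1])) next
      if (sum((ca[i, ] - ca[j, ])^2) > 81) next
      e <- hbond_energy(bb[i, "O", ], bb[i, "C", ], bb[j, "N", ], hpos[j, ])
      if (e < energy_cutoff) hb[i, j] <- TRUE
    }
  }
  contiguous <- function(i, j) {
    # i < j on the same contiguous segment
    i < j && j <= n && all(linked[(i + 1):j])
  }
  # n-turns: CO(i) -> NH(i+k); helix when two consecutive turns exist
  helix <- rep(FALSE, n)
  for (k in c(4, 3, 5)) {
    turn <- vapply(seq_len(n), function(i)
      i + k <= n && contiguous(i, i + k) && hb[i, i + k], logical(1))
    for (i in seq_len(n - 1)) {
      if (turn[i] && turn[i + 1] && contiguous(i, i + 1 + k))
        helix[(i + 1):(i + k)] <- TRUE
    }
  }
  # bridges
  strand <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3 && contiguous(min(i, j), max(i, j))) next
      para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (para || anti) { strand[i] <- TRUE; strand[j] <- TRUE }
    }
  }
  rt$ss[strand] <- "E"
  rt$ss[helix] <- "H" # helix takes precedence over strand, as in DSSP
  rt
}
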