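# Deterministic synthetic-structure generation: ideal-geometry peptide
# scaffolds, rigid placement of cysteine pairs at target disulfide
# geometries, jittered multi-model ensembles emulating coarse-grained
# flexibility sampling, and synthetic PTM-site tables with injected errors.
#
# Ideal backbone constants (Engh & Huber protein geometry): N-CA 1.458,
# CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom; N-CA-C 111.2, CA-C-N 116.2,
# C-N-CA 121.7, CA-C-O 120.5 degrees; omega fixed at 180.

.aa_three_to_one <- c(G = "GLY", A = "ALA", C = "CYS", S = "SER", T = "THR",
                      V = "VAL", L = "LEU", I = "ILE", M = "MET", D = "ASP",
                      E = "GLU", N = "ASN", Q = "GLN", K = "LYS", R = "ARG",
                      H = "HIS")

# place atom d bonded to c: |c-d| = bond, angle(b,c,d) = ang, torsion
# (a,b,c,d) = tor (degrees); the NeRF construction
.place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# side-chain internal coordinates: per atom (refs are previous atoms of the
# same residue), torsion given as fixed degrees or "chi1"/"chi1+off"
.sc_zmat <- list(
  ALA = list(),
  CYS = list(list("SG", c("N", "CA", "CB"), 1.808, 114.4, "chi1")),
  SER = list(list("OG", c("N", "CA", "CB"), 1.417, 110.8, "chi1")),
  THR = list(list("OG1", c("N", "CA", "CB"), 1.433, 109.6, "chi1"),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5, "chi1-120")),
  VAL = list(list("CG1", c("N", "CA", "CB"), 1.521, 110.5, "chi1"),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5, "chi1+122")),
  LEU = list(list("CG", c("N", "CA", "CB"), 1.530, 116.3, "chi1"),
             list("CD1", c("CA", "CB", "CG"), 1.521, 110.7, 180),
             list("CD2", c("CA", "CB", "CG"), 1.521, 110.7, -58)),
  ILE = list(list("CG1", c("N", "CA", "CB"), 1.530, 110.4, "chi1"),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5, "chi1-122"),
             list("CD1", c("CA", "CB", "CG1"), 1.513, 113.8, 180)),
  MET = list(list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
             list("SD", c("CA", "CB", "CG"), 1.803, 112.7, 180),
             list("CE", c("CB", "CG", "SD"), 1.791, 100.9, 180)),
  ASP = list(list("CG", c("N", "CA", "CB"), 1.516, 112.6, "chi1"),
             list("OD1", c("CA", "CB", "CG"), 1.249, 118.4, 0),
             list("OD2", c("CA", "CB", "CG"), 1.249, 118.4, 180)),
  ASN = list(list("CG", c("N", "CA", "CB"), 1.516, 112.6, "chi1"),
             list("OD1", c("CA", "CB", "CG"), 1.231, 120.8, 0),
             list("ND2", c("CA", "CB", "CG"), 1.328, 116.4, 180)),
  GLU = list(list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.516, 112.6, 180),
             list("OE1", c("CB", "CG", "CD"), 1.249, 118.4, 0),
             list("OE2", c("CB", "CG", "CD"), 1.249, 118.4, 180)),
  GLN = list(list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.516, 112.6, 180),
             list("OE1", c("CB", "CG", "CD"), 1.231, 120.8, 0),
             list("NE2", c("CB", "CG", "CD"), 1.328, 116.4, 180)),
  LYS = list(list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.520, 111.3, 180),
             list("CE", c("CB", "CG", "CD"), 1.520, 111.3, 180),
             list("NZ", c("CG", "CD", "CE"), 1.489, 111.9, 180)),
  ARG = list(list("CG", c("N", "CA", "CB"), 1.520, 114.1, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.520, 111.3, 180),
             list("NE", c("CB", "CG", "CD"), 1.461, 112.0, 180),
             list("CZ", c("CG", "CD", "NE"), 1.330, 124.2, 180),
             list("NH1", c("CD", "NE", "CZ"), 1.326, 120.0, 0),
             list("NH2", c("CD", "NE", "CZ"), 1.326, 120.0, 180)),
  HIS = list(list("CG", c("N", "CA", "CB"), 1.497, 113.8, "chi1"),
             list("ND1", c("CA", "CB", "CG"), 1.378, 122.7, -70),
             list("CD2", c("CA", "CB", "CG"), 1.354, 131.1, 110),
             list("CE1", c("CB", "CG", "ND1"), 1.321, 109.3, 180),
             list("NE2", c("CB", "CG", "CD2"), 1.374, 107.2, 180)))

.sc_torsion <- function(spec, chi1) {
  if (is.numeric(spec)) return(spec)
  eval(parse(text = sub("chi1", chi1, spec)))
}

#' Build an ideal-geometry peptide scaffold
#'
#' Constructs a single-chain all-heavy-atom model with ideal backbone bond
#' lengths and angles at the requested phi/psi, omega fixed at 180 degrees.
#' Side chains are placed at ideal internal coordinates with chi1 = -60
#' degrees (the minus rotamer) unless overridden. Defaults: helix
#' phi/psi = -57/-47, strand -139/135, coil randomized per residue.
#'
#' @param spec list with fields `ss_type` ("helix", "strand" or "coil"),
#'   `sequence` (1-letter string; supported alphabet
#'   GACSTVLIMDENQKRH), optional `length` (checked against the sequence),
#'   `phi`/`psi` (degrees, recycled), `chi1` (degrees, recycled across
#'   residues), `bfactor` (default 90), `chain` ("A"), `start_resno` (1),
#'   `seed` (coil randomization, default 1).
#' @return `sno_model`.
#' @export
build_scaffold <- function(spec) {
  ss <- match.arg(spec$ss_type, c("helix", "strand", "coil"))
  seq1 <- strsplit(spec$sequence, "")[[1]]
  n <- length(seq1)
  if (!is.null(spec$length) && spec$length != n)
    stop("length does not match sequence")
  bad <- setdiff(seq1, names(.aa_three_to_one))
  if (length(bad) > 0) stop("unknown residue letter: ", bad[1])
  resn <- unname(.aa_three_to_one[seq1])
  defaults <- switch(ss, helix = c(-57, -47), strand = c(-139, 135),
                     coil = c(NA, NA))
  if (ss == "coil") {
    seed <- if (is.null(spec$seed)) 1L else spec$seed
    rng <- .with_seed(seed, list(phi = runif(n, -180, 180),
                                 psi = runif(n, -180, 180)))
    phi <- rng$phi; psi <- rng$psi
  } else {
    phi <- rep(if (is.null(spec$phi)) defaults[1] else spec$phi, length.out = n)
    psi <- rep(if (is.null(spec$psi)) defaults[2] else spec$psi, length.out = n)
  }
  if (!is.null(spec$phi) && ss == "coil") phi <- rep(spec$phi, length.out = n)
  if (!is.null(spec$psi) && ss == "coil") psi <- rep(spec$psi, length.out = n)
  chi1 <- rep(if (is.null(spec$chi1)) -60 else spec$chi1, length.out = n)
  bfac <- rep(if (is.null(spec$bfactor)) 90 else spec$bfactor, length.out = n)
  chain <- if (is.null(spec$chain)) "A" else spec$chain
  start <- if (is.null(spec$start_resno)) 1L else as.integer(spec$start_resno)

  coords <- list() # per residue: named list of atom coordinates
  for (i in seq_len(n)) {
    res <- list()
    if (i == 1) {
      res$N <- c(0, 0, 0)
      res$CA <- c(1.458, 0, 0)
      th <- 111.2 * pi / 180
      res$C <- res$CA + 1.525 * c(-cos(th), sin(th), 0)
    } else {
      prev <- coords[[i - 1]]
      res$N <- .place_atom(prev$N, prev$CA, prev$C, 1.329, 116.2, psi[i - 1])
      res$CA <- .place_atom(prev$CA, prev$C, res$N, 1.458, 121.7, 180)
      res$C <- .place_atom(prev$C, res$N, res$CA, 1.525, 111.2, phi[i])
    }
    coords[[i]] <- res
  }
  for (i in seq_len(n)) {
    res <- coords[[i]]
    # carbonyl O anti to the next amide N (trans peptide)
    o_tor <- psi[i] + 180
    res$O <- .place_atom(res$N, res$CA, res$C, 1.231, 120.5, o_tor)
    if (resn[i] != "GLY") {
      res$CB <- .place_atom(res$N, res$C, res$CA, 1.530, 110.6, 123.0)
      for (z in .sc_zmat[[resn[i]]]) {
        refs <- lapply(z[[2]], function(a) res[[a]])
        res[[z[[1]]]] <- .place_atom(refs[[1]], refs[[2]], refs[[3]],
                                     z[[3]], z[[4]],
                                     .sc_torsion(z[[5]], chi1[i]))
      }
    }
    coords[[i]] <- res
  }
  rows <- list()
  eleno <- 0L
  for (i in seq_len(n)) {
    for (a in names(coords[[i]])) {
      eleno <- eleno + 1L
      p <- coords[[i]][[a]]
      rows[[eleno]] <- data.frame(
        type = "ATOM", eleno = eleno, elety = a, alt = "", resid = resn[i],
        chain = chain, resno = start + i - 1L, insert = "",
        x = round(p[1], 3), y = round(p[2], 3), z = round(p[3], 3),
        o = 1, b = bfac[i], elesy = substr(a, 1, 1), stringsAsFactors = FALSE)
    }
  }
  sno_model(do.call(rbind, rows), model_id = 1L)
}

# run expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Kabsch rigid superposition: rotation+translation mapping points P onto Q
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cq - as.vector(R %*% cp))
}

.apply_rigid <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, t, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

.single_cys <- function(model) {
  rt <- residue_table(model)
  cys <- rt[rt$resid == "CYS", , drop = FALSE]
  if (nrow(cys) != 1) stop("scaffold spec must contain exactly one cysteine")
  cys
}

#' Place two cysteine-bearing scaffolds at a target disulfide geometry
#'
#' Builds both scaffolds, then rigidly places the second so that the
#' measured Sgamma-Sgamma distance is within 0.05 Angstrom of
#' `target_sg_sg` and the CB-SG-SG-CB torsion within 2 degrees of
#' `target_dihedral`. The free orientation parameters (approach direction
#' and spin of the second scaffold) are scanned until the backbones are
#' clash-free (no backbone-backbone contact under 1 Angstrom... in practice
#' a 2.5 Angstrom safety floor is enforced, with the hard failure below 1).
#' The merged model is a single chain; the second scaffold is renumbered to
#' start at `b_start_resno`.
#'
#' @param modelA_spec,modelB_spec scaffold specs (see [build_scaffold()]),
#'   each containing exactly one Cys.
#' @param target_sg_sg target sulfur-sulfur distance, Angstrom.
#' @param target_dihedral target CB-SG-SG-CB torsion, degrees.
#' @param b_start_resno first residue number of the second scaffold
#'   (default: length of A + 14, i.e., a sequence-distal pair).
#' @param ss_cb_angle CB-SG-SG approach angle, degrees (default 104).
#' @return `sno_model` with attributes `sno_resno` (Cys of A) and
#'   `proxy_resno` (Cys of B).
#' @export
place_cys_pair <- function(modelA_spec, modelB_spec, target_sg_sg,
                           target_dihedral, b_start_resno = NULL,
                           ss_cb_angle = 104) {
  A <- build_scaffold(modelA_spec)
  B <- build_scaffold(modelB_spec)
  cysA <- .single_cys(A); cysB <- .single_cys(B)
  resA <- get_residue(A, cysA$resno, cysA$chain)
  caA <- atom_coord(resA, "CA"); cbA <- atom_coord(resA, "CB")
  sgA <- atom_coord(resA, "SG")
  resB <- get_residue(B, cysB$resno, cysB$chain)
  caB <- atom_coord(resB, "CA"); cbB <- atom_coord(resB, "CB")
  sgB <- atom_coord(resB, "SG")
  len_cb_sg <- sqrt(sum((cbB - sgB)^2))
  len_cb_ca <- sqrt(sum((cbB - caB)^2))
  ang_sg_cb_ca <- acos(sum((sgB - cbB) * (caB - cbB)) /
                         (len_cb_sg * len_cb_ca)) * 180 / pi
  bbA <- A$atoms[A$atoms$elety %in% c("N", "CA", "C", "O"), c("x", "y", "z")]
  best <- NULL
  for (t1 in seq(-180, 150, by = 30)) {
    for (t2 in seq(-180, 120, by = 60)) {
      sg_t <- .place_atom(caA, cbA, sgA, target_sg_sg, ss_cb_angle, t1)
      cb_t <- .place_atom(cbA, sgA, sg_t, len_cb_sg, ss_cb_angle,
                          target_dihedral)
      ca_t <- .place_atom(sgA, sg_t, cb_t, len_cb_ca, ang_sg_cb_ca, t2)
      fit <- .kabsch(rbind(sgB, cbB, caB), rbind(sg_t, cb_t, ca_t))
      cand <- .apply_rigid(B, fit$R, fit$t)
      bbB <- cand$atoms[cand$atoms$elety %in% c("N", "CA", "C", "O"),
                        c("x", "y", "z")]
      mind <- min(as.matrix(stats::dist(rbind(bbA, bbB)))[
        seq_len(nrow(bbA)), nrow(bbA) + seq_len(nrow(bbB))])
      if (is.null(best) || mind > best$mind) best <- list(B = cand,
                                                          mind = mind)
      if (mind >= 2.5) break
    }
    if (!is.null(best) && best$mind >= 2.5) break
  }
  if (best$mind < 1)
    stop("placement error: steric clash between backbones (",
         round(best$mind, 2), " Angstrom)")
  Bp <- best$B
  nA <- nrow(residue_table(A))
  if (is.null(b_start_resno)) b_start_resno <- nA + 14L
  Bp$atoms$resno <- Bp$atoms$resno - min(Bp$atoms$resno) + b_start_resno
  Bp$atoms$chain <- A$atoms$chain[1]
  atoms <- rbind(A$atoms, Bp$atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  out <- sno_model(atoms, model_id = 1L)
  attr(out, "sno_resno") <- cysA$resno
  attr(out, "proxy_resno") <- cysB$resno - min(B$atoms$resno) + b_start_resno
  out
}

#' Build an ideal antiparallel two-strand sheet
#'
#' Two extended strands placed antiparallel: the second strand is the first
#' rotated 180 degrees about the sheet's in-plane axis perpendicular to the
#' strand direction and offset by about 4 Angstrom, the canonical
#' antiparallel-sheet spacing. A small deterministic grid refinement around
#' that placement picks the register with the most backbone hydrogen
#' bonds, so interior residues of both strands are assigned strand (`E`)
#' by [assign_ss3()].
#'
#' @param sequence_a,sequence_b 1-letter sequences (equal length).
#' @param b_start_resno first residue number of the second strand
#'   (default: length of A + 21).
#' @return `sno_model` (single chain, numbering gap between the strands).
#' @export
build_strand_pair <- function(sequence_a, sequence_b = sequence_a,
                              b_start_resno = NULL) {
  if (nchar(sequence_a) != nchar(sequence_b))
    stop("strand sequences must have equal length")
  A <- build_scaffold(list(ss_type = "strand", sequence = sequence_a))
  B0 <- build_scaffold(list(ss_type = "strand", sequence = sequence_b))
  xyzB <- as.matrix(B0$atoms[, c("x", "y", "z")])
  ca <- as.matrix(A$atoms[A$atoms$elety == "CA", c("x", "y", "z")])
  pc <- prcomp(ca)$rotation
  axis <- pc[, 1]; perp <- pc[, 2]
  ctr <- colMeans(ca)
  u <- perp / sqrt(sum(perp^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + 2 * K %*% K # 180-degree rotation about perp
  nA <- nrow(residue_table(A))
  if (is.null(b_start_resno)) b_start_resno <- nA + 21L
  best <- NULL
  for (dy in c(-4.25, -4, -3.75, 3.75, 4, 4.25)) {
    for (dx in seq(-1.5, 1.5, by = 0.5)) {
      B <- B0
      m <- sweep(xyzB, 2, ctr) %*% t(R)
      m <- sweep(m, 2, ctr + dx * axis + dy * perp, "+")
      B$atoms$x <- m[, 1]; B$atoms$y <- m[, 2]; B$atoms$z <- m[, 3]
      B$atoms$resno <- B$atoms$resno - min(B$atoms$resno) + b_start_resno
      B$atoms$chain <- A$atoms$chain[1]
      atoms <- rbind(A$atoms, B$atoms)
      atoms$eleno <- seq_len(nrow(atoms))
      comb <- sno_model(atoms)
      nE <- sum(assign_ss3(comb)$ss == "E")
      if (is.null(best) || nE > best$nE) best <- list(nE = nE, model = comb)
    }
  }
  best$model
}

#' Synthetic multi-model ensemble from a base structure
#'
#' Emulates the output of a coarse-grained flexibility sampler: `n_models`
#' copies of the base model with cysteine chi1 rotamers resampled from a
#' weight vector and Gaussian Cartesian jitter. The chi1 of every cysteine
#' is set by rebuilding its Sgamma at the sampled rotamer's canonical angle
#' (t = 180, m = -60, p = +60) plus `chi1_sd` degrees of noise; jitter is
#' applied afterwards in Cartesian space, so rotamer fractions are exact
#' only at small jitter. Reproducible byte-for-byte given `seed`.
#'
#' @param base `sno_model`.
#' @param spec list: `n_models` (20), `coordinate_jitter` (Angstrom sd,
#'   default 0.15), `chi1_distribution` (weights for t/m/p, default
#'   c(t=0.4, m=0.5, p=0.1)), `chi1_sd` (degrees, default 8), `seed` (1).
#' @return `sno_ensemble`.
#' @export
synth_ensemble <- function(base, spec = list()) {
  spec <- modifyList(list(n_models = 20L, coordinate_jitter = 0.15,
                          chi1_distribution = c(t = 0.4, m = 0.5, p = 0.1),
                          chi1_sd = 8, seed = 1L), spec)
  w <- spec$chi1_distribution
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("chi1_distribution weights must be nonnegative and sum to 1")
  canon <- c(t = 180, m = -60, p = 60)
  rt <- residue_table(base)
  cys <- rt[rt$resid == "CYS", , drop = FALSE]
  .with_seed(spec$seed, {
    models <- vector("list", spec$n_models)
    for (k in seq_len(spec$n_models)) {
      m <- base
      for (i in seq_len(nrow(cys))) {
        state <- sample(names(canon), 1, prob = w[c("t", "m", "p")])
        chi1 <- canon[[state]] + rnorm(1, 0, spec$chi1_sd)
        res <- get_residue(m, cys$resno[i], cys$chain[i], cys$insert[i])
        sg_new <- .place_atom(atom_coord(res, "N"), atom_coord(res, "CA"),
                              atom_coord(res, "CB"), 1.808, 114.4, chi1)
        sel <- m$atoms$type == "ATOM" & m$atoms$chain == cys$chain[i] &
          m$atoms$resno == cys$resno[i] & m$atoms$elety == "SG"
        m$atoms$x[sel] <- sg_new[1]; m$atoms$y[sel] <- sg_new[2]
        m$atoms$z[sel] <- sg_new[3]
      }
      nat <- nrow(m$atoms)
      m$atoms$x <- round(m$atoms$x + rnorm(nat, 0, spec$coordinate_jitter), 3)
      m$atoms$y <- round(m$atoms$y + rnorm(nat, 0, spec$coordinate_jitter), 3)
      m$atoms$z <- round(m$atoms$z + rnorm(nat, 0, spec$coordinate_jitter), 3)
      m$model_id <- k
      models[[k]] <- m
    }
    sno_ensemble(models)
  })
}

#' Ensemble of cysteine pairs at prescribed per-model distances
#'
#' Builds one model per entry of `distances` with [place_cys_pair()] (same
#' scaffolds, same dihedral target, varying sulfur-sulfur distance), stacked
#' into an ensemble with identical topology. Useful for exercising
#' per-model metric summaries against known arithmetic.
#'
#' @param modelA_spec,modelB_spec scaffold specs with one Cys each.
#' @param distances numeric vector of target Sgamma-Sgamma distances.
#' @param dihedral target CB-SG-SG-CB torsion (default -90).
#' @param b_start_resno see [place_cys_pair()].
#' @return `sno_ensemble` with attributes `sno_resno`, `proxy_resno`.
#' @export
synth_pair_ensemble <- function(modelA_spec, modelB_spec, distances,
                                dihedral = -90, b_start_resno = NULL) {
  models <- vector("list", length(distances))
  sno <- proxy <- NULL
  for (k in seq_along(distances)) {
    m <- place_cys_pair(modelA_spec, modelB_spec, distances[k], dihedral,
                        b_start_resno = b_start_resno)
    sno <- attr(m, "sno_resno"); proxy <- attr(m, "proxy_resno")
    m$model_id <- k
    models[[k]] <- m
  }
  ens <- sno_ensemble(models)
  attr(ens, "sno_resno") <- sno
  attr(ens, "proxy_resno") <- proxy
  ens
}

#' Synthetic PTM-site table with matching model files
#'
#' Writes a dbPTM-like tab-separated site table and one PDB model per
#' accession into `dir`, with controllable injected bookkeeping errors:
#' accessions without a model file, site positions falling on a
#' non-cysteine residue, and positions outside the model. Valid sites are
#' cysteine pairs (vicinal or proximal by construction). Returns a manifest
#' with the expected bookkeeping so pipeline runs close the loop.
#'
#' @param n_proteins number of valid pair-bearing proteins.
#' @param error_injections list: `missing_model`, `non_cys`, `out_of_range`
#'   (counts, default 0 each).
#' @param seed RNG seed for distances and vicinal/proximal choice.
#' @param dir output directory (created).
#' @param vicinal_fraction fraction of valid proteins built as vicinal
#'   (same-scaffold) pairs, default 0.5.
#' @return list: `sites_path`, `model_dir`, `sites` (data.frame),
#'   `expected` (named counts: n_input_sites, n_missing_model,
#'   n_not_cysteine, n_out_of_range, n_analyzed), `expected_category`
#'   (accession -> "vicinal"/"proximal").
#' @export
synth_sites_table <- function(n_proteins, error_injections = list(),
                              seed = 1L, dir = tempfile("sno_sites_"),
                              vicinal_fraction = 0.5) {
  inj <- modifyList(list(missing_model = 0L, non_cys = 0L,
                         out_of_range = 0L), error_injections)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .with_seed(seed, {
    rows <- list(); cat_map <- character(0)
    for (i in seq_len(n_proteins)) {
      acc <- sprintf("SYN%04d", i)
      vic <- runif(1) < vicinal_fraction
      if (vic) {
        # one helix with a CXXXC-like motif: both cysteines on one face
        m <- build_scaffold(list(ss_type = "helix",
                                 sequence = "AAAALCAAACLAAAA"))
        sno <- 6L; proxy <- 10L
        cat_map[acc] <- "vicinal"
      } else {
        d <- runif(1, 3.5, 6.5)
        m <- place_cys_pair(
          list(ss_type = "helix", sequence = "AAAALCAAA"),
          list(ss_type = "helix", sequence = "AAAALCAAA"),
          target_sg_sg = d, target_dihedral = -90)
        sno <- attr(m, "sno_resno"); proxy <- attr(m, "proxy_resno")
        cat_map[acc] <- "proximal"
      }
      write_structure(m, file.path(dir, paste0(acc, ".pdb")))
      rows[[length(rows) + 1]] <- data.frame(
        accession = acc, position = sno, ptm_type = "S-nitrosylation",
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(inj$missing_model)) {
      rows[[length(rows) + 1]] <- data.frame(
        accession = sprintf("MISS%03d", i), position = 6L,
        ptm_type = "S-nitrosylation", stringsAsFactors = FALSE)
    }
    for (i in seq_len(inj$non_cys)) {
      acc <- sprintf("NCYS%03d", i)
      m <- build_scaffold(list(ss_type = "helix", sequence = "AAAASAAAA"))
      write_structure(m, file.path(dir, paste0(acc, ".pdb")))
      rows[[length(rows) + 1]] <- data.frame(
        accession = acc, position = 5L, ptm_type = "S-nitrosylation",
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(inj$out_of_range)) {
      acc <- sprintf("OOR%04d", i)
      m <- build_scaffold(list(ss_type = "helix", sequence = "AAAACAAAA"))
      write_structure(m, file.path(dir, paste0(acc, ".pdb")))
      rows[[length(rows) + 1]] <- data.frame(
        accession = acc, position = 999L, ptm_type = "S-nitrosylation",
        stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
    sites_path <- file.path(dir, "sites.tsv")
    write.table(sites, sites_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(sites_path = sites_path, model_dir = dir, sites = sites,
         expected = c(n_input_sites = nrow(sites),
                      n_missing_model = inj$missing_model,
                      n_not_cysteine = inj$non_cys,
                      n_out_of_range = inj$out_of_range,
                      n_analyzed = n_proteins),
         expected_category = cat_map)
  })
}
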