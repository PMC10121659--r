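# shared in-code fixtures; everything is generated, nothing is stored

# minimal hand-built atom row
atom_row <- function(elety, resid, resno, x, y, z, chain = "A", alt = "",
                     type = "ATOM", o = 1, b = 90) {
  data.frame(type = type, elety = elety, alt = alt, resid = resid,
             chain = chain, resno = resno, insert = "", x = x, y = y, z = z,
             o = o, b = b, elesy = substr(elety, 1, 1),
             stringsAsFactors = FALSE)
}

# a bare cysteine residue (N, CA, CB, SG) at controllable SG position
cys_residue_atoms <- function(resno, sg = c(3.2, 1.5, 0), chain = "A") {
  rbind(atom_row("N", "CYS", resno, 0, 0, 0, chain),
        atom_row("CA", "CYS", resno, 1.458, 0, 0, chain),
        atom_row("CB", "CYS", resno, 2.0, 1.4, 0, chain),
        atom_row("SG", "CYS", resno, sg[1], sg[2], sg[3], chain))
}

# shift a block of atom rows rigidly
shift_atoms <- function(at, dx = 0, dy = 0, dz = 0) {
  at$x <- at$x + dx; at$y <- at$y + dy; at$z <- at$z + dz
  at
}

# random "cysteine cloud" model: n_cys two-atom (CB, SG) side chains at
# random positions in a box; backbone atoms far away so only side chains
# matter for center-of-mass contacts
random_cys_cloud <- function(n_cys, box = 20, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_cys)) {
    p <- runif(3, 0, box)
    sg <- p + runif(3, -0.8, 0.8)
    rows[[i]] <- rbind(
      atom_row("N", "CYS", i, p[1] - 0.5, p[2], p[3]),
      atom_row("CA", "CYS", i, p[1] - 0.2, p[2], p[3]),
      atom_row("CB", "CYS", i, p[1], p[2], p[3]),
      atom_row("SG", "CYS", i, sg[1], sg[2], sg[3]))
  }
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  sno_model(at)
}

# brute-force all-pairs side-chain COM contact scan (independent oracle)
brute_force_partners <- function(model, sno_resno, cutoff = 8) {
  rt <- residue_table(model)
  rt <- rt[rt$resid == "CYS", , drop = FALSE]
  com <- function(resno) {
    r <- get_residue(model, resno)
    sc <- r[r$elety %in% c("CB", "SG"), , drop = FALSE]
    m <- c(CB = 12.011, SG = 32.06)[sc$elety]
    c(sum(sc$x * m), sum(sc$y * m), sum(sc$z * m)) / sum(m)
  }
  c0 <- com(sno_resno)
  hits <- integer(0)
  for (rn in rt$resno) {
    if (rn == sno_resno) next
    if (sqrt(sum((com(rn) - c0)^2)) <= cutoff) hits <- c(hits, rn)
  }
  sort(hits)
}

# canonical helix-pair base model used across ensemble tests
helix_pair_base <- function(d = 4.5, dihedral = -90) {
  place_cys_pair(list(ss_type = "helix", sequence = "AAAALCAAA"),
                 list(ss_type = "helix", sequence = "AAAALCAAA"),
                 target_sg_sg = d, target_dihedral = dihedral)
}

# per-model metric table with prescribed moments, for classifier tests
synth_metric_summary <- function(n_models, mean_dist, mean_pka,
                                 sd_dist = 0.5, sd_pka = 0.4,
                                 threshold = 6) {
  per <- data.frame(
    model_id = seq_len(n_models),
    sg_sg_distance = rnorm(n_models, mean_dist, sd_dist),
    pka_sno = rnorm(n_models, mean_pka, sd_pka),
    pka_proxy = rnorm(n_models, mean_pka, sd_pka))
  new_ensemble_summary(per, distance_threshold = threshold)
}

# rigid rotation matrix from an axis (unnormalized) and angle in degrees
rot3 <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2)); th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
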