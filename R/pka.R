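# Empirical cysteine pKa model: a transparent three-term perturbation of
# the thiol model pKa (desolvation, hydrogen-bond donors, charged groups),
# with the conventional 99.99 sentinel for disulfide-locked cysteines.
# This is the package's own documented empirical model, with every
# coefficient exposed in the parameter list; an optional delegate hook
# passes an external predictor's values through verbatim.

#' Default parameters of the cysteine pKa model
#'
#' @return named list: `model_pka` (9.0, the thiol reference), `c_des`
#'   (+2.0 pKa units at full burial), `hb_delta` (-0.8 per donor),
#'   `hb_cutoff` (3.5 Angstrom, donor heavy atom to Sgamma),
#'   `coulomb_delta` (0.5 pKa units at zero distance), `coulomb_cutoff`
#'   (7 Angstrom), `sentinel_distance` (2.5 Angstrom Sgamma-Sgamma),
#'   `his_charged` (TRUE: histidine counted as a cation, worst case).
#' @export
pka_params <- function() {
  list(model_pka = 9.0, c_des = 2.0, hb_delta = -0.8, hb_cutoff = 3.5,
       coulomb_delta = 0.5, coulomb_cutoff = 7.0, sentinel_distance = 2.5,
       his_charged = TRUE)
}

# hydrogen-bond donor heavy atoms by residue type (side chains), plus the
# backbone amide N of every residue
.sidechain_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1")

# charge centers: q is the sign of the pKa effect on a thiolate
# (cations stabilize the anion and lower pKa: q = -1)
.charge_centers <- function(his_charged = TRUE) {
  cc <- list(LYS = list(atoms = "NZ", q = -1),
             ARG = list(atoms = "CZ", q = -1),
             ASP = list(atoms = c("OD1", "OD2"), q = +1),
             GLU = list(atoms = c("OE1", "OE2"), q = +1))
  if (his_charged) cc$HIS <- list(atoms = c("ND1", "NE2"), q = -1)
  cc
}

#' Environment terms of the cysteine pKa model
#'
#' The three additive contributions (pKa units) for a cysteine:
#' * desolvation: `c_des * max(0, 1 - relSASA/100)` - burial raises pKa;
#' * hbond: `hb_delta` for every hydrogen-bond donor (backbone amide N or
#'   side-chain O-H/N-H heavy atom, other residues only) within `hb_cutoff`
#'   of Sgamma - donors stabilize the thiolate and lower pKa;
#' * coulomb: for every charged group center within `coulomb_cutoff`,
#'   `q * coulomb_delta * (cutoff - d)/cutoff` - cations (Lys/Arg/His+)
#'   lower pKa, anions (Asp/Glu) raise it.
#'
#' @param model `sno_model`.
#' @param resno cysteine residue number; `chain` optional.
#' @param chain chain id.
#' @param params parameter list, see [pka_params()].
#' @param rel_sasa optional precomputed relative side-chain SASA (percent)
#'   for the cysteine; computed via [relative_sidechain_sasa()] when `NULL`.
#' @param altloc conformer used for the Sgamma position.
#' @return named numeric vector `(desolvation, hbond, coulomb)`.
#' @export
pka_environment_terms <- function(model, resno, chain = NULL,
                                  params = pka_params(), rel_sasa = NULL,
                                  altloc = "") {
  params <- modifyList(pka_params(), params)
  res <- get_residue(model, resno, chain)
  if (is.null(res)) stop("residue not found: ", resno)
  if (res$resid[1] != "CYS") stop("not a cysteine: ", res$resid[1], resno)
  sg <- atom_coord(res, "SG", altloc)
  if (is.null(sg)) stop("incomplete residue: missing atom SG")
  chain <- res$chain[1]
  if (is.null(rel_sasa))
    rel_sasa <- relative_sidechain_sasa(model, resno, chain)
  desolv <- params$c_des * max(0, 1 - rel_sasa / 100)

  at <- model$atoms[model$atoms$type == "ATOM", , drop = FALSE]
  other <- !(at$chain == chain & at$resno == resno & at$insert == res$insert[1])
  dist_sg <- sqrt((at$x - sg[1])^2 + (at$y - sg[2])^2 + (at$z - sg[3])^2)

  donor_sel <- rep(FALSE, nrow(at))
  donor_sel[at$elety == "N" & at$resid != "PRO"] <- TRUE
  for (rn in names(.sidechain_donors))
    donor_sel[at$resid == rn & at$elety %in% .sidechain_donors[[rn]]] <- TRUE
  n_donors <- sum(donor_sel & other & dist_sg <= params$hb_cutoff)
  hbond <- params$hb_delta * n_donors

  coulomb <- 0
  cc <- .charge_centers(params$his_charged)
  grp <- at[other, , drop = FALSE]
  key <- unique(paste(grp$chain, grp$resno, grp$insert, grp$resid))
  for (k in key) {
    parts <- strsplit(k, " ")[[1]]
    rn <- parts[4]
    if (is.null(cc[[rn]])) next
    sel <- grp$chain == parts[1] & grp$resno == as.integer(parts[2]) &
      grp$insert == parts[3] & grp$elety %in% cc[[rn]]$atoms
    if (!any(sel)) next
    ctr <- colMeans(grp[sel, c("x", "y", "z"), drop = FALSE])
    d <- sqrt(sum((ctr - sg)^2))
    if (d <= params$coulomb_cutoff)
      coulomb <- coulomb + cc[[rn]]$q * params$coulomb_delta *
        (params$coulomb_cutoff - d) / params$coulomb_cutoff
  }
  c(desolvation = desolv, hbond = hbond, coulomb = coulomb)
}

#' Predict the pKa of a cysteine
#'
#' Empirical three-term model: `pKa = model_pka + desolvation + hbond +
#' coulomb` (see [pka_environment_terms()]). When another cysteine's Sgamma
#' lies within `sentinel_distance` (default 2.5 Angstrom) the thiol is
#' effectively disulfide-locked and its pKa is unphysical to predict: the
#' sentinel value 99.99 is returned with `is_unphysical = TRUE`, the
#' convention used for disulfide-engaged cysteines in pKa predictors. An
#' optional `delegate` function (`function(model, resno, chain)` returning a
#' numeric pKa) replaces the built-in model; its values, including a 99.99
#' sentinel, pass through verbatim.
#'
#' @inheritParams pka_environment_terms
#' @param delegate optional external predictor function.
#' @return list of class `sno_pka`: `value`, `is_unphysical`, `terms`.
#' @export
predict_cys_pka <- function(model, resno, chain = NULL, params = pka_params(),
                            rel_sasa = NULL, altloc = "", delegate = NULL) {
  params <- modifyList(pka_params(), params)
  res <- get_residue(model, resno, chain)
  if (is.null(res)) stop("residue not found: ", resno)
  if (res$resid[1] != "CYS") stop("not a cysteine: ", res$resid[1], resno)
  sg <- atom_coord(res, "SG", altloc)
  if (is.null(sg)) stop("incomplete residue: missing atom SG")
  chain <- res$chain[1]
  if (!is.null(delegate)) {
    v <- delegate(model, resno, chain)
    return(structure(list(value = v, is_unphysical = isTRUE(v == 99.99),
                          terms = c(desolvation = NA_real_, hbond = NA_real_,
                                    coulomb = NA_real_)),
                     class = "sno_pka"))
  }
  at <- model$atoms
  other_sg <- at$type == "ATOM" & at$resid == "CYS" & at$elety == "SG" &
    !(at$chain == chain & at$resno == resno & at$insert == res$insert[1])
  if (any(other_sg)) {
    d <- sqrt((at$x[other_sg] - sg[1])^2 + (at$y[other_sg] - sg[2])^2 +
                (at$z[other_sg] - sg[3])^2)
    if (any(d <= params$sentinel_distance))
      return(structure(list(value = 99.99, is_unphysical = TRUE,
                            terms = c(desolvation = NA_real_,
                                      hbond = NA_real_, coulomb = NA_real_)),
                       class = "sno_pka"))
  }
  terms <- pka_environment_terms(model, resno, chain, params = params,
                                 rel_sasa = rel_sasa, altloc = altloc)
  structure(list(value = params$model_pka + sum(terms),
                 is_unphysical = FALSE, terms = terms),
            class = "sno_pka")
}

#' @export
print.sno_pka <- function(x, ...) {
  if (x$is_unphysical) cat("<sno_pka> 99.99 (unphysical: disulfide-locked)\n")
  else cat(sprintf("<sno_pka> %.2f (des %.2f, hbond %.2f, coulomb %.2f)\n",
                   x$value, x$terms[1], x$terms[2], x$terms[3]))
  invisible(x)
}
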