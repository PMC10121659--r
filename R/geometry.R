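# Pair-geometry observables for candidate disulfides: Sgamma-Sgamma
# distance, chi1 of each cysteine with its rotamer state, the inter-residue
# CB-SG-SG-CB torsion, and an A-D stereochemical grade.

#' Signed torsion angle of four points
#'
#' IUPAC sign convention: looking from `p2` towards `p3`, a clockwise
#' rotation of the far bond is positive. Result in (-180, 180\] degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b2^2) < 1e-12 || sum(b1^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop("degenerate geometry: coincident points or zero bond")
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("degenerate geometry: collinear points")
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * b2 / sqrt(sum(b2^2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# gamma heavy atom used for chi1, by residue type
.gamma_atom <- function(resname) {
  switch(resname,
         CYS = "SG", SER = "OG", THR = "OG1", VAL = "CG1", ILE = "CG1",
         "CG")
}

#' chi1 torsion and rotamer state of a residue
#'
#' chi1 is the N-CA-CB-gamma torsion. Rotamer bins follow the standard
#' thirds of the circle: plus `p` on (0, 120\], minus `m` on (-120, 0\],
#' trans `t` elsewhere (|chi1| > 120).
#'
#' @param residue `sno_residue` atom table (see [get_residue()]).
#' @param altloc conformer label to resolve alternate locations.
#' @return list with `chi1` (degrees) and `rotamer` (`"t"`, `"m"` or `"p"`).
#' @export
chi1_and_rotamer <- function(residue, altloc = "") {
  g <- .gamma_atom(residue$resid[1])
  pts <- lapply(c("N", "CA", "CB", g), atom_coord, residue = residue,
                altloc = altloc)
  missing <- c("N", "CA", "CB", g)[vapply(pts, is.null, logical(1))]
  if (length(missing) > 0)
    stop("incomplete residue ", residue$resid[1], residue$resno[1],
         ": missing atom ", missing[1])
  chi1 <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  list(chi1 = chi1, rotamer = rotamer_state(chi1))
}

#' Rotamer bin for a chi1 value
#'
#' @param chi1 angle in degrees, any representation (wrapped internally).
#' @return `"p"`, `"m"` or `"t"`.
#' @export
rotamer_state <- function(chi1) {
  x <- ((chi1 + 180) %% 360) - 180
  ifelse(x > 0 & x <= 120, "p", ifelse(x > -120 & x <= 0, "m", "t"))
}

#' Disulfide pair geometry between two cysteines
#'
#' Computes, for every combination of alternate locations present on the two
#' Sgamma atoms, the Sgamma-Sgamma distance, chi1 of the SNO-site and the
#' partner cysteine with their rotamer states, the CB-SG-SG-CB torsion, and
#' the stereochemical grade. A blank altloc is one conformer in its own
#' right.
#'
#' @param model `sno_model`.
#' @param sno_resno,proxy_resno residue numbers of the SNO-site cysteine and
#'   the candidate partner.
#' @param chain optional chain identifier applied to both.
#' @param grade_params see [grade_disulfide()].
#' @return data.frame with one row per altloc combination: `altloc_sno`,
#'   `altloc_proxy`, `sg_sg_distance`, `chi1_sno`, `chi1_proxy`,
#'   `cb_sg_sg_cb`, `rotamer_sno`, `rotamer_proxy`, `grade`.
#' @export
pair_geometry <- function(model, sno_resno, proxy_resno, chain = NULL,
                          grade_params = list()) {
  if (identical(sno_resno, proxy_resno))
    stop("self-pair rejected: SNO and partner residue are identical")
  rs <- get_residue(model, sno_resno, chain)
  rp <- get_residue(model, proxy_resno, chain)
  if (is.null(rs) || is.null(rp))
    stop("residue not found in model: ",
         if (is.null(rs)) sno_resno else proxy_resno)
  for (r in list(rs, rp))
    if (r$resid[1] != "CYS")
      stop("not a cysteine: ", r$resid[1], r$resno[1])
  alts_s <- atom_altlocs(rs, "SG")
  alts_p <- atom_altlocs(rp, "SG")
  if (length(alts_s) == 0 || length(alts_p) == 0)
    stop("incomplete residue: missing atom SG in all altlocs")
  out <- list()
  for (as_ in alts_s) for (ap in alts_p) {
    sgs <- atom_coord(rs, "SG", as_); sgp <- atom_coord(rp, "SG", ap)
    cbs <- atom_coord(rs, "CB", as_); cbp <- atom_coord(rp, "CB", ap)
    if (is.null(cbs) || is.null(cbp))
      stop("incomplete residue: missing atom CB")
    cs <- chi1_and_rotamer(rs, as_); cp <- chi1_and_rotamer(rp, ap)
    row <- data.frame(
      altloc_sno = as_, altloc_proxy = ap,
      sg_sg_distance = sqrt(sum((sgs - sgp)^2)),
      chi1_sno = cs$chi1, chi1_proxy = cp$chi1,
      cb_sg_sg_cb = dihedral(cbs, sgs, sgp, cbp),
      rotamer_sno = cs$rotamer, rotamer_proxy = cp$rotamer,
      stringsAsFactors = FALSE)
    row$grade <- grade_disulfide(row, params = grade_params)
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}

#' Stereochemical grade of a candidate disulfide
#'
#' A four-letter quality scheme for potential S-S bridges, in the spirit of
#' disulfide-database stereochemistry classes: canonical disulfides have
#' sulfur-sulfur distances of 2.5 Angstrom or lower and CB-SG-SG-CB torsions
#' near +/-90 degrees.
#'
#' * `A` - distance within \[d_min, d_max\] and |torsion| within the window
#'   around 90 degrees, both chi1 rotamers relaxed (`m` or `t`);
#' * `B` - distance in range but torsion outside the window (distorted);
#' * `C` - sulfurs closer than `d_min` (too close for a disulfide);
#' * `D` - distance and torsion in range but a strained `p` chi1 rotamer;
#' * `none` - sulfurs farther apart than `d_max`.
#'
#' @param pg one-row data.frame (or list) with `sg_sg_distance`,
#'   `cb_sg_sg_cb`, `rotamer_sno`, `rotamer_proxy`.
#' @param params optional overrides: `d_min` (1.8), `d_max` (2.5),
#'   `dihedral_center` (90), `dihedral_window` (30).
#' @return character grade.
#' @export
grade_disulfide <- function(pg, params = list()) {
  p <- modifyList(list(d_min = 1.8, d_max = 2.5,
                       dihedral_center = 90, dihedral_window = 30), params)
  d <- pg$sg_sg_distance
  if (d > p$d_max) return("none")
  if (d < p$d_min) return("C")
  dih_ok <- abs(abs(pg$cb_sg_sg_cb) - p$dihedral_center) <= p$dihedral_window
  if (!dih_ok) return("B")
  if (pg$rotamer_sno == "p" || pg$rotamer_proxy == "p") return("D")
  "A"
}
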