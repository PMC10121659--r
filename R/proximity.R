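# Side-chain center-of-mass contact searches: candidate partner cysteines
# for SNO sites, sequence-based pair classification, and neighborhood
# selection for mutation analysis.

.atomic_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, H = 1.008)

#' Default contact-search parameters
#'
#' @return list: `com_cutoff` (8 Angstrom center-of-mass contact cutoff;
#'   11 Angstrom is the standard control value), `vicinal_max_sep`
#'   (8 residues, exclusive: pairs fewer than 8 residues apart in sequence
#'   are vicinal).
#' @export
contact_params <- function() {
  list(com_cutoff = 8.0, vicinal_max_sep = 8L)
}

#' Side-chain center of mass of a residue
#'
#' Mass-weighted center of the heavy side-chain atoms (beyond the alpha
#' carbon). Glycine - and any residue without side-chain heavy atoms -
#' has no center and yields `NULL`, mirroring contact-network conventions
#' that cannot represent glycines.
#'
#' @param residue `sno_residue` atom table.
#' @param altloc conformer label.
#' @return numeric 3-vector, or `NULL`.
#' @export
sidechain_com <- function(residue, altloc = "") {
  if (is.null(residue)) return(NULL)
  sel <- !(residue$elety %in% .backbone_names) & residue$elesy != "H" &
    (residue$alt == "" | residue$alt == altloc)
  sc <- residue[sel, , drop = FALSE]
  # prefer exact altloc rows over blank-label duplicates of the same atom
  if (any(sc$alt == altloc & altloc != "")) {
    dup <- sc$elety %in% sc$elety[sc$alt == altloc] & sc$alt == ""
    sc <- sc[!dup, , drop = FALSE]
  }
  if (nrow(sc) == 0) return(NULL)
  m <- .atomic_masses[sc$elesy]
  if (any(is.na(m))) m[is.na(m)] <- 12.011
  c(weighted.mean(sc$x, m), weighted.mean(sc$y, m), weighted.mean(sc$z, m))
}

# all side-chain COMs of a model: data.frame(chain, resno, insert, resid,
# alt, x, y, z); one row per altloc present on the side chain
.all_coms <- function(model, resnames = NULL) {
  rt <- residue_table(model)
  if (!is.null(resnames)) rt <- rt[rt$resid %in% resnames, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rt))) {
    res <- get_residue(model, rt$resno[i], rt$chain[i], rt$insert[i])
    alts <- unique(res$alt[!(res$elety %in% .backbone_names)])
    if (length(alts) == 0) next
    if (length(alts) > 1) alts <- setdiff(alts, "")
    for (a in alts) {
      com <- sidechain_com(res, a)
      if (is.null(com)) next
      out[[length(out) + 1]] <- data.frame(
        chain = rt$chain[i], resno = rt$resno[i], insert = rt$insert[i],
        resid = rt$resid[i], alt = a, x = com[1], y = com[2], z = com[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      alt = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  do.call(rbind, out)
}

#' Find candidate partner cysteines for an SNO site
#'
#' All cysteines (other than the site itself) whose side-chain center of
#' mass lies within `com_cutoff` of the SNO cysteine's side-chain center of
#' mass. With alternate locations, a pair qualifies when any altloc
#' combination is within the cutoff (inclusive), and the qualifying
#' combination is recorded.
#'
#' @param model `sno_model`.
#' @param sno_resno SNO-site residue number; `chain` optional.
#' @param chain chain id.
#' @param params see [contact_params()].
#' @return data.frame of partners: `chain`, `resno`, `insert`,
#'   `com_distance`, `altloc_sno`, `altloc_proxy`, `interchain`.
#' @export
find_partner_cys <- function(model, sno_resno, chain = NULL,
                             params = contact_params()) {
  params <- modifyList(contact_params(), params)
  res <- get_residue(model, sno_resno, chain)
  if (is.null(res)) stop("residue not found: ", sno_resno)
  if (res$resid[1] != "CYS") stop("not a cysteine: ", res$resid[1], sno_resno)
  chain <- res$chain[1]
  coms <- .all_coms(model, "CYS")
  self <- coms$chain == chain & coms$resno == sno_resno &
    coms$insert == res$insert[1]
  sno_coms <- coms[self, , drop = FALSE]
  others <- coms[!self, , drop = FALSE]
  hits <- list()
  for (k in unique(paste(others$chain, others$resno, others$insert))) {
    cand <- others[paste(others$chain, others$resno, others$insert) == k, ,
                   drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(sno_coms))) for (j in seq_len(nrow(cand))) {
      d <- sqrt(sum((c(sno_coms$x[i], sno_coms$y[i], sno_coms$z[i]) -
                       c(cand$x[j], cand$y[j], cand$z[j]))^2))
      if (d <= params$com_cutoff && (is.null(best) || d < best$d))
        best <- list(d = d, i = i, j = j)
    }
    if (!is.null(best)) {
      hits[[length(hits) + 1]] <- data.frame(
        chain = cand$chain[1], resno = cand$resno[1], insert = cand$insert[1],
        com_distance = best$d, altloc_sno = sno_coms$alt[best$i],
        altloc_proxy = cand$alt[best$j],
        interchain = cand$chain[1] != chain, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), com_distance = numeric(0),
                      altloc_sno = character(0), altloc_proxy = character(0),
                      interchain = logical(0)))
  out <- do.call(rbind, hits)
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Classify an SNO/partner cysteine pair by sequence separation
#'
#' Pairs fewer than `vicinal_max_sep` residues apart in sequence are
#' `vicinal` (CXXC-like motifs); pairs spatially close but at least that far
#' apart are `proximal`. Directly consecutive cysteines additionally carry
#' the `sequence_adjacent` flag. Pairs on different chains have no sequence
#' separation and are classified proximal with the `interchain` flag.
#'
#' @param sno_pos,partner_pos residue numbers.
#' @param params see [contact_params()].
#' @param same_chain are the two residues on one chain? (default `TRUE`).
#' @return list: `category` ("vicinal"/"proximal"), `sequence_adjacent`,
#'   `interchain`, `separation`.
#' @export
classify_pair_by_sequence <- function(sno_pos, partner_pos,
                                      params = contact_params(),
                                      same_chain = TRUE) {
  params <- modifyList(contact_params(), params)
  if (!same_chain)
    return(list(category = "proximal", sequence_adjacent = FALSE,
                interchain = TRUE, separation = NA_integer_))
  sep <- abs(sno_pos - partner_pos)
  list(category = if (sep < params$vicinal_max_sep) "vicinal" else "proximal",
       sequence_adjacent = sep == 1L, interchain = FALSE, separation = sep)
}

#' Residues in the side-chain contact neighborhood of a site
#'
#' All residues whose side-chain center of mass lies within `com_cutoff` of
#' the query residue's side-chain center of mass. Glycines have no
#' side-chain center and are never returned: mutation effects on glycines
#' cannot be assessed by this contact model.
#'
#' @param model `sno_model`.
#' @param resno query residue number; `chain` optional.
#' @param chain chain id.
#' @param params see [contact_params()].
#' @return data.frame `chain`, `resno`, `insert`, `resid`, `com_distance`.
#' @export
residues_near_site <- function(model, resno, chain = NULL,
                               params = contact_params()) {
  params <- modifyList(contact_params(), params)
  res <- get_residue(model, resno, chain)
  if (is.null(res)) stop("residue not found: ", resno)
  com0 <- sidechain_com(res)
  if (is.null(com0))
    stop("residue ", res$resid[1], resno,
         " has no side-chain center of mass (glycine?)")
  chain <- res$chain[1]
  coms <- .all_coms(model)
  self <- coms$chain == chain & coms$resno == resno &
    coms$insert == res$insert[1]
  coms <- coms[!self & coms$resid != "GLY", , drop = FALSE]
  d <- sqrt((coms$x - com0[1])^2 + (coms$y - com0[2])^2 +
              (coms$z - com0[3])^2)
  keep <- d <= params$com_cutoff
  out <- coms[keep, c("chain", "resno", "insert", "resid"), drop = FALSE]
  out$com_distance <- d[keep]
  out <- out[!duplicated(paste(out$chain, out$resno, out$insert)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
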