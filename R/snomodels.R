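# Ensemble pipeline: per-model pair metrics over multi-model structural
# ensembles, summary statistics with threshold fractions, histogram-based
# 1-D pseudo-free-energy profiles, the nine-class secondary-structure pair
# taxonomy, and cofactor-proximity flags.

#' Default ensemble-analysis parameters
#'
#' @return list: `distance_threshold` (6 Angstrom, the sulfur-sulfur
#'   distance below which a frame counts as disulfide-competent; strict
#'   `<`), `sasa_n_points` (240), `cofactor_cutoff` (4 Angstrom).
#' @export
snomodels_params <- function() {
  list(distance_threshold = 6.0, sasa_n_points = 240, cofactor_cutoff = 4.0)
}

#' Fraction of values below a threshold
#'
#' Strict comparison: a value exactly at the threshold counts in the upper
#' bin.
#'
#' @param values numeric vector (nonempty).
#' @param threshold numeric scalar.
#' @return fraction in \[0, 1\].
#' @export
fraction_below <- function(values, threshold) {
  if (length(values) == 0) stop("fraction undefined for empty input")
  mean(values < threshold)
}

# population standard deviation (ensembles are treated as the full
# population of sampled models, so a single model has sd 0)
.pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Per-model metrics and summary statistics for a cysteine pair
#'
#' For every model of the ensemble: Sgamma-Sgamma distance, chi1 of both
#' cysteines, CB-SG-SG-CB torsion, relative side-chain SASA and predicted
#' pKa of both residues (highest-occupancy altloc per model when alternate
#' locations exist). The summary holds mean and population standard
#' deviation per metric - pKa statistics over non-sentinel values only -
#' and the fraction of models with distance strictly below
#' `distance_threshold`.
#'
#' @param ensemble `sno_ensemble`.
#' @param sno_resno,proxy_resno cysteine residue numbers.
#' @param chain optional chain id.
#' @param params see [snomodels_params()].
#' @return object of class `sno_ensemble_summary`: `per_model` (data.frame),
#'   `summary` (data.frame metric/mean/sd), `fraction_below`,
#'   `distance_threshold`, `n_models`, `sno_resno`, `proxy_resno`.
#' @export
analyze_ensemble <- function(ensemble, sno_resno, proxy_resno, chain = NULL,
                             params = snomodels_params()) {
  params <- modifyList(snomodels_params(), params)
  stopifnot(inherits(ensemble, "sno_ensemble"))
  rows <- list()
  for (m in ensemble$models) {
    rs <- get_residue(m, sno_resno, chain)
    rp <- get_residue(m, proxy_resno, chain)
    if (is.null(rs) || is.null(rp))
      stop("residue not found in ensemble model: ",
           if (is.null(rs)) sno_resno else proxy_resno)
    for (r in list(rs, rp))
      if (r$resid[1] != "CYS") stop("not a cysteine: ", r$resid[1],
                                    r$resno[1])
    pick_alt <- function(res) {
      alts <- atom_altlocs(res, "SG")
      if (length(alts) <= 1) return(alts[1])
      occ <- vapply(alts, function(a)
        res$o[res$elety == "SG" & res$alt == a][1], numeric(1))
      alts[which.max(occ)]
    }
    as_ <- pick_alt(rs); ap <- pick_alt(rp)
    pg <- pair_geometry(m, sno_resno, proxy_resno, chain)
    pg <- pg[pg$altloc_sno == as_ & pg$altloc_proxy == ap, , drop = FALSE]
    sasa <- shrake_rupley(m, n_points = params$sasa_n_points)
    sasa_s <- relative_sidechain_sasa(m, sno_resno, rs$chain[1], sasa = sasa)
    sasa_p <- relative_sidechain_sasa(m, proxy_resno, rp$chain[1],
                                      sasa = sasa)
    pk_s <- predict_cys_pka(m, sno_resno, rs$chain[1], rel_sasa = sasa_s,
                            altloc = as_)
    pk_p <- predict_cys_pka(m, proxy_resno, rp$chain[1], rel_sasa = sasa_p,
                            altloc = ap)
    rows[[length(rows) + 1]] <- data.frame(
      model_id = m$model_id, sg_sg_distance = pg$sg_sg_distance,
      chi1_sno = pg$chi1_sno, chi1_proxy = pg$chi1_proxy,
      cb_sg_sg_cb = pg$cb_sg_sg_cb, rotamer_sno = pg$rotamer_sno,
      rotamer_proxy = pg$rotamer_proxy, rel_sasa_sno = sasa_s,
      rel_sasa_proxy = sasa_p, pka_sno = pk_s$value,
      pka_sno_unphysical = pk_s$is_unphysical, pka_proxy = pk_p$value,
      pka_proxy_unphysical = pk_p$is_unphysical, stringsAsFactors = FALSE)
  }
  per_model <- do.call(rbind, rows)
  new_ensemble_summary(per_model, params$distance_threshold,
                       sno_resno, proxy_resno)
}

#' Assemble an ensemble summary from a per-model metric table
#'
#' Computes the mean / population-sd summary block and the threshold
#' fraction from per-model rows. Sentinel (99.99) pKa values are excluded
#' from the pKa statistics; when every model is sentinel the pKa mean is
#' `NA`. Exposed so that metric tables from external tools - or synthetic
#' tables with known moments - can reuse the summary and classification
#' machinery.
#'
#' @param per_model data.frame with at least `sg_sg_distance`, `pka_sno`,
#'   `pka_proxy` columns (sentinel flags optional, inferred from 99.99).
#' @param distance_threshold Angstrom, strict `<` fraction.
#' @param sno_resno,proxy_resno bookkeeping labels.
#' @return `sno_ensemble_summary`.
#' @export
new_ensemble_summary <- function(per_model, distance_threshold = 6.0,
                                 sno_resno = NA, proxy_resno = NA) {
  if (is.null(per_model$pka_sno_unphysical))
    per_model$pka_sno_unphysical <- per_model$pka_sno == 99.99
  if (is.null(per_model$pka_proxy_unphysical))
    per_model$pka_proxy_unphysical <- per_model$pka_proxy == 99.99
  num <- intersect(c("sg_sg_distance", "chi1_sno", "chi1_proxy",
                     "cb_sg_sg_cb", "rel_sasa_sno", "rel_sasa_proxy",
                     "pka_sno", "pka_proxy"), names(per_model))
  stats <- lapply(num, function(v) {
    x <- per_model[[v]]
    if (v == "pka_sno") x <- x[!per_model$pka_sno_unphysical]
    if (v == "pka_proxy") x <- x[!per_model$pka_proxy_unphysical]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    c(mean(x), .pop_sd(x))
  })
  summary <- data.frame(metric = num,
                        mean = vapply(stats, `[`, numeric(1), 1),
                        sd = vapply(stats, `[`, numeric(1), 2),
                        stringsAsFactors = FALSE)
  structure(list(per_model = per_model, summary = summary,
                 fraction_below = fraction_below(per_model$sg_sg_distance,
                                                 distance_threshold),
                 distance_threshold = distance_threshold,
                 n_models = nrow(per_model), sno_resno = sno_resno,
                 proxy_resno = proxy_resno),
            class = "sno_ensemble_summary")
}

#' @export
print.sno_ensemble_summary <- function(x, ...) {
  cat("<sno_ensemble_summary>", x$n_models, "model(s), pair",
      x$sno_resno, "/", x$proxy_resno, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  fraction(Sg-Sg < %.1f A) = %.3f\n", x$distance_threshold,
              x$fraction_below))
  invisible(x)
}

# mean of a metric from a summary object
.summary_mean <- function(s, metric) {
  s$summary$mean[s$summary$metric == metric]
}

#' One-dimensional pseudo-free-energy profile from samples
#'
#' Histogram estimate `F_i = -RT ln(p_i)` (kcal/mol,
#' R = 1.9872e-3 kcal/(mol K)) over `n_bins` equal-width bins spanning the
#' sample range, shifted so the minimum is 0. Empty bins have undefined
#' (NA) free energy, not zero. This is a population estimate from an
#' ensemble or trajectory sample, not a biased-sampling reconstruction.
#'
#' @param samples numeric vector (nonempty).
#' @param n_bins number of bins (>= 2).
#' @param temperature_K temperature in Kelvin (default 298).
#' @return data.frame `bin_mid`, `count`, `probability`, `free_energy`.
#' @export
pmf_1d <- function(samples, n_bins, temperature_K = 298) {
  if (length(samples) == 0) stop("empty sample")
  if (n_bins < 2) stop("n_bins must be >= 2")
  RT <- 1.9872e-3 * temperature_K
  rng <- range(samples)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(samples, breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  count <- tabulate(idx, n_bins)
  p <- count / length(samples)
  fe <- ifelse(count > 0, -RT * log(p), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  data.frame(bin_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
             count = count, probability = p, free_energy = fe)
}

#' Nine-class secondary-structure pair label
#'
#' Ordered label of the secondary-structure elements carrying the SNO site
#' (first) and the proximal cysteine (second): helix/strand/loop crossed
#' with itself.
#'
#' @param ss_sno,ss_proxy one of `"H"`, `"E"`, `"C"`.
#' @return character label, e.g. `"strand-helix"`.
#' @export
classify_pair_ss <- function(ss_sno, ss_proxy) {
  lab <- c(H = "helix", E = "strand", C = "loop")
  if (!ss_sno %in% names(lab) || !ss_proxy %in% names(lab))
    stop("secondary-structure symbols must be H, E or C")
  paste(lab[[ss_sno]], lab[[ss_proxy]], sep = "-")
}

#' Flag cofactor proximity of a cysteine
#'
#' TRUE when any non-water HETATM atom lies within `cutoff` of the
#' residue's Sgamma. Coarse-grained ensemble analyses cannot model
#' cofactors, so pairs near ligands or metal ions (zinc sites in
#' particular) deserve a warning flag.
#'
#' @param model `sno_model`.
#' @param resno cysteine residue number; `chain` optional.
#' @param chain chain id.
#' @param cutoff Angstrom (default 4).
#' @return list: `flag`, `nearest_ligand` (resid or `NA`),
#'   `nearest_distance`.
#' @export
cofactor_proximity_flag <- function(model, resno, chain = NULL,
                                    cutoff = 4.0) {
  res <- get_residue(model, resno, chain)
  if (is.null(res)) stop("residue not found: ", resno)
  sg <- atom_coord(res, "SG")
  if (is.null(sg)) sg <- sidechain_com(res)
  if (is.null(sg)) stop("no side-chain reference point for residue ", resno)
  lig <- ligand_atoms(model)
  if (nrow(lig) == 0)
    return(list(flag = FALSE, nearest_ligand = NA_character_,
                nearest_distance = NA_real_))
  d <- sqrt((lig$x - sg[1])^2 + (lig$y - sg[2])^2 + (lig$z - sg[3])^2)
  i <- which.min(d)
  list(flag = d[i] <= cutoff, nearest_ligand = lig$resid[i],
       nearest_distance = d[i])
}
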