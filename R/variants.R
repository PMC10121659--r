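# Variant-effect classification for the SNO-induced disulfide
# population-shift mechanism: compare a mutant ensemble's pair metrics to
# the wild type and call the variant stabilizing, neutral, destabilizing
# or uncertain.

#' Default variant-classification thresholds
#'
#' @return list: `tol_pka` (0.5 pKa units: changes within this are
#'   "similar"), `tol_distance` (0.5 Angstrom), `large_pka` (2.0 pKa
#'   units: increases at least this large are destabilizing on their own).
#'   The thresholds sit at roughly the sampling noise of ensemble means
#'   and are deliberately explicit - the underlying notion of "similar"
#'   and "large" changes is qualitative.
#' @export
variant_params <- function() {
  list(tol_pka = 0.5, tol_distance = 0.5, large_pka = 2.0)
}

#' Classify a variant's effect on the SNO population-shift mechanism
#'
#' With `dp` = mean SNO-site pKa (mutant - wild type) and `dd` = mean
#' Sgamma-Sgamma distance (mutant - wild type), both over ensemble means:
#'
#' * `dp >= large_pka` - destabilizing (a large pKa increase alone
#'   impairs the mechanism);
#' * `|dp| <= tol_pka` and `|dd| <= tol_distance` - neutral;
#' * `dp < -tol_pka` and `dd < -tol_distance` - stabilizing (more
#'   reactive thiol and shorter approach);
#' * `dp > tol_pka` and `dd > tol_distance` - destabilizing;
#' * anything else - uncertain (discordant or borderline changes).
#'
#' Ensembles whose SNO-site pKa is sentinel (99.99) in every model carry no
#' usable pKa mean and are classified uncertain with a reason.
#'
#' @param wt,mut `sno_ensemble_summary` objects for the same cysteine pair.
#' @param params see [variant_params()].
#' @return list of class `sno_variant_effect`: `label`, `delta_pka`,
#'   `delta_distance`, `reason` (NA unless uncertain by degeneracy).
#' @export
classify_variant_effect <- function(wt, mut, params = variant_params()) {
  params <- modifyList(variant_params(), params)
  stopifnot(inherits(wt, "sno_ensemble_summary"),
            inherits(mut, "sno_ensemble_summary"))
  pk_wt <- .summary_mean(wt, "pka_sno")
  pk_mut <- .summary_mean(mut, "pka_sno")
  d_wt <- .summary_mean(wt, "sg_sg_distance")
  d_mut <- .summary_mean(mut, "sg_sg_distance")
  if (length(pk_wt) == 0 || is.na(pk_wt) || length(pk_mut) == 0 ||
      is.na(pk_mut)) {
    return(structure(list(label = "uncertain", delta_pka = NA_real_,
                          delta_distance = d_mut - d_wt,
                          reason = "sentinel-only pKa"),
                     class = "sno_variant_effect"))
  }
  dp <- pk_mut - pk_wt
  dd <- d_mut - d_wt
  label <- if (dp >= params$large_pka) "destabilizing"
  else if (abs(dp) <= params$tol_pka && abs(dd) <= params$tol_distance)
    "neutral"
  else if (dp < -params$tol_pka && dd < -params$tol_distance) "stabilizing"
  else if (dp > params$tol_pka && dd > params$tol_distance) "destabilizing"
  else "uncertain"
  structure(list(label = label, delta_pka = dp, delta_distance = dd,
                 reason = NA_character_), class = "sno_variant_effect")
}

#' @export
print.sno_variant_effect <- function(x, ...) {
  cat(sprintf("<sno_variant_effect> %s (dpKa %+.2f, ddist %+.2f A)\n",
              x$label, x$delta_pka, x$delta_distance))
  invisible(x)
}

#' Parse a mutation token
#'
#' One substitution per token, `<WT-aa><position><mut-aa>` (e.g. "N235H").
#'
#' @param token character scalar.
#' @return list `wt_aa`, `position`, `mut_aa`.
#' @export
parse_mutation <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$",
                                 trimws(token)))[[1]]
  if (length(m) != 4) stop("malformed mutation token: ", token)
  list(wt_aa = toupper(m[2]), position = as.integer(m[3]),
       mut_aa = toupper(m[4]))
}

#' Run the variant pipeline over a directory of mutant ensembles
#'
#' Reads the wild-type ensemble and one multi-model PDB per mutation
#' (`<mutation>.pdb` in `mut_dir`), summarizes each with
#' [analyze_ensemble()] for the given cysteine pair, and classifies every
#' variant against the wild type. Mutations whose residue is not in the
#' contact neighborhood of either cysteine can be pre-filtered with
#' [residues_near_site()]; this function classifies whatever list it is
#' given.
#'
#' @param wt_path wild-type ensemble PDB (or an `sno_ensemble`).
#' @param mut_dir directory with `<mutation>.pdb` ensembles.
#' @param mutations character vector of tokens (or a file path, one per
#'   line).
#' @param sno_resno,proxy_resno cysteine pair.
#' @param params see [snomodels_params()]; `variant` sub-list forwarded to
#'   [classify_variant_effect()].
#' @return data.frame: `mutation`, `delta_pka`, `delta_distance`, `label`,
#'   `reason`.
#' @export
run_variant_pipeline <- function(wt_path, mut_dir, mutations, sno_resno,
                                 proxy_resno, params = snomodels_params()) {
  if (length(mutations) == 1 && file.exists(mutations))
    mutations <- readLines(mutations, warn = FALSE)
  mutations <- trimws(mutations)
  mutations <- mutations[nzchar(mutations)]
  wt_ens <- if (inherits(wt_path, "sno_ensemble")) wt_path
  else read_structure(wt_path)
  wt <- analyze_ensemble(wt_ens, sno_resno, proxy_resno, params = params)
  vparams <- if (is.null(params$variant)) variant_params() else params$variant
  out <- list()
  for (tok in mutations) {
    parse_mutation(tok) # validates the token
    path <- file.path(mut_dir, paste0(tok, ".pdb"))
    if (!file.exists(path)) {
      warning("no ensemble for mutation ", tok, call. = FALSE)
      next
    }
    mut <- analyze_ensemble(read_structure(path), sno_resno, proxy_resno,
                            params = params)
    eff <- classify_variant_effect(wt, mut, vparams)
    out[[length(out) + 1]] <- data.frame(
      mutation = tok, delta_pka = eff$delta_pka,
      delta_distance = eff$delta_distance, label = eff$label,
      reason = eff$reason, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(mutation = character(0), delta_pka = numeric(0),
                      delta_distance = numeric(0), label = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
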