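# Site-discovery pipeline: from a PTM-site table and a directory of
# structure models to annotated vicinal/proximal cysteine-pair tables with
# bookkeeping of missing models, non-cysteine sites and out-of-range
# positions.

#' Default site-discovery parameters
#'
#' @return list combining [contact_params()] with `sasa_min` (10 percent:
#'   sites whose side chain has at least this relative solvent accessibility
#'   pass the accessibility filter), `plddt_threshold` (50) and
#'   `disorder_min_len` (20 residues: sites inside low-confidence segments
#'   at least this long are flagged as disordered), `sasa_n_points` (SASA
#'   point count, 240 for pipeline throughput).
#' @export
snofinder_params <- function() {
  c(contact_params(),
    list(sasa_min = 10, plddt_threshold = 50, disorder_min_len = 20,
         sasa_n_points = 240))
}

#' Read a PTM-site table
#'
#' Tab-separated, with at least accession, position and PTM-type columns.
#' A header row naming `accession`/`position` is honored; otherwise the
#' first three columns are taken as (accession, position, ptm_type), and
#' extra columns are ignored. Rows with unparseable positions are dropped
#' with a warning.
#'
#' @param path TSV file path.
#' @return data.frame `accession`, `position`, `ptm_type`.
#' @export
read_sno_sites <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("accession|position", first, ignore.case = TRUE)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    names(df) <- tolower(names(df))
    need <- c("accession", "position")
    if (!all(need %in% names(df)))
      stop("site table header lacks accession/position columns")
    if (is.null(df$ptm_type)) df$ptm_type <- NA_character_
  } else {
    if (ncol(df) < 2) stop("site table needs at least two columns")
    df <- df[, seq_len(min(3, ncol(df)))]
    names(df) <- c("accession", "position", "ptm_type")[seq_len(ncol(df))]
    if (is.null(df$ptm_type)) df$ptm_type <- NA_character_
  }
  pos <- suppressWarnings(as.integer(df$position))
  bad <- is.na(pos)
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with unparseable positions")
    df <- df[!bad, , drop = FALSE]
    pos <- pos[!bad]
  }
  data.frame(accession = as.character(df$accession), position = pos,
             ptm_type = as.character(df$ptm_type), stringsAsFactors = FALSE)
}

# locate <dir>/<acc>.pdb or an AlphaFold-style AF-<acc>-F1-model*.pdb
.find_model_file <- function(model_dir, accession) {
  p <- file.path(model_dir, paste0(accession, ".pdb"))
  if (file.exists(p)) return(p)
  g <- Sys.glob(file.path(model_dir,
                          paste0("AF-", accession, "-F1-model*.pdb")))
  if (length(g) > 0) return(g[1])
  NA_character_
}

.empty_pairs <- function() {
  data.frame(accession = character(0), sno_pos = integer(0),
             partner_pos = integer(0), category = character(0),
             sequence_adjacent = logical(0), interchain = logical(0),
             com_distance = numeric(0), altloc_sno = character(0),
             altloc_proxy = character(0), sg_sg_distance = numeric(0),
             chi1_sno = numeric(0), chi1_proxy = numeric(0),
             cb_sg_sg_cb = numeric(0), rotamer_sno = character(0),
             rotamer_proxy = character(0), grade = character(0),
             rel_sasa_sno = numeric(0), rel_sasa_proxy = numeric(0),
             ss_sno = character(0), ss_proxy = character(0),
             plddt_sno = numeric(0), plddt_proxy = numeric(0),
             pka_sno = numeric(0), pka_sno_unphysical = logical(0),
             pka_proxy = numeric(0), pka_proxy_unphysical = logical(0),
             disordered_region = logical(0), stringsAsFactors = FALSE)
}

#' Run the site-discovery pipeline
#'
#' For every site: locate the model (`n_missing_model` when absent), check
#' the position exists (`n_out_of_range`) and is a cysteine
#' (`n_not_cysteine`), find partner cysteines by side-chain
#' center-of-mass contact, and annotate every (site, partner, altloc
#' combination) row with pair geometry and grade, relative side-chain
#' SASA, secondary structure, per-residue confidence (pLDDT) and predicted
#' pKa (99.99 sentinel rows are retained and flagged). Pairs are split into
#' vicinal and proximal by sequence separation; the filtered table keeps
#' pairs whose SNO site has relative SASA of at least `sasa_min` percent.
#' Sites inside long low-confidence segments are flagged
#' `disordered_region` (rows retained, so the discard policy stays with the
#' caller).
#'
#' @param sites data.frame from [read_sno_sites()], or a path to a TSV.
#' @param model_dir directory of PDB models named `<accession>.pdb` (or
#'   AlphaFold-style `AF-<accession>-F1-model*.pdb`).
#' @param params see [snofinder_params()].
#' @return list of class `snofinder_result`: `pairs_all`, `pairs_vicinal`,
#'   `pairs_proximal`, `pairs_filtered` (data.frames), `bookkeeping`
#'   (named counts satisfying n_input_sites = n_missing_model +
#'   n_not_cysteine + n_out_of_range + n_analyzed).
#' @export
run_snofinder <- function(sites, model_dir, params = snofinder_params()) {
  params <- modifyList(snofinder_params(), params)
  if (is.character(sites)) sites <- read_sno_sites(sites)
  bk <- c(n_input_sites = nrow(sites), n_missing_model = 0L,
          n_not_cysteine = 0L, n_out_of_range = 0L, n_analyzed = 0L,
          n_with_partner = 0L, n_pass_sasa = 0L)
  rows <- list()
  model_cache <- new.env(parent = emptyenv())
  for (s in seq_len(nrow(sites))) {
    acc <- sites$accession[s]; pos <- sites$position[s]
    path <- .find_model_file(model_dir, acc)
    if (is.na(path)) {
      bk["n_missing_model"] <- bk["n_missing_model"] + 1L
      warning("no model file for ", acc, call. = FALSE)
      next
    }
    ctx <- model_cache[[acc]]
    if (is.null(ctx)) {
      model <- read_structure(path)$models[[1]]
      ctx <- list(model = model,
                  sasa = shrake_rupley(model,
                                       n_points = params$sasa_n_points),
                  ss = assign_ss3(model), plddt = plddt_profile(model))
      model_cache[[acc]] <- ctx
    }
    res <- get_residue(ctx$model, pos)
    if (is.null(res)) {
      bk["n_out_of_range"] <- bk["n_out_of_range"] + 1L
      warning(acc, " position ", pos, " not in model", call. = FALSE)
      next
    }
    if (res$resid[1] != "CYS") {
      bk["n_not_cysteine"] <- bk["n_not_cysteine"] + 1L
      warning(acc, " position ", pos, " is ", res$resid[1],
              ", not CYS", call. = FALSE)
      next
    }
    bk["n_analyzed"] <- bk["n_analyzed"] + 1L
    partners <- find_partner_cys(ctx$model, pos, params = params)
    if (nrow(partners) == 0) next
    bk["n_with_partner"] <- bk["n_with_partner"] + 1L
    trim <- trim_low_confidence(ctx$model, params$plddt_threshold,
                                params$disorder_min_len, sites = pos)
    disordered <- unname(trim$disqualified[as.character(pos)])
    sasa_sno <- relative_sidechain_sasa(ctx$model, pos, sasa = ctx$sasa)
    ann_res <- function(rt, p) rt[rt$resno == p, , drop = FALSE][1, ]
    for (q in seq_len(nrow(partners))) {
      ppos <- partners$resno[q]
      pg <- pair_geometry(ctx$model, pos, ppos)
      cls <- classify_pair_by_sequence(pos, ppos, params,
                                       same_chain = !partners$interchain[q])
      sasa_proxy <- relative_sidechain_sasa(ctx$model, ppos,
                                            sasa = ctx$sasa)
      pka_s <- predict_cys_pka(ctx$model, pos, rel_sasa = sasa_sno)
      pka_p <- predict_cys_pka(ctx$model, ppos, rel_sasa = sasa_proxy)
      for (g in seq_len(nrow(pg))) {
        rows[[length(rows) + 1]] <- data.frame(
          accession = acc, sno_pos = pos, partner_pos = ppos,
          category = cls$category, sequence_adjacent = cls$sequence_adjacent,
          interchain = cls$interchain,
          com_distance = partners$com_distance[q],
          altloc_sno = pg$altloc_sno[g], altloc_proxy = pg$altloc_proxy[g],
          sg_sg_distance = pg$sg_sg_distance[g], chi1_sno = pg$chi1_sno[g],
          chi1_proxy = pg$chi1_proxy[g], cb_sg_sg_cb = pg$cb_sg_sg_cb[g],
          rotamer_sno = pg$rotamer_sno[g],
          rotamer_proxy = pg$rotamer_proxy[g], grade = pg$grade[g],
          rel_sasa_sno = sasa_sno, rel_sasa_proxy = sasa_proxy,
          ss_sno = ann_res(ctx$ss, pos)$ss, ss_proxy = ann_res(ctx$ss, ppos)$ss,
          plddt_sno = ann_res(ctx$plddt, pos)$confidence,
          plddt_proxy = ann_res(ctx$plddt, ppos)$confidence,
          pka_sno = pka_s$value, pka_sno_unphysical = pka_s$is_unphysical,
          pka_proxy = pka_p$value,
          pka_proxy_unphysical = pka_p$is_unphysical,
          disordered_region = disordered, stringsAsFactors = FALSE)
      }
    }
  }
  pairs_all <- if (length(rows) > 0) do.call(rbind, rows) else .empty_pairs()
  rownames(pairs_all) <- NULL
  bk["n_pass_sasa"] <- length(unique(pairs_all$accession[
    pairs_all$rel_sasa_sno >= params$sasa_min]))
  structure(list(
    pairs_all = pairs_all,
    pairs_vicinal = pairs_all[pairs_all$category == "vicinal", , drop = FALSE],
    pairs_proximal = pairs_all[pairs_all$category == "proximal", ,
                               drop = FALSE],
    pairs_filtered = pairs_all[pairs_all$rel_sasa_sno >= params$sasa_min, ,
                               drop = FALSE],
    bookkeeping = bk, params = params), class = "snofinder_result")
}

#' @export
print.snofinder_result <- function(x, ...) {
  cat("<snofinder_result>\n")
  cat("  sites:", x$bookkeeping["n_input_sites"],
      "(analyzed", x$bookkeeping["n_analyzed"], ")\n")
  cat("  pairs:", nrow(x$pairs_all), "- vicinal", nrow(x$pairs_vicinal),
      "/ proximal", nrow(x$pairs_proximal), "/ SASA-filtered",
      nrow(x$pairs_filtered), "\n")
  invisible(x)
}

#' Per-protein summary of a discovery run
#'
#' Rolls the pair tables up to proteins: how many have at least one
#' partnered site, how many have only vicinal, only proximal, or both kinds
#' of pairs, and how many carry a single versus multiple SNO sites.
#'
#' @param result `snofinder_result`.
#' @return list of counts: `n_proteins_with_partner`, `n_vicinal_only`,
#'   `n_proximal_only`, `n_both`, `n_single_sno`, `n_multi_sno`.
#' @export
summarize_dataset <- function(result) {
  pa <- result$pairs_all
  if (nrow(pa) == 0)
    return(list(n_proteins_with_partner = 0L, n_vicinal_only = 0L,
                n_proximal_only = 0L, n_both = 0L, n_single_sno = 0L,
                n_multi_sno = 0L))
  acc <- unique(pa$accession)
  has_vic <- vapply(acc, function(a)
    any(pa$category[pa$accession == a] == "vicinal"), logical(1))
  has_prox <- vapply(acc, function(a)
    any(pa$category[pa$accession == a] == "proximal"), logical(1))
  n_sites <- vapply(acc, function(a)
    length(unique(pa$sno_pos[pa$accession == a])), integer(1))
  list(n_proteins_with_partner = length(acc),
       n_vicinal_only = sum(has_vic & !has_prox),
       n_proximal_only = sum(!has_vic & has_prox),
       n_both = sum(has_vic & has_prox),
       n_single_sno = sum(n_sites == 1L),
       n_multi_sno = sum(n_sites > 1L))
}

#' Write discovery-run outputs to a directory
#'
#' Writes `pairs_all.csv`, `pairs_vicinal.csv`, `pairs_proximal.csv`,
#' `pairs_filtered.csv` and `bookkeeping.json`.
#'
#' @param result `snofinder_result`.
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_snofinder_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("pairs_all", "pairs_vicinal", "pairs_proximal",
               "pairs_filtered"))
    write.csv(result[[nm]], file.path(outdir, paste0(nm, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(as.list(result$bookkeeping),
                       file.path(outdir, "bookkeeping.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}
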