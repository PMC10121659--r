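# Structure input/output and the atomic data model.
#
# A `sno_model` holds one set of atomic coordinates as a data.frame in
# bio3d column convention (type, eleno, elety, alt, resid, chain, resno,
# insert, x, y, z, o, b, elesy). Blank altloc / insertion codes are stored
# as "". The B-factor column carries pLDDT for AlphaFold-style models.
# A `sno_ensemble` is an ordered list of models sharing residue topology.

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame in bio3d atom-table convention; minimally
#'   `type`, `elety`, `resid`, `chain`, `resno`, `x`, `y`, `z`. Missing
#'   optional columns (`alt`, `insert`, `o`, `b`, `elesy`, `eleno`) are
#'   filled with defaults. Occupancies outside \[0, 1\] are clamped with a
#'   warning; non-finite coordinates are an error.
#' @param model_id integer model identifier (MODEL record number).
#' @param source optional path the model was read from.
#' @return An object of class `sno_model`.
#' @export
sno_model <- function(atoms, model_id = 1L, source = NA_character_) {
  stopifnot(is.data.frame(atoms))
  need <- c("type", "elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks required column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- .guess_element(atoms$elety)
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- "A"
  bad_o <- !is.na(atoms$o) & (atoms$o < 0 | atoms$o > 1)
  if (any(bad_o)) {
    warning("clamping ", sum(bad_o), " occupancy value(s) to [0, 1]")
    atoms$o <- pmin(pmax(atoms$o, 0), 1)
  }
  key <- paste(atoms$type, atoms$chain, atoms$resno, atoms$insert,
               atoms$elety, atoms$alt)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue/altloc: ",
         key[duplicated(key)][1])
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 source = source),
            class = "sno_model")
}

#' Construct a structural ensemble from a list of models
#'
#' All models must share residue topology: the same ordered
#' (chain, resseq, resname) sequence. The first mismatching residue is
#' named in the error.
#'
#' @param models list of `sno_model` objects (length >= 1).
#' @param source optional path.
#' @return An object of class `sno_ensemble`.
#' @export
sno_ensemble <- function(models, source = NA_character_) {
  stopifnot(length(models) >= 1)
  lapply(models, function(m) stopifnot(inherits(m, "sno_model")))
  ref <- residue_table(models[[1]])
  ref_key <- paste(ref$chain, ref$resno, ref$resid)
  for (k in seq_along(models)[-1]) {
    cur <- residue_table(models[[k]])
    cur_key <- paste(cur$chain, cur$resno, cur$resid)
    if (length(cur_key) != length(ref_key) || any(cur_key != ref_key)) {
      n <- min(length(cur_key), length(ref_key))
      i <- which(cur_key[seq_len(n)] != ref_key[seq_len(n)])[1]
      if (is.na(i)) i <- n + 1L
      bad <- if (i <= length(cur_key)) cur_key[i] else "(missing residue)"
      stop("inconsistent topology across models: model ", models[[k]]$model_id,
           " differs at residue ", bad)
    }
  }
  structure(list(models = models, source = source), class = "sno_ensemble")
}

#' @export
print.sno_model <- function(x, ...) {
  rt <- residue_table(x)
  cat("<sno_model> model", x$model_id, "-", nrow(x$atoms), "atoms,",
      nrow(rt), "polymer residues\n")
  invisible(x)
}

#' @export
print.sno_ensemble <- function(x, ...) {
  cat("<sno_ensemble>", length(x$models), "model(s);",
      nrow(residue_table(x$models[[1]])), "polymer residues\n")
  invisible(x)
}

#' @export
length.sno_ensemble <- function(x) length(x$models)

.guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  substr(e, 1, 1)
}

#' Read a structure file into an ensemble
#'
#' Every MODEL record becomes one model; single-model files yield an
#' ensemble of size 1. Alternate-location atoms are preserved, never
#' collapsed. HETATM records are kept on the atom table with
#' `type == "HETATM"`; waters are dropped at analysis time, not at parse
#' time. Parsing is delegated to \pkg{bio3d}.
#'
#' @param path PDB file path.
#' @param format only `"pdb"` is supported.
#' @return `sno_ensemble`.
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_model <- startsWith(lines, "MODEL")
  blocks <- if (any(is_model)) {
    starts <- which(is_model)
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
  } else list(lines)
  models <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    blk <- blocks[[k]]
    if (!any(startsWith(blk, "ATOM")))
      stop("no ATOM records in ", path,
           if (length(blocks) > 1) paste0(" (model block ", k, ")") else "")
    tf <- tempfile(fileext = ".pdb")
    writeLines(blk[!startsWith(blk, "MODEL") & !startsWith(blk, "ENDMDL")], tf)
    p <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE,
                                          rm.insert = FALSE, verbose = FALSE))
    unlink(tf)
    at <- p$atom[, c("type", "eleno", "elety", "alt", "resid", "chain",
                     "resno", "insert", "x", "y", "z", "o", "b", "elesy")]
    at$o[is.na(at$o)] <- 1
    at$b[is.na(at$b)] <- 0
    models[[k]] <- sno_model(at, model_id = k, source = path)
  }
  sno_ensemble(models, source = path)
}

#' Write a model or ensemble to a PDB file
#'
#' Ensembles of size > 1 are written as multi-MODEL files. Coordinates are
#' kept to PDB precision (3 decimals); altloc labels and occupancies are
#' preserved.
#'
#' @param x `sno_model` or `sno_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "sno_model")) x <- sno_ensemble(list(x))
  stopifnot(inherits(x, "sno_ensemble"))
  at <- x$models[[1]]$atoms
  xyz <- do.call(rbind, lapply(x$models, function(m)
    as.vector(t(as.matrix(m$atoms[, c("x", "y", "z")])))))
  alt <- at$alt; alt[alt == ""] <- NA
  ins <- at$insert; ins[ins == ""] <- NA
  bio3d::write.pdb(file = path, xyz = xyz, type = at$type, resno = at$resno,
                   resid = at$resid, eleno = at$eleno, elety = at$elety,
                   chain = at$chain, insert = ins, alt = alt, o = at$o,
                   b = at$b, elesy = at$elesy)
  invisible(path)
}

#' Table of polymer residues of a model
#'
#' One row per (chain, resseq, icode) in file order, with the 3-letter
#' residue name. HETATM records are excluded.
#'
#' @param model `sno_model`.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`.
#' @export
residue_table <- function(model) {
  at <- model$atoms
  at <- at[at$type == "ATOM", , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert)
  idx <- !duplicated(key)
  data.frame(chain = at$chain[idx], resno = at$resno[idx],
             insert = at$insert[idx], resid = at$resid[idx],
             stringsAsFactors = FALSE)
}

#' Extract one residue's atom table
#'
#' @param model `sno_model`.
#' @param resno author residue number.
#' @param chain chain identifier; default the first chain carrying `resno`.
#' @param insert insertion code (default blank).
#' @return data.frame of the residue's atoms (class `sno_residue`), or
#'   `NULL` when the residue does not exist.
#' @export
get_residue <- function(model, resno, chain = NULL, insert = "") {
  at <- model$atoms
  sel <- at$type == "ATOM" & at$resno == resno & at$insert == insert
  if (!is.null(chain)) sel <- sel & at$chain == chain
  if (!any(sel)) return(NULL)
  if (is.null(chain)) {
    ch <- at$chain[sel][1]
    sel <- sel & at$chain == ch
  }
  res <- at[sel, , drop = FALSE]
  class(res) <- c("sno_residue", class(res))
  res
}

# Coordinate of a named atom in a residue, honoring altloc: an atom stored
# with blank altloc serves every conformer; otherwise the matching label is
# required. Returns NULL when absent.
atom_coord <- function(residue, name, altloc = "") {
  sel <- residue$elety == name & (residue$alt == "" | residue$alt == altloc)
  if (!any(sel)) return(NULL)
  # prefer the exact altloc match over a blank-label atom
  hit <- which(sel & residue$alt == altloc)
  if (length(hit) == 0) hit <- which(sel)
  unlist(residue[hit[1], c("x", "y", "z")], use.names = FALSE)
}

# altloc labels present on a given atom name ("" when single conformer)
atom_altlocs <- function(residue, name) {
  a <- unique(residue$alt[residue$elety == name])
  if (length(a) == 0) character(0) else sort(a)
}

#' Per-residue confidence profile
#'
#' Mean of the atom B-factors per polymer residue. For AlphaFold-style
#' models the B-factor column holds the pLDDT score (0-100); experimental
#' B-factors pass through unchanged and their interpretation is left to the
#' caller. Residues without atoms yield `NA`.
#'
#' @param model `sno_model`.
#' @return data.frame `chain`, `resno`, `insert`, `resid`, `confidence`.
#' @export
plddt_profile <- function(model) {
  rt <- residue_table(model)
  at <- model$atoms[model$atoms$type == "ATOM", , drop = FALSE]
  key_at <- paste(at$chain, at$resno, at$insert)
  key_rt <- paste(rt$chain, rt$resno, rt$insert)
  m <- tapply(at$b, key_at, mean)
  rt$confidence <- as.numeric(m[key_rt])
  rt
}

#' Trim low-confidence regions from a model
#'
#' Contiguous runs of residues with confidence below `plddt_threshold` are
#' removed when they are terminal (either end of a chain) or when they are
#' internal and at least `max_internal_loop` residues long. Shorter internal
#' low-confidence loops connecting confident segments are kept. Query sites
#' falling inside a removed segment, or inside any low-confidence segment of
#' length >= `max_internal_loop`, are flagged as disqualified: such sites sit
#' in long disordered regions where a static-model analysis is unreliable.
#'
#' @param model `sno_model` with pLDDT-style confidence in the B-factors.
#' @param plddt_threshold confidence below which a residue is "low"
#'   (default 50, the AlphaFold "very low" band; must lie in \[0, 100\]).
#' @param max_internal_loop minimum length for removing an internal
#'   low-confidence loop (default 20 residues).
#' @param sites integer vector of residue numbers to check (optional).
#' @return list with `model` (trimmed), `removed` (data.frame of removed
#'   segments: chain, start, end, length, terminal), and `disqualified`
#'   (named logical, one per entry of `sites`).
#' @export
trim_low_confidence <- function(model, plddt_threshold = 50,
                                max_internal_loop = 20, sites = integer(0)) {
  if (plddt_threshold < 0 || plddt_threshold > 100)
    stop("plddt_threshold must be in [0, 100]")
  prof <- plddt_profile(model)
  removed <- data.frame(chain = character(0), start = integer(0),
                        end = integer(0), length = integer(0),
                        terminal = logical(0), stringsAsFactors = FALSE)
  disq <- setNames(rep(FALSE, length(sites)), as.character(sites))
  drop_keys <- character(0)
  for (ch in unique(prof$chain)) {
    pc <- prof[prof$chain == ch, , drop = FALSE]
    low <- !is.na(pc$confidence) & pc$confidence < plddt_threshold
    if (!any(low)) next
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in seq_along(r$values)) {
      if (!r$values[s]) next
      i1 <- starts[s]; i2 <- ends[s]; len <- i2 - i1 + 1L
      terminal <- (i1 == 1L) || (i2 == nrow(pc))
      long <- len >= max_internal_loop
      in_seg <- sites %in% pc$resno[i1:i2]
      if (terminal || long) {
        removed <- rbind(removed, data.frame(
          chain = ch, start = pc$resno[i1], end = pc$resno[i2], length = len,
          terminal = terminal, stringsAsFactors = FALSE))
        drop_keys <- c(drop_keys, paste(ch, pc$resno[i1:i2], pc$insert[i1:i2]))
      }
      if (terminal || long) disq[in_seg] <- TRUE
    }
  }
  at <- model$atoms
  keep <- !(at$type == "ATOM" &
              paste(at$chain, at$resno, at$insert) %in% drop_keys)
  trimmed <- model
  trimmed$atoms <- at[keep, , drop = FALSE]
  list(model = trimmed, removed = removed, disqualified = disq)
}

#' Non-water HETATM records of a model
#'
#' @param model `sno_model`.
#' @return data.frame of HETATM atoms with waters (HOH) removed.
#' @export
ligand_atoms <- function(model) {
  at <- model$atoms
  at[at$type == "HETATM" & at$resid != "HOH", , drop = FALSE]
}
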