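#' Read a coordinate file into a ComplexStructure
#'
#' Parses a PDB file through \pkg{bio3d}, keeping polymer residues and
#' hetero ligands (waters are excluded), and supplements the parse with the
#' two record types bio3d does not expose: CONECT bonds between hetero
#' atoms and the REMARK 2 resolution. Multi-model files yield the requested
#' model only (the first by default; NMR-style entries are handled by
#' taking model 1, with a message).
#'
#' Occupancy is taken as 1.0 when absent, per PDB convention. Elements are
#' taken from columns 77-78 and inferred from the atom name when blank.
#'
#' @param path path to a PDB file
#' @param model 1-based model index (default 1)
#' @param id structure identifier (default: file stem)
#' @return a \linkS4class{ComplexStructure}
#' @examples
#' pdb <- makeDimer(d = 3.75, alpha = 0, theta = 0)
#' readStructure(pdb)
#' @export
readStructure <- function(path, model = 1L, id = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e)))
  nmodel <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1 || model > nmodel)
    stop("model ", model, " not present (file has ", nmodel, " model(s))")
  if (nmodel > 1 && model == 1)
    message("multi-model file: using model 1 of ", nmodel)

  a <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  coords <- matrix(xyz, ncol = 3, byrow = TRUE)
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- .elementFromName(a$elety[blank])
  atoms <- data.frame(
    serial = a$eleno,
    name = a$elety,
    elem = toupper(trimws(elem)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occ = ifelse(is.na(a$o), 1.0, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  water <- atoms$het & atoms$resid %in% c("HOH", "DOD", "WAT")
  atoms <- atoms[!water, , drop = FALSE]
  rownames(atoms) <- NULL

  bonds <- .parseConect(lines, atoms$serial)
  res <- .parseResolution(lines)
  hel <- .rangesFromHeader(pdb$helix)
  she <- .rangesFromHeader(pdb$sheet)
  if (is.null(id)) id <- sub("\\.(pdb|ent|cif)$", "", basename(path))
  new("ComplexStructure", id = id, atoms = atoms, bonds = bonds,
      resolution = res, helixRanges = hel, sheetRanges = she)
}

#' @keywords internal
.parseConect <- function(lines, serials) {
  con <- lines[startsWith(lines, "CONECT")]
  if (!length(con))
    return(data.frame(i = integer(), j = integer()))
  idx <- stats::setNames(seq_along(serials), serials)
  pairs <- matrix(integer(), ncol = 2)
  out <- list()
  for (ln in con) {
    flds <- substring(ln, c(7, 12, 17, 22, 27), c(11, 16, 21, 26, 31))
    nums <- suppressWarnings(as.integer(flds))
    nums <- nums[!is.na(nums)]
    if (length(nums) < 2) next
    from <- nums[1]
    for (to in nums[-1]) out[[length(out) + 1L]] <- c(from, to)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  i <- idx[as.character(pmin(m[, 1], m[, 2]))]
  j <- idx[as.character(pmax(m[, 1], m[, 2]))]
  keep <- !is.na(i) & !is.na(j) & i != j
  b <- unique(data.frame(i = unname(i[keep]), j = unname(j[keep])))
  rownames(b) <- NULL
  b
}

#' @keywords internal
.parseResolution <- function(lines) {
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  tail <- sub("^REMARK   2 RESOLUTION\\.?", "", rem[1])
  m <- regmatches(tail, regexpr("[0-9]+\\.?[0-9]*", tail))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

#' @keywords internal
.rangesFromHeader <- function(h) {
  if (is.null(h) || is.null(h$start) || !length(h$start))
    return(data.frame(chain = character(), start = integer(), end = integer()))
  data.frame(chain = as.character(h$chain),
             start = as.integer(h$start), end = as.integer(h$end))
}

#' Resolve alternate locations to a single conformer
#'
#' For each atom name occurring with multiple altLoc codes within a residue,
#' keeps the highest-occupancy conformer; ties keep the lexicographically
#' smallest altLoc. Idempotent.
#'
#' @param x a \linkS4class{ComplexStructure}
#' @return a \linkS4class{ComplexStructure} with unique atom names per residue
#' @export
resolveAltLoc <- function(x) {
  a <- atoms(x)
  if (!nrow(a)) return(x)
  key <- paste(a$chain, a$resno, a$insert, a$resid, a$name, sep = "\r")
  ord <- order(key, -a$occ, a$alt)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  if (length(keep) == nrow(a)) return(x)
  dropped <- setdiff(seq_len(nrow(a)), keep)
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  b <- bonds(x)
  if (nrow(b)) {
    ok <- !(b$i %in% dropped) & !(b$j %in% dropped)
    b <- data.frame(i = remap[b$i[ok]], j = remap[b$j[ok]])
  }
  a <- a[keep, , drop = FALSE]
  rownames(a) <- NULL
  initialize(x, atoms = a, bonds = b)
}

#' Extract hetero ligand instances
#'
#' Groups hetero atoms into ligand instances by (component id, chain,
#' residue number, insertion code), excluding waters and a configurable
#' deny-list of common crystallization additives and ions. The molecular
#' weight is computed over the recorded heavy atoms only (no implicit
#' hydrogens): crystal structures rarely record H, and the drug-likeness
#' weight gate is coarse.
#'
#' @param x a \linkS4class{ComplexStructure}
#' @param denylist component ids never considered ligand candidates
#' @return list of ligand instances, each a list with \code{comp_id},
#'   \code{chain}, \code{resno}, \code{insert}, \code{atomIdx} (rows of
#'   \code{atoms(x)}), \code{bonds} (local index pairs) and \code{mol_weight}
#' @export
ligandInstances <- function(x, denylist = .defaultLigandDenylist) {
  a <- atoms(x)
  sel <- which(a$het & !(a$resid %in% denylist))
  if (!length(sel)) return(list())
  key <- paste(a$resid[sel], a$chain[sel], a$resno[sel], a$insert[sel],
               sep = "\r")
  b <- bonds(x)
  lapply(split(sel, key), function(idx) {
    loc <- stats::setNames(seq_along(idx), idx)
    lb <- if (nrow(b)) {
      ok <- b$i %in% idx & b$j %in% idx
      cbind(unname(loc[as.character(b$i[ok])]),
            unname(loc[as.character(b$j[ok])]))
    } else matrix(integer(), ncol = 2)
    list(comp_id = a$resid[idx[1]], chain = a$chain[idx[1]],
         resno = a$resno[idx[1]], insert = a$insert[idx[1]],
         atomIdx = idx, bonds = lb,
         mol_weight = sum(.elementLookup(.atomicMasses, a$elem[idx],
                                         "molecular weight")))
  })
}

#' Drug-likeness filter for ligand instances
#'
#' Keeps ligands with heavy-atom molecular weight >= \code{minWeight} Da
#' that occur in at most \code{maxOccurrence} distinct crystals. Both
#' boundaries are inclusive. With an empty occurrence map the occurrence
#' filter is skipped (with a warning); components absent from a non-empty
#' map are kept.
#'
#' @param ligands list of ligand instances (see \code{\link{ligandInstances}})
#' @param occurrence named integer vector, component id -> number of
#'   distinct crystals, or NULL
#' @param minWeight Da, default 100
#' @param maxOccurrence default 10
#' @return the surviving subset of \code{ligands}
#' @export
filterDrugLike <- function(ligands, occurrence = NULL,
                           minWeight = 100, maxOccurrence = 10) {
  if (!length(ligands)) return(ligands)
  if (is.null(occurrence) || !length(occurrence)) {
    warning("no ligand occurrence table supplied; occurrence filter skipped")
    occ_ok <- rep(TRUE, length(ligands))
  } else {
    occ <- occurrence[vapply(ligands, `[[`, "", "comp_id")]
    occ_ok <- is.na(occ) | occ <= maxOccurrence
  }
  mw_ok <- vapply(ligands, `[[`, 0, "mol_weight") >= minWeight
  ligands[occ_ok & mw_ok]
}

#' Resolution filter for a set of structures
#'
#' Keeps structures whose stated crystallographic resolution is at or below
#' \code{maxRes} Angstrom; structures with no stated resolution are dropped
#' with a message.
#'
#' @param structures list of \linkS4class{ComplexStructure}
#' @param maxRes Angstrom, default 2.5
#' @return the surviving subset
#' @export
filterResolution <- function(structures, maxRes = 2.5) {
  if (!length(structures)) return(structures)
  res <- vapply(structures, resolution, 0)
  miss <- is.na(res)
  if (any(miss))
    message(sum(miss), " structure(s) dropped: no stated resolution")
  structures[!miss & res <= maxRes]
}

#' Classify a structure into the analysis datasets
#'
#' A structure belongs to the protein-drug dataset (\code{"PD"}) when at
#' least one ligand survives the drug-likeness filters, and to the
#' protein-protein dataset (\code{"PP"}) when it has exactly two polymer
#' chains; a two-chain complex with a drug-like ligand carries both labels
#' and enters both analyses. Anything else is \code{"other"}.
#'
#' @param x a \linkS4class{ComplexStructure}
#' @param occurrence optional occurrence map for \code{\link{filterDrugLike}}
#' @param ... further arguments to \code{\link{filterDrugLike}}
#' @return character vector of labels
#' @export
classifyDataset <- function(x, occurrence = NULL, ...) {
  a <- atoms(x)
  nchain <- length(unique(a$chain[!a$het]))
  lig <- ligandInstances(x)
  druglike <- if (length(lig))
    suppressWarnings(filterDrugLike(lig, occurrence, ...)) else list()
  labels <- character()
  if (length(druglike)) labels <- c(labels, "PD")
  if (nchain == 2) labels <- c(labels, "PP")
  if (!length(labels)) labels <- "other"
  labels
}

#' Read a two-column table (id, value) as a named vector
#'
#' Used for the ligand occurrence table (component id, number of crystals)
#' and for precomputed sequence-cluster membership (structure id, cluster).
#'
#' @param path CSV or TSV file with two columns
#' @return named vector keyed on the first column
#' @export
readIdTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected two columns in ", path)
  stats::setNames(tab[[2]], tab[[1]])
}
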