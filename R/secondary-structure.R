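#' Assign three-class secondary structure to polymer residues
#'
#' Three assignment modes:
#' \describe{
#'   \item{internal}{a Kabsch-Sander-style approximation: backbone
#'     hydrogen bonds are detected by the electrostatic criterion
#'     E = 27.888 (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol with the amide
#'     H inferred from the previous residue's C=O (bond iff E < -0.5).
#'     Runs of n -> n+4 bonds make Helix; parallel/antiparallel ladder
#'     bridges make Sheet; everything else is Loop. Helix takes precedence
#'     over Sheet.}
#'   \item{dssp}{parse a classic DSSP output file and collapse the 8
#'     states to 3 (H, G, I -> Helix; E, B -> Sheet; rest -> Loop).}
#'   \item{header}{use the PDB HELIX/SHEET header records.}
#' }
#' Residues with missing backbone atoms are assigned Loop with a warning.
#'
#' @param x a \linkS4class{ComplexStructure}
#' @param mode assignment mode
#' @param dsspFile path to a .dssp file (dssp mode)
#' @return named character vector, key \code{"chain:resno:insert"} ->
#'   class in \code{Helix}/\code{Sheet}/\code{Loop}
#' @export
assignSS <- function(x, mode = c("internal", "dssp", "header"),
                     dsspFile = NULL) {
  mode <- match.arg(mode)
  a <- atoms(x)
  poly <- a[!a$het, , drop = FALSE]
  resKey <- unique(paste(poly$chain, poly$resno, poly$insert, sep = ":"))
  out <- stats::setNames(rep("Loop", length(resKey)), resKey)
  if (mode == "internal") {
    res <- .backboneTable(poly)
    if (any(!res$complete))
      warning(sum(!res$complete),
              " residue(s) missing backbone atoms: assigned Loop")
    hb <- .ksHbonds(res)
    cls <- .ssFromHbonds(res, hb)
    cls[!res$complete] <- "Loop"
    out[res$key] <- cls
  } else if (mode == "dssp") {
    if (is.null(dsspFile)) stop("dssp mode needs a dsspFile")
    d <- readDSSP(dsspFile)
    hit <- intersect(names(d), names(out))
    out[hit] <- d[hit]
  } else {
    for (k in seq_len(nrow(x@helixRanges))) {
      h <- x@helixRanges[k, ]
      sel <- grepl(paste0("^", h$chain, ":"), names(out)) &
        as.integer(sub("^.*?:(-?[0-9]+):.*$", "\\1", names(out))) >= h$start &
        as.integer(sub("^.*?:(-?[0-9]+):.*$", "\\1", names(out))) <= h$end
      out[sel] <- "Helix"
    }
    for (k in seq_len(nrow(x@sheetRanges))) {
      s <- x@sheetRanges[k, ]
      sel <- grepl(paste0("^", s$chain, ":"), names(out)) &
        as.integer(sub("^.*?:(-?[0-9]+):.*$", "\\1", names(out))) >= s$start &
        as.integer(sub("^.*?:(-?[0-9]+):.*$", "\\1", names(out))) <= s$end
      out[sel] <- "Sheet"
    }
  }
  out
}

# Per-residue backbone coordinates in chain order, with sequence-neighbour
# pointers broken where the peptide bond distance exceeds 2.5 Angstrom.
#' @keywords internal
.backboneTable <- function(poly) {
  key <- paste(poly$chain, poly$resno, poly$insert, sep = ":")
  ukey <- unique(key)
  n <- length(ukey)
  get1 <- function(idx, nm) {
    hit <- idx[match(nm, poly$name[idx])]
    if (is.na(hit)) rep(NA_real_, 3) else
      as.numeric(poly[hit, c("x", "y", "z")])
  }
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  chain <- character(n); resno <- integer(n)
  byKey <- split(seq_len(nrow(poly)), key)
  for (k in seq_len(n)) {
    idx <- byKey[[ukey[k]]]
    N[k, ] <- get1(idx, "N"); CA[k, ] <- get1(idx, "CA")
    C[k, ] <- get1(idx, "C"); O[k, ] <- get1(idx, "O")
    chain[k] <- poly$chain[idx[1]]; resno[k] <- poly$resno[idx[1]]
  }
  ord <- order(chain, resno)
  N <- N[ord, , drop = FALSE]; CA <- CA[ord, , drop = FALSE]
  C <- C[ord, , drop = FALSE]; O <- O[ord, , drop = FALSE]
  chain <- chain[ord]; resno <- resno[ord]; ukey <- ukey[ord]
  complete <- stats::complete.cases(cbind(N, CA, C, O))
  prev <- c(NA_integer_, seq_len(n - 1))
  if (n > 1) {
    brk <- chain[-1] != chain[-n]
    d <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2))
    brk <- brk | is.na(d) | d > 2.5
    prev[which(brk) + 1L] <- NA_integer_
  }
  list(key = ukey, chain = chain, resno = resno, N = N, CA = CA, C = C,
       O = O, complete = complete, prev = prev, n = n)
}

# Kabsch-Sander H-bond matrix: hb[i, j] TRUE when the NH of residue i
# donates to the CO of residue j (E < -0.5 kcal/mol). The amide H sits
# 1.01 Angstrom from N, anti to the previous residue's carbonyl.
#' @keywords internal
.ksHbonds <- function(res, cutoff = -0.5) {
  n <- res$n
  hb <- matrix(FALSE, n, n)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    p <- res$prev[i]
    if (is.na(p) || !res$complete[i] || !res$complete[p]) next
    dir <- res$C[p, ] - res$O[p, ]
    H[i, ] <- res$N[i, ] + 1.01 * dir / sqrt(sum(dir^2))
  }
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ]))) next
    for (j in seq_len(n)) {
      if (!res$complete[j] || abs(i - j) < 2) next
      rON <- sqrt(sum((res$O[j, ] - res$N[i, ])^2))
      if (rON > 5.2) next  # E cannot reach -0.5 beyond this separation
      rCH <- sqrt(sum((res$C[j, ] - H[i, ])^2))
      rOH <- sqrt(sum((res$O[j, ] - H[i, ])^2))
      rCN <- sqrt(sum((res$C[j, ] - res$N[i, ])^2))
      E <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- E < cutoff
    }
  }
  hb
}

# 3-class assignment from the H-bond matrix: two consecutive 4-turns make
# a minimal helix i..i+3; parallel/antiparallel bridges make Sheet.
#' @keywords internal
.ssFromHbonds <- function(res, hb) {
  n <- res$n
  cls <- rep("Loop", n)
  seqNext <- function(i) which(res$prev == i)[1]
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    j <- i
    ok <- TRUE
    for (s in 1:4) {       # i+4 along the chain without breaks
      j <- seqNext(j)
      if (is.na(j)) { ok <- FALSE; break }
    }
    if (ok && hb[j, i]) turn4[i] <- TRUE
  }
  sheet <- rep(FALSE, n)
  for (i in seq_len(n)) {
    im <- res$prev[i]; ip <- seqNext(i)
    for (j in seq_len(n)) {
      if (abs(i - j) < 3) next
      jm <- res$prev[j]; jp <- seqNext(j)
      par <- (!is.na(im) && !is.na(ip) && hb[im, j] && hb[j, ip]) ||
             (!is.na(jm) && !is.na(jp) && hb[jm, i] && hb[i, jp])
      anti <- (hb[i, j] && hb[j, i]) ||
              (!is.na(im) && !is.na(ip) && !is.na(jm) && !is.na(jp) &&
               hb[im, jp] && hb[jm, ip])
      if (isTRUE(par) || isTRUE(anti)) { sheet[i] <- TRUE; break }
    }
  }
  cls[sheet] <- "Sheet"
  for (i in seq_len(n - 1)) {
    i2 <- seqNext(i)
    if (!is.na(i2) && turn4[i] && turn4[i2]) {
      j <- i2
      for (s in 0:3) {
        if (is.na(j)) break
        cls[j] <- "Helix"
        j <- seqNext(j)
      }
    }
  }
  cls
}

#' Parse a classic DSSP output file to three classes
#'
#' Reads the per-residue block after the \code{"#  RESIDUE"} header and
#' maps the 8-state code (column 17) to Helix (H, G, I), Sheet (E, B) or
#' Loop (anything else). Chain-break records are skipped.
#'
#' @param path path to a .dssp file
#' @return named character vector, key \code{"chain:resno:"} -> class
#' @export
readDSSP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("not a DSSP file: missing residue header")
  body <- lines[(start[1] + 1):length(lines)]
  out <- character(); keys <- character()
  for (ln in body) {
    if (nchar(ln) < 17) next
    if (substr(ln, 14, 14) == "!") next
    resno <- suppressWarnings(as.integer(substr(ln, 6, 10)))
    if (is.na(resno)) next
    chain <- trimws(substr(ln, 12, 12))
    code <- substr(ln, 17, 17)
    cls <- if (code %in% c("H", "G", "I")) "Helix"
           else if (code %in% c("E", "B")) "Sheet" else "Loop"
    keys <- c(keys, paste0(chain, ":", resno, ":"))
    out <- c(out, cls)
  }
  stats::setNames(out, keys)
}

#' Secondary-structure preference log-odds
#'
#' The preference of a ring in context class c to contact a residue in
#' class p is the log odds ratio
#' \deqn{Preference(c, p) = \log_{10} \frac{P(p \mid c)}{P(p)}}
#' with \eqn{P(p \mid c)} from the row-normalized contingency table and
#' the background \eqn{P(p)} estimated from the partner marginal of the
#' same table unless supplied. Independence gives 0 in every cell;
#' enrichment is positive, depletion negative. When the table contains a
#' zero, 0.5 is added to every cell (Jeffreys) with a message so the
#' log-odds stay finite.
#'
#' @param counts contingency matrix, rows = context classes, columns =
#'   partner classes
#' @param background optional named background probabilities over the
#'   partner classes (strictly positive, summing to 1)
#' @param base logarithm base (default 10)
#' @return matrix of log-odds values; rows with zero total are NA
#' @export
preferenceTable <- function(counts, background = NULL, base = 10) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(counts == 0)) {
    message("zero cell(s) in contingency: Jeffreys +0.5 applied")
    counts <- counts + 0.5
  }
  if (is.null(background)) {
    background <- colSums(counts) / sum(counts)
  } else {
    stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-6)
  }
  out <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (r in seq_len(nrow(counts))) {
    tot <- sum(counts[r, ])
    if (tot == 0) next
    out[r, ] <- log(counts[r, ] / tot / background, base = base)
  }
  out
}
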