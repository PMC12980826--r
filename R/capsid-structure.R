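# PDB input and biological-assembly geometry for capsid structures.
# Atom records and REMARK 350 BIOMT matrices are parsed with bio3d; a
# plain-text transform file (12 numbers per row: row-major rotation then
# translation) can stand in when the PDB carries no assembly remark.

.backboneNames <- c("N", "CA", "C", "O", "OXT")

#' Read a capsid structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), drops hydrogens, assigns Bondi
#' van der Waals radii and side-chain flags (heavy atoms other than N, CA,
#' C, O, OXT; glycine therefore contributes no side-chain atoms), and
#' collects the biological-assembly transforms from REMARK 350 BIOMT or
#' from a supplied transform file.
#'
#' @param file path to a PDB file
#' @param transforms optional transforms when the PDB has no REMARK 350:
#'   a path to a transform file (see [readTransformFile()]) or a list of
#'   3x4 matrices
#' @return a [CapsidStructure-class]
#' @seealso [expandAssembly()], [generateToyCapsid()]
#' @export
readCapsidStructure <- function(file, transforms = NULL) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("no ATOM/HETATM coordinates in ", file)
  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | element == ""
  # fall back on the first letter of the atom name (synthetic files)
  element[noel] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[noel])), 1, 1)
  keep <- !element %in% c("H", "D")
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  if (!nrow(at)) stop("no heavy atoms in ", file)

  atoms <- data.frame(
    eleno = at$eleno,
    elety = trimws(at$elety),
    resid = toupper(trimws(at$resid)),
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    element = element,
    vdw = vdwRadius(element),
    sidechain = !trimws(at$elety) %in% .backboneNames,
    copy = 0L,
    stringsAsFactors = FALSE)

  tr <- .resolveTransforms(pdb, transforms, file)
  methods::new("CapsidStructure", atoms = atoms, transforms = tr,
               source = basename(file))
}

.resolveTransforms <- function(pdb, transforms, file) {
  if (!is.null(transforms)) {
    if (is.character(transforms)) return(readTransformFile(transforms))
    stopifnot(is.list(transforms))
    return(lapply(transforms, function(m) {
      m <- as.matrix(m)
      stopifnot(all(dim(m) == c(3L, 4L)))
      m
    }))
  }
  biomat <- pdb$remark$biomat
  if (is.null(biomat) || !length(biomat$mat))
    stop("PDB file ", file, " carries no REMARK 350 assembly transforms; ",
         "pass them via the 'transforms' argument")
  mats <- biomat$mat[[1]]
  lapply(mats, function(m) as.matrix(m)[, 1:4, drop = FALSE])
}

#' Read rigid-body transforms from a plain-text file
#'
#' One transform per row as 12 whitespace-separated numbers: the rotation
#' matrix in row-major order followed by the translation vector (Angstrom).
#'
#' @param file path
#' @return list of 3x4 matrices `[R | t]`
#' @export
readTransformFile <- function(file) {
  m <- as.matrix(utils::read.table(file, header = FALSE))
  if (ncol(m) != 12L)
    stop("transform file must have 12 numbers per row (row-major rotation, ",
         "then translation)")
  lapply(seq_len(nrow(m)), function(i) {
    R <- matrix(m[i, 1:9], 3, 3, byrow = TRUE)
    unname(cbind(R, unname(m[i, 10:12])))
  })
}

#' Write rigid-body transforms to a plain-text file
#' @param transforms list of 3x4 matrices
#' @param file path
#' @export
writeTransformFile <- function(transforms, file) {
  rows <- t(vapply(transforms, function(m)
    c(t(m[, 1:3]), m[, 4]), numeric(12)))
  utils::write.table(format(rows, digits = 15, scientific = TRUE),
                     file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Write a structure's deposited atoms as a PDB file
#'
#' Emits ATOM records plus a REMARK 350 block with the assembly BIOMT
#' matrices, in a form [readCapsidStructure()] round-trips (coordinates to
#' the PDB's 0.001-Angstrom precision).
#'
#' @param structure a [CapsidStructure-class]
#' @param file output path
#' @export
writeCapsidPDB <- function(structure, file) {
  stopifnot(methods::is(structure, "CapsidStructure"))
  a <- structure@atoms
  remark <- character(0)
  remark <- c(remark, "REMARK 350 BIOMOLECULE: 1",
              "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A")
  for (i in seq_along(structure@transforms)) {
    m <- structure@transforms[[i]]
    for (r in 1:3)
      remark <- c(remark, sprintf(
        "REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f     %10.5f",
        r, i, m[r, 1], m[r, 2], m[r, 3], m[r, 4]))
  }
  # fixed PDB columns: name 13-16, resName 18-20, chain 22, resSeq 23-26,
  # coordinates 31-54, element 77-78
  recs <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    a$eleno %% 100000L,
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
    a$resid, a$chain, a$resno %% 10000L, a$x, a$y, a$z, a$element)
  writeLines(c(remark, recs, "END"), file)
  invisible(file)
}

#' @rdname expandAssembly
#' @export
setMethod("expandAssembly", "CapsidStructure", function(object) {
  methods::validObject(object)
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  parts <- lapply(seq_along(object@transforms), function(i) {
    m <- object@transforms[[i]]
    new <- xyz %*% t(m[, 1:3]) + rep(m[, 4], each = nrow(xyz))
    a <- object@atoms
    a$x <- new[, 1]; a$y <- new[, 2]; a$z <- new[, 3]
    a$copy <- i - 1L
    a
  })
  atoms <- do.call(rbind, parts)
  rownames(atoms) <- NULL
  methods::new("CapsidAssembly", atoms = atoms,
               center = colMeans(atoms[, c("x", "y", "z")]),
               nCopies = length(object@transforms))
})

# minimum cross distance^2 between two coordinate blocks
.minCross2 <- function(a, b) {
  min(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
}

#' @rdname selectNeighborhood
#' @export
setMethod("selectNeighborhood", "CapsidAssembly",
  function(object, referenceCopy = 0L, contactCutoff = 6) {
    stopifnot(contactCutoff > 0)
    atoms <- object@atoms
    if (!referenceCopy %in% atoms$copy)
      stop("reference copy ", referenceCopy, " not present in assembly")
    ref <- atoms[atoms$copy == referenceCopy, , drop = FALSE]
    refXyz <- as.matrix(ref[, c("x", "y", "z")])
    refCtr <- colMeans(refXyz)
    refSpan <- sqrt(max(rowSums(sweep(refXyz, 2, refCtr)^2)))

    others <- setdiff(unique(atoms$copy), referenceCopy)
    keep <- integer(0)
    cut2 <- contactCutoff^2
    for (cp in others) {
      blk <- as.matrix(atoms[atoms$copy == cp, c("x", "y", "z"), drop = FALSE])
      ctr <- colMeans(blk)
      span <- sqrt(max(rowSums(sweep(blk, 2, ctr)^2)))
      # bounding-sphere prefilter before the exact all-pairs scan
      if (sqrt(sum((ctr - refCtr)^2)) > refSpan + span + contactCutoff) next
      if (.minCross2(refXyz, blk) <= cut2) keep <- c(keep, cp)
    }
    if (!length(keep))
      warning("no assembly copy within ", contactCutoff,
              " A of reference copy ", referenceCopy,
              "; returning the reference alone")
    out <- atoms[atoms$copy %in% c(referenceCopy, keep), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "referenceCopy") <- as.integer(referenceCopy)
    out
  })
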