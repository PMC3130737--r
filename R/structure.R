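# Fixed-backbone toy structures: one anchor (C-alpha) per residue plus an
# orthonormal local frame from which side-chain bead placements are derived.

#' Construct a toy structure
#'
#' A structure is an ordered set of residues, each carrying a chain id, a
#' 1-based residue number, a wildtype amino acid, a 3D anchor coordinate
#' (the C-alpha position, in Angstrom) and an orthonormal local frame.  The
#' frame's first axis plays the role of the C-alpha to C-beta direction and
#' orients the discrete side-chain bead placements.
#'
#' @param chain character vector of single-character chain ids.
#' @param resnum integer vector of residue numbers (>= 1).
#' @param aa one-letter wildtype amino-acid codes.
#' @param xyz numeric matrix (n x 3) of anchor coordinates in Angstrom.
#' @param frames optional 3 x 3 x n array of orthonormal frames (columns are
#'   axes).  When `NULL`, frames are derived deterministically from the chain
#'   geometry (see [residue_frames()]).
#' @param cb optional n x 3 matrix of C-beta coordinates; rows may be `NA`
#'   for residues without one.  When given, the frame's first axis follows
#'   the C-alpha to C-beta direction.
#' @return an object of class `toy_structure`.
#' @export
toy_structure <- function(chain, resnum, aa, xyz, frames = NULL, cb = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(chain)
  stopifnot(length(resnum) == n, length(aa) == n, nrow(xyz) == n, ncol(xyz) == 3)
  if (any(!is.finite(xyz))) stop("non-finite anchor coordinates")
  if (any(resnum < 1)) stop("residue numbers must be >= 1")
  if (any(nchar(chain) != 1)) stop("chain ids must be single characters")
  check_aa(aa)
  key <- paste(chain, resnum)
  if (anyDuplicated(key)) stop("duplicate (chain, residue number) pairs")
  s <- structure(list(
    residues = data.frame(chain = as.character(chain),
                          resnum = as.integer(resnum),
                          aa = as.character(aa),
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE),
    chains = unique(as.character(chain))),
    class = "toy_structure")
  s$frames <- if (is.null(frames)) residue_frames(s, cb = cb) else frames
  s
}

#' @export
print.toy_structure <- function(x, ...) {
  cat("toy_structure:", nrow(x$residues), "residues,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = ", "), "]\n")
  invisible(x)
}

#' @export
format.toy_structure <- function(x, ...) {
  paste0("toy_structure<", nrow(x$residues), " res>")
}

anchors <- function(s) as.matrix(s$residues[, c("x", "y", "z")])

residue_index <- function(s, chain, resnum) {
  i <- match(paste(chain, resnum), paste(s$residues$chain, s$residues$resnum))
  if (any(is.na(i)))
    stop("residue(s) absent from structure: ",
         paste(paste0(chain, "/", resnum)[is.na(i)], collapse = ", "))
  i
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) return(NULL)
  v / nv
}

perp_to <- function(t) {
  # deterministic unit vector perpendicular to t
  e <- diag(3)[, which.min(abs(t))]
  unit(e - sum(e * t) * t)
}

#' Deterministic residue frames from chain geometry
#'
#' For each residue the frame is an orthonormal axis triple: the first axis
#' points "outward" (along C-alpha minus the midpoint of the flanking
#' anchors, i.e. a pseudo C-beta direction for a helical trace; or along the
#' actual C-alpha to C-beta bond when C-beta coordinates are supplied), the
#' second along the local chain tangent, the third completes a right-handed
#' set.  Frames depend only on the coordinates of the residue's own chain,
#' so a chain extracted from a complex keeps identical frames -- the
#' precondition for matched-backbone binding energies and for identical
#' rotamer sets across states.
#'
#' @param s a [toy_structure()].
#' @param cb optional n x 3 matrix of C-beta coordinates (NA rows allowed).
#' @return a 3 x 3 x n array; columns of each slice are the axes.
#' @export
residue_frames <- function(s, cb = NULL) {
  res <- s$residues
  xyz <- anchors(s)
  n <- nrow(res)
  fr <- array(NA_real_, c(3, 3, n))
  for (ch in s$chains) {
    idx <- which(res$chain == ch)
    k <- length(idx)
    for (j in seq_len(k)) {
      i <- idx[j]
      p <- idx[max(1, j - 1)]; q <- idx[min(k, j + 1)]
      t <- unit(xyz[q, ] - xyz[p, ])
      if (is.null(t)) t <- c(0, 0, 1)
      a1 <- NULL
      if (!is.null(cb) && !anyNA(cb[i, ]))
        a1 <- unit(cb[i, ] - xyz[i, ])
      if (is.null(a1)) {
        v <- xyz[i, ] - (xyz[p, ] + xyz[q, ]) / 2
        a1 <- unit(v - sum(v * t) * t)
      }
      if (is.null(a1)) a1 <- perp_to(t)
      a2 <- unit(t - sum(t * a1) * a1)
      if (is.null(a2)) a2 <- perp_to(a1)
      a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
              a1[3] * a2[1] - a1[1] * a2[3],
              a1[1] * a2[2] - a1[2] * a2[1])
      fr[, , i] <- cbind(a1, a2, a3)
    }
  }
  fr
}

#' Extract chains from a structure
#'
#' Keeps coordinates and frames unchanged, so the extracted monomer shares
#' its backbone with the parent complex exactly.
#'
#' @param s a [toy_structure()].
#' @param chains chain ids to keep.
#' @return a [toy_structure()].
#' @export
extract_chains <- function(s, chains) {
  keep <- s$residues$chain %in% chains
  if (!any(keep)) stop("no residues on chain(s) ", paste(chains, collapse = ","))
  out <- structure(list(
    residues = s$residues[keep, , drop = FALSE],
    chains = intersect(s$chains, chains),
    frames = s$frames[, , keep, drop = FALSE]), class = "toy_structure")
  rownames(out$residues) <- NULL
  out
}

#' Rigidly transform selected chains of a structure
#'
#' @param s a [toy_structure()].
#' @param chains chain ids to move.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (Angstrom).
#' @param center optional point about which the rotation is applied
#'   (defaults to the moved chains' anchor centroid).
#' @return the transformed structure; frames are rotated with the chain.
#' @export
transform_chains <- function(s, chains, rotation = diag(3),
                             translation = c(0, 0, 0), center = NULL) {
  keep <- s$residues$chain %in% chains
  xyz <- anchors(s)
  if (is.null(center)) center <- colMeans(xyz[keep, , drop = FALSE])
  moved <- sweep(xyz[keep, , drop = FALSE], 2, center) %*% t(rotation)
  moved <- sweep(moved, 2, center + translation, `+`)
  s$residues[keep, c("x", "y", "z")] <- moved
  for (i in which(keep)) s$frames[, , i] <- rotation %*% s$frames[, , i]
  s
}

#' Coordinate RMS without superposition
#'
#' Root-mean-square deviation between two coordinate sets taken as-is: no
#' alignment is performed, so rigid-body displacement contributes fully.
#' This is the mutual C-alpha RMS used to enforce diversity among docked
#' conformations.
#'
#' @param coords_a,coords_b numeric matrices (n x 3) or [toy_structure()]s.
#' @return RMS distance in Angstrom.
#' @export
rms_no_superposition <- function(coords_a, coords_b) {
  if (inherits(coords_a, "toy_structure")) coords_a <- anchors(coords_a)
  if (inherits(coords_b, "toy_structure")) coords_b <- anchors(coords_b)
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b) || nrow(coords_a) < 1)
    stop("coordinate lists must have equal, positive length")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

# ---------------------------------------------------------------------------
# I/O: native toy format and a PDB subset

#' Read / write the native toy-structure format
#'
#' One residue per line: `chain resnum aa x y z`, `#` comments allowed.
#' Written and read losslessly (full double precision).
#'
#' @param path file path.
#' @return [read_toy_structure()] returns a [toy_structure()].
#' @export
read_toy_structure <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(f) != 6)) stop("malformed toy-structure line(s)")
  f <- do.call(rbind, f)
  toy_structure(chain = f[, 1], resnum = as.integer(f[, 2]), aa = f[, 3],
                xyz = cbind(as.numeric(f[, 4]), as.numeric(f[, 5]),
                            as.numeric(f[, 6])))
}

#' @param s a [toy_structure()].
#' @rdname read_toy_structure
#' @export
write_toy_structure <- function(s, path) {
  r <- s$residues
  writeLines(sprintf("%s %d %s %.17g %.17g %.17g",
                     r$chain, r$resnum, r$aa, r$x, r$y, r$z), path)
  invisible(path)
}

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Read / write a PDB subset
#'
#' Only `ATOM` records are interpreted.  `CA` atoms define residue anchors;
#' `CB` atoms, when present, define the first frame axis, otherwise a
#' deterministic pseudo C-beta is derived from chain geometry.  Residue
#' numbers are 1-based and chains single characters.
#'
#' @param path file path.
#' @return a [toy_structure()].
#' @export
read_pdb_subset <- function(path) {
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  if (length(lines) == 0) stop("no ATOM records in ", path)
  atom <- trimws(substr(lines, 13, 16))
  res3 <- trimws(substr(lines, 18, 20))
  chain <- trimws(substr(lines, 22, 22))
  resnum <- as.integer(substr(lines, 23, 26))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  ca <- atom == "CA"
  if (!any(ca)) stop("no CA atoms in ", path)
  aa <- names(AA3)[match(res3[ca], AA3)]
  if (anyNA(aa)) stop("unknown residue name(s) in ", path)
  key <- paste(chain, resnum)
  cb <- matrix(NA_real_, sum(ca), 3)
  iscb <- which(atom == "CB")
  m <- match(key[iscb], key[ca])
  cb[m[!is.na(m)], ] <- cbind(x[iscb], y[iscb], z[iscb])[!is.na(m), , drop = FALSE]
  toy_structure(chain = chain[ca], resnum = resnum[ca], aa = aa,
                xyz = cbind(x[ca], y[ca], z[ca]), cb = cb)
}

#' @param s a [toy_structure()].
#' @rdname read_pdb_subset
#' @export
write_pdb_subset <- function(s, path) {
  r <- s$residues
  n <- nrow(r)
  ca <- sprintf("ATOM  %5d  CA  %s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                seq_len(n) * 2L - 1L, AA3[r$aa], r$chain, r$resnum,
                r$x, r$y, r$z)
  # pseudo-CB 1.53 A along the first frame axis (omitted for glycine)
  cbxyz <- t(vapply(seq_len(n), function(i)
    c(r$x[i], r$y[i], r$z[i]) + 1.53 * s$frames[, 1, i], numeric(3)))
  cb <- sprintf("ATOM  %5d  CB  %s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                seq_len(n) * 2L, AA3[r$aa], r$chain, r$resnum,
                cbxyz[, 1], cbxyz[, 2], cbxyz[, 3])
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, ca[i])
    if (r$aa[i] != "G") lines <- c(lines, cb[i])
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
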