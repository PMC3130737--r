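# The bead-rotamer energy model: one sphere per side chain, a 12-6 well with
# hydrophobicity-weighted depth, and a finite interaction cutoff.  The model
# is exactly specified -- no fitted constants -- and preserves the
# combinatorial structure (one-body + sparse two-body terms, clashes, burial)
# that rotamer-optimization algorithms manipulate.

#' Energy-model parameters
#'
#' @param epsilon0 base well depth (REU).
#' @param pair_cutoff interaction cutoff between bead centers (Angstrom).
#' @param backbone_sphere_radius radius of the fixed backbone sphere placed at
#'   every residue anchor (Angstrom).
#' @param radius_base,radius_scale side-chain bead radius is
#'   `radius_base + radius_scale * c^(1/3)` with `c` the side-chain
#'   heavy-atom count (Angstrom).
#' @param offset_base,offset_scale bead center sits at
#'   `anchor + (offset_base + offset_scale * sqrt(c)) * axis` (Angstrom).
#' @return a list of class `toy_energy_params`.
#' @export
toy_energy_params <- function(epsilon0 = 0.5, pair_cutoff = 6.0,
                              backbone_sphere_radius = 1.7,
                              radius_base = 1.0, radius_scale = 0.25,
                              offset_base = 0.5, offset_scale = 0.35) {
  p <- list(epsilon0 = epsilon0, pair_cutoff = pair_cutoff,
            backbone_sphere_radius = backbone_sphere_radius,
            radius_base = radius_base, radius_scale = radius_scale,
            offset_base = offset_base, offset_scale = offset_scale)
  if (any(unlist(p) <= 0)) stop("all energy parameters must be positive")
  if (pair_cutoff <= 2 * (radius_base + radius_scale * 10^(1 / 3)))
    stop("pair_cutoff too small relative to the largest bead diameter")
  class(p) <- "toy_energy_params"
  p
}

#' Pairwise bead-bead energy
#'
#' `E = eps_ij * ((sigma/d)^12 - 2 (sigma/d)^6)` for center distance
#' `d <= pair_cutoff` and 0 beyond, with `sigma = r_i + r_j` (the well
#' minimum, of depth `-eps_ij`) and `eps_ij = epsilon0 * (1 + h_i h_j)` so
#' that like-signed hydrophobicities deepen the contact.
#'
#' @param rot_i,rot_j rotamers as returned by [build_rotamers()] (lists with
#'   `center`, `radius`, `hydrophobicity`).
#' @param params a [toy_energy_params()].
#' @return energy in REU; symmetric in its arguments.
#' @export
pair_energy <- function(rot_i, rot_j, params = toy_energy_params()) {
  d <- sqrt(sum((rot_i$center - rot_j$center)^2))
  pair_energy_d(d, rot_i$radius + rot_j$radius,
                rot_i$hydrophobicity * rot_j$hydrophobicity, params)
}

# vectorized kernel on distances; hh = product of hydrophobicities
pair_energy_d <- function(d, sigma, hh, params) {
  if (any(d == 0)) stop("coincident bead centers (d = 0)")
  eps <- params$epsilon0 * (1 + hh)
  sr6 <- (sigma / d)^6
  e <- eps * (sr6^2 - 2 * sr6)
  e[d > params$pair_cutoff] <- 0
  e
}

# All pair energies between two rotamer sets (matrices of centers + vectors
# of radii/hydrophobicities); returns an n_i x n_j matrix.
pair_energy_block <- function(ci, ri, hi, cj, rj, hj, params) {
  d2 <- outer(rowSums(ci^2), rowSums(cj^2), `+`) - 2 * ci %*% t(cj)
  d <- sqrt(pmax(d2, 0))
  pair_energy_d(d, outer(ri, rj, `+`), outer(hi, hj), params)
}

aa_radius <- function(aa, params) params$radius_base + params$radius_scale * AA_HEAVY[aa]^(1 / 3)
aa_offset <- function(aa, params) params$offset_base + params$offset_scale * sqrt(AA_HEAVY[aa])
aa_hydro <- function(aa) unname(AA_KD[aa] / 4.5)

#' Build the discrete rotamer set for one residue
#'
#' For each allowed amino acid, one rotamer is placed per orientation in the
#' amino acid's orientation set: the six directions `+/-` each local frame
#' axis, except that a side chain with zero heavy atoms (glycine) gets a
#' single degenerate rotamer at the anchor.  Bead radius, center offset and
#' hydrophobicity are deterministic functions of the amino acid (heavy-atom
#' count and Kyte-Doolittle hydropathy / 4.5), so identical (amino acid,
#' local geometry) yields identical rotamer sets in every state -- the
#' missing-rotamer safeguard.
#'
#' In `multistate_mode` the bump check is forced off and the full orientation
#' set is always built.  With `bump_check = TRUE` (single-state use),
#' rotamers whose summed interaction with the fixed backbone spheres exceeds
#' `bump_threshold` are removed.
#'
#' @param structure a [toy_structure()].
#' @param position residue key `c(chain, resnum)` or a single row index.
#' @param allowed_aas character vector of one-letter codes.
#' @param bump_check prune backbone-clashing rotamers?
#' @param bump_threshold pruning threshold (REU).
#' @param multistate_mode force the full, state-independent rotamer set.
#' @param params a [toy_energy_params()].
#' @return a data.frame with one row per rotamer: `aa`, `orientation_index`,
#'   `cx`, `cy`, `cz`, `radius`, `hydrophobicity`.
#' @export
build_rotamers <- function(structure, position, allowed_aas,
                           bump_check = FALSE, bump_threshold = 5.0,
                           multistate_mode = TRUE,
                           params = toy_energy_params()) {
  check_aa(allowed_aas)
  i <- if (length(position) == 2 && is.character(position))
    residue_index(structure, position[1], as.integer(position[2]))
  else as.integer(position)
  if (i < 1 || i > nrow(structure$residues)) stop("position not in structure")
  anchor <- unlist(structure$residues[i, c("x", "y", "z")], use.names = FALSE)
  fr <- structure$frames[, , i]
  axes <- cbind(fr[, 1], -fr[, 1], fr[, 2], -fr[, 2], fr[, 3], -fr[, 3])
  out <- do.call(rbind, lapply(allowed_aas, function(aa) {
    if (AA_HEAVY[aa] == 0) {
      centers <- matrix(anchor, 1, 3)
      ori <- 0L
    } else {
      off <- aa_offset(aa, params)
      centers <- t(anchor + off * axes)
      ori <- 1:6
    }
    data.frame(aa = aa, orientation_index = ori,
               cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
               radius = unname(aa_radius(aa, params)),
               hydrophobicity = aa_hydro(aa),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (multistate_mode) bump_check <- FALSE
  if (bump_check) {
    bb <- rotamer_backbone_energy(out, structure, i, params)
    out <- out[bb <= bump_threshold, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# summed interaction of each rotamer with the fixed backbone spheres at every
# residue anchor except the rotamer's own
rotamer_backbone_energy <- function(rots, structure, own_index, params) {
  bb <- anchors(structure)[-own_index, , drop = FALSE]
  if (nrow(bb) == 0) return(rep(0, nrow(rots)))
  e <- pair_energy_block(as.matrix(rots[, c("cx", "cy", "cz")]),
                         rots$radius, rots$hydrophobicity,
                         bb, rep(params$backbone_sphere_radius, nrow(bb)),
                         rep(0, nrow(bb)), params)
  rowSums(e)
}

# backbone-backbone background energy of a structure (constant per geometry)
backbone_background_energy <- function(structure, params) {
  bb <- anchors(structure)
  n <- nrow(bb)
  if (n < 2) return(0)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  d <- sqrt(rowSums((bb[idx[, 1], , drop = FALSE] -
                     bb[idx[, 2], , drop = FALSE])^2))
  sum(pair_energy_d(d, 2 * params$backbone_sphere_radius, 0, params))
}
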