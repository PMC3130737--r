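# Toy rigid-body redocking.  The fixed-backbone assumption restricts the
# search to the six rigid-body degrees of freedom of the second (mobile)
# chain; side chains are repacked from scratch at every pose, so the
# chain-split/repack/concatenate preamble of the full-atom protocol is
# implicit here.  Binding energies always compare a packed complex against
# its separately packed chains on matched backbones.

random_axis_rotation <- function(sd_deg) {
  ax <- stats::rnorm(3)
  n <- sqrt(sum(ax^2))
  if (n < 1e-12) ax <- c(0, 0, 1) else ax <- ax / n
  th <- stats::rnorm(1, 0, sd_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# state-like description restricted to one sequence: every designed residue
# carries exactly its threaded amino acid, repack-only residues their
# wildtype.  Cheap enough to rebuild per docking pose.
pose_pack <- function(spec, seq, structure, params = toy_energy_params()) {
  letters_ <- entity_letters(seq)
  aas <- lapply(seq_len(max(1, spec$correspondence$entity_length)),
                function(p) if (p <= length(letters_)) letters_[p] else "A")
  sp <- spec
  sp$structure <- structure
  ctx <- state_context(sp, allowed_aas = aas, params = params)
  if (nrow(ctx$universe$positions) == 0)
    return(list(energy = ctx$universe$e_const, assignment = integer(0)))
  problem <- build_packing_problem(ctx, seq)
  res <- pack_faster(problem)
  list(energy = res$energy, assignment = res$assignment$choice)
}

chain_spec <- function(spec, chain, name_suffix = chain) {
  ce <- spec$correspondence$entries
  sec <- spec$secondary
  state_spec(paste0(spec$name, "_", name_suffix),
             extract_chains(spec$structure, chain),
             new_correspondence(ce[ce$chain == chain, , drop = FALSE],
                                spec$correspondence$entity_length),
             sec[sec$chain == chain, , drop = FALSE])
}

#' Matched-backbone binding energy
#'
#' `dG = E(bound, packed) - E(chain 1 alone, packed) - E(chain 2 alone,
#' packed)`, all three packed with the same threaded sequence and with the
#' monomer backbones extracted from the complex itself.  Beyond the
#' interaction cutoff the three terms cancel exactly and `dG = 0`, which is
#' what caps the apparent destabilization any "undocked" arrangement can
#' contribute.
#'
#' @param spec a [state_spec()] whose structure has exactly two chains.
#' @param seq entity sequence threaded onto all species.
#' @param structure optional override of the spec's structure (e.g. a
#'   docked pose).
#' @param params a [toy_energy_params()].
#' @return binding energy in REU.
#' @export
binding_energy <- function(spec, seq, structure = NULL,
                           params = toy_energy_params()) {
  s <- structure %||% spec$structure
  if (length(s$chains) != 2) stop("binding_energy needs exactly 2 chains")
  eb <- pose_pack(spec, seq, s, params)$energy
  e1 <- pose_pack(chain_spec(spec, s$chains[1]), seq,
                  extract_chains(s, s$chains[1]), params)$energy
  e2 <- pose_pack(chain_spec(spec, s$chains[2]), seq,
                  extract_chains(s, s$chains[2]), params)$energy
  eb - e1 - e2
}

# Incremental pose evaluator: intra-chain energies are invariant under
# rigid motion of chain 2, so they are computed once; each pose recomputes
# only cross-chain one-body contributions, cross-chain pair submatrices and
# the cross-chain backbone background.  The mobile chain's placement is an
# affine map x -> A x + b of its base coordinates.
build_dock_evaluator <- function(spec, seq, params = toy_energy_params()) {
  s <- spec$structure
  ch <- s$chains
  letters_ <- entity_letters(seq)
  ce <- spec$correspondence$entries
  sec <- spec$secondary
  # packable positions with their single threaded amino acid
  pos <- rbind(
    if (nrow(ce) > 0) data.frame(chain = ce$chain, resnum = ce$resnum,
                                 aa = letters_[ce$entity_position]),
    if (nrow(sec) > 0) data.frame(chain = sec$chain, resnum = sec$resnum,
                                  aa = s$residues$aa[residue_index(
                                    s, sec$chain, sec$resnum)]))
  pos$index <- residue_index(s, pos$chain, pos$resnum)
  np <- nrow(pos)
  rot <- lapply(seq_len(np), function(r) {
    rr <- build_rotamers(s, pos$index[r], pos$aa[r], multistate_mode = TRUE,
                         params = params)
    list(centers = as.matrix(rr[, c("cx", "cy", "cz")]), radius = rr$radius,
         hydro = rr$hydrophobicity)
  })
  bb <- anchors(s)
  own <- s$residues$chain
  bbr <- params$backbone_sphere_radius
  mobile2 <- pos$chain == ch[2]
  res2 <- which(own == ch[2])
  # intra-chain one-body (vs same-chain backbone spheres, excluding own)
  ob_intra <- lapply(seq_len(np), function(r) {
    sel <- which(own == pos$chain[r]); sel <- setdiff(sel, pos$index[r])
    if (length(sel) == 0) return(rep(0, nrow(rot[[r]]$centers)))
    rowSums(pair_energy_block(rot[[r]]$centers, rot[[r]]$radius,
                              rot[[r]]$hydro, bb[sel, , drop = FALSE],
                              rep(bbr, length(sel)), rep(0, length(sel)),
                              params))
  })
  # intra-chain pair submatrices (fixed) and cross pairs (per pose)
  max_off <- vapply(pos$aa, function(a)
    if (AA_HEAVY[a] == 0) 0 else aa_offset(a, params), 1)
  reach <- params$pair_cutoff + outer(max_off, max_off, `+`)
  intra <- list(); ii <- integer(0); jj <- integer(0)
  cross_idx <- matrix(integer(0), 0, 2)
  for (i in seq_len(np - 1)) for (j in seq(i + 1, np)) {
    if (pos$chain[i] == pos$chain[j]) {
      d <- sqrt(sum((bb[pos$index[i], ] - bb[pos$index[j], ])^2))
      if (d <= reach[i, j]) {
        M <- pair_energy_block(rot[[i]]$centers, rot[[i]]$radius,
                               rot[[i]]$hydro, rot[[j]]$centers,
                               rot[[j]]$radius, rot[[j]]$hydro, params)
        if (any(M != 0)) {
          ii <- c(ii, i); jj <- c(jj, j); intra <- c(intra, list(M))
        }
      }
    } else cross_idx <- rbind(cross_idx, c(i, j))
  }
  e_intra <- backbone_background_energy(extract_chains(s, ch[1]), params) +
    backbone_background_energy(extract_chains(s, ch[2]), params)
  bb1 <- bb[own == ch[1], , drop = FALSE]
  bb2_base <- bb[res2, , drop = FALSE]
  cross_bg <- function(bb2) {
    d2 <- outer(rowSums(bb1^2), rowSums(bb2^2), `+`) - 2 * bb1 %*% t(bb2)
    sum(pair_energy_d(sqrt(pmax(d2, 0)), 2 * bbr, 0, params))
  }
  function(A, b) {
    bb2 <- bb2_base %*% t(A) + rep(b, each = nrow(bb2_base))
    bbx <- bb
    bbx[res2, ] <- bb2
    rotx <- rot
    for (r in which(mobile2)) {
      rotx[[r]]$centers <- rot[[r]]$centers %*% t(A) +
        rep(b, each = nrow(rot[[r]]$centers))
    }
    anch <- bbx[pos$index, , drop = FALSE]
    # cross one-body: rotamers vs the other chain's backbone spheres
    one_body <- lapply(seq_len(np), function(r) {
      sel <- which(own != pos$chain[r])
      ob_intra[[r]] + rowSums(pair_energy_block(
        rotx[[r]]$centers, rotx[[r]]$radius, rotx[[r]]$hydro,
        bbx[sel, , drop = FALSE], rep(bbr, length(sel)),
        rep(0, length(sel)), params))
    })
    pi <- ii; pj <- jj; mats <- intra
    for (k in seq_len(nrow(cross_idx))) {
      i <- cross_idx[k, 1]; j <- cross_idx[k, 2]
      d <- sqrt(sum((anch[i, ] - anch[j, ])^2))
      if (d <= reach[i, j]) {
        M <- pair_energy_block(rotx[[i]]$centers, rotx[[i]]$radius,
                               rotx[[i]]$hydro, rotx[[j]]$centers,
                               rotx[[j]]$radius, rotx[[j]]$hydro, params)
        if (any(M != 0)) { pi <- c(pi, i); pj <- c(pj, j); mats <- c(mats, list(M)) }
      }
    }
    ord <- order(pi, pj)
    prob <- new_packing_problem(
      positions = paste0(pos$chain, ":", pos$resnum),
      rotamer_aa = lapply(seq_len(np), function(r) rep(pos$aa[r], length(one_body[[r]]))),
      one_body = one_body, pi = pi[ord], pj = pj[ord], mats = mats[ord],
      e_const = e_intra + cross_bg(bb2))
    pack_faster(prob)$energy
  }
}

#' Rigid-body redocking (perturb-and-refine protocol)
#'
#' Each trajectory starts from the input conformation, applies a random
#' rigid-body perturbation of the mobile (second) chain -- per-axis normal
#' translation `trans_sd`, rotation about a random axis through the mobile
#' chain's centroid with angle sd `rot_sd` degrees -- and then runs
#' Metropolis rigid-body refinement (`refine_cycles` cycles of a 0.2-scaled
#' perturbation, full side-chain repack, accept at `kT`).  The best pose by
#' packed total energy over `n_traj` trajectories is returned together with
#' its matched-backbone binding energy.
#'
#' @param spec a [state_spec()] for the complex (two chains).
#' @param seq entity sequence.
#' @param n_traj number of independent trajectories.
#' @param seed numeric seed (each trajectory mixes its own stream).
#' @param trans_sd,rot_sd perturbation scales (Angstrom, degrees).
#' @param refine_cycles Monte-Carlo refinement cycles per trajectory.
#' @param kT Metropolis temperature for refinement.
#' @param structure optional starting conformation override.
#' @param params a [toy_energy_params()].
#' @return an object of class `dock_result`: `conformation`
#'   ([toy_structure()]), `total_energy`, `binding_energy`, `rotation`,
#'   `translation`.
#' @export
dock_pert <- function(spec, seq, n_traj = 50, seed = 0, trans_sd = 3,
                      rot_sd = 8, refine_cycles = 50, kT = 0.8,
                      structure = NULL, params = toy_energy_params()) {
  s0 <- structure %||% spec$structure
  if (length(s0$chains) != 2) stop("dock_pert needs exactly 2 chains")
  mobile <- s0$chains[2]
  sp <- spec; sp$structure <- s0
  evalE <- build_dock_evaluator(sp, seq, params)
  c0 <- colMeans(anchors(extract_chains(s0, mobile)))
  # affine pose state: mobile-chain coords x -> A x + b (base coordinates)
  compose <- function(A, b, Rc, tc) {
    cc <- as.vector(A %*% c0 + b)       # current centroid
    list(A = Rc %*% A, b = as.vector(Rc %*% (b - cc)) + cc + tc)
  }
  best <- NULL
  for (t in seq_len(n_traj)) {
    with_seed(stable_mix(seed, "dock", spec$name, t), {
      pose <- compose(diag(3), c(0, 0, 0), random_axis_rotation(rot_sd),
                      stats::rnorm(3, 0, trans_sd))
      E <- evalE(pose$A, pose$b)
      tbest <- list(pose = pose, E = E)
      for (cyc in seq_len(refine_cycles)) {
        cand <- compose(pose$A, pose$b, random_axis_rotation(0.2 * rot_sd),
                        stats::rnorm(3, 0, 0.2 * trans_sd))
        Ec <- evalE(cand$A, cand$b)
        if (Ec <= E || runif(1) < exp(-(Ec - E) / kT)) {
          pose <- cand; E <- Ec
          if (E < tbest$E) tbest <- list(pose = pose, E = E)
        }
      }
      if (is.null(best) || tbest$E < best$E) best <- tbest
    })
  }
  # materialize the winning conformation
  conf <- transform_chains(s0, mobile, best$pose$A,
                           translation = as.vector(
                             best$pose$A %*% c0 + best$pose$b) - c0,
                           center = c0)
  dg <- binding_energy(sp, seq, structure = conf, params = params)
  structure(list(conformation = conf, total_energy = best$E,
                 binding_energy = dg, rotation = best$pose$A,
                 translation = best$pose$b),
            class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat("dock_result: total", format(x$total_energy, digits = 8),
      "REU, binding", format(x$binding_energy, digits = 8), "REU\n")
  invisible(x)
}

#' Energy and diversity filtering of docked conformations
#'
#' Keeps conformations with binding energy at or below `dG_keep`, then makes
#' a greedy pass in ascending binding-energy order keeping a conformation
#' only if its mutual C-alpha RMS (without superposition) to every already
#' kept conformation -- including any in `existing` -- is at least
#' `rms_min`.  Idempotent by construction.
#'
#' @param confs list of `dock_result`s.
#' @param dG_keep binding-energy admission threshold (REU).
#' @param rms_min minimum mutual RMS between kept conformations (Angstrom).
#' @param existing list of [toy_structure()]s already in the ensemble.
#' @return list of [toy_structure()]s, each with a `binding_energy`
#'   attribute.
#' @export
filter_conformations <- function(confs, dG_keep = -1, rms_min = 0.5,
                                 existing = list()) {
  dgs <- vapply(confs, function(cf) cf$binding_energy, 1)
  confs <- confs[dgs <= dG_keep]
  dgs <- dgs[dgs <= dG_keep]
  kept <- list()
  for (i in order(dgs)) {
    s <- confs[[i]]$conformation
    ok <- TRUE
    for (k in c(existing, kept)) {
      if (rms_no_superposition(s, k) < rms_min) { ok <- FALSE; break }
    }
    if (ok) {
      attr(s, "binding_energy") <- dgs[i]
      kept[[length(kept) + 1]] <- s
    }
  }
  kept
}
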