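#' Build a coarse-grained Go-type model from a reference structure
#'
#' Constructs a bead-per-residue structure-based model: harmonic virtual
#' bonds between consecutive beads, attractive 12-10 Lennard-Jones native
#' wells for every non-adjacent bead pair within `contact_cutoff` of the
#' reference geometry, excluded-volume repulsion for all remaining pairs,
#' and harmonic pair restraints drawing the CCHC Zn-finger quartet
#' (C200, C203, H220, C227) together when those residues are present. The
#' 166-185 helix-helix pair, the surrogate for the hydrogen bond tying the
#' first two helices, gets a deepened well (`hbond_eps_factor * eps`).
#'
#' @param reference List with `resid` (unique 1-based residue ids) and
#'   `coords` (n x 3 matrix, Angstrom), e.g. [bir2_reference()].
#' @param contact_cutoff Native-contact distance cutoff, Angstrom; must
#'   exceed the longest virtual bond.
#' @param eps Native-contact well depth, kcal/mol.
#' @param bond_k Virtual-bond spring constant, kcal/mol/A^2.
#' @param zn_k Zn-finger restraint spring constant, kcal/mol/A^2.
#' @param rep_sigma,rep_eps Excluded-volume size (A) and strength (kcal/mol).
#' @param hbond_eps_factor Well-depth multiplier for the 166-185 surrogate.
#' @return Object of class `cg_model`: `resid`, `coords`, `bonds`,
#'   `contacts`, `restraints`, `tethers` tibbles (pair columns hold residue
#'   ids) plus the scalar parameters.
#' @export
build_cg_model <- function(reference, contact_cutoff = 6.5, eps = 0.7,
                           bond_k = 100, zn_k = 5,
                           rep_sigma = 4, rep_eps = 1,
                           hbond_eps_factor = 2) {
  resid <- as.integer(reference$resid)
  coords <- reference$coords
  n <- length(resid)
  stopifnot(n >= 3, nrow(coords) == n)
  if (anyDuplicated(resid)) abort("residue ids must be unique")

  d <- as.matrix(stats::dist(coords))
  bond_len <- d[cbind(seq_len(n - 1), 2:n)]
  if (contact_cutoff <= max(bond_len)) {
    abort("contact_cutoff must exceed the longest virtual bond length")
  }

  bonds <- tibble(i = resid[seq_len(n - 1)], j = resid[2:n],
                  r0 = bond_len, k = bond_k)

  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  pair_idx <- which(upper.tri(d) & sep >= 2 & d < contact_cutoff,
                    arr.ind = TRUE)
  contacts <- tibble(i = resid[pair_idx[, 1]], j = resid[pair_idx[, 2]],
                     r0 = d[pair_idx], eps = eps)
  hb <- (contacts$i == 166 & contacts$j == 185) |
    (contacts$i == 185 & contacts$j == 166)
  contacts$eps[hb] <- eps * hbond_eps_factor

  zn_ids <- intersect(resid, c(200L, 203L, 220L, 227L))
  restraints <- tibble(i = integer(), j = integer(), r0 = numeric(),
                       k = numeric(), label = character())
  if (length(zn_ids) >= 2) {
    zp <- utils::combn(sort(zn_ids), 2)
    restraints <- tibble(
      i = zp[1, ], j = zp[2, ],
      r0 = d[cbind(match(zp[1, ], resid), match(zp[2, ], resid))],
      k = zn_k, label = "zn")
  }

  structure(
    list(resid = resid, coords = coords, bonds = bonds, contacts = contacts,
         restraints = restraints,
         tethers = tibble(i = integer(), x = numeric(), y = numeric(),
                          z = numeric(), k = numeric()),
         rep_sigma = rep_sigma, rep_eps = rep_eps),
    class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat("<cg_model>", length(x$resid), "beads,",
      nrow(x$contacts), "native contacts,",
      nrow(x$restraints), "restraints\n")
  invisible(x)
}

# pack a cg_model into the flat index-based list the compiled core expects;
# every non-bonded pair that is not a native contact becomes repulsive
cg_pack <- function(model) {
  resid <- model$resid
  n <- length(resid)
  ix <- function(r) match(r, resid)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  all_pairs <- which(upper.tri(sep) & sep >= 2, arr.ind = TRUE)
  key <- paste(pmin(ix(model$contacts$i), ix(model$contacts$j)),
               pmax(ix(model$contacts$i), ix(model$contacts$j)))
  allkey <- paste(all_pairs[, 1], all_pairs[, 2])
  rep_pairs <- all_pairs[!(allkey %in% key), , drop = FALSE]
  list(bond_i = ix(model$bonds$i), bond_j = ix(model$bonds$j),
       bond_r0 = model$bonds$r0, bond_k = model$bonds$k,
       con_i = ix(model$contacts$i), con_j = ix(model$contacts$j),
       con_r0 = model$contacts$r0, con_eps = model$contacts$eps,
       rep_i = rep_pairs[, 1], rep_j = rep_pairs[, 2],
       rep_sigma = rep(model$rep_sigma, nrow(rep_pairs)),
       rep_eps = rep(model$rep_eps, nrow(rep_pairs)),
       res_i = ix(model$restraints$i), res_j = ix(model$restraints$j),
       res_r0 = model$restraints$r0, res_k = model$restraints$k,
       teth_i = ix(model$tethers$i),
       teth_xyz = cbind(model$tethers$x, model$tethers$y, model$tethers$z),
       teth_k = model$tethers$k)
}

#' Catalog of simulated BIR2 variants and their destabilization mechanisms
#'
#' The eight simulated pathogenic variants plus wild type, each assigned one
#' of four mechanism classes: collapse of the 11-residue hydrophobic core
#' (W173G, L189P, V198M, L207P), loss of the 166-185 helix-helix hydrogen
#' bond (R166I, R166K), spatial rearrangement around the buried 188 position
#' and the 201-204 turn (G188E), and Zn-finger loss (H220Y). The previously
#' characterized Zn-finger variants C203Y and G204del are listed but excluded
#' from the default simulation set (`simulated = FALSE`).
#'
#' @return Tibble with columns `name`, `mechanism`, `resid`, `simulated`.
#' @export
variant_catalog <- function() {
  tibble(
    name = c("WT", "R166I", "R166K", "W173G", "G188E", "L189P", "V198M",
             "L207P", "H220Y", "C203Y", "G204del"),
    mechanism = c("none", "helix_hbond_loss", "helix_hbond_loss",
                  "core_collapse", "rearrangement", "core_collapse",
                  "core_collapse", "core_collapse", "zn_loss", "zn_loss",
                  "zn_loss"),
    resid = c(NA, 166L, 166L, 173L, 188L, 189L, 198L, 207L, 220L, 203L,
              204L),
    simulated = c(TRUE, rep(TRUE, 8), FALSE, FALSE))
}

#' Apply a variant perturbation to a coarse-grained model
#'
#' Returns a perturbed copy of the model; the input is left unmodified.
#' Perturbations by mechanism class:
#' \describe{
#'   \item{none}{identity (wild type).}
#'   \item{core_collapse}{deletes every native contact of the mutated
#'     residue (deleted pairs revert to plain excluded-volume repulsion).}
#'   \item{helix_hbond_loss}{deletes the 166-185 surrogate contact.}
#'   \item{rearrangement}{weakens (well depth x `weaken_factor`) every
#'     contact touching the 201-204 turn or the 187-189 neighbourhood of
#'     the buried 188 position.}
#'   \item{zn_loss}{removes all Zn-finger restraints.}
#' }
#'
#' @param model A [build_cg_model()] object.
#' @param spec One row of [variant_catalog()] (or a data frame with `name`,
#'   `mechanism`, `resid`).
#' @param weaken_factor Multiplier for weakened contacts (rearrangement).
#' @return A perturbed `cg_model`.
#' @export
apply_variant <- function(model, spec, weaken_factor = 0.25) {
  stopifnot(inherits(model, "cg_model"), is.data.frame(spec), nrow(spec) == 1)
  mech <- spec$mechanism
  known <- c("none", "core_collapse", "helix_hbond_loss", "rearrangement",
             "zn_loss")
  if (!mech %in% known) abort(paste("unknown mechanism:", mech))
  if (!is.na(spec$resid) && !spec$resid %in% model$resid) {
    abort(sprintf("variant residue %d not present in the model", spec$resid))
  }
  out <- model
  if (mech == "core_collapse") {
    keep <- out$contacts$i != spec$resid & out$contacts$j != spec$resid
    out$contacts <- out$contacts[keep, ]
  } else if (mech == "helix_hbond_loss") {
    hb <- (out$contacts$i == 166 & out$contacts$j == 185) |
      (out$contacts$i == 185 & out$contacts$j == 166)
    out$contacts <- out$contacts[!hb, ]
  } else if (mech == "rearrangement") {
    nb <- c(187:189, 201:204)
    touch <- out$contacts$i %in% nb | out$contacts$j %in% nb
    out$contacts$eps[touch] <- out$contacts$eps[touch] * weaken_factor
  } else if (mech == "zn_loss") {
    out$restraints <- out$restraints[out$restraints$label != "zn", ]
  }
  out
}

#' Fraction of wild-type native contacts formed per frame
#'
#' A contact counts as formed when the bead pair sits within
#' `formed_factor` times its native distance.
#'
#' @param traj A [cg_trajectory()].
#' @param model The (wild-type) `cg_model` providing the contact list.
#' @param formed_factor Distance multiplier defining "formed" (default 1.2).
#' @return Tibble with columns `frame`, `q`.
#' @export
native_contact_fraction <- function(traj, model, formed_factor = 1.2) {
  stopifnot(inherits(traj, "cg_trajectory"), inherits(model, "cg_model"))
  ii <- match(model$contacts$i, traj$resid)
  jj <- match(model$contacts$j, traj$resid)
  if (anyNA(ii) || anyNA(jj)) abort("contact residues missing from trajectory")
  thr <- (model$contacts$r0 * formed_factor)^2
  q <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- traj_frame(traj, f)
    dv <- x[ii, , drop = FALSE] - x[jj, , drop = FALSE]
    mean(rowSums(dv^2) <= thr)
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), q = q)
}
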