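#' @name metrics
#' @title Interface quality metrics
#'
#' @description
#' The four CAPRI interface metrics for one (model, target-interface) pair:
#'
#' * `fnat` -- fraction of the target's native inter-chain residue contacts
#'   recalled by the model. The denominator is always the target's contact
#'   count; contacts whose residues are missing from the model count as not
#'   recalled, so truncated models cannot inflate recall.
#' * `lrms` -- backbone RMSD of the ligand chain after superposing the
#'   receptor backbones over the common residue set (no re-fit on the
#'   ligand).
#' * `irms` -- backbone RMSD over the interface residues (10 Angstrom rule,
#'   defined on the target) after superposing those residues themselves.
#' * `srms` -- RMSD over side-chain heavy atoms of the interface residues,
#'   evaluated under the `irms` backbone fit; `NA` when no side-chain atom
#'   is shared (e.g. an all-glycine interface).
#'
#' All distances use heavy atoms only; hydrogens are stripped at parse time.
NULL

# matched (target, model) atom coordinate pairs for a set of target residues
matched_coords <- function(model, target, corr, target_keys,
                           part = c("backbone", "sidechain", "all")) {
  part <- match.arg(part)
  sel <- corr[corr$target_key %in% target_keys, , drop = FALSE]
  t_at <- target; t_at$key <- atom_keys(target)
  t_at <- t_at[t_at$key %in% sel$target_key, , drop = FALSE]
  if (part == "backbone") {
    t_at <- t_at[t_at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  } else if (part == "sidechain") {
    t_at <- t_at[!(t_at$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  }
  m_at <- model; m_at$key <- atom_keys(model)
  m_at <- m_at[m_at$key %in% sel$model_key, , drop = FALSE]
  mk <- stats::setNames(sel$model_key, sel$target_key)
  t_at$mkey <- unname(mk[t_at$key])
  j <- inner_join(
    as_tibble(t_at)[, c("key", "mkey", "elety", "x", "y", "z")],
    as_tibble(m_at)[, c("key", "elety", "x", "y", "z")],
    by = c(mkey = "key", elety = "elety"), suffix = c("_t", "_m"))
  list(target = as.matrix(j[, c("x_t", "y_t", "z_t")]),
       model = as.matrix(j[, c("x_m", "y_m", "z_m")]),
       n = nrow(j))
}

# model-side chains corresponding to the interface's receptor/ligand chains
model_chains_for <- function(corr, iface) {
  cm <- attr(corr, "chain_map")
  list(rec = names(cm)[match(iface$receptor_chain, cm)],
       lig = names(cm)[match(iface$ligand_chain, cm)])
}

#' Fraction of native contacts recalled by the model
#'
#' @param model an `assembly`.
#' @param corr `residue_correspondence` (model vs the interface's target).
#' @param iface an `interface_def` from [native_contacts()].
#' @return Fraction in \[0, 1\].
#' @export
fnat <- function(model, corr, iface) {
  nc <- iface$native_contacts
  if (nrow(nc) == 0) abort("interface has no native contacts (non-assessable)")
  mc <- model_chains_for(corr, iface)
  if (is.na(mc$rec) || is.na(mc$lig)) return(0)
  model_pairs <- residue_contact_pairs(model, mc$rec, mc$lig,
                                       iface$contact_threshold)
  mk <- stats::setNames(corr$model_key, corr$target_key)
  have <- paste(model_pairs$key_a, model_pairs$key_b)
  want <- paste(mk[nc$rec_key], mk[nc$lig_key])  # NA when residue missing
  mean(want %in% have)
}

common_chain_keys <- function(corr, chain) {
  corr$target_key[corr$target_chain == chain]
}

#' Ligand RMSD after receptor superposition
#'
#' @inheritParams fnat
#' @param target the reference `assembly`.
#' @return RMSD in Angstrom, or `NA` when fewer than 3 backbone atoms are
#'   shared on either chain (non-assessable).
#' @export
lrms <- function(model, target, corr, iface) {
  rec_keys <- common_chain_keys(corr, iface$receptor_chain)
  lig_keys <- common_chain_keys(corr, iface$ligand_chain)
  rec <- matched_coords(model, target, corr, rec_keys, "backbone")
  lig <- matched_coords(model, target, corr, lig_keys, "backbone")
  if (rec$n < 3 || lig$n < 3) return(NA_real_)
  sp <- superpose(rec$model, rec$target)
  rmsd_pts(apply_superposition(lig$model, sp), lig$target)
}

# the irms superposition, reused by srms
irms_fit <- function(model, target, corr, iface) {
  keys <- intersect(iface$interface_residues, corr$target_key)
  bb <- matched_coords(model, target, corr, keys, "backbone")
  if (bb$n < 3) return(NULL)
  list(sp = superpose(bb$model, bb$target), keys = keys)
}

#' Interface RMSD
#'
#' @inheritParams lrms
#' @return RMSD in Angstrom of the interface-backbone fit, or `NA` when
#'   fewer than 3 interface backbone atoms are shared.
#' @export
irms <- function(model, target, corr, iface) {
  fit <- irms_fit(model, target, corr, iface)
  if (is.null(fit)) return(NA_real_)
  fit$sp$rmsd
}

#' Side-chain RMSD under the interface-backbone fit
#'
#' @inheritParams lrms
#' @return RMSD in Angstrom, or `NA` when the interface shares no side-chain
#'   heavy atom (flagged undefined) or the `irms` fit is unavailable.
#' @export
srms <- function(model, target, corr, iface) {
  fit <- irms_fit(model, target, corr, iface)
  if (is.null(fit)) return(NA_real_)
  sc <- matched_coords(model, target, corr, fit$keys, "sidechain")
  if (sc$n < 1) return(NA_real_)
  rmsd_pts(apply_superposition(sc$model, fit$sp), sc$target)
}

#' All metrics for one model interface
#'
#' @inheritParams lrms
#' @param clash_threshold Angstrom (default 3).
#' @return One-row tibble: `interface_id`, `fnat`, `lrms`, `irms`, `srms`,
#'   `clashes`, `n_common` (common residues across the two chains),
#'   `assessable`.
#' @export
interface_metrics <- function(model, target, corr, iface, clash_threshold = 3) {
  mc <- model_chains_for(corr, iface)
  n_common <- sum(corr$target_chain %in%
                    c(iface$receptor_chain, iface$ligand_chain))
  if (!iface$assessable || is.na(mc$rec) || is.na(mc$lig) || n_common == 0) {
    return(tibble(interface_id = iface$id, fnat = NA_real_, lrms = NA_real_,
                  irms = NA_real_, srms = NA_real_, clashes = NA_integer_,
                  n_common = n_common, assessable = FALSE))
  }
  tibble(
    interface_id = iface$id,
    fnat = fnat(model, corr, iface),
    lrms = lrms(model, target, corr, iface),
    irms = irms(model, target, corr, iface),
    srms = srms(model, target, corr, iface),
    clashes = clash_count(model, mc$rec, mc$lig, clash_threshold),
    n_common = n_common,
    assessable = TRUE)
}
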