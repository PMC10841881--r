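#' Inter-set neighbor pairs via a spatial grid
#'
#' Cell-list search: atoms are binned into cubic cells of edge `cutoff`, and
#' only the 27 neighboring cells of each query atom are examined. Exact: the
#' returned pairs equal those of a full all-pairs scan.
#'
#' @param a,b n x 3 coordinate matrices.
#' @param cutoff distance cutoff in Angstrom (strict `<`).
#' @return Tibble `i` (row in `a`), `j` (row in `b`), `d` (distance).
#' @export
neighbor_pairs <- function(a, b, cutoff) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(cutoff > 0)
  ca <- floor(a / cutoff); cb <- floor(b / cutoff)
  bkey <- paste(cb[, 1], cb[, 2], cb[, 3])
  bmap <- split(seq_len(nrow(b)), bkey)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(offs))) {
    key <- paste(ca[, 1] + offs[k, 1], ca[, 2] + offs[k, 2], ca[, 3] + offs[k, 3])
    hit <- bmap[key]
    n <- lengths(hit)
    if (sum(n) == 0) next
    ii <- c(ii, rep.int(seq_len(nrow(a)), n))
    jj <- c(jj, unlist(hit, use.names = FALSE))
  }
  if (length(ii) == 0) return(tibble(i = integer(0), j = integer(0), d = numeric(0)))
  d <- sqrt(rowSums((a[ii, , drop = FALSE] - b[jj, , drop = FALSE])^2))
  keep <- d < cutoff
  ord <- order(ii[keep], jj[keep])
  tibble(i = ii[keep][ord], j = jj[keep][ord], d = d[keep][ord])
}

# residue-level contact pairs between two chains of one assembly
residue_contact_pairs <- function(s, chain_a, chain_b, cutoff) {
  A <- chain_atoms(s, chain_a); B <- chain_atoms(s, chain_b)
  np <- neighbor_pairs(coords(A), coords(B), cutoff)
  if (nrow(np) == 0) {
    return(tibble(key_a = character(0), key_b = character(0)))
  }
  distinct(tibble(key_a = atom_keys(A)[np$i], key_b = atom_keys(B)[np$j]))
}

#' Native contacts and interface residues of a target chain pair
#'
#' A residue pair (one residue per chain) is a native contact when any of its
#' heavy-atom pairs lies below `contact_threshold` (5 Angstrom default, the
#' CAPRI/DockQ convention). Interface residues are defined separately: any
#' residue with a heavy atom within `interface_threshold` (10 Angstrom) of
#' any atom of the partner chain. The receptor is the chain of the pair with
#' more residues (ties broken by chain id), fixing the asymmetric L_rms
#' convention.
#'
#' @param target `assembly` of the reference complex.
#' @param chain_a,chain_b the two chain ids.
#' @param contact_threshold,interface_threshold Angstrom.
#' @return List of class `interface_def`: `receptor_chain`, `ligand_chain`,
#'   `native_contacts` (tibble `rec_key`, `lig_key`), `interface_residues`
#'   (character keys over both chains), thresholds, and `assessable`.
#' @export
native_contacts <- function(target, chain_a, chain_b,
                            contact_threshold = 5, interface_threshold = 10) {
  stopifnot(contact_threshold > 0, interface_threshold > 0)
  ids <- chain_ids(target)
  if (!all(c(chain_a, chain_b) %in% ids)) {
    abort("both chains must exist in the target")
  }
  nres <- residue_table(target) |> count(.data$chain)
  na <- nres$n[nres$chain == chain_a]; nb <- nres$n[nres$chain == chain_b]
  if (na > nb || (na == nb && chain_a < chain_b)) {
    rec <- chain_a; lig <- chain_b
  } else {
    rec <- chain_b; lig <- chain_a
  }
  contacts <- residue_contact_pairs(target, rec, lig, contact_threshold)
  names(contacts) <- c("rec_key", "lig_key")
  iface <- residue_contact_pairs(target, rec, lig, interface_threshold)
  interface_residues <- unique(c(iface$key_a, iface$key_b))
  structure(list(
    id = paste0(rec, ":", lig),
    receptor_chain = rec, ligand_chain = lig,
    native_contacts = contacts,
    interface_residues = interface_residues,
    contact_threshold = contact_threshold,
    interface_threshold = interface_threshold,
    assessable = nrow(contacts) > 0
  ), class = "interface_def")
}

#' Count inter-chain atomic clashes
#'
#' Clashes are inter-chain heavy-atom pairs closer than `clash_threshold`
#' (3 Angstrom); models with too many clashes are disqualified (see
#' [disqualify_clashes()]).
#'
#' @param model an `assembly`.
#' @param receptor,ligand chain ids in the model.
#' @param clash_threshold Angstrom (default 3).
#' @return Integer count of clashing atom pairs.
#' @export
clash_count <- function(model, receptor, ligand, clash_threshold = 3) {
  A <- chain_atoms(model, receptor); B <- chain_atoms(model, ligand)
  nrow(neighbor_pairs(coords(A), coords(B), clash_threshold))
}

#' Flag models with too many clashes
#'
#' The disqualification threshold is batch-relative: a model is flagged when
#' its clash count exceeds the mean + 2 SD over all models submitted for the
#' target. With a single model (no batch context) an absolute cap applies
#' instead; the default cap is `Inf`, i.e. no single-model disqualification.
#'
#' @param clashes integer vector of clash counts (one per model).
#' @param cap absolute fallback cap for a single model.
#' @return Logical vector, `TRUE` = disqualified.
#' @export
disqualify_clashes <- function(clashes, cap = Inf) {
  if (length(clashes) >= 2 && stats::sd(clashes) > 0) {
    clashes > mean(clashes) + 2 * stats::sd(clashes)
  } else {
    clashes > cap
  }
}
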