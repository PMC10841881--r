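#' @import dplyr
#' @import tibble
#' @importFrom rlang .data abort warn
#' @importFrom purrr map map_chr map_int map_dbl imap keep
NULL

# Three-letter -> one-letter amino-acid code, with common modified residues
# mapped to their parent amino acid (MSE -> M etc.).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S", TPO = "T",
  PTR = "Y", CSO = "C", MLY = "K"
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct an assembly structure from an atom-level data frame
#'
#' An assembly is stored as a tibble with one row per heavy atom and columns
#' `chain`, `resno`, `ins`, `resid`, `elety`, `element`, `x`, `y`, `z`, `o`.
#' Hydrogens must already be absent; [read_structure()] guarantees this.
#'
#' @param atoms data frame with the columns above (`ins` and `o` optional).
#' @param source_format "PDB", "mmCIF" or "synthetic".
#' @return A tibble of class `assembly`.
#' @export
as_assembly <- function(atoms, source_format = "synthetic") {
  atoms <- as_tibble(atoms)
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"o" %in% names(atoms)) atoms$o <- 1
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[0-9']", "", atoms$elety), 1, 1)
  }
  need <- c("chain", "resno", "ins", "resid", "elety", "element",
            "x", "y", "z", "o")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) {
    abort(paste("assembly atoms lack columns:", paste(missing, collapse = ", ")))
  }
  atoms <- atoms[, need]
  atoms$ins[is.na(atoms$ins)] <- ""
  if (nrow(atoms) == 0) abort("empty structure: no protein atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    abort("occupancy outside [0, 1]")
  }
  structure(atoms,
            class = c("assembly", setdiff(class(atoms), "assembly")),
            source_format = source_format)
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d chains, %d residues, %d atoms (%s)\n",
              length(chain_ids(x)), nrow(residue_table(x)), nrow(x),
              attr(x, "source_format") %||% "?"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain identifiers of an assembly, in file order
#' @param s an `assembly`.
#' @return Character vector of chain ids.
#' @export
chain_ids <- function(s) unique(s$chain)

#' Residue-level view of an assembly
#'
#' @param s an `assembly`.
#' @return Tibble with one row per residue (`chain`, `resno`, `ins`, `resid`,
#'   `key`), in atom order.
#' @export
residue_table <- function(s) {
  s |>
    distinct(.data$chain, .data$resno, .data$ins, .data$resid) |>
    mutate(key = res_key(.data$chain, .data$resno, .data$ins))
}

res_key <- function(chain, resno, ins) paste(chain, resno, ins, sep = "|")

atom_keys <- function(s) res_key(s$chain, s$resno, s$ins)

#' One-letter sequence of one chain
#'
#' Unknown residue names become "X".
#' @param s an `assembly`.
#' @param chain chain id.
#' @return A single string.
#' @export
chain_sequence <- function(s, chain) {
  rt <- residue_table(s) |> filter(.data$chain == !!chain)
  paste(dplyr::coalesce(AA3TO1[rt$resid], "X"), collapse = "")
}

coords <- function(s) as.matrix(s[, c("x", "y", "z")])

chain_atoms <- function(s, chain) s[s$chain == chain, , drop = FALSE]

#' Stoichiometry of an assembly
#'
#' Chains are grouped into sequence-equivalence classes (exact sequence
#' identity); classes are labelled A, B, ... by decreasing copy number then
#' first occurrence.
#'
#' @param s an `assembly`.
#' @return Tibble with `class`, `chains` (list column), `n`; the compact
#'   formula (e.g. "A2", "A3B1") is in attribute `formula`.
#' @export
stoichiometry <- function(s) {
  ids <- chain_ids(s)
  seqs <- vapply(ids, function(ch) chain_sequence(s, ch), character(1))
  cls <- split(ids, factor(seqs, levels = unique(seqs)))
  ord <- order(-lengths(cls), vapply(cls, function(x) match(x[1], ids), 1L))
  cls <- cls[ord]
  out <- tibble(
    class = LETTERS[seq_along(cls)],
    chains = unname(cls),
    n = lengths(cls)
  )
  attr(out, "formula") <- paste0(out$class, out$n, collapse = "")
  out
}

#' Sequence-equivalence class of every chain
#' @param s an `assembly`.
#' @return Named character vector chain id -> class label.
#' @keywords internal
chain_classes <- function(s) {
  st <- stoichiometry(s)
  out <- character(0)
  for (i in seq_len(nrow(st))) out[st$chains[[i]]] <- st$class[i]
  out
}

#' Backbone / side-chain atom split
#'
#' Backbone is the set {N, CA, C, O}; side chain is every other heavy atom.
#' @param s an `assembly`.
#' @param backbone if `TRUE` keep backbone atoms, else side-chain atoms.
#' @return Filtered `assembly` rows.
#' @export
backbone <- function(s, backbone = TRUE) {
  if (backbone) s[s$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  else s[!(s$elety %in% BACKBONE_ATOMS), , drop = FALSE]
}

#' Apply a rigid transform to (part of) an assembly
#'
#' @param s an `assembly`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector, applied after rotation.
#' @param chains chains to transform (default all).
#' @param center rotation center (default origin).
#' @return Transformed `assembly`.
#' @export
transform_assembly <- function(s, rotation = diag(3), translation = c(0, 0, 0),
                               chains = NULL, center = c(0, 0, 0)) {
  idx <- if (is.null(chains)) rep(TRUE, nrow(s)) else s$chain %in% chains
  xyz <- coords(s)[idx, , drop = FALSE]
  xyz <- sweep(xyz, 2, center)
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, center + translation, FUN = "+")
  s$x[idx] <- xyz[, 1]; s$y[idx] <- xyz[, 2]; s$z[idx] <- xyz[, 3]
  s
}
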