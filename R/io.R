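#' Read an assembly structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d (`read.pdb` / `read.cif`); the result is
#' normalized into the package's atom-level tibble: hydrogens (and deuterium)
#' are stripped, HETATM records are dropped except for modified amino acids
#' with a standard parent (MSE and friends), and for alternate locations only
#' the highest-occupancy conformer is kept (ties broken by altloc letter).
#'
#' @param path file path.
#' @param format_hint "pdb", "cif"/"mmcif", or `NULL` to infer from the file
#'   extension (default pdb).
#' @return An [as_assembly()] tibble.
#' @export
read_structure <- function(path, format_hint = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  fmt <- tolower(format_hint %||% tools::file_ext(path))
  fmt <- switch(fmt, cif = , mmcif = "mmCIF", "PDB")
  raw <- tryCatch(
    if (fmt == "mmCIF") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
    } else {
      suppressMessages(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
    },
    error = function(e) abort(paste0("cannot parse ", path, " as ", fmt,
                                     ": ", conditionMessage(e)))
  )
  at <- raw$atom
  keep <- at$type == "ATOM" | at$resid %in% names(AA3TO1)
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem))) {
    elem <- substr(gsub("^[0-9]*", "", at$elety), 1, 1)
  }
  elem <- toupper(trimws(elem))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(elem %in% c("H", "D"))]
  if (nrow(at) == 0) abort(paste("empty structure (no protein heavy atoms):", path))

  atoms <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt))
  )
  # altloc: highest occupancy wins, ties by altloc letter order; file
  # order of the surviving atoms is preserved
  atoms <- atoms |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$chain, .data$resno, .data$ins, .data$elety) |>
    arrange(desc(.data$o), .data$alt, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-"alt", -".row")
  as_assembly(atoms, source_format = fmt)
}

#' Write an assembly structure to PDB or mmCIF
#'
#' Coordinates are written at PDB precision (3 decimals); a read/write
#' round-trip preserves the chain/residue/atom inventory exactly and
#' coordinates to 1e-3 Angstrom.
#'
#' @param s an `assembly`.
#' @param path output file path.
#' @param format "pdb" (default) or "cif".
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  if (!inherits(s, "assembly") || nrow(s) == 0) {
    abort("write_structure() needs a non-empty assembly")
  }
  lines <- if (format == "pdb") format_pdb(s) else format_mmcif(s)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) abort(paste("cannot write", path, ":",
                                                 conditionMessage(e))))
  invisible(path)
}

format_pdb <- function(s) {
  out <- character(0)
  serial <- 0L
  for (ch in chain_ids(s)) {
    ca <- chain_atoms(s, ch)
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1L
      name <- ca$elety[i]
      # atom-name column convention: 1-3 char names start in column 14
      name <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else name
      out <- c(out, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name, ca$resid[i], ch, ca$resno[i],
        ifelse(ca$ins[i] == "", " ", ca$ins[i]),
        ca$x[i], ca$y[i], ca$z[i], ca$o[i], 0, ca$element[i]))
    }
    last <- ca[nrow(ca), ]
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d", serial, last$resid,
                          ch, last$resno))
  }
  c(out, "END")
}

format_mmcif <- function(s) {
  hdr <- c(
    "data_capriq",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
    seq_len(nrow(s)), s$element, s$elety, s$resid, s$chain, s$resno,
    ifelse(s$ins == "", "?", s$ins), s$x, s$y, s$z, s$o,
    s$resno, s$resid, s$chain, s$elety)
  c(hdr, rows, "#")
}
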