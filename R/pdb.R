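#' Parse a protein structure from PDB-format text
#'
#' Reads fixed-column `ATOM`/`HETATM` records into a `structure_model`: a light
#' wrapper holding the protein atoms as a tibble, the co-crystallized ligand
#' heteroatoms (if any), the structure id and the crystallographic resolution.
#' Crystallographic waters (`HOH`, `WAT`, `DOD`) are dropped. Resolution is
#' taken from the `REMARK   2 RESOLUTION.` header unless overridden.
#'
#' @param text character; either a single PDB-format string or a character
#'   vector of lines.
#' @param id 4-character structure identifier; defaults to the `HEADER` idCode
#'   when present, else `"XXXX"`.
#' @param ligand_code optional 3-character HET code naming the co-crystallized
#'   ligand. When `NULL`, every non-water `HETATM` is treated as ligand.
#' @param resolution optional resolution override in Angstrom (for headerless
#'   fixtures).
#' @return A `structure_model`: list with elements `id`, `resolution`, `atoms`
#'   (tibble: serial, name, residue_name, chain, residue_number, element,
#'   x, y, z) and `het_ligand` (same columns, possibly 0 rows).
#' @examples
#' pdb <- gen_toy_complex(n_residues = 5, hot_positions = 3, seed = 1)
#' txt <- write_pdb(pdb$receptor)
#' read_pdb(txt)
#' @export
read_pdb <- function(text, id = NULL, ligand_code = NULL, resolution = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) {
    abort("no ATOM/HETATM records found in PDB input", class = "dockscreen_parse_error")
  }
  if (is.null(resolution)) {
    rem2 <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(rem2)) {
      resolution <- suppressWarnings(
        as.numeric(stringr::str_match(rem2[1], "RESOLUTION\\.\\s+([0-9.]+)")[, 2])
      )
    }
  }
  if (is.null(id)) {
    hdr <- grep("^HEADER", lines, value = TRUE)
    id <- if (length(hdr) && nchar(hdr[1]) >= 66) {
      trimws(substr(hdr[1], 63, 66))
    } else {
      "XXXX"
    }
    if (!nzchar(id)) id <- "XXXX"
  }

  idx <- which(is_atom)
  al <- lines[idx]
  num_field <- function(s, from, to, what) {
    raw <- trimws(substr(s, from, to))
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(out) | !nzchar(raw))
    if (length(bad)) {
      abort(
        sprintf("unparseable %s field '%s' at PDB line %d", what, raw[bad[1]], idx[bad[1]]),
        class = "dockscreen_parse_error"
      )
    }
    out
  }
  atoms <- tibble(
    record = rec[idx],
    serial = as.integer(num_field(al, 7, 11, "serial")),
    name = trimws(substr(al, 13, 16)),
    residue_name = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    residue_number = as.integer(num_field(al, 23, 26, "residue number")),
    element = trimws(substr(al, 77, 78)),
    x = num_field(al, 31, 38, "x coordinate"),
    y = num_field(al, 39, 46, "y coordinate"),
    z = num_field(al, 47, 54, "z coordinate")
  )
  # element column is optional in older files; fall back to the atom name
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- substr(gsub("[^A-Za-z].*", "", atoms$name[noel]), 1, 1)
  atoms <- filter(atoms, !.data$residue_name %in% c("HOH", "WAT", "DOD"))

  het <- filter(atoms, .data$record == "HETATM")
  if (!is.null(ligand_code)) het <- filter(het, .data$residue_name == ligand_code)
  prot <- filter(atoms, .data$record == "ATOM  ")
  if (nrow(prot) == 0L && nrow(het) == 0L) {
    abort("all atoms were waters; nothing to parse", class = "dockscreen_parse_error")
  }
  new_structure_model(
    id = id, resolution = resolution,
    atoms = select(prot, -"record"), het_ligand = select(het, -"record")
  )
}

new_structure_model <- function(id, resolution, atoms, het_ligand) {
  if (nrow(atoms) + nrow(het_ligand) < 1L) abort("structure_model needs >= 1 atom")
  all_serial <- c(atoms$serial, het_ligand$serial)
  if (anyDuplicated(all_serial)) abort("duplicate atom serials within model")
  structure(
    list(id = id, resolution = resolution, atoms = atoms, het_ligand = het_ligand),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model %s>  %d protein atoms, %d ligand atoms, resolution %s A\n",
    x$id, nrow(x$atoms), nrow(x$het_ligand),
    if (is.null(x$resolution) || is.na(x$resolution)) "NA" else format(x$resolution)
  ))
  invisible(x)
}

#' Write a structure back to PDB-format text
#'
#' Emits fixed-column `ATOM`/`HETATM` records (plus a `REMARK   2` resolution
#' header when known) that [read_pdb()] round-trips to 1e-3 Angstrom, the PDB
#' coordinate precision.
#'
#' @param model a `structure_model`.
#' @param path optional file path; when given the text is also written there.
#' @return character scalar of PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  fmt <- function(df, record) {
    sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, df$serial,
      ifelse(nchar(df$name) < 4, paste0(" ", df$name), df$name),
      df$residue_name, df$chain, df$residue_number,
      df$x, df$y, df$z, 1, 0, df$element
    )
  }
  lines <- character(0)
  if (!is.null(model$resolution) && !is.na(model$resolution)) {
    lines <- sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", model$resolution)
  }
  if (nrow(model$atoms)) lines <- c(lines, fmt(model$atoms, "ATOM"))
  if (nrow(model$het_ligand)) lines <- c(lines, fmt(model$het_ligand, "HETATM"))
  lines <- c(lines, "END")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Read a multi-model PDB file as a snapshot series
#'
#' Frames are delimited by `MODEL`/`ENDMDL` records; each frame is parsed with
#' [read_pdb()]. Used to consume externally produced trajectory snapshots.
#'
#' @param text PDB text or lines containing >= 1 `MODEL` block (a file without
#'   `MODEL` records yields a single frame).
#' @inheritParams read_pdb
#' @return list of `structure_model`, one per frame.
#' @export
read_pdb_frames <- function(text, ligand_code = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    return(list(read_pdb(lines, ligand_code = ligand_code)))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) abort("unbalanced MODEL/ENDMDL records")
  purrr::map2(starts, ends, function(s, e) {
    read_pdb(lines[(s + 1):(e - 1)], ligand_code = ligand_code, resolution = NA_real_)
  })
}
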