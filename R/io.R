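#' Read / write a long-format docking score table as CSV
#'
#' Columns `compound_id`, `conformation_id`, `mode`, `score`, optional
#' `label`; round-trips losslessly (scores at full precision).
#'
#' @param score_table long score tibble.
#' @param path file path.
#' @return `read_score_table()` returns the tibble.
#' @export
write_score_table <- function(score_table, path) {
  readr::write_csv(score_table, path)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  ct <- readr::cols(
    compound_id = "c", conformation_id = "c", mode = "c",
    score = "d", label = "i"
  )
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  ct$cols <- ct$cols[intersect(names(ct$cols), hdr)]
  readr::read_csv(path, col_types = ct)
}

#' Read / write a descriptor table as CSV
#'
#' One row per compound; fixed numeric columns (`mw`, `logp`, `hbd`, `hba`,
#' `rotb`, `tpsa`, `formal_charge`, `heavy_atoms`) plus logical `reactive_*`
#' flag columns.
#'
#' @param descriptors descriptor tibble.
#' @param path file path.
#' @return `read_descriptors()` returns the tibble.
#' @export
write_descriptors <- function(descriptors, path) {
  readr::write_csv(descriptors, path)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  for (col in grep("^reactive_", names(df), value = TRUE)) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write ligand poses as SDF V2000
#'
#' Minimal V2000 blocks: one molecule per compound with its coordinates and
#' element symbols (no bond block) plus a `frame` data tag when present.
#' Readable back with [read_poses_sdf()] or any V2000-capable toolkit.
#'
#' @param poses tibble with `compound_id`, `element`, `x`, `y`, `z` and
#'   optional `frame`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_poses_sdf <- function(poses, path) {
  poses <- as_tibble(poses)
  out <- character(0)
  for (id in unique(poses$compound_id)) {
    sub <- filter(poses, .data$compound_id == id)
    blk <- c(
      id, "  dockscreen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(sub), 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              sub$x, sub$y, sub$z, sub$element),
      "M  END"
    )
    if ("frame" %in% names(sub)) {
      blk <- c(blk, "> <frame>", as.character(sub$frame[1]), "")
    }
    out <- c(out, blk, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read ligand poses from an SDF V2000 file
#'
#' Parses the counts line, atom block coordinates and element symbols of each
#' molecule; data tags are attached as columns when scalar.
#'
#' @param path file path.
#' @return tibble (`compound_id`, `atom`, `element`, `x`, `y`, `z`, plus any
#'   scalar data tags such as `frame`).
#' @export
read_poses_sdf <- function(path) {
  lines <- readLines(path)
  breaks <- c(0L, which(lines == "$$$$"))
  mols <- purrr::map(seq_len(length(breaks) - 1L), function(i) {
    lines[(breaks[i] + 1L):(breaks[i + 1L] - 1L)]
  })
  purrr::map_dfr(mols, function(blk) {
    if (length(blk) < 4L) return(NULL)
    id <- blk[1]
    n_at <- as.integer(substr(blk[4], 1, 3))
    at <- blk[4 + seq_len(n_at)]
    pose <- tibble(
      compound_id = id, atom = seq_len(n_at),
      element = trimws(substr(at, 32, 34)),
      x = as.numeric(substr(at, 1, 10)),
      y = as.numeric(substr(at, 11, 20)),
      z = as.numeric(substr(at, 21, 30))
    )
    tags <- grep("^> *<", blk)
    for (t in tags) {
      key <- stringr::str_match(blk[t], "<([^>]+)>")[, 2]
      val <- blk[t + 1L]
      pose[[key]] <- if (grepl("^-?[0-9.]+$", val)) as.numeric(val) else val
    }
    pose
  })
}

#' Write an interaction or occupancy report as CSV
#' @param records interaction tibble (from [detect_interactions()] or
#'   [interaction_occupancy()]).
#' @param path file path.
#' @return `read_interactions()` returns the tibble.
#' @export
write_interactions <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a cluster assignment as two-column CSV (id, cluster)
#' @param assignment tibble with an id column and `cluster`.
#' @param path file path.
#' @export
write_clusters <- function(assignment, path) {
  readr::write_csv(assignment, path)
  invisible(path)
}
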