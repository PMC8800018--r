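pose_atoms <- function(pose) {
  pose <- as_tibble(pose)
  needed <- c("element", "x", "y", "z")
  missing <- setdiff(needed, names(pose))
  if (length(missing)) abort(sprintf("pose is missing column(s): %s", paste(missing, collapse = ", ")))
  if (!nrow(pose)) abort("pose has no atoms")
  if (!all(is.finite(as.matrix(pose[, c("x", "y", "z")])))) abort("pose coordinates must be finite")
  pose
}

receptor_atoms <- function(receptor) {
  at <- if (inherits(receptor, "structure_model")) receptor$atoms else as_tibble(receptor)
  if (!nrow(at)) abort("receptor has no atoms")
  at
}

dist_xyz <- function(A, B) {
  # |A| x |B| Euclidean distance matrix
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B) -> d2
  sqrt(pmax(d2, 0))
}

finish_records <- function(rec) {
  if (!nrow(rec)) {
    return(tibble(
      chain = character(), residue_number = integer(), residue_name = character(),
      itype = character(), distance = numeric(), angle = numeric(),
      ligand_atom = integer()
    ))
  }
  arrange(rec, .data$chain, .data$residue_number, .data$itype, .data$distance)
}

#' Detect hydrogen bonds between a ligand pose and the receptor
#'
#' Geometric criterion: a ligand N/O and a receptor N/O heavy-atom pair within
#' `d_max`, and -- when an explicit hydrogen on the ligand donor is present in
#' the pose (an H atom within 1.2 Angstrom of the heavy atom) -- a D-H...A
#' angle of at least `angle_min`. When no hydrogen position is available the
#' angle gate is skipped with a warning, as receptor protons are typically
#' absent from crystallographic models.
#'
#' @param pose tibble with `element`, `x`, `y`, `z` (H atoms allowed; used
#'   only for donor geometry).
#' @param receptor a `structure_model` or its atoms tibble.
#' @param d_max donor-acceptor heavy-atom distance cutoff, default 3.5.
#' @param angle_min minimum D-H...A angle in degrees, default 120.
#' @return interaction tibble: `chain`, `residue_number`, `residue_name`,
#'   `itype = "hbond"`, `distance`, `angle` (NA when ungated),
#'   `ligand_atom` (row index in the pose). Sorted by residue then distance.
#' @export
detect_hbonds <- function(pose, receptor, d_max = 3.5, angle_min = 120) {
  pose <- pose_atoms(pose)
  rat <- receptor_atoms(receptor)
  lig_heavy <- which(pose$element %in% c("N", "O"))
  rec_polar <- which(rat$element %in% c("N", "O"))
  if (!length(lig_heavy) || !length(rec_polar)) return(finish_records(tibble()))
  L <- as.matrix(pose[lig_heavy, c("x", "y", "z")])
  Rm <- as.matrix(rat[rec_polar, c("x", "y", "z")])
  D <- dist_xyz(L, Rm)
  hyd <- which(pose$element == "H")
  H <- as.matrix(pose[hyd, c("x", "y", "z"), drop = FALSE])
  warned <- FALSE
  rec <- list()
  hits <- which(D <= d_max, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    li <- hits[r, 1]; rj <- hits[r, 2]
    dpos <- L[li, ]
    apos <- Rm[rj, ]
    ang <- NA_real_
    if (length(hyd)) {
      dh <- sqrt(rowSums(sweep(H, 2, dpos)^2))
      att <- which(dh <= 1.2)
      if (length(att)) {
        angs <- vapply(att, function(k) {
          v1 <- dpos - H[k, ]; v2 <- apos - H[k, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }, numeric(1))
        ang <- max(angs)
        if (ang < angle_min) next
      }
    }
    if (is.na(ang) && !warned) {
      warn("no donor hydrogen positions: D-H...A angle gate skipped")
      warned <- TRUE
    }
    ri <- rec_polar[rj]
    rec[[length(rec) + 1L]] <- tibble(
      chain = rat$chain[ri], residue_number = rat$residue_number[ri],
      residue_name = rat$residue_name[ri], itype = "hbond",
      distance = D[li, rj], angle = ang, ligand_atom = lig_heavy[li]
    )
  }
  finish_records(bind_rows(rec))
}

backbone_names <- c("N", "CA", "C", "O")

#' Detect hydrophobic contacts (ligand carbon to side-chain carbon)
#'
#' Carbon-carbon pairs within `d_max` where the receptor carbon belongs to a
#' side chain (atom name outside the backbone set); contacts are aggregated
#' to one record per residue at the minimum distance.
#'
#' @inheritParams detect_hbonds
#' @param d_max contact cutoff, default 4.5 Angstrom.
#' @return interaction tibble with `itype = "hydrophobic"`.
#' @export
detect_hydrophobic <- function(pose, receptor, d_max = 4.5) {
  pose <- pose_atoms(pose)
  rat <- receptor_atoms(receptor)
  li <- which(pose$element == "C")
  ri <- which(rat$element == "C" & !rat$name %in% backbone_names)
  if (!length(li) || !length(ri)) return(finish_records(tibble()))
  D <- dist_xyz(
    as.matrix(pose[li, c("x", "y", "z")]),
    as.matrix(rat[ri, c("x", "y", "z")])
  )
  hits <- which(D <= d_max, arr.ind = TRUE)
  if (!nrow(hits)) return(finish_records(tibble()))
  rec <- tibble(
    chain = rat$chain[ri[hits[, 2]]],
    residue_number = rat$residue_number[ri[hits[, 2]]],
    residue_name = rat$residue_name[ri[hits[, 2]]],
    itype = "hydrophobic",
    distance = D[hits], angle = NA_real_,
    ligand_atom = li[hits[, 1]]
  ) %>%
    group_by(.data$chain, .data$residue_number, .data$residue_name, .data$itype) %>%
    arrange(.data$distance, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  finish_records(rec)
}

charged_group_center <- function(rat) {
  # one charged-group center per ionizable residue
  spec <- list(
    ASP = list(atoms = c("OD1", "OD2"), charge = -1),
    GLU = list(atoms = c("OE1", "OE2"), charge = -1),
    LYS = list(atoms = "NZ", charge = +1),
    ARG = list(atoms = c("NH1", "NH2", "CZ"), charge = +1),
    HIS = list(atoms = c("ND1", "NE2"), charge = +1)
  )
  out <- list()
  grp <- rat %>% filter(.data$residue_name %in% names(spec)) %>%
    group_by(.data$chain, .data$residue_number, .data$residue_name)
  keys <- dplyr::group_keys(grp)
  rows <- dplyr::group_rows(grp)
  for (g in seq_len(nrow(keys))) {
    sp <- spec[[keys$residue_name[g]]]
    sub <- rat[rows[[g]], ]
    sub <- filter(sub, .data$name %in% sp$atoms)
    if (!nrow(sub)) next
    out[[length(out) + 1L]] <- tibble(
      chain = keys$chain[g], residue_number = keys$residue_number[g],
      residue_name = keys$residue_name[g], charge = sp$charge,
      x = mean(sub$x), y = mean(sub$y), z = mean(sub$z)
    )
  }
  bind_rows(out)
}

#' Detect ionic interactions (salt bridges)
#'
#' Oppositely charged group centers -- ligand atoms carrying a non-zero
#' `charge` column versus the charged-group centers of Asp/Glu (carboxylate,
#' -1) and Lys/Arg/His (+1) -- within `d_max`.
#'
#' @inheritParams detect_hbonds
#' @param d_max center-center cutoff, default 4.0 Angstrom.
#' @return interaction tibble with `itype = "ionic"`.
#' @export
detect_ionic <- function(pose, receptor, d_max = 4) {
  pose <- pose_atoms(pose)
  if (!"charge" %in% names(pose)) return(finish_records(tibble()))
  rat <- receptor_atoms(receptor)
  lig <- filter(pose, !is.na(.data$charge) & .data$charge != 0)
  ctr <- charged_group_center(rat)
  if (!nrow(lig) || !nrow(ctr)) return(finish_records(tibble()))
  D <- dist_xyz(as.matrix(lig[, c("x", "y", "z")]), as.matrix(ctr[, c("x", "y", "z")]))
  opp <- outer(sign(lig$charge), sign(ctr$charge), function(a, b) a * b < 0)
  hits <- which(D <= d_max & opp, arr.ind = TRUE)
  if (!nrow(hits)) return(finish_records(tibble()))
  rec <- tibble(
    chain = ctr$chain[hits[, 2]], residue_number = ctr$residue_number[hits[, 2]],
    residue_name = ctr$residue_name[hits[, 2]], itype = "ionic",
    distance = D[hits], angle = NA_real_,
    ligand_atom = match(
      paste(lig$x[hits[, 1]], lig$y[hits[, 1]], lig$z[hits[, 1]]),
      paste(pose$x, pose$y, pose$z)
    )
  )
  finish_records(rec)
}

#' Detect water-bridged hydrogen bonds (optional detector)
#'
#' A ligand N/O and a receptor N/O both within `d_max` of the same water
#' oxygen. Requires explicit water coordinates, which the PDB reader drops
#' from protein models, so waters are passed separately; excluded from the
#' default detector set.
#'
#' @inheritParams detect_hbonds
#' @param waters tibble of water oxygen positions (`x`, `y`, `z`).
#' @param d_max both legs' distance cutoff, default 3.5 Angstrom.
#' @return interaction tibble with `itype = "water_bridge"`; `distance` is
#'   the water-residue leg.
#' @export
detect_water_bridges <- function(pose, receptor, waters, d_max = 3.5) {
  pose <- pose_atoms(pose)
  rat <- receptor_atoms(receptor)
  waters <- as_tibble(waters)
  li <- which(pose$element %in% c("N", "O"))
  ri <- which(rat$element %in% c("N", "O"))
  if (!length(li) || !length(ri) || !nrow(waters)) return(finish_records(tibble()))
  W <- as.matrix(waters[, c("x", "y", "z")])
  DL <- dist_xyz(as.matrix(pose[li, c("x", "y", "z")]), W)
  DR <- dist_xyz(W, as.matrix(rat[ri, c("x", "y", "z")]))
  rec <- list()
  for (w in seq_len(nrow(W))) {
    lig_ok <- which(DL[, w] <= d_max)
    res_ok <- which(DR[w, ] <= d_max)
    if (!length(lig_ok) || !length(res_ok)) next
    for (rj in res_ok) {
      k <- ri[rj]
      rec[[length(rec) + 1L]] <- tibble(
        chain = rat$chain[k], residue_number = rat$residue_number[k],
        residue_name = rat$residue_name[k], itype = "water_bridge",
        distance = DR[w, rj], angle = NA_real_,
        ligand_atom = li[lig_ok[which.min(DL[lig_ok, w])]]
      )
    }
  }
  out <- bind_rows(rec)
  if (nrow(out)) {
    out <- out %>%
      group_by(.data$chain, .data$residue_number, .data$residue_name, .data$itype) %>%
      arrange(.data$distance, .by_group = TRUE) %>%
      slice(1) %>%
      ungroup()
  }
  finish_records(out)
}

#' Run the configured interaction detectors on one pose
#'
#' @inheritParams detect_hbonds
#' @param detectors character subset of `c("hbond", "hydrophobic", "ionic")`.
#' @param config named list of detector parameter overrides, e.g.
#'   `list(hbond = list(d_max = 3.2))`.
#' @return combined interaction tibble.
#' @export
detect_interactions <- function(pose, receptor,
                                detectors = c("hbond", "hydrophobic", "ionic"),
                                config = list()) {
  out <- list()
  if ("hbond" %in% detectors) {
    out$hb <- do.call(detect_hbonds, c(list(pose, receptor), config$hbond))
  }
  if ("hydrophobic" %in% detectors) {
    out$ph <- do.call(detect_hydrophobic, c(list(pose, receptor), config$hydrophobic))
  }
  if ("ionic" %in% detectors) {
    out$io <- do.call(detect_ionic, c(list(pose, receptor), config$ionic))
  }
  finish_records(bind_rows(out))
}

#' Parse residue labels like "Val882" into name + number
#'
#' @param x character vector of `<ResName><number>` labels.
#' @return tibble (`residue_name` upper-case 3-letter, `residue_number`).
#' @export
parse_residue_labels <- function(x) {
  m <- stringr::str_match(x, "^([A-Za-z]{3})(\\d+)$")
  if (anyNA(m[, 1])) abort(sprintf("unparseable residue label: %s", x[is.na(m[, 1])][1]))
  tibble(residue_name = toupper(m[, 2]), residue_number = as.integer(m[, 3]))
}

#' Default hot-residue set of the PI3Kgamma ATP pocket profile
#'
#' Union of the recurrent crucial-interaction residues of the ensemble
#' validation (hinge Val882 foremost) and the selectivity-determining
#' residues of the binding-mode analysis. Fully user-overridable; supplied as
#' the package's shipped default profile.
#' @return character vector of residue labels.
#' @export
pi3kg_hot_residues <- function() {
  c("Val882", "Lys833", "Tyr867", "Asp964", "Asp836",
    "Thr886", "Thr887", "Met953", "Ile963")
}

#' Hot-residue interaction filter
#'
#' Keeps a pose iff its detected interactions of the requested types touch
#' the hot-residue set: `require = "any"` (default) needs at least one hot
#' residue contacted, `"all"` needs every one.
#'
#' @param records interaction tibble (from [detect_interactions()] or a
#'   precomputed CSV) with `residue_name`, `residue_number`, `itype`.
#' @param hot_set character vector of residue labels (e.g.
#'   [pi3kg_hot_residues()]) or a tibble (`residue_name`, `residue_number`).
#' @param require `"any"` or `"all"`.
#' @param itypes interaction types that count, default `"hbond"`.
#' @return logical: keep or drop.
#' @export
hot_residue_filter <- function(records, hot_set, require = c("any", "all"),
                               itypes = "hbond") {
  require <- match.arg(require)
  if (is.character(hot_set)) hot_set <- parse_residue_labels(hot_set)
  if (!nrow(hot_set)) abort("hot_set must be non-empty")
  hits <- records %>%
    filter(.data$itype %in% itypes) %>%
    semi_join(hot_set, by = c("residue_name", "residue_number")) %>%
    distinct(.data$residue_name, .data$residue_number)
  if (require == "any") nrow(hits) > 0 else nrow(hits) == nrow(hot_set)
}

#' Per-atom RMSF of a ligand over trajectory frames
#'
#' \eqn{RMSF_i = \sqrt{\langle \|x_i(t) - \bar x_i\|^2 \rangle_t}} over >= 2
#' frames of equal atom count and order. Frames are taken as pre-aligned on
#' the receptor; when a per-frame receptor list is supplied, each frame is
#' first superposed onto the first frame's receptor CA atoms with
#' [kabsch_superpose()] and the fitted rigid motion applied to the ligand.
#'
#' @param traj tibble with columns `frame`, `atom`, `element`, `x`, `y`, `z`
#'   (e.g. from [gen_snapshot_series()]).
#' @param receptors optional list of `structure_model`, one per frame, for
#'   CA-based alignment.
#' @return tibble (`atom`, `element`, `rmsf`).
#' @export
ligand_rmsf <- function(traj, receptors = NULL) {
  traj <- as_tibble(traj)
  frames <- sort(unique(traj$frame))
  if (length(frames) < 2) abort("RMSF needs >= 2 frames")
  counts <- traj %>% group_by(.data$frame) %>% summarise(n = n())
  if (length(unique(counts$n)) != 1) abort("frames differ in atom count")
  if (!is.null(receptors)) {
    if (length(receptors) != length(frames)) abort("one receptor per frame required")
    ca_ref <- filter(receptors[[1]]$atoms, .data$name == "CA")
    ref <- as.matrix(ca_ref[, c("x", "y", "z")])
    traj <- purrr::map_dfr(seq_along(frames), function(k) {
      sub <- filter(traj, .data$frame == frames[k])
      ca <- filter(receptors[[k]]$atoms, .data$name == "CA")
      fit <- kabsch_superpose(ref, as.matrix(ca[, c("x", "y", "z")]))
      xyz <- as.matrix(sub[, c("x", "y", "z")]) %*% t(fit$rotation)
      xyz <- sweep(xyz, 2, fit$translation, "+")
      mutate(sub, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    })
  }
  traj %>%
    group_by(.data$atom, .data$element) %>%
    summarise(
      rmsf = sqrt(mean((.data$x - mean(.data$x))^2 +
                       (.data$y - mean(.data$y))^2 +
                       (.data$z - mean(.data$z))^2)),
      .groups = "drop"
    ) %>%
    arrange(.data$atom)
}

#' Interaction occupancy over trajectory frames
#'
#' Fraction of frames in which each (residue, interaction type) contact is
#' detected; multiple simultaneous contacts to the same residue count once
#' per frame, so occupancies live in \[0, 1\].
#'
#' @inheritParams ligand_rmsf
#' @param receptor static `structure_model`, or a list (one per frame).
#' @inheritParams detect_interactions
#' @return tibble (`chain`, `residue_number`, `residue_name`, `itype`,
#'   `n_frames`, `occupancy`).
#' @export
interaction_occupancy <- function(traj, receptor,
                                  detectors = c("hbond", "hydrophobic", "ionic"),
                                  config = list()) {
  traj <- as_tibble(traj)
  frames <- sort(unique(traj$frame))
  per_frame <- purrr::map_dfr(seq_along(frames), function(k) {
    pose <- filter(traj, .data$frame == frames[k])
    rec <- if (is.list(receptor) && !inherits(receptor, "structure_model")) receptor[[k]] else receptor
    det <- detect_interactions(pose, rec, detectors = detectors, config = config)
    if (!nrow(det)) return(det)
    distinct(det, .data$chain, .data$residue_number, .data$residue_name, .data$itype)
  })
  if (!nrow(per_frame)) {
    return(tibble(
      chain = character(), residue_number = integer(), residue_name = character(),
      itype = character(), n_frames = integer(), occupancy = numeric()
    ))
  }
  per_frame %>%
    group_by(.data$chain, .data$residue_number, .data$residue_name, .data$itype) %>%
    summarise(n_frames = n(), .groups = "drop") %>%
    mutate(occupancy = .data$n_frames / length(frames)) %>%
    arrange(.data$chain, .data$residue_number, .data$itype)
}
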