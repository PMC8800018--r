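#' Kabsch superposition of two point sets
#'
#' Least-squares rigid superposition of `Q` onto `P` by the SVD (Kabsch)
#' method: both sets are centered, the optimal proper rotation is
#' `R = V diag(1, 1, det(VU')) U'` from `svd(P'Q)`, and the RMSD is the
#' residual after applying it. Positional correspondence between rows is
#' assumed (one shared sequence across ensemble members).
#'
#' @param P,Q numeric n x 3 coordinate matrices, n >= 3, same n.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3; `Q %*% t(rotation)` + translation superposes onto `P`), and
#'   `rmsd` in Angstrom.
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' kabsch_superpose(P, P)$rmsd
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L) abort("P and Q must be matching n x 3 matrices")
  n <- nrow(P)
  if (n < 3L) abort("need >= 3 points for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinear/degenerate sets have no unique rotation
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L) {
    abort("degenerate (collinear) point set: superposition is not unique")
  }
  s <- svd(crossprod(Pc, Qc)) # P'Q
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Qr <- Qc %*% t(R)
  rmsd <- sqrt(sum((Pc - Qr)^2) / n)
  list(rotation = R, translation = as.numeric(cp - cq %*% t(R)), rmsd = rmsd)
}

#' Extract the ligand binding site of a structure
#'
#' A residue belongs to the binding site iff any of its atoms lies within
#' `cutoff` (inclusive) of any co-crystallized ligand atom.
#'
#' @param model a `structure_model` with non-empty `het_ligand`.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return tibble with columns `chain`, `residue_number`, `residue_name`,
#'   one row per binding-site residue, sorted by chain then number.
#' @export
extract_binding_site <- function(model, cutoff = 10) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model$het_ligand) == 0L) abort("model has no co-crystallized ligand")
  lig <- as.matrix(model$het_ligand[, c("x", "y", "z")])
  at <- model$atoms
  pm <- as.matrix(at[, c("x", "y", "z")])
  # min distance of each protein atom to any ligand atom
  d2min <- rep(Inf, nrow(pm))
  for (k in seq_len(nrow(lig))) {
    d2 <- (pm[, 1] - lig[k, 1])^2 + (pm[, 2] - lig[k, 2])^2 + (pm[, 3] - lig[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  at %>%
    mutate(.near = sqrt(d2min) <= cutoff) %>%
    group_by(.data$chain, .data$residue_number, .data$residue_name) %>%
    summarise(keep = any(.data$.near), .groups = "drop") %>%
    filter(.data$keep) %>%
    select(-"keep") %>%
    arrange(.data$chain, .data$residue_number)
}

site_coords <- function(model, site, atom_subset = "CA") {
  at <- model$atoms
  if (!identical(atom_subset, "heavy")) at <- filter(at, .data$name %in% atom_subset)
  else at <- filter(at, .data$element != "H")
  key <- paste(site$chain, site$residue_number)
  at <- filter(at, paste(.data$chain, .data$residue_number) %in% key)
  at <- arrange(at, .data$chain, .data$residue_number, .data$name)
  missing <- setdiff(key, paste(at$chain, at$residue_number))
  if (length(missing)) {
    abort(sprintf(
      "model %s is missing binding-site residue(s): %s",
      model$id, paste(missing, collapse = ", ")
    ))
  }
  at
}

#' Pairwise binding-site RMSD matrix over an ensemble
#'
#' Every pair of conformations is superposed with [kabsch_superpose()] on the
#' shared binding-site selection (CA atoms by default, all heavy atoms with
#' `atom_subset = "heavy"`) and the optimal RMSD recorded. The matrix is
#' symmetric with a zero diagonal; the triangle inequality is not guaranteed
#' because each pair is fitted independently.
#'
#' @param models list of `structure_model`.
#' @param site tibble of (`chain`, `residue_number`) shared residues, e.g.
#'   from [extract_binding_site()].
#' @param atom_subset `"CA"` (default), `"heavy"`, or a character vector of
#'   atom names.
#' @return object of class `dist_matrix`: square numeric matrix with model ids
#'   as dimnames.
#' @export
pairwise_rmsd_matrix <- function(models, site, atom_subset = "CA") {
  ids <- purrr::map_chr(models, "id")
  if (anyDuplicated(ids)) abort("model ids must be unique")
  coords <- purrr::map(models, function(m) {
    at <- site_coords(m, site, atom_subset)
    as.matrix(at[, c("x", "y", "z")])
  })
  ns <- purrr::map_int(coords, nrow)
  if (length(unique(ns)) != 1L) abort("models disagree on selected atom count")
  n <- length(models)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d[i, j] <- d[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  class(d) <- c("dist_matrix", class(d))
  d
}

#' UPGMA (average-linkage) clustering of a distance matrix into k groups
#'
#' Agglomerates with unweighted average linkage, stopping when `k` clusters
#' remain. Ties between candidate merges are broken deterministically: the
#' pair whose (sorted) member id pair is lexicographically smallest merges
#' first, so repeated runs give identical assignments.
#'
#' @param d symmetric distance matrix with id dimnames (e.g. from
#'   [pairwise_rmsd_matrix()]).
#' @param k number of clusters, `1 <= k <= nrow(d)`.
#' @return tibble with columns `id`, `cluster` (integer 1..k, numbered by
#'   first id appearance).
#' @export
upgma_cluster <- function(d, k) {
  d <- unclass(as.matrix(d))
  ids <- rownames(d)
  n <- nrow(d)
  if (is.null(ids)) abort("distance matrix needs id dimnames")
  if (k < 1 || k > n) abort(sprintf("k must be in 1..%d", n))
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0)) abort("matrix must be symmetric with zero diagonal")

  members <- lapply(ids, identity) # cluster -> member ids
  sizes <- rep(1L, n)
  act <- rep(TRUE, n)
  dm <- d
  lead <- ids # lexicographically smallest member, for tie-breaking
  while (sum(act) > k) {
    ai <- which(act)
    best <- NULL
    for (p in seq_along(ai)) {
      for (q in seq_along(ai)) {
        if (q <= p) next
        i <- ai[p]; j <- ai[q]
        key <- sort(c(lead[i], lead[j]))
        if (is.null(best) ||
            dm[i, j] < best$d - 1e-12 ||
            (abs(dm[i, j] - best$d) <= 1e-12 &&
             (key[1] < best$key[1] || (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dm[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    # unweighted average linkage update
    for (m in which(act)) {
      if (m == i || m == j) next
      dm[i, m] <- dm[m, i] <- (sizes[i] * dm[i, m] + sizes[j] * dm[j, m]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    lead[i] <- min(lead[i], lead[j])
    act[j] <- FALSE
  }
  out <- tibble(
    id = unlist(members[act]),
    cluster = rep(seq_len(sum(act)), times = sizes[act])
  )
  # renumber clusters by first appearance in the original id order
  first <- out[match(ids, out$id), ]
  lv <- unique(first$cluster)
  out$cluster <- match(out$cluster, lv)
  arrange(out, match(.data$id, ids))
}

#' Select one representative per cluster by best resolution
#'
#' Within each cluster the structure with the smallest resolution value
#' (smaller Angstrom = higher resolution) is chosen; ties go to the
#' lexicographically smallest id.
#'
#' @param assignment tibble (`id`, `cluster`) from [upgma_cluster()].
#' @param resolutions named numeric vector or tibble (`id`, `resolution`)
#'   covering every clustered id.
#' @return tibble (`cluster`, `id`, `resolution`), one row per cluster.
#' @export
select_representatives <- function(assignment, resolutions) {
  if (is_tibble(resolutions) || is.data.frame(resolutions)) {
    res <- setNames(resolutions$resolution, resolutions$id)
  } else {
    res <- resolutions
  }
  missing <- setdiff(assignment$id, names(res))
  if (length(missing)) {
    abort(sprintf("missing resolution for: %s", paste(missing, collapse = ", ")))
  }
  if (anyNA(res[assignment$id])) abort("NA resolution supplied")
  assignment %>%
    mutate(resolution = unname(res[.data$id])) %>%
    group_by(.data$cluster) %>%
    arrange(.data$resolution, .data$id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("cluster", "id", "resolution") %>%
    arrange(.data$cluster)
}

#' Write / read a distance matrix as CSV with an id header row and column
#' @param d `dist_matrix` (or plain square matrix with dimnames).
#' @param path file path.
#' @return `read_dist_matrix()` returns a `dist_matrix`.
#' @export
write_dist_matrix <- function(d, path) {
  m <- unclass(as.matrix(d))
  df <- as.data.frame(m)
  df <- cbind(id = rownames(m), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  colnames(m) <- colnames(df)[-1]
  class(m) <- c("dist_matrix", class(m))
  m
}
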