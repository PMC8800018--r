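lipinski_rules <- list(
  "MW>500" = function(d) d$mw > 500,
  "logP>5" = function(d) d$logp > 5,
  "HBD>5" = function(d) d$hbd > 5,
  "HBA>10" = function(d) d$hba > 10
)
veber_rules <- list(
  "RotB>10" = function(d) d$rotb > 10,
  "TPSA>140" = function(d) d$tpsa > 140
)
reos_rules <- list(
  "MW<200" = function(d) d$mw < 200,
  "MW>500" = function(d) d$mw > 500,
  "logP<-5" = function(d) d$logp < -5,
  "logP>5" = function(d) d$logp > 5,
  "HBD>5" = function(d) d$hbd > 5,
  "HBA>10" = function(d) d$hba > 10,
  "charge<-2" = function(d) d$formal_charge < -2,
  "charge>2" = function(d) d$formal_charge > 2,
  "RotB>8" = function(d) d$rotb > 8,
  "heavy<15" = function(d) d$heavy_atoms < 15,
  "heavy>50" = function(d) d$heavy_atoms > 50
)

check_descriptor_fields <- function(descriptors, fields) {
  missing <- setdiff(fields, names(descriptors))
  if (length(missing)) {
    abort(sprintf("descriptor table is missing field(s): %s", paste(missing, collapse = ", ")))
  }
  for (f in fields) {
    if (anyNA(descriptors[[f]])) abort(sprintf("descriptor field '%s' contains NA", f))
  }
}

apply_rules <- function(descriptors, rules) {
  viol <- vapply(rules, function(r) r(descriptors), logical(nrow(descriptors)))
  if (nrow(descriptors) == 1L) viol <- matrix(viol, nrow = 1, dimnames = list(NULL, names(rules)))
  viol
}

#' Lipinski + Veber drug-likeness filter
#'
#' Lipinski's rule of five (MW <= 500 Da, logP <= 5, H-bond donors <= 5,
#' acceptors <= 10) with a configurable violation allowance, plus Veber's
#' oral-bioavailability criteria (rotatable bonds <= 10, TPSA <= 140 A^2),
#' which are not waivable. All boundaries are inclusive on the passing side.
#'
#' @param descriptors tibble with columns `compound_id`, `mw`, `logp`, `hbd`,
#'   `hba`, `rotb`, `tpsa`.
#' @param max_lipinski_violations Lipinski violations tolerated (default 0).
#' @return the input with `pass` (logical) and `violations`
#'   (semicolon-joined rule names, `""` when clean) appended.
#' @examples
#' rec <- tibble::tibble(compound_id = "a", mw = 450, logp = 3, hbd = 2,
#'                       hba = 6, rotb = 5, tpsa = 90)
#' filter_druglike(rec)
#' @export
filter_druglike <- function(descriptors, max_lipinski_violations = 0) {
  descriptors <- as_tibble(descriptors)
  check_descriptor_fields(descriptors, c("mw", "logp", "hbd", "hba", "rotb", "tpsa"))
  lv <- apply_rules(descriptors, lipinski_rules)
  vv <- apply_rules(descriptors, veber_rules)
  viol <- cbind(lv, vv)
  reasons <- apply(viol, 1, function(r) paste(colnames(viol)[r], collapse = ";"))
  mutate(descriptors,
    pass = rowSums(lv) <= max_lipinski_violations & rowSums(vv) == 0,
    violations = reasons
  )
}

#' REOS (rapid elimination of swill) filter
#'
#' Property windows MW 200-500 Da, logP -5..5, HBD <= 5, HBA <= 10, formal
#' charge -2..+2, rotatable bonds <= 8, heavy atoms 15-50 (all boundaries
#' inclusive), plus exclusion of any compound with a flagged reactive group.
#' Reactive groups arrive as boolean `reactive_*` columns (e.g.
#' `reactive_aldehyde`); the vocabulary is whatever columns are present, so it
#' is config-editable upstream.
#'
#' @param descriptors tibble with `compound_id`, `mw`, `logp`, `hbd`, `hba`,
#'   `rotb`, `formal_charge`, `heavy_atoms` and optional `reactive_*` logical
#'   columns.
#' @return the input with `pass` and `violations` appended (reactive failures
#'   are reported as `reactive:<name>`).
#' @export
filter_reos <- function(descriptors) {
  descriptors <- as_tibble(descriptors)
  check_descriptor_fields(
    descriptors,
    c("mw", "logp", "hbd", "hba", "rotb", "formal_charge", "heavy_atoms")
  )
  viol <- apply_rules(descriptors, reos_rules)
  rx_cols <- grep("^reactive_", names(descriptors), value = TRUE)
  if (length(rx_cols)) {
    rx <- as.matrix(descriptors[, rx_cols, drop = FALSE])
    colnames(rx) <- paste0("reactive:", sub("^reactive_", "", rx_cols))
    viol <- cbind(viol, rx)
  }
  reasons <- apply(viol, 1, function(r) paste(colnames(viol)[as.logical(r)], collapse = ";"))
  mutate(descriptors, pass = rowSums(viol) == 0, violations = reasons)
}

#' Tanimoto similarity of two bit-set fingerprints
#'
#' `|A intersect B| / |A union B|` on the on-bit sets. Two empty fingerprints
#' are defined as similarity 1 (logged once per call).
#'
#' @param a,b integer vectors of on-bit positions (as stored in the `fp`
#'   list-column of a fingerprint tibble).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (!length(a) && !length(b)) {
    inform("both fingerprints empty: similarity 1 by convention")
    return(1)
  }
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

tanimoto_matrix <- function(fps) {
  n <- length(fps)
  sizes <- lengths(fps)
  s <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      inter <- length(intersect(fps[[i]], fps[[j]]))
      uni <- sizes[i] + sizes[j] - inter
      s[i, j] <- s[j, i] <- if (uni == 0) 1 else inter / uni
    }
  }
  s
}

#' Butina (sphere-exclusion) diversity clustering of fingerprints
#'
#' Compounds whose Tanimoto similarity reaches the cutoff belong to the same
#' group. Centroids are taken in order of descending neighbor count (ties:
#' lexicographically smallest id); every unassigned compound joins the first
#' centroid it is similar enough to, and leftovers become singletons, so the
#' result is a partition. `strict = TRUE` switches the membership test from
#' `>= cutoff` to `> cutoff`.
#'
#' @param fingerprints tibble with `compound_id` and `fp` list-column of
#'   on-bit integer vectors (see [gen_fingerprints()] / [read_fingerprints()]).
#' @param cutoff similarity threshold, default 0.8.
#' @param strict logical; membership requires strictly greater similarity.
#' @return tibble (`compound_id`, `cluster`, `is_centroid`), clusters numbered
#'   in centroid-selection order.
#' @export
butina_cluster <- function(fingerprints, cutoff = 0.8, strict = FALSE) {
  fps <- fingerprints$fp
  ids <- fingerprints$compound_id
  n <- length(ids)
  if (n < 1L) abort("need >= 1 fingerprint")
  s <- tanimoto_matrix(fps)
  ok <- if (strict) s > cutoff else s >= cutoff
  diag(ok) <- FALSE
  nbr <- rowSums(ok)
  order_idx <- order(-nbr, ids)
  cluster <- rep(NA_integer_, n)
  centroid <- rep(FALSE, n)
  k <- 0L
  for (c_i in order_idx) {
    if (!is.na(cluster[c_i])) next
    k <- k + 1L
    cluster[c_i] <- k
    centroid[c_i] <- TRUE
    mem <- which(is.na(cluster) & ok[c_i, ])
    cluster[mem] <- k
  }
  tibble(compound_id = ids, cluster = cluster, is_centroid = centroid)
}

#' Diversity-aware pick of n compounds across clusters
#'
#' Round-robin over clusters ordered by their best member's ranking score
#' (higher = better): each pass takes every cluster's best unused member
#' until `n` compounds are collected, preferring scaffold diversity over
#' depth within a cluster. Deterministic: ties in score break by compound id.
#'
#' @param assignment tibble (`compound_id`, `cluster`), e.g. from
#'   [butina_cluster()].
#' @param ranking_scores named numeric vector or tibble (`compound_id`,
#'   `score`), higher = better.
#' @param n number of compounds to pick (`n` <= population).
#' @return character vector of `n` compound ids.
#' @export
diversity_pick <- function(assignment, ranking_scores, n) {
  if (is_tibble(ranking_scores) || is.data.frame(ranking_scores)) {
    ranking_scores <- setNames(ranking_scores$score, ranking_scores$compound_id)
  }
  if (n > nrow(assignment)) abort("n exceeds the population")
  missing <- setdiff(assignment$compound_id, names(ranking_scores))
  if (length(missing)) abort(sprintf("no ranking score for: %s", paste(head(missing, 5), collapse = ", ")))
  tab <- assignment %>%
    mutate(score = unname(ranking_scores[.data$compound_id])) %>%
    group_by(.data$cluster) %>%
    arrange(desc(.data$score), .data$compound_id, .by_group = TRUE) %>%
    mutate(depth = row_number(), best = .data$score[1]) %>%
    ungroup() %>%
    arrange(.data$depth, desc(.data$best), desc(.data$score), .data$compound_id)
  head(tab$compound_id, n)
}

#' Read / write fingerprints as CSV of hex strings
#'
#' Columns `compound_id`, `fp_hex`; bits are packed 4 per hex digit,
#' most-significant first, total length `nbits / 4` digits.
#'
#' @param fingerprints tibble with `compound_id`, `fp` list-column and an
#'   `nbits` attribute (or `nbits` argument).
#' @param path file path.
#' @param nbits fingerprint length in bits.
#' @return `read_fingerprints()` returns the fingerprint tibble.
#' @export
write_fingerprints <- function(fingerprints, path, nbits = attr(fingerprints, "nbits")) {
  if (is.null(nbits)) abort("nbits unknown; pass nbits=")
  hex <- vapply(fingerprints$fp, function(bits) {
    v <- integer(nbits)
    v[bits] <- 1L
    nib <- matrix(v, nrow = 4)
    paste(sprintf("%x", colSums(nib * c(8L, 4L, 2L, 1L))), collapse = "")
  }, character(1))
  readr::write_csv(tibble(compound_id = fingerprints$compound_id, fp_hex = hex), path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  nbits <- nchar(df$fp_hex[1]) * 4L
  fp <- lapply(df$fp_hex, function(h) {
    nib <- strtoi(strsplit(h, "")[[1]], base = 16L)
    bits <- as.vector(vapply(nib, function(x) as.integer(bitwAnd(x, c(8L, 4L, 2L, 1L)) > 0), integer(4)))
    which(bits == 1L)
  })
  out <- tibble(compound_id = df$compound_id, fp = fp)
  attr(out, "nbits") <- nbits
  out
}
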