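#' Heavy-atom RMSD between two ligand poses
#'
#' No superposition is applied: both poses are assumed to sit in the shared
#' receptor frame, as in re-docking validation. Hydrogens are excluded.
#' `matching = "ordered"` pairs atoms by position in the table;
#' `matching = "element_hungarian"` solves, within each element class, the
#' minimum-cost assignment of squared distances (optimal over all
#' element-preserving atom relabelings, e.g. chemically equivalent symmetric
#' pairs).
#'
#' @param a,b pose tibbles with columns `element`, `x`, `y`, `z` (extra
#'   columns ignored); same heavy-atom count, and for `"ordered"` the same
#'   atom order.
#' @param matching `"ordered"` (default) or `"element_hungarian"`.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, matching = c("ordered", "element_hungarian")) {
  matching <- match.arg(matching)
  a <- filter(as_tibble(a), .data$element != "H")
  b <- filter(as_tibble(b), .data$element != "H")
  if (nrow(a) != nrow(b)) abort("poses differ in heavy-atom count")
  if (nrow(a) == 0L) abort("poses have no heavy atoms")
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  if (matching == "ordered") {
    if (!identical(a$element, b$element)) abort("element sequences differ for ordered matching")
    return(sqrt(mean(rowSums((A - B)^2))))
  }
  if (!identical(sort(a$element), sort(b$element))) abort("element compositions differ")
  ss <- 0
  for (el in unique(a$element)) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    if (length(ia) == 1L) {
      ss <- ss + sum((A[ia, ] - B[ib, ])^2)
    } else {
      cost <- outer(ia, ib, Vectorize(function(i, j) sum((A[i, ] - B[j, ])^2)))
      asg <- solve_assignment(cost)
      ss <- ss + sum(cost[cbind(seq_along(ia), asg)])
    }
  }
  sqrt(ss / nrow(a))
}

# Jonker-Volgenant shortest augmenting path solver for the square linear
# assignment problem; returns, for each row, the assigned column index.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j]: row matched to column j (0 = free); p[n+1] is scratch
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  asg <- integer(n)
  for (j in seq_len(n)) asg[p[j]] <- j
  asg
}

#' Docking-power success flag
#'
#' Re-docking reproduces the crystallographic pose when the heavy-atom RMSD is
#' at most the threshold (2.0 Angstrom by convention, inclusive).
#'
#' @param redock_rmsd non-negative RMSD in Angstrom.
#' @param threshold success threshold, default 2.0.
#' @return logical.
#' @export
docking_power <- function(redock_rmsd, threshold = 2) {
  if (any(redock_rmsd < 0)) abort("RMSD cannot be negative")
  redock_rmsd <= threshold
}

#' Two-sample t-test on docking-score distributions
#'
#' Student (pooled variance, df = n1 + n2 - 2) or Welch (Satterthwaite df)
#' statistic with a two-sided p-value. Because score separations in screening
#' validation routinely push p below double underflow (magnitudes down to
#' 1e-255 and beyond), the log10 p-value is always computed in log space and
#' returned alongside. Degenerate inputs follow fixed conventions: zero
#' pooled variance with equal means gives p = 1; with unequal means p = 0 and
#' `degenerate = TRUE`.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @param variant `"student"` (default) or `"welch"`.
#' @return tibble with `t`, `df`, `p_value`, `log10_p`, `degenerate`.
#' @examples
#' score_ttest(c(1, 2, 3), c(2, 3, 4))
#' @export
score_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 observations")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("scores must be finite")
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- var(a); v2 <- var(b)
  if (variant == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0 || !is.finite(df)) {
    if (m1 == m2) {
      return(tibble(t = 0, df = NA_real_, p_value = 1, log10_p = 0, degenerate = TRUE))
    }
    warn("zero variance with unequal means: p = 0 by convention")
    return(tibble(
      t = sign(m1 - m2) * Inf, df = NA_real_, p_value = 0,
      log10_p = -Inf, degenerate = TRUE
    ))
  }
  t <- (m1 - m2) / se
  lp <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE) # log P(T > |t|)
  log10_p <- (lp + log(2)) / log(10)
  tibble(
    t = t, df = df, p_value = min(1, 2 * exp(lp)),
    log10_p = log10_p, degenerate = FALSE
  )
}

#' ROC AUC by the rank (Mann-Whitney) method
#'
#' AUC = P(active outranks decoy) + 1/2 P(tie). With
#' `orientation = "lower_is_active"` a smaller score outranks (the docking
#' convention: more negative = better); with `"higher_is_active"` the reverse.
#' Ties contribute 1/2 via midranks, so
#' `roc_auc(s, y) + roc_auc(s, 1 - y) == 1` exactly.
#'
#' @param scores numeric vector (NAs dropped pairwise with their labels).
#' @param labels 0/1 vector, 1 = active; both classes must be present.
#' @param orientation `"lower_is_active"` (default) or `"higher_is_active"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, orientation = c("lower_is_active", "higher_is_active")) {
  orientation <- match.arg(orientation)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  na <- sum(labels == 1L)
  nd <- sum(labels == 0L)
  if (na == 0L || nd == 0L) abort("both classes must be present")
  r <- rank(if (orientation == "lower_is_active") -scores else scores,
            ties.method = "average")
  (sum(r[labels == 1L]) - na * (na + 1) / 2) / (na * nd)
}

#' Enrichment factor at a top fraction of the ranked list
#'
#' Fraction of actives recovered in the top `top_fraction` of the ranking,
#' relative to the active rate in the whole library. Ranking follows the
#' docking convention (lower score first) unless flipped.
#'
#' @inheritParams roc_auc
#' @param top_fraction fraction of the library taken from the top, in (0, 1].
#' @return enrichment factor (1 = random expectation).
#' @export
enrichment_factor <- function(scores, labels, top_fraction,
                              orientation = c("lower_is_active", "higher_is_active")) {
  orientation <- match.arg(orientation)
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0, 1]")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n <- length(scores)
  n_top <- floor(n * top_fraction)
  if (n_top < 1L) abort("top slice is empty at this fraction")
  ord <- order(if (orientation == "lower_is_active") scores else -scores)
  top <- labels[ord][seq_len(n_top)]
  (sum(top) / n_top) / (sum(labels) / n)
}

#' Validate docking and screening power per conformation and mode
#'
#' For every (conformation, mode) column of a long score table with activity
#' labels, computes the inhibitor/decoy t-test (Student by default) and the
#' ROC AUC, joins the re-dock RMSD when supplied, and flags docking success
#' (RMSD <= 2 Angstrom) and screening satisfaction (AUC > 0.7).
#'
#' @param score_table long tibble with columns `compound_id`,
#'   `conformation_id`, `mode`, `score` and either a `label` column or a
#'   separate `labels` tibble (`compound_id`, `label`).
#' @param labels optional tibble (`compound_id`, `label` in 0/1).
#' @param redock optional tibble (`conformation_id`, `mode`, `redock_rmsd`).
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @return tibble, one row per (conformation, mode): `t`, `p_value`,
#'   `log10_p`, `auc`, `n_active`, `n_decoy`, plus `redock_rmsd` /
#'   `dock_success` when supplied and `satisfactory` (AUC > 0.7).
#' @export
validate_conformations <- function(score_table, labels = NULL, redock = NULL,
                                   variant = "student") {
  tab <- join_labels(score_table, labels)
  out <- tab %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$conformation_id, .data$mode) %>%
    summarise(
      res = list({
        sc <- .data$score
        lb <- .data$label
        act <- sc[lb == 1]
        dec <- sc[lb == 0]
        tt <- score_ttest(act, dec, variant = variant)
        tibble(
          t = tt$t, p_value = tt$p_value, log10_p = tt$log10_p,
          auc = roc_auc(sc, lb, "lower_is_active"),
          n_active = length(act), n_decoy = length(dec)
        )
      }),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res")
  if (!is.null(redock)) {
    out <- left_join(out, redock, by = c("conformation_id", "mode")) %>%
      mutate(dock_success = docking_power(.data$redock_rmsd))
  }
  mutate(out, satisfactory = .data$auc > 0.7)
}

join_labels <- function(score_table, labels) {
  tab <- as_tibble(score_table)
  if (!is.null(labels)) {
    tab <- left_join(select(tab, -dplyr::any_of("label")), labels, by = "compound_id")
  }
  if (!"label" %in% names(tab)) abort("activity labels are required (column 'label' or labels=)")
  if (anyNA(tab$label)) abort("labels must cover all compounds")
  if (!all(tab$label %in% c(0, 1))) abort("labels must be 0/1")
  tab
}

#' Choose the preferred docking mode per conformation
#'
#' The mode with the stronger screening power wins: smaller t-test p-value
#' (compared in log10 space, which stays informative far below double
#' underflow); ties broken by higher AUC, then by first-listed mode.
#'
#' @param report tibble from [validate_conformations()] (needs
#'   `conformation_id`, `mode`, `log10_p`, `auc`).
#' @return tibble (`conformation_id`, `chosen_mode`).
#' @export
choose_mode <- function(report) {
  report %>%
    group_by(.data$conformation_id) %>%
    mutate(.ord = row_number()) %>%
    arrange(.data$log10_p, desc(.data$auc), .data$.ord, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("conformation_id", chosen_mode = "mode")
}
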