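#' Configuration of the sequential screening cascade
#'
#' Stage sizes default to the scaled published profile of the sequential
#' protocol this package implements: library -> 10,000 top-ranked by docking
#' -> 2,000 by Bayesian consensus score -> 200 drug-like (Lipinski/Veber +
#' REOS) -> 100 scaffold-diverse (Butina at 0.8) -> 49 with required
#' hot-residue interactions. Sizes must be strictly decreasing.
#'
#' @param dock_keep,bayes_keep,druglike_keep,diversity_keep,final_keep stage
#'   survivor caps.
#' @param rank_rule `"best_across_conformations"` (minimum score, the common
#'   ensemble-docking convention; default) or `"mean_across_conformations"`.
#' @param nbc_bins bins for the consensus classifier (default 10).
#' @param similarity_cutoff Butina similarity threshold in (0, 1].
#' @param similarity_strict logical; membership requires `>` rather than `>=`.
#' @param hot_set hot-residue labels (default [pi3kg_hot_residues()]).
#' @param hot_require `"any"` (default) or `"all"`.
#' @param hot_itypes interaction types satisfying the hot filter.
#' @param max_lipinski_violations allowance passed to [filter_druglike()].
#' @param seed integer seed recorded for provenance.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(dock_keep = 10000, bayes_keep = 2000, druglike_keep = 200,
                           diversity_keep = 100, final_keep = 49,
                           rank_rule = c("best_across_conformations",
                                         "mean_across_conformations"),
                           nbc_bins = 10, similarity_cutoff = 0.8,
                           similarity_strict = FALSE,
                           hot_set = pi3kg_hot_residues(),
                           hot_require = "any", hot_itypes = "hbond",
                           max_lipinski_violations = 0, seed = 1) {
  rank_rule <- match.arg(rank_rule)
  sizes <- c(dock_keep, bayes_keep, druglike_keep, diversity_keep, final_keep)
  if (any(diff(sizes) >= 0)) abort("stage sizes must be strictly decreasing", class = "dockscreen_config_error")
  if (similarity_cutoff <= 0 || similarity_cutoff > 1) abort("similarity_cutoff must be in (0, 1]", class = "dockscreen_config_error")
  structure(
    list(
      dock_keep = dock_keep, bayes_keep = bayes_keep, druglike_keep = druglike_keep,
      diversity_keep = diversity_keep, final_keep = final_keep,
      rank_rule = rank_rule, nbc_bins = nbc_bins,
      similarity_cutoff = similarity_cutoff, similarity_strict = similarity_strict,
      hot_set = hot_set, hot_require = hot_require, hot_itypes = hot_itypes,
      max_lipinski_violations = max_lipinski_violations, seed = seed
    ),
    class = "cascade_config"
  )
}

#' @export
print.cascade_config <- function(x, ...) {
  cat(sprintf(
    "<cascade_config>  keep %d -> %d -> %d -> %d -> %d, rank = %s, cutoff = %.2f\n",
    x$dock_keep, x$bayes_keep, x$druglike_keep, x$diversity_keep, x$final_keep,
    x$rank_rule, x$similarity_cutoff
  ))
  invisible(x)
}

#' Read / write a cascade configuration as YAML
#' @param config a `cascade_config`.
#' @param path file path.
#' @return `read_cascade_config()` returns a `cascade_config`.
#' @export
write_cascade_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_cascade_config
#' @export
read_cascade_config <- function(path) {
  do.call(cascade_config, yaml::read_yaml(path))
}

impute_missing_scores <- function(score_table) {
  # failed dockings rank behind everything: worst observed score + 1.0
  score_table %>%
    group_by(.data$conformation_id) %>%
    mutate(score = ifelse(is.na(.data$score), max(.data$score, na.rm = TRUE) + 1, .data$score)) %>%
    ungroup()
}

#' Run the sequential multi-conformation screening cascade
#'
#' Five deterministic stages with a full audit trail:
#' \enumerate{
#'   \item \strong{dock}: rank by the aggregate docking score across
#'     conformations (minimum under `best_across_conformations`, lower =
#'     better; missing scores imputed as worst observed + 1.0), keep
#'     `dock_keep`.
#'   \item \strong{bayes}: re-score survivors with the fitted naive Bayesian
#'     consensus `model`, keep the `bayes_keep` highest.
#'   \item \strong{druglike}: Lipinski/Veber then REOS; keep at most
#'     `druglike_keep` passing compounds, best Bayesian score first.
#'   \item \strong{diversity}: Butina clustering of survivor fingerprints at
#'     `similarity_cutoff`, then a round-robin diversity pick of
#'     `diversity_keep`.
#'   \item \strong{interactions}: hot-residue filter on detected (pose +
#'     receptor) or precomputed interactions; keep at most `final_keep` by
#'     Bayesian score.
#' }
#' Boundary ties break by compound id; survivors of each stage nest in the
#' previous stage's, and a stage with zero survivors completes the run with
#' a warning and empty downstream stages.
#'
#' @param config a [cascade_config()].
#' @param score_table long tibble (`compound_id`, `conformation_id`, `score`)
#'   for the screening library (one mode per conformation).
#' @param model fitted [fit_nbc()] classifier (trained on the labeled
#'   validation set).
#' @param descriptors descriptor tibble covering the library (see
#'   [filter_druglike()] / [filter_reos()]); compounds absent from it are
#'   dropped at stage 3 with a log entry.
#' @param fingerprints fingerprint tibble (`compound_id`, `fp`).
#' @param poses optional named list or tibble of poses per compound (tibble
#'   needs `compound_id`, `element`, `x`, `y`, `z`); used with `receptor`
#'   for geometric interaction detection.
#' @param receptor `structure_model` for detection.
#' @param interactions optional precomputed interaction tibble with a
#'   `compound_id` column (used when poses are not given; detection is
#'   preferred when both are supplied).
#' @return object of class `cascade_result`: `stages` (tibble: stage, n_in,
#'   n_out), `survivors` (list of id vectors per stage), `final` (character),
#'   `log` (per-compound verdict tibble), `config`.
#' @export
run_cascade <- function(config, score_table, model, descriptors, fingerprints,
                        poses = NULL, receptor = NULL, interactions = NULL) {
  stopifnot(inherits(config, "cascade_config"), inherits(model, "nbc_model"))
  score_table <- as_tibble(score_table)
  log <- list()
  note <- function(stage, ids, kept, reason) {
    log[[length(log) + 1L]] <<- tibble(
      stage = stage, compound_id = ids, kept = kept, reason = reason
    )
  }
  all_ids <- sort(unique(score_table$compound_id))

  # stage 1: aggregate docking rank
  agg <- impute_missing_scores(score_table) %>%
    group_by(.data$compound_id) %>%
    summarise(
      agg_score = if (config$rank_rule == "best_across_conformations") {
        min(.data$score)
      } else {
        mean(.data$score)
      },
      .groups = "drop"
    ) %>%
    arrange(.data$agg_score, .data$compound_id)
  s1 <- head(agg$compound_id, config$dock_keep)
  note("dock", agg$compound_id, agg$compound_id %in% s1, "aggregate docking rank")

  # stage 2: Bayesian consensus re-score
  sc <- nbc_score(model, filter(score_table, .data$compound_id %in% s1)) %>%
    arrange(desc(.data$nbc_score), .data$compound_id)
  s2 <- head(sc$compound_id, config$bayes_keep)
  note("bayes", sc$compound_id, sc$compound_id %in% s2, "consensus score rank")
  bayes_rank <- setNames(sc$nbc_score, sc$compound_id)

  # stage 3: drug-likeness
  desc2 <- filter(as_tibble(descriptors), .data$compound_id %in% s2)
  absent <- setdiff(s2, desc2$compound_id)
  if (length(absent)) {
    warn(sprintf("%d compound(s) lack descriptors; dropped at drug-likeness stage", length(absent)))
    note("druglike", absent, FALSE, "no descriptor record")
  }
  dl <- filter_druglike(desc2, max_lipinski_violations = config$max_lipinski_violations)
  re <- filter_reos(desc2)
  verdict <- tibble(
    compound_id = desc2$compound_id,
    ok = dl$pass & re$pass,
    reason = dplyr::if_else(
      dl$pass & re$pass, "drug-like",
      paste(dl$violations, re$violations, sep = ";")
    )
  )
  passing <- verdict$compound_id[verdict$ok]
  passing <- passing[order(-bayes_rank[passing], passing)]
  s3 <- head(passing, config$druglike_keep)
  note("druglike", verdict$compound_id, verdict$compound_id %in% s3, verdict$reason)

  # stage 4: diversity clustering
  s4 <- character(0)
  if (length(s3)) {
    fp3 <- filter(as_tibble(fingerprints), .data$compound_id %in% s3)
    absent <- setdiff(s3, fp3$compound_id)
    if (length(absent)) {
      warn(sprintf("%d compound(s) lack fingerprints; dropped at diversity stage", length(absent)))
      note("diversity", absent, FALSE, "no fingerprint")
    }
    cl <- butina_cluster(fp3, cutoff = config$similarity_cutoff,
                         strict = config$similarity_strict)
    s4 <- diversity_pick(cl, bayes_rank[cl$compound_id],
                         n = min(config$diversity_keep, nrow(cl)))
    note("diversity", cl$compound_id, cl$compound_id %in% s4, "scaffold diversity pick")
  }

  # stage 5: hot-residue interactions
  s5 <- character(0)
  if (length(s4)) {
    get_records <- function(id) {
      if (!is.null(poses) && !is.null(receptor)) {
        pose <- if (is.data.frame(poses)) filter(as_tibble(poses), .data$compound_id == id) else poses[[id]]
        if (is.null(pose) || !nrow(pose)) return(NULL)
        detect_interactions(pose, receptor)
      } else if (!is.null(interactions)) {
        filter(as_tibble(interactions), .data$compound_id == id)
      } else {
        NULL
      }
    }
    kept <- vapply(s4, function(id) {
      recs <- get_records(id)
      if (is.null(recs)) return(NA)
      hot_residue_filter(recs, config$hot_set, require = config$hot_require,
                         itypes = config$hot_itypes)
    }, logical(1))
    if (anyNA(kept)) {
      warn(sprintf("%d compound(s) lack poses/interactions; dropped at interaction stage", sum(is.na(kept))))
      kept[is.na(kept)] <- FALSE
    }
    ok <- s4[kept]
    ok <- ok[order(-bayes_rank[ok], ok)]
    s5 <- head(ok, config$final_keep)
    note("interactions", s4, s4 %in% s5,
         ifelse(kept, "hot-residue contact", "no hot-residue contact"))
  }

  survivors <- list(dock = s1, bayes = s2, druglike = s3, diversity = s4, interactions = s5)
  n_in <- c(length(all_ids), lengths(survivors)[-5])
  stages <- tibble(
    stage = names(survivors),
    n_in = as.integer(n_in),
    n_out = as.integer(lengths(survivors))
  )
  for (i in seq_len(nrow(stages))) {
    if (stages$n_out[i] == 0L) {
      warn(sprintf("stage '%s' produced 0 survivors; downstream stages are empty", stages$stage[i]))
      break
    }
  }
  structure(
    list(stages = stages, survivors = survivors, final = s5,
         log = bind_rows(log), config = config),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  cat(sprintf("final: %d compound(s)\n", length(x$final)))
  invisible(x)
}

#' @rdname run_cascade
#' @param x,object a `cascade_result`.
#' @param ... unused.
#' @return `tidy()` returns the stage table; `glance()` a one-row summary.
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) x$stages

#' @rdname run_cascade
#' @method glance cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  tibble(
    n_library = x$stages$n_in[1], n_final = length(x$final),
    rank_rule = x$config$rank_rule, similarity_cutoff = x$config$similarity_cutoff
  )
}

#' @rdname run_cascade
#' @method autoplot cascade_result
#' @export
autoplot.cascade_result <- function(object, ...) {
  st <- mutate(object$stages, stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "survivors (log scale)",
                  title = "Sequential screening cascade")
}

#' Validate an ensemble and fit the consensus classifier
#'
#' End-to-end screening-power validation: per (conformation, mode) t-test and
#' AUC via [validate_conformations()], preferred-mode choice per
#' [choose_mode()], single-feature naive Bayesian AUC per conformation, and
#' the combined consensus model over all conformations at their chosen modes,
#' with its resubstitution AUC. Conformations at or below AUC 0.7 are
#' flagged unsatisfactory.
#'
#' @param score_table long tibble (`compound_id`, `conformation_id`, `mode`,
#'   `score`) covering >= 2 conformations.
#' @param labels tibble (`compound_id`, `label` 0/1); required.
#' @param redock optional tibble (`conformation_id`, `mode`, `redock_rmsd`).
#' @param n_bins classifier bins (default 10).
#' @param variant t-test variant.
#' @return object of class `ensemble_validation`: `report` (per
#'   conformation x mode), `chosen` (per conformation), `single_auc`,
#'   `combined_auc`, `model` (the fitted `nbc_model`).
#' @export
validate_ensemble <- function(score_table, labels, redock = NULL, n_bins = 10,
                              variant = "student") {
  if (is.null(labels)) abort("labels are required")
  tab <- join_labels(score_table, labels)
  if (length(unique(tab$conformation_id)) < 2) {
    abort("ensemble validation requires >= 2 conformations")
  }
  report <- validate_conformations(tab, redock = redock, variant = variant)
  chosen <- choose_mode(report)
  best <- tab %>%
    dplyr::inner_join(chosen, by = "conformation_id") %>%
    filter(.data$mode == .data$chosen_mode)
  single <- purrr::map_dfr(unique(best$conformation_id), function(cid) {
    sub <- filter(best, .data$conformation_id == cid)
    m1 <- fit_nbc(sub, n_bins = n_bins)
    tibble(conformation_id = cid, single_auc = model_auc(m1, sub))
  })
  model <- fit_nbc(best, n_bins = n_bins)
  structure(
    list(
      report = report, chosen = chosen, single_auc = single,
      combined_auc = model_auc(model, best), model = model
    ),
    class = "ensemble_validation"
  )
}

#' @export
print.ensemble_validation <- function(x, ...) {
  cat(sprintf(
    "<ensemble_validation>  %d conformations; combined consensus AUC %.3f (best single %.3f)\n",
    nrow(x$chosen), x$combined_auc, max(x$single_auc$single_auc)
  ))
  invisible(x)
}

#' @rdname validate_ensemble
#' @param x,object an `ensemble_validation`.
#' @param ... unused.
#' @return `tidy()` returns the per-conformation report joined with the
#'   chosen mode and single-feature AUC; `glance()` the combined model
#'   summary.
#' @method tidy ensemble_validation
#' @export
tidy.ensemble_validation <- function(x, ...) {
  x$report %>%
    left_join(x$chosen, by = "conformation_id") %>%
    left_join(x$single_auc, by = "conformation_id")
}

#' @rdname validate_ensemble
#' @method glance ensemble_validation
#' @export
glance.ensemble_validation <- function(x, ...) {
  tibble(
    n_conformations = nrow(x$chosen),
    best_single_auc = max(x$single_auc$single_auc),
    combined_auc = x$combined_auc,
    consensus_gain = x$combined_auc - max(x$single_auc$single_auc),
    all_satisfactory = all(x$single_auc$single_auc > 0.7)
  )
}

#' @rdname validate_ensemble
#' @method autoplot ensemble_validation
#' @export
autoplot.ensemble_validation <- function(object, ...) {
  df <- bind_rows(
    mutate(object$single_auc, what = .data$conformation_id) %>%
      rename(auc = "single_auc") %>% select("what", "auc"),
    tibble(what = "combined", auc = object$combined_auc)
  )
  df$what <- factor(df$what, levels = df$what)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$auc)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = 2) +
    ggplot2::labs(x = NULL, y = "ROC AUC",
                  title = "Single-conformation vs combined consensus AUC") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
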