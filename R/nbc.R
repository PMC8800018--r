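#' Equal-frequency bin edges for a continuous feature
#'
#' Interior edges at the empirical quantiles i/n_bins (type-7 quantiles, the
#' midpoint convention for even samples). Duplicate quantiles -- heavy ties in
#' the data -- are collapsed with a warning, shrinking the effective bin
#' count.
#'
#' @param values numeric vector (NAs dropped).
#' @param n_bins integer >= 2.
#' @return ascending numeric vector of at most `n_bins - 1` interior edges
#'   (possibly length 0 when all values tie).
#' @examples
#' equal_frequency_edges(1:10, 2) # 5.5
#' @export
equal_frequency_edges <- function(values, n_bins) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  values <- values[!is.na(values)]
  if (!length(values)) abort("no non-missing values to bin")
  if (length(unique(values)) == 1L) {
    warn(sprintf("all values identical: %d requested bins, 1 effective", n_bins))
    return(numeric(0))
  }
  edges <- unname(quantile(values, probs = seq_len(n_bins - 1) / n_bins, type = 7))
  ue <- unique(edges)
  if (length(ue) < length(edges)) {
    warn(sprintf(
      "duplicate quantiles collapsed: %d requested bins, %d effective",
      n_bins, length(ue) + 1L
    ))
  }
  ue
}

#' Fit the Laplacian-corrected naive Bayesian consensus classifier
#'
#' One feature per protein conformation: its docking score, discretized into
#' equal-frequency bins fitted on the full training pool (both classes). For
#' conformation j and bin b holding `A_b` actives out of `N_b` training
#' compounds, the bin weight is the Laplacian-corrected log relative
#' likelihood
#' \deqn{w_{jb} = \ln\frac{A_b + 1}{(N_b + 1)\,\pi},\qquad \pi = A_{tot}/N_{tot},}
#' the estimator standard in the Bayesian-categorization tool family. The
#' class prior \eqn{\pi} absorbs the 1:20 inhibitor:decoy imbalance; no
#' resampling is done. A Gaussian class-conditional likelihood is available
#' behind `likelihood = "gaussian"` for sensitivity analysis.
#'
#' @param score_table long tibble (`compound_id`, `conformation_id`, `score`;
#'   at most one row per compound x conformation; `NA` or absent rows =
#'   missing scores) with a `label` column or a separate `labels` tibble.
#' @param labels optional tibble (`compound_id`, `label` 0/1).
#' @param n_bins bins per conformation, default 10.
#' @param likelihood `"binned"` (default) or `"gaussian"`.
#' @return object of class `nbc_model`.
#' @examples
#' tab <- tibble::tibble(
#'   compound_id = sprintf("c%d", 1:8), conformation_id = "conf1",
#'   score = c(-9, -8, -8, -7, -5, -4, -4, -3),
#'   label = c(1, 1, 1, 1, 0, 0, 0, 0)
#' )
#' fit_nbc(tab, n_bins = 2)
#' @export
fit_nbc <- function(score_table, labels = NULL, n_bins = 10,
                    likelihood = c("binned", "gaussian")) {
  likelihood <- match.arg(likelihood)
  tab <- join_labels(score_table, labels)
  if (anyDuplicated(tab[, c("compound_id", "conformation_id")])) {
    abort("one score per compound x conformation expected; pick a mode first")
  }
  lab_by_cpd <- distinct(tab, .data$compound_id, .data$label)
  if (anyDuplicated(lab_by_cpd$compound_id)) abort("conflicting labels for a compound")
  n_total <- nrow(lab_by_cpd)
  a_total <- sum(lab_by_cpd$label == 1)
  if (a_total == 0 || a_total == n_total) abort("both classes must be present")
  prior <- a_total / n_total

  conf_ids <- unique(tab$conformation_id)
  per_conf <- lapply(conf_ids, function(cid) {
    sub <- filter(tab, .data$conformation_id == cid, !is.na(.data$score))
    if (!nrow(sub)) abort(sprintf("conformation %s has no non-missing scores", cid))
    if (likelihood == "gaussian") {
      act <- sub$score[sub$label == 1]; dec <- sub$score[sub$label == 0]
      if (length(act) < 2 || length(dec) < 2) abort("gaussian likelihood needs >= 2 per class")
      return(list(
        mu_a = mean(act), sd_a = sd(act), mu_d = mean(dec), sd_d = sd(dec)
      ))
    }
    edges <- withCallingHandlers(
      equal_frequency_edges(sub$score, n_bins),
      warning = function(w) {
        warn(sprintf("conformation %s: %s", cid, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    bin <- findInterval(sub$score, edges) + 1L
    nb <- length(edges) + 1L
    A <- tabulate(bin[sub$label == 1], nbins = nb)
    N <- tabulate(bin, nbins = nb)
    list(
      edges = edges,
      weights = log((A + 1) / ((N + 1) * prior)),
      n_active = A, n_total = N
    )
  })
  names(per_conf) <- conf_ids
  structure(
    list(
      conformation_ids = conf_ids, per_conf = per_conf,
      prior_active = prior, n_bins = n_bins, likelihood = likelihood,
      n_train = n_total, n_train_active = a_total
    ),
    class = "nbc_model"
  )
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf(
    "<nbc_model>  %d conformation feature(s), %s likelihood, prior_active %.4f (n = %d)\n",
    length(x$conformation_ids), x$likelihood, x$prior_active, x$n_train
  ))
  invisible(x)
}

#' Score compounds with a fitted naive Bayesian model
#'
#' The consensus score of a compound is the sum over conformations of the
#' weight of the bin its docking score falls in; scores outside the training
#' range clamp to the first/last bin, and missing per-conformation scores are
#' simply skipped (the naive-Bayes marginalization). Higher = more
#' inhibitor-like. A compound missing every score is an error.
#'
#' @param model an `nbc_model`.
#' @param score_table long tibble (`compound_id`, `conformation_id`, `score`);
#'   conformations unknown to the model are ignored with a warning.
#' @return tibble (`compound_id`, `nbc_score`), one row per compound, input
#'   order of first appearance preserved.
#' @export
nbc_score <- function(model, score_table) {
  stopifnot(inherits(model, "nbc_model"))
  tab <- as_tibble(score_table)
  extra <- setdiff(unique(tab$conformation_id), model$conformation_ids)
  if (length(extra)) {
    warn(sprintf("ignoring unknown conformation(s): %s", paste(extra, collapse = ", ")))
    tab <- filter(tab, !.data$conformation_id %in% extra)
  }
  cpds <- unique(tab$compound_id)
  if (!length(cpds)) abort("no compounds to score")
  tab <- filter(tab, !is.na(.data$score))
  if (length(setdiff(cpds, unique(tab$compound_id)))) {
    abort(sprintf(
      "compound(s) with all scores missing: %s",
      paste(head(setdiff(cpds, unique(tab$compound_id)), 5), collapse = ", ")
    ))
  }
  contrib <- tab %>%
    group_by(.data$conformation_id) %>%
    mutate(w = {
      pc <- model$per_conf[[.data$conformation_id[1]]]
      if (model$likelihood == "gaussian") {
        la <- stats::dnorm(.data$score, pc$mu_a, pc$sd_a, log = FALSE)
        ld <- stats::dnorm(.data$score, pc$mu_d, pc$sd_d, log = FALSE)
        mix <- model$prior_active * la + (1 - model$prior_active) * ld
        log(pmax(la, 1e-300)) - log(pmax(mix, 1e-300))
      } else {
        pc$weights[findInterval(.data$score, pc$edges) + 1L]
      }
    }) %>%
    ungroup()
  out <- contrib %>%
    group_by(.data$compound_id) %>%
    summarise(nbc_score = sum(.data$w), .groups = "drop")
  out[match(cpds, out$compound_id), ]
}

#' Resubstitution AUC of a fitted naive Bayesian model
#'
#' Scores the table with [nbc_score()] and measures the ROC AUC of the
#' consensus score against the activity labels (higher score = more active).
#' An AUC above 0.7 is the conventional satisfaction line for a screening
#' model.
#'
#' @inheritParams nbc_score
#' @param labels optional tibble (`compound_id`, `label`); otherwise a
#'   `label` column of `score_table` is used.
#' @return AUC in \[0, 1\].
#' @export
model_auc <- function(model, score_table, labels = NULL) {
  tab <- join_labels(score_table, labels)
  sc <- nbc_score(model, tab)
  lab <- distinct(tab, .data$compound_id, .data$label)
  sc <- left_join(sc, lab, by = "compound_id")
  roc_auc(sc$nbc_score, sc$label, orientation = "higher_is_active")
}

#' Stratified k-fold cross-validated AUC of the consensus model
#'
#' Optional check of generalization: the headline validation protocol is
#' resubstitution, matching standard screening practice.
#'
#' @inheritParams fit_nbc
#' @param k folds (default 5).
#' @param seed integer seed for the stratified shuffle.
#' @return tibble (`fold`, `auc`).
#' @export
nbc_cv_auc <- function(score_table, labels = NULL, n_bins = 10, k = 5, seed = 1) {
  tab <- join_labels(score_table, labels)
  lab <- distinct(tab, .data$compound_id, .data$label)
  set.seed(seed)
  fold_of <- integer(0)
  for (ids in split(lab$compound_id, lab$label)) {
    fold_of[ids] <- sample(rep_len(seq_len(k), length(ids)))
  }
  purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- names(fold_of)[fold_of == f]
    train <- filter(tab, !.data$compound_id %in% test_ids)
    test <- filter(tab, .data$compound_id %in% test_ids)
    m <- fit_nbc(train, n_bins = n_bins)
    sc <- left_join(nbc_score(m, test), lab, by = "compound_id")
    tibble(fold = f, auc = roc_auc(sc$nbc_score, sc$label, "higher_is_active"))
  })
}

#' @rdname fit_nbc
#' @param x an `nbc_model`.
#' @param ... unused.
#' @return `tidy()` returns one row per conformation x bin with the edge
#'   interval, Laplacian-corrected weight and training counts; `glance()` a
#'   one-row model summary.
#' @method tidy nbc_model
#' @export
tidy.nbc_model <- function(x, ...) {
  if (x$likelihood == "gaussian") {
    return(purrr::imap_dfr(x$per_conf, function(pc, cid) {
      tibble(conformation_id = cid, mu_active = pc$mu_a, sd_active = pc$sd_a,
             mu_decoy = pc$mu_d, sd_decoy = pc$sd_d)
    }))
  }
  purrr::imap_dfr(x$per_conf, function(pc, cid) {
    nb <- length(pc$weights)
    tibble(
      conformation_id = cid, bin = seq_len(nb),
      lower = c(-Inf, pc$edges), upper = c(pc$edges, Inf),
      weight = pc$weights, n_active = pc$n_active, n_total = pc$n_total
    )
  })
}

#' @rdname fit_nbc
#' @method glance nbc_model
#' @export
glance.nbc_model <- function(x, ...) {
  tibble(
    n_conformations = length(x$conformation_ids), n_bins = x$n_bins,
    likelihood = x$likelihood, prior_active = x$prior_active,
    n_train = x$n_train, n_train_active = x$n_train_active
  )
}

#' @rdname fit_nbc
#' @param object an `nbc_model` (for `autoplot`).
#' @method autoplot nbc_model
#' @export
autoplot.nbc_model <- function(object, ...) {
  td <- tidy(object)
  if (object$likelihood == "gaussian") abort("autoplot supports the binned likelihood")
  td$mid <- ifelse(
    is.finite(td$lower) & is.finite(td$upper), (td$lower + td$upper) / 2,
    ifelse(is.finite(td$upper), td$upper - 0.5, td$lower + 0.5)
  )
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mid, y = .data$weight)) +
    ggplot2::geom_col(width = 0.8 * min(diff(sort(unique(td$mid))), na.rm = TRUE)) +
    ggplot2::facet_wrap(~conformation_id) +
    ggplot2::labs(
      x = "docking score (bin midpoint, kcal/mol-like)",
      y = "log likelihood-ratio weight",
      title = "Naive Bayesian classifier bin weights"
    )
}

#' Serialize / restore an nbc_model as versioned JSON
#'
#' Deterministic field order; edges, weights, per-bin counts and the class
#' prior are stored at full double precision.
#'
#' @param model an `nbc_model`.
#' @param path file path.
#' @return `read_nbc()` returns the restored `nbc_model`.
#' @export
write_nbc <- function(model, path) {
  stopifnot(inherits(model, "nbc_model"))
  doc <- list(
    format = "dockscreen-nbc", version = 1L,
    likelihood = model$likelihood, n_bins = model$n_bins,
    prior_active = model$prior_active,
    n_train = model$n_train, n_train_active = model$n_train_active,
    conformations = lapply(model$conformation_ids, function(cid) {
      pc <- model$per_conf[[cid]]
      c(list(id = cid), pc)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_nbc
#' @export
read_nbc <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$format, "dockscreen-nbc")) abort("not a dockscreen NBC document")
  per_conf <- lapply(doc$conformations, function(pc) {
    out <- pc[setdiff(names(pc), "id")]
    if (!is.null(out$edges)) out$edges <- as.numeric(out$edges)
    out
  })
  names(per_conf) <- vapply(doc$conformations, `[[`, "", "id")
  structure(
    list(
      conformation_ids = names(per_conf), per_conf = per_conf,
      prior_active = doc$prior_active, n_bins = doc$n_bins,
      likelihood = doc$likelihood, n_train = doc$n_train,
      n_train_active = doc$n_train_active
    ),
    class = "nbc_model"
  )
}
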