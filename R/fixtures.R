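#' Synthetic ensemble docking-score table
#'
#' Emulates inhibitor/decoy score distributions over an ensemble of receptor
#' conformations with a Gaussian equicorrelation factor model: per compound a
#' latent aptitude `z ~ N(0,1)` and, for conformation j,
#' `score_j = mu_class_j + sigma * (sqrt(rho) z + sqrt(1-rho) eps_j)`,
#' `eps_j ~ N(0,1)`. Lower scores = better docking, so inhibitor means sit
#' below decoy means; the single-conformation ROC AUC is the closed form
#' `pnorm((mu_decoy - mu_active) / (sigma * sqrt(2)))` at `rho = 0`. Entries
#' are masked missing (failed docking) at `missing_rate`. The default sizes
#' mirror the validation design this package targets: 800 inhibitors against
#' 16,000 decoys (1:20) over 10 conformations.
#'
#' @param n_active,n_decoy class sizes (defaults 800 / 16,000).
#' @param n_conformations ensemble size (default 10).
#' @param mu_active,mu_decoy class score means, scalar or per-conformation
#'   vector (defaults -8 / -6, about AUC 0.92 per conformation at sigma 1).
#' @param sigma score standard deviation (> 0, default 1).
#' @param rho inter-conformation correlation in \[0, 1).
#' @param missing_rate fraction of entries masked missing, in \[0, 1).
#' @param seed integer seed; identical seed + config reproduces the table
#'   byte-identically.
#' @return long tibble (`compound_id`, `conformation_id`, `mode`, `score`,
#'   `label`) with `mode = "SIM"`.
#' @export
gen_score_table <- function(n_active = 800, n_decoy = 16000, n_conformations = 10,
                            mu_active = -8, mu_decoy = -6, sigma = 1,
                            rho = 0, missing_rate = 0, seed = 1) {
  if (n_active < 1 || n_decoy < 1 || n_conformations < 1) abort("counts must be >= 1")
  if (sigma <= 0) abort("sigma must be > 0")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  mu_active <- rep_len(mu_active, n_conformations)
  mu_decoy <- rep_len(mu_decoy, n_conformations)
  if (!all(is.finite(c(mu_active, mu_decoy)))) abort("means must be finite")
  set.seed(seed)
  n <- n_active + n_decoy
  wid <- nchar(as.character(n))
  ids <- sprintf(paste0("CPD%0", wid, "d"), seq_len(n))
  label <- c(rep(1L, n_active), rep(0L, n_decoy))
  z <- rnorm(n)
  eps <- matrix(rnorm(n * n_conformations), n, n_conformations)
  mu <- matrix(rep(mu_decoy, each = n), n, n_conformations)
  mu[label == 1L, ] <- matrix(rep(mu_active, each = n_active), n_active, n_conformations)
  sc <- mu + sigma * (sqrt(rho) * z + sqrt(1 - rho) * eps)
  if (missing_rate > 0) sc[runif(n * n_conformations) < missing_rate] <- NA_real_
  conf <- sprintf("conf%02d", seq_len(n_conformations))
  tibble(
    compound_id = rep(ids, times = n_conformations),
    conformation_id = rep(conf, each = n),
    mode = "SIM",
    score = as.vector(sc),
    label = rep(label, times = n_conformations)
  )
}

#' Separation giving a target single-conformation Gaussian AUC
#'
#' Inverts the closed form `AUC = pnorm(delta / (sigma * sqrt(2)))`: the
#' decoy-minus-active mean gap that calibrates one conformation's score
#' feature to a wanted AUC under the [gen_score_table()] model.
#'
#' @param auc target AUC in (0.5, 1).
#' @param sigma score SD (default 1).
#' @return mean separation `mu_decoy - mu_active`.
#' @export
auc_to_separation <- function(auc, sigma = 1) {
  if (auc <= 0 || auc >= 1) abort("auc must be in (0, 1)")
  qnorm(auc) * sigma * sqrt(2)
}

#' Synthetic physicochemical descriptor table
#'
#' Each filter-relevant property is drawn from a two-component mixture:
#' with the rule's pass probability a value uniform inside the passing window,
#' otherwise uniform in a flanking out-of-range band, so the marginal pass
#' rate of each rule equals the requested probability and rules are
#' independent across properties. Reactive-group flags are Bernoulli with
#' fail probability `1 - pass_probability`.
#'
#' @param n number of compounds.
#' @param pass_probability scalar or named vector over
#'   `c("mw", "logp", "hbd", "hba", "rotb", "tpsa", "formal_charge",
#'   "heavy_atoms", "reactive")` (default 0.9 for each).
#' @param seed integer seed.
#' @return descriptor tibble consumable by [filter_druglike()] and
#'   [filter_reos()], with `reactive_aldehyde` and `reactive_michael_acceptor`
#'   flag columns.
#' @export
gen_descriptor_table <- function(n, pass_probability = 0.9, seed = 1) {
  props <- c("mw", "logp", "hbd", "hba", "rotb", "tpsa", "formal_charge",
             "heavy_atoms", "reactive")
  p <- if (length(pass_probability) == 1L && is.null(names(pass_probability))) {
    setNames(rep(pass_probability, length(props)), props)
  } else {
    out <- setNames(rep(0.9, length(props)), props)
    out[names(pass_probability)] <- pass_probability
    out
  }
  if (any(p < 0 | p > 1)) abort("pass probabilities must be in [0, 1]")
  set.seed(seed)
  wid <- nchar(as.character(n))
  mix <- function(prob, lo, hi, bad_lo, bad_hi, integer = FALSE) {
    pass <- runif(n) < prob
    v <- ifelse(pass, runif(n, lo, hi), runif(n, bad_lo, bad_hi))
    if (integer) round(v) else v
  }
  tibble(
    compound_id = sprintf(paste0("CPD%0", wid, "d"), seq_len(n)),
    # passing windows: intersection of the Lipinski/Veber and REOS ranges
    mw = mix(p["mw"], 200, 500, 501, 900),
    logp = mix(p["logp"], -5, 5, 5.01, 12),
    hbd = mix(p["hbd"], 0, 5.49, 6, 12, integer = TRUE),
    hba = mix(p["hba"], 0, 10.49, 11, 20, integer = TRUE),
    rotb = mix(p["rotb"], 0, 8.49, 9, 20, integer = TRUE),
    tpsa = mix(p["tpsa"], 20, 140, 140.1, 300),
    formal_charge = mix(p["formal_charge"], -2.49, 2.49, 3, 6, integer = TRUE),
    heavy_atoms = mix(p["heavy_atoms"], 15, 50.49, 51, 90, integer = TRUE),
    reactive_aldehyde = runif(n) >= sqrt(p["reactive"]),
    reactive_michael_acceptor = runif(n) >= sqrt(p["reactive"])
  )
}

#' Synthetic clustered fingerprint population
#'
#' Per planted cluster a random template bit set (near-disjoint across
#' clusters); members copy the template and flip member-specific bits at a
#' rate calibrated so the expected within-cluster Tanimoto similarity is
#' approximately `within_sim_target`.
#'
#' @param n_clusters,members_per_cluster planted structure.
#' @param within_sim_target expected within-cluster similarity in (0, 1].
#' @param nbits fingerprint length (default 2048).
#' @param n_on approximate on-bits per template (default 64).
#' @param seed integer seed.
#' @return fingerprint tibble (`compound_id`, `cluster_truth`, `fp`
#'   list-column) with attribute `nbits`.
#' @export
gen_fingerprints <- function(n_clusters, members_per_cluster, within_sim_target = 0.9,
                             nbits = 2048, n_on = 64, seed = 1) {
  if (within_sim_target <= 0 || within_sim_target > 1) abort("within_sim_target must be in (0, 1]")
  set.seed(seed)
  # two members share ~n(1-f)^2 bits of a union ~n(2-(1-f)^2), so
  # E[sim] = (1-f)^2 / (2-(1-f)^2); inverting gives the flip fraction
  t <- within_sim_target
  f <- if (t >= 1) 0 else 1 - sqrt(2 * t / (1 + t))
  pool <- seq_len(nbits)
  out <- list()
  for (k in seq_len(n_clusters)) {
    # templates near-disjoint while bit capacity lasts, then recycled
    if (length(pool) < n_on) pool <- seq_len(nbits)
    tmpl <- sort(sample(pool, n_on))
    pool <- setdiff(pool, tmpl)
    for (m in seq_len(members_per_cluster)) {
      drop_n <- rbinom(1, n_on, f)
      keep <- if (drop_n > 0) sort(sample(tmpl, n_on - drop_n)) else tmpl
      gain_n <- rbinom(1, n_on, f)
      gain <- if (gain_n > 0 && length(pool) >= gain_n) sort(sample(pool, gain_n)) else integer(0)
      out[[length(out) + 1L]] <- list(
        compound_id = sprintf("FP%02d_%02d", k, m),
        cluster_truth = k,
        fp = sort(c(keep, gain))
      )
    }
  }
  res <- tibble(
    compound_id = purrr::map_chr(out, "compound_id"),
    cluster_truth = purrr::map_int(out, "cluster_truth"),
    fp = purrr::map(out, "fp")
  )
  attr(res, "nbits") <- nbits
  res
}

#' Toy receptor + ligand pose with controllable hot-residue geometry
#'
#' Builds a small helical-spacing chain of `n_residues` residues (backbone
#' N/CA/C/O plus a CB side-chain carbon each; designated hot positions get
#' Val-like naming) and a ligand pose. With `ligand_near = TRUE` the ligand
#' places, for every hot residue, an O acceptor 2.9 Angstrom from that
#' residue's backbone N plus a donor O-H pair, so the H-bond detector fires;
#' with `FALSE` the whole ligand sits >= 6 Angstrom from every residue.
#'
#' @param n_residues chain length.
#' @param hot_positions integer residue positions designated hot (named
#'   `VAL`); others are `ALA`.
#' @param ligand_near logical (default TRUE).
#' @param seed integer seed (jitters non-essential atoms only).
#' @return list with `receptor` (`structure_model`, resolution 2.0) and
#'   `pose` (tibble `element`, `x`, `y`, `z`, `charge`), plus `hot_set`
#'   labels.
#' @export
gen_toy_complex <- function(n_residues = 8, hot_positions = c(3, 6),
                            ligand_near = TRUE, seed = 1) {
  if (any(hot_positions > n_residues | hot_positions < 1)) {
    abort("hot_positions must index generated residues")
  }
  set.seed(seed)
  res <- purrr::map_dfr(seq_len(n_residues), function(i) {
    # helical spacing keeps the CA trace non-collinear
    base <- c(3.8 * i, 2.0 * sin(i), 2.0 * cos(i))
    tibble(
      name = c("N", "CA", "C", "O", "CB"),
      residue_name = if (i %in% hot_positions) "VAL" else "ALA",
      chain = "A",
      residue_number = 880L + i,
      element = c("N", "C", "C", "O", "C"),
      x = base[1] + c(0, 0.8, 1.6, 1.9, 0.9),
      y = base[2] + c(0, 1.0, 0.4, -0.7, 2.1),
      z = base[3] + c(0, 0.3, 1.0, 1.4, 0.6)
    )
  })
  res$serial <- seq_len(nrow(res))
  receptor <- new_structure_model(
    id = "TOYX", resolution = 2.0,
    atoms = select(res, "serial", "name", "residue_name", "chain",
                   "residue_number", "element", "x", "y", "z"),
    het_ligand = res[0, c("serial", "name", "residue_name", "chain",
                          "residue_number", "element", "x", "y", "z")]
  )
  hot <- filter(res, .data$residue_number %in% (880L + hot_positions), .data$name == "N")
  pose <- purrr::map_dfr(seq_len(nrow(hot)), function(k) {
    # acceptor O 2.9 A from the backbone N, plus a donor O-H aimed at it
    acc <- c(hot$x[k], hot$y[k] - 2.9, hot$z[k])
    don <- acc + c(1.2, -2.2, 0)
    h <- don + 0.97 * (c(hot$x[k], hot$y[k], hot$z[k]) - don) /
      sqrt(sum((c(hot$x[k], hot$y[k], hot$z[k]) - don)^2))
    tibble(
      element = c("O", "O", "H", "C"),
      x = c(acc[1], don[1], h[1], don[1] + 1.4),
      y = c(acc[2], don[2], h[2], don[2] - 1.0),
      z = c(acc[3], don[3], h[3], don[3])
    )
  })
  pose$charge <- 0
  if (!ligand_near) {
    pose <- mutate(pose, y = .data$y - 30) # > 6 A from every residue
  }
  list(
    receptor = receptor,
    pose = pose,
    hot_set = paste0("Val", 880L + hot_positions)
  )
}

#' Synthetic snapshot series around a base pose
#'
#' Frame 1 is the base pose; later frames add isotropic per-atom Gaussian
#' jitter of SD `jitter_sigma` per axis, so the closed-form per-atom RMSF of
#' a long series approaches `jitter_sigma * sqrt(3)`.
#'
#' @param pose base pose tibble (`element`, `x`, `y`, `z`).
#' @param n_frames number of frames (>= 2).
#' @param jitter_sigma per-axis jitter SD in Angstrom.
#' @param seed integer seed.
#' @return trajectory tibble (`frame`, `atom`, `element`, `x`, `y`, `z`).
#' @export
gen_snapshot_series <- function(pose, n_frames, jitter_sigma = 0.5, seed = 1) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  pose <- pose_atoms(pose)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_frames), function(fr) {
    j <- if (fr == 1L) 0 else matrix(rnorm(3 * nrow(pose), 0, jitter_sigma), ncol = 3)
    tibble(
      frame = fr, atom = seq_len(nrow(pose)), element = pose$element,
      x = pose$x + if (fr == 1L) 0 else j[, 1],
      y = pose$y + if (fr == 1L) 0 else j[, 2],
      z = pose$z + if (fr == 1L) 0 else j[, 3]
    )
  })
}
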