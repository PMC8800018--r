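small_screen <- function(seed = 1, n_active = 60, n_decoy = 1200, n_library = 2000) {
  sep <- auc_to_separation(0.85)
  train <- gen_score_table(n_active, n_decoy, 4, mu_active = -6 - sep,
                           mu_decoy = -6, rho = 0, seed = seed)
  model <- fit_nbc(train, n_bins = 10)
  lib <- gen_score_table(
    n_active = max(2, round(n_library * 0.05)),
    n_decoy = n_library - max(2, round(n_library * 0.05)),
    n_conformations = 4, mu_active = -6 - sep, mu_decoy = -6, rho = 0,
    seed = seed + 100
  ) %>%
    dplyr::mutate(compound_id = paste0("LIB", .data$compound_id)) %>%
    dplyr::select(-"label")
  desc <- gen_descriptor_table(dplyr::n_distinct(lib$compound_id),
                               pass_probability = 0.93, seed = seed + 200) %>%
    dplyr::mutate(compound_id = sort(unique(lib$compound_id)))
  fps <- gen_fingerprints(
    n_clusters = ceiling(dplyr::n_distinct(lib$compound_id) / 4),
    members_per_cluster = 4, within_sim_target = 0.9, nbits = 512,
    n_on = 48, seed = seed + 300
  )[seq_len(dplyr::n_distinct(lib$compound_id)), ] %>%
    dplyr::mutate(compound_id = sort(unique(lib$compound_id)))
  # precomputed interactions: every library compound H-bonds Val882 except
  # ids ending in 0 (drops ~10% at the final stage)
  ids <- sort(unique(lib$compound_id))
  inter <- tibble::tibble(
    compound_id = ids[!grepl("0$", ids)],
    chain = "A", residue_number = 882L, residue_name = "VAL",
    itype = "hbond", distance = 2.9, angle = 160, ligand_atom = 1L
  )
  list(model = model, lib = lib, desc = desc, fps = fps, inter = inter)
}

test_config <- function(...) {
  cascade_config(dock_keep = 200, bayes_keep = 100, druglike_keep = 20,
                 diversity_keep = 10, final_keep = 5, ...)
}

test_that("config validation rejects non-decreasing sizes and bad cutoffs", {
  expect_error(cascade_config(dock_keep = 100, bayes_keep = 100),
               class = "dockscreen_config_error")
  expect_error(cascade_config(similarity_cutoff = 0),
               class = "dockscreen_config_error")
  cfg <- test_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cascade_config(cfg, path)
  cfg2 <- read_cascade_config(path)
  expect_equal(cfg2$dock_keep, cfg$dock_keep)
  expect_equal(cfg2$hot_set, cfg$hot_set)
})

test_that("cascade hits the configured stage sizes and nests monotonically", {
  sc <- small_screen(seed = 3)
  res <- run_cascade(test_config(), sc$lib, sc$model, sc$desc, sc$fps,
                     interactions = sc$inter)
  expect_equal(res$stages$n_out, c(200L, 100L, 20L, 10L, 5L))
  sv <- res$survivors
  expect_true(all(sv$bayes %in% sv$dock))
  expect_true(all(sv$druglike %in% sv$bayes))
  expect_true(all(sv$diversity %in% sv$druglike))
  expect_true(all(sv$interactions %in% sv$diversity))
  expect_equal(res$final, sv$interactions)
  # audit log covers every stage decision
  expect_setequal(unique(res$log$stage),
                  c("dock", "bayes", "druglike", "diversity", "interactions"))
})

test_that("cascade reruns are identical and row order does not matter", {
  sc <- small_screen(seed = 5)
  r1 <- run_cascade(test_config(), sc$lib, sc$model, sc$desc, sc$fps,
                    interactions = sc$inter)
  r2 <- run_cascade(test_config(), sc$lib, sc$model, sc$desc, sc$fps,
                    interactions = sc$inter)
  expect_identical(r1$final, r2$final)
  shuffle <- function(df) df[sample(nrow(df)), ]
  set.seed(9)
  r3 <- run_cascade(test_config(), shuffle(sc$lib), sc$model,
                    shuffle(sc$desc), sc$fps[sample(nrow(sc$fps)), ],
                    interactions = shuffle(sc$inter))
  expect_identical(r1$final, r3$final)
  expect_equal(r1$stages, r3$stages)
})

test_that("affine score transforms leave ranking and consensus order alone", {
  sc <- small_screen(seed = 7)
  cfg <- test_config()
  r1 <- run_cascade(cfg, sc$lib, sc$model, sc$desc, sc$fps,
                    interactions = sc$inter)
  # positive affine transform of all scores; classifier refitted on the
  # identically transformed training pool
  sep <- auc_to_separation(0.85)
  train <- gen_score_table(60, 1200, 4, mu_active = -6 - sep, mu_decoy = -6,
                           rho = 0, seed = 7)
  t_train <- dplyr::mutate(train, score = 2.5 * score + 7)
  t_lib <- dplyr::mutate(sc$lib, score = 2.5 * score + 7)
  model_t <- fit_nbc(t_train, n_bins = 10)
  r2 <- run_cascade(cfg, t_lib, model_t, sc$desc, sc$fps,
                    interactions = sc$inter)
  expect_identical(r1$final, r2$final)
  expect_equal(r1$stages, r2$stages)
})

test_that("a stage that annihilates the pool warns and empties downstream", {
  sc <- small_screen(seed = 11)
  desc_fail <- dplyr::mutate(sc$desc, mw = 1500) # everything fails REOS + Lipinski
  expect_warning(
    res <- run_cascade(test_config(), sc$lib, sc$model, desc_fail, sc$fps,
                       interactions = sc$inter),
    "0 survivors"
  )
  expect_equal(res$stages$n_out[3:5], c(0L, 0L, 0L))
  expect_length(res$final, 0)
})

test_that("geometric detection path keeps only hot-residue binders", {
  sc <- small_screen(seed = 13)
  ids4 <- run_cascade(test_config(), sc$lib, sc$model, sc$desc, sc$fps,
                      interactions = sc$inter)$survivors$diversity
  near <- gen_toy_complex(n_residues = 8, hot_positions = 3, seed = 1)
  far <- gen_toy_complex(n_residues = 8, hot_positions = 3,
                         ligand_near = FALSE, seed = 1)
  # half the stage-4 survivors get a binding pose, half a distant one
  poses <- purrr::map_dfr(seq_along(ids4), function(i) {
    p <- if (i %% 2 == 1) near$pose else far$pose
    dplyr::mutate(p, compound_id = ids4[i])
  })
  cfg <- test_config(hot_set = near$hot_set)
  res <- suppressWarnings(
    run_cascade(cfg, sc$lib, sc$model, sc$desc, sc$fps,
                poses = poses, receptor = near$receptor)
  )
  expect_setequal(res$final, ids4[seq_along(ids4) %% 2 == 1][1:5])
})

test_that("validate_ensemble picks modes, fits the consensus and reports gain", {
  sep <- auc_to_separation(0.75)
  sp <- gen_score_table(100, 2000, 5, mu_active = -6 - sep, mu_decoy = -6,
                        rho = 0, seed = 17)
  xp <- gen_score_table(100, 2000, 5, mu_active = -6 - sep / 2, mu_decoy = -6,
                        rho = 0, seed = 18) %>%
    dplyr::mutate(mode = "XP")
  tab <- dplyr::bind_rows(dplyr::mutate(sp, mode = "SP"), xp)
  labels <- dplyr::distinct(tab, compound_id, label)
  ev <- validate_ensemble(dplyr::select(tab, -label), labels = labels)
  expect_s3_class(ev, "ensemble_validation")
  # SP separates better by construction: chosen everywhere
  expect_true(all(ev$chosen$chosen_mode == "SP"))
  g <- glance(ev)
  expect_gt(g$consensus_gain, 0)
  expect_gt(g$combined_auc, g$best_single_auc)
  td <- tidy(ev)
  expect_equal(nrow(td), 10) # 5 conformations x 2 modes
  expect_error(
    validate_ensemble(dplyr::filter(tab, conformation_id == "conf01"), labels),
    ">= 2 conformations"
  )
})

test_that("plot constructors return ggplot objects", {
  sc <- small_screen(seed = 19)
  res <- run_cascade(test_config(), sc$lib, sc$model, sc$desc, sc$fps,
                     interactions = sc$inter)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(sc$model), "ggplot")
  tab <- gen_score_table(50, 1000, 2, seed = 20)
  expect_s3_class(plot_roc(tab$score, tab$label), "ggplot")
  expect_s3_class(plot_score_distributions(tab), "ggplot")
})
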