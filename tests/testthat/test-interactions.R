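simple_receptor <- function() {
  atoms <- tibble::tibble(
    serial = 1:6,
    name = c("N", "CA", "C", "O", "CB", "CG"),
    residue_name = "VAL", chain = "A", residue_number = 882L,
    element = c("N", "C", "C", "O", "C", "C"),
    x = c(0, 1.5, 2.5, 3.4, 1.8, 2.6),
    y = c(0, 0.8, 0, -0.8, 2.2, 3.3),
    z = 0
  )
  dockscreen:::new_structure_model("RCPT", 2, atoms, atoms[0, ])
}

donor_pose <- function(dist, angle_deg) {
  # ligand donor O with explicit H aimed so that D-H...A = angle_deg, where
  # A is the receptor backbone N at the origin
  d <- c(0, -dist, 0)
  theta <- (180 - angle_deg) * pi / 180
  h <- d + 0.97 * c(sin(theta), cos(theta), 0)
  tibble::tibble(
    element = c("O", "H"),
    x = c(d[1], h[1]), y = c(d[2], h[2]), z = 0,
    charge = 0
  )
}

test_that("H-bond detection gates on distance and D-H...A angle", {
  rec <- simple_receptor()
  hit <- detect_hbonds(donor_pose(2.9, 165), rec)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$itype, "hbond")
  expect_equal(hit$residue_number, 882L)
  expect_equal(hit$distance, 2.9, tolerance = 1e-6)
  expect_gt(hit$angle, 150)
  expect_equal(nrow(detect_hbonds(donor_pose(3.6, 165), rec)), 0)
  expect_equal(nrow(detect_hbonds(donor_pose(3.0, 100), rec)), 0)
})

test_that("without donor hydrogens the angle gate is skipped with a warning", {
  rec <- simple_receptor()
  bare <- tibble::tibble(element = "O", x = 0, y = -2.9, z = 0, charge = 0)
  expect_warning(hit <- detect_hbonds(bare, rec), "angle gate skipped")
  expect_equal(nrow(hit), 1)
  expect_true(is.na(hit$angle))
})

test_that("hydrophobic contacts use side-chain carbons, aggregated per residue", {
  rec <- simple_receptor()
  # carbon at 4.0 from CB (side chain): contact
  near <- tibble::tibble(element = "C", x = 1.8, y = 6.2, z = 0) # 4.0 from CB
  hit <- detect_hydrophobic(near, rec)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, min(sqrt((1.8 - 1.8)^2 + (6.2 - 2.2)^2),
                                 sqrt((1.8 - 2.6)^2 + (6.2 - 3.3)^2)),
               tolerance = 1e-6)
  far <- tibble::tibble(element = "C", x = 1.8, y = 7.9, z = 0) # > 4.5 from CB and CG
  expect_equal(nrow(detect_hydrophobic(far, rec)), 0)
  # two qualifying ligand atoms still one record per residue
  two <- dplyr::bind_rows(near, dplyr::mutate(near, x = 2.0))
  expect_equal(nrow(detect_hydrophobic(two, rec)), 1)
})

test_that("ionic detection requires opposite charges within the cutoff", {
  asp <- tibble::tibble(
    serial = 1:3, name = c("CB", "OD1", "OD2"), residue_name = "ASP",
    chain = "A", residue_number = 964L, element = c("C", "O", "O"),
    x = c(0, 0.5, -0.5), y = c(0, 1, 1), z = 0
  )
  rec <- dockscreen:::new_structure_model("ASPX", 2, asp, asp[0, ])
  cation <- tibble::tibble(element = "N", x = 0, y = 4.5, z = 0, charge = 1)
  hit <- detect_ionic(cation, rec)
  expect_equal(nrow(hit), 1) # carboxylate center (0,1,0) at 3.5
  expect_equal(hit$distance, 3.5, tolerance = 1e-6)
  anion <- dplyr::mutate(cation, charge = -1)
  expect_equal(nrow(detect_ionic(anion, rec)), 0) # like charges
  far <- dplyr::mutate(cation, y = 5.1) # 4.1 away
  expect_equal(nrow(detect_ionic(far, rec)), 0)
})

test_that("detectors are invariant under joint rigid motion", {
  set.seed(91)
  toy <- gen_toy_complex(n_residues = 8, hot_positions = c(3, 6), seed = 91)
  before <- suppressWarnings(detect_interactions(toy$pose, toy$receptor))
  for (rep in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 10)
    after <- suppressWarnings(detect_interactions(
      rigid_transform_pose(toy$pose, R, shift),
      rigid_transform_model(toy$receptor, R, shift)
    ))
    expect_equal(after$residue_number, before$residue_number)
    expect_equal(after$itype, before$itype)
    expect_equal(after$distance, before$distance, tolerance = 1e-8)
  }
})

test_that("detector output is independent of atom ordering", {
  toy <- gen_toy_complex(n_residues = 8, hot_positions = c(3, 6), seed = 17)
  a <- suppressWarnings(detect_interactions(toy$pose, toy$receptor))
  pose2 <- toy$pose[rev(seq_len(nrow(toy$pose))), ]
  b <- suppressWarnings(detect_interactions(pose2, toy$receptor))
  expect_equal(a$residue_number, b$residue_number)
  expect_equal(a$itype, b$itype)
  expect_equal(a$distance, b$distance, tolerance = 1e-12)
})

test_that("hot-residue filter honors itypes and any/all policies", {
  recs <- tibble::tibble(
    chain = "A", residue_number = c(882L, 882L, 833L),
    residue_name = c("VAL", "VAL", "LYS"),
    itype = c("hbond", "hydrophobic", "hydrophobic"),
    distance = c(2.9, 4.0, 4.2), angle = NA_real_, ligand_atom = 1L
  )
  expect_true(hot_residue_filter(recs, c("Val882"), require = "any"))
  # only hydrophobic contact to Lys833 does not satisfy an hbond-only filter
  expect_false(hot_residue_filter(dplyr::filter(recs, residue_number == 833),
                                  c("Lys833")))
  expect_false(hot_residue_filter(recs, c("Val882", "Lys833"), require = "all"))
  expect_true(hot_residue_filter(recs, c("Val882", "Lys833"), require = "all",
                                 itypes = c("hbond", "hydrophobic")))
  expect_error(hot_residue_filter(recs, character(0)), "label|non-empty")
})

test_that("toy complex keeps/drops through the hot filter as constructed", {
  near <- gen_toy_complex(n_residues = 8, hot_positions = c(3, 6),
                          ligand_near = TRUE, seed = 2)
  far <- gen_toy_complex(n_residues = 8, hot_positions = c(3, 6),
                         ligand_near = FALSE, seed = 2)
  keep <- hot_residue_filter(
    suppressWarnings(detect_interactions(near$pose, near$receptor)), near$hot_set
  )
  drop <- hot_residue_filter(
    suppressWarnings(detect_interactions(far$pose, far$receptor)), far$hot_set
  )
  expect_true(keep)
  expect_false(drop)
})

test_that("ligand RMSF: static zero, two-state closed form, order invariance", {
  pose <- tibble::tibble(element = c("C", "O"), x = c(0, 3), y = 0, z = 0)
  static <- gen_snapshot_series(pose, n_frames = 10, jitter_sigma = 0, seed = 1)
  expect_equal(ligand_rmsf(static)$rmsf, c(0, 0))
  # atom alternating between two points distance d apart: RMSF = d/2
  d <- 1.6
  traj <- purrr::map_dfr(1:8, function(fr) {
    tibble::tibble(frame = fr, atom = 1L, element = "C",
                   x = ifelse(fr %% 2 == 0, d, 0), y = 0, z = 0)
  })
  expect_equal(ligand_rmsf(traj)$rmsf, d / 2)
  shuffled <- traj[sample(nrow(traj)), ]
  expect_equal(ligand_rmsf(shuffled)$rmsf, d / 2)
  expect_error(ligand_rmsf(dplyr::filter(traj, frame == 1)), ">= 2 frames")
})

test_that("isotropic jitter RMSF approaches sigma * sqrt(3)", {
  pose <- tibble::tibble(element = rep("C", 5), x = 1:5, y = 0, z = 0)
  traj <- gen_snapshot_series(pose, n_frames = 200, jitter_sigma = 0.5, seed = 8)
  r <- ligand_rmsf(traj)
  expect_equal(mean(r$rmsf), 0.5 * sqrt(3), tolerance = 0.1 * 0.5 * sqrt(3))
})

test_that("per-frame receptor alignment restores a rigidly tumbling trajectory", {
  set.seed(27)
  toy <- gen_toy_complex(n_residues = 8, hot_positions = 3, seed = 27)
  frames <- 1:5
  receptors <- list()
  traj <- purrr::map_dfr(frames, function(fr) {
    R <- random_rotation(); shift <- rnorm(3, sd = 5)
    receptors[[fr]] <<- rigid_transform_model(toy$receptor, R, shift)
    p <- rigid_transform_pose(toy$pose, R, shift)
    tibble::tibble(frame = fr, atom = seq_len(nrow(p)), element = p$element,
                   x = p$x, y = p$y, z = p$z)
  })
  r <- ligand_rmsf(traj, receptors = receptors)
  expect_true(all(r$rmsf < 1e-8))
})

test_that("occupancy counts detection fraction per residue and type", {
  toy <- gen_toy_complex(n_residues = 6, hot_positions = 2, seed = 33)
  # 4 frames: 3 near (contact), 1 translated far (no contact)
  near <- toy$pose
  far <- dplyr::mutate(near, y = y - 30)
  traj <- dplyr::bind_rows(
    purrr::map_dfr(1:3, ~dplyr::mutate(near, frame = .x, atom = dplyr::row_number())),
    dplyr::mutate(far, frame = 4L, atom = dplyr::row_number())
  )
  occ <- suppressWarnings(interaction_occupancy(traj, toy$receptor, detectors = "hbond"))
  hot <- dplyr::filter(occ, residue_number == 882L)
  expect_equal(hot$occupancy, 0.75)
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
  # union over itypes covers at least each individual type
  occ2 <- suppressWarnings(interaction_occupancy(traj, toy$receptor))
  for (rn in unique(occ$residue_number)) {
    expect_gte(max(occ2$occupancy[occ2$residue_number == rn]),
               max(occ$occupancy[occ$residue_number == rn]))
  }
})

test_that("water bridges require both legs within the cutoff", {
  rec <- simple_receptor()
  lig <- tibble::tibble(element = "O", x = 0, y = -6, z = 0)
  mid <- tibble::tibble(x = 0, y = -3, z = 0) # 3.0 to both N and ligand O
  hit <- detect_water_bridges(lig, rec, mid)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$itype, "water_bridge")
  far_water <- tibble::tibble(x = 0, y = -4.0, z = 0) # 4.0 to receptor N
  expect_equal(nrow(detect_water_bridges(lig, rec, far_water)), 0)
  expect_equal(nrow(detect_water_bridges(lig, rec, mid[0, ])), 0)
})
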