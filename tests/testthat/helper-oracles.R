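# Independent oracles used to cross-check the package implementations.
# Each deliberately uses a different algorithm than the code under test.

# Horn quaternion-eigenvalue superposition RMSD: the optimal rigid-fit RMSD is
# sqrt((G_P + G_Q - 2*lambda_max)/n) where lambda_max is the largest
# eigenvalue of the 4x4 key matrix built from the covariance of the centered
# point sets.
quaternion_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Qc, Pc) # moving onto fixed
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(Pc^2) + sum(Qc^2)
  sqrt(max(0, g - 2 * lam) / n)
}

# Exhaustive pairwise-counting AUC (Mann-Whitney by definition).
pairwise_auc <- function(scores, labels, lower_is_active = TRUE) {
  a <- scores[labels == 1]
  d <- scores[labels == 0]
  tot <- 0
  for (x in a) {
    tot <- tot + sum(if (lower_is_active) x < d else x > d) + 0.5 * sum(x == d)
  }
  tot / (length(a) * length(d))
}

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

# Brute-force minimum RMSD over all element-preserving atom relabelings.
bruteforce_pose_rmsd <- function(a, b) {
  a <- a[a$element != "H", ]
  b <- b[b$element != "H", ]
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  els <- unique(a$element)
  per_el <- lapply(els, function(el) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    pm <- perms(length(ia))
    apply(pm, 1, function(p) {
      list(ia = ia, ib = ib[p], ss = sum((A[ia, , drop = FALSE] - B[ib[p], , drop = FALSE])^2))
    }, simplify = FALSE)
  })
  # min over the product of per-element permutations = sum of per-element minima
  ss <- sum(vapply(per_el, function(opts) min(vapply(opts, `[[`, 0, "ss")), 0))
  sqrt(ss / nrow(a))
}

# UPGMA oracle: cluster distance recomputed from scratch as the mean of all
# original cross-pair distances (the defining property of average linkage),
# no incremental updates.
upgma_oracle <- function(d, k) {
  ids <- rownames(d)
  clusters <- lapply(ids, identity)
  while (length(clusters) > k) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || dd < best$d - 1e-12 ||
            (abs(dd - best$d) <= 1e-12 &&
             paste(key, collapse = "|") < paste(best$key, collapse = "|"))) {
          best <- list(i = i, j = j, d = dd, key = key)
        }
      }
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  clusters
}

# Membership sets ignoring cluster numbering.
cluster_sets <- function(assignment, id_col = "id") {
  unname(lapply(
    split(assignment[[id_col]], assignment$cluster),
    function(x) sort(x)
  ))
}

same_partition <- function(a, b) {
  setequal(
    vapply(a, paste, "", collapse = "|"),
    vapply(b, paste, "", collapse = "|")
  )
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_transform_pose <- function(pose, R, shift) {
  xyz <- as.matrix(pose[, c("x", "y", "z")]) %*% t(R)
  pose$x <- xyz[, 1] + shift[1]
  pose$y <- xyz[, 2] + shift[2]
  pose$z <- xyz[, 3] + shift[3]
  pose
}

rigid_transform_model <- function(model, R, shift) {
  model$atoms <- rigid_transform_pose(model$atoms, R, shift)
  if (nrow(model$het_ligand)) model$het_ligand <- rigid_transform_pose(model$het_ligand, R, shift)
  model
}
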