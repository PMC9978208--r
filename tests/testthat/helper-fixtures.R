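# Shared fixtures, generated once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

# A mixed GPCR + kinase annotation fixture with toy conformers.
shared_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "statefold-fixture")
    .fixture_cache$fx <- make_annotation_fixture(
      dir, n_active = 8L, n_inactive = 8L, n_kinase = 12L, seed = 101L)
  }
  .fixture_cache$fx
}

# Minimal valid record table for selection tests.
toy_records <- function(n = 6L, state = "Active", prefix = "9T") {
  template_records(data.frame(
    pdb_id = sprintf("%s%02d", prefix, seq_len(n)), chain_id = "A",
    sequence = "ACDEFG", rank_score = rev(seq_len(n)) * 10,
    seq_identity = 50, family = "fam", subfamily = "sub",
    gpcr_state = state, coords_path = NA))
}

toy_kinase_records <- function(dfg, ac_helix, prefix = "9Q") {
  stopifnot(length(dfg) == length(ac_helix))
  template_records(data.frame(
    pdb_id = sprintf("%s%02d", prefix, seq_along(dfg)), chain_id = "A",
    sequence = "ACDEFG", rank_score = rev(seq_along(dfg)) * 10,
    seq_identity = 50, family = "fam", subfamily = "sub",
    gpcr_state = "unknown", dfg = dfg, ac_helix = ac_helix,
    coords_path = NA))
}

# Brute-force rigid superposition oracle: center both clouds, search a
# rotation grid (ZYZ Euler angles) with iterative refinement, report the
# minimal RMSD.  Independent of the closed-form Kabsch path.
grid_rmsd_oracle <- function(P, Q, levels = 4L) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  rot_zyz <- function(a, b, g) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
    rz(a) %*% ry(b) %*% rz(g)
  }
  score <- function(a, b, g) {
    M <- P0 %*% t(rot_zyz(a, b, g))
    sqrt(mean(rowSums((M - Q0)^2)))
  }
  best <- c(0, 0, 0); best_r <- score(0, 0, 0)
  step <- pi / 9  # 20 degrees
  grid <- expand.grid(a = seq(-pi, pi, by = step),
                      b = seq(0, pi, by = step),
                      g = seq(-pi, pi, by = step))
  for (i in seq_len(nrow(grid))) {
    r <- score(grid$a[i], grid$b[i], grid$g[i])
    if (r < best_r) { best_r <- r; best <- unlist(grid[i, ]) }
  }
  for (lev in seq_len(levels)) {
    step <- step / 4
    off <- seq(-3, 3) * step
    repeat {  # hill-climb on this grid until no cell improves
      improved <- FALSE
      for (da in off) for (db in off) for (dg in off) {
        r <- score(best[1] + da, best[2] + db, best[3] + dg)
        if (r < best_r - 1e-12) {
          best_r <- r; best_new <- best + c(da, db, dg); improved <- TRUE
        }
      }
      if (!improved) break
      best <- best_new
    }
  }
  best_r
}

random_cloud <- function(n, seed, scale = 5) {
  set.seed(seed)
  matrix(rnorm(n * 3, 0, scale), n, 3)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
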