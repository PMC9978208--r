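# Superposition, segment RMSD, ensemble summaries, rank correlation and
# kinase feature classification.

test_that("superposing a structure on itself or a translate gives rmsd 0", {
  cloud <- random_cloud(10, seed = 1)
  a <- structure_coords(1:10, cloud)
  fit <- kabsch_superpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  b <- structure_coords(1:10, sweep(cloud, 2, c(-5, 0, 0)))  # +5 on x
  fit2 <- kabsch_superpose(a, b)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit2$translation, c(5, 0, 0), tolerance = 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch matches the rotation-grid brute-force oracle within 1e-3 A", {
  for (seed in 1:4) {
    P <- random_cloud(10, seed = seed)
    R <- random_rotation(seed + 50)
    set.seed(seed + 100)
    Q <- P %*% t(R) + matrix(rnorm(30, 0, 0.4), 10, 3)
    fit <- kabsch_superpose(structure_coords(1:10, P),
                            structure_coords(1:10, Q))
    oracle <- grid_rmsd_oracle(P, Q)
    expect_lte(fit$rmsd, oracle + 1e-3)
    expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
  }
})

test_that("Kabsch agrees with an independent library implementation", {
  P <- random_cloud(8, seed = 9)
  set.seed(10)
  Q <- P %*% t(random_rotation(11)) + matrix(rnorm(24, 0, 0.5), 8, 3)
  fit <- kabsch_superpose(structure_coords(1:8, P), structure_coords(1:8, Q))
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(Q)), mobile = as.numeric(t(P))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, 8, 3, byrow = TRUE) - Q)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate selections are rejected", {
  line <- structure_coords(1:5, cbind(1:5, 0, 0))
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
  small <- structure_coords(1:2, random_cloud(2, 3))
  expect_error(kabsch_superpose(small, small), "at least 3")
  disjoint_a <- structure_coords(1:5, random_cloud(5, 4))
  disjoint_b <- structure_coords(6:10, random_cloud(5, 5))
  expect_error(kabsch_superpose(disjoint_a, disjoint_b), "at least 3")
})

test_that("RMSD is symmetric and invariant to rigid motions of both inputs", {
  a <- structure_coords(1:12, random_cloud(12, 21))
  b <- structure_coords(1:12, random_cloud(12, 22))
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-9)
  R <- random_rotation(23); tv <- c(3, -2, 7)
  move <- function(x) structure_coords(x$residue_ids,
                                       x$ca %*% t(R) + matrix(tv, nrow(x$ca), 3, byrow = TRUE))
  expect_equal(kabsch_superpose(move(a), move(b))$rmsd,
               kabsch_superpose(a, b)$rmsd, tolerance = 1e-9)
})

test_that("scoring on the superposed selection is optimal for that selection", {
  # no other transform gives lower RMSD on the selection it was fit on
  a <- structure_coords(1:10, random_cloud(10, 31))
  b <- structure_coords(1:10, random_cloud(10, 32))
  opt <- kabsch_superpose(a, b)$rmsd
  for (s in 1:5) {
    R <- random_rotation(40 + s)
    moved <- structure_coords(a$residue_ids, a$ca %*% t(R))
    # best translation for this rotation is centroid matching
    shifted <- sweep(moved$ca, 2, colMeans(moved$ca) - colMeans(b$ca))
    expect_gte(sqrt(mean(rowSums((shifted - b$ca)^2))), opt - 1e-9)
  }
})

test_that("segment RMSD separates TM and loop accuracy", {
  fx <- shared_fixture()
  ref <- read_structure(fx$active_ref)
  segs <- fetch_segment_map(fx$segment_maps, "GPCR_QUERY")
  same <- segment_rmsd(ref, ref, segs)
  expect_equal(same$tm_rmsd, 0, tolerance = 1e-9)
  expect_equal(same$loop_rmsd, 0, tolerance = 1e-9)
  expect_equal(same$global_rmsd, 0, tolerance = 1e-9)
  # displace every loop residue rigidly by 3 A: tm_rmsd stays 0 and
  # loop_rmsd is exactly 3 in the TM-superposed frame
  loop_ids <- setdiff(ref$residue_ids, segment_residues(segs, "^TM[0-9]+$"))
  ca <- ref$ca
  ca[match(loop_ids, ref$residue_ids), 3] <-
    ca[match(loop_ids, ref$residue_ids), 3] + 3
  shifted <- structure_coords(ref$residue_ids, ca)
  rep_ <- segment_rmsd(shifted, ref, segs)
  expect_equal(rep_$tm_rmsd, 0, tolerance = 1e-9)
  expect_equal(rep_$loop_rmsd, 3, tolerance = 1e-9)
  expect_gt(rep_$global_rmsd, 0)
  expect_equal(rep_$n_tm + rep_$n_loop, rep_$n_global)
})

test_that("the active/inactive toy pair scores at its built-in TM6 swing", {
  pair <- make_conformer_pair(conformer_spec("gpcr", state_displacement = 4))
  # without superposition the TM6-restricted deviation is exactly 4 A;
  # after TM-union superposition the TM-RMSD is positive but below 4
  tm6 <- segment_residues(pair$segments, "^TM6$")
  d <- pair$state_a$ca[tm6, ] - pair$state_b$ca[tm6, ]
  expect_equal(sqrt(mean(rowSums(d^2))), 4, tolerance = 1e-9)
  rep_ <- segment_rmsd(pair$state_b, pair$state_a, pair$segments)
  expect_gt(rep_$tm_rmsd, 0.5)
  expect_lt(rep_$tm_rmsd, 4)
})

test_that("ensemble summaries order by model index and pick the best TM-RMSD", {
  fx <- shared_fixture()
  ref <- read_structure(fx$active_ref)
  segs <- fetch_segment_map(fx$segment_maps, "GPCR_QUERY")
  m <- list(predicted_model(0, ref, rep(90, length(ref$residue_ids)), 0.9),
            predicted_model(1, ref, rep(90, length(ref$residue_ids)), 0.9),
            predicted_model(2, ref, rep(90, length(ref$residue_ids)), 0.9))
  s <- ensemble_summary(m, ref, segs)
  expect_equal(nrow(s$table), 3L)
  expect_equal(unique(round(s$table$tm_rmsd, 12)), 0)
  expect_equal(s$best, 0L)  # ties resolved by model index
  single <- ensemble_summary(m[2], ref, segs)
  expect_equal(single$best, 1L)
})

test_that("Spearman rho matches a hand-ranked oracle and handles ties/NA", {
  # strictly decreasing pTM in RMSD: rho = -1
  expect_equal(ptm_rmsd_correlation(c(.9, .8, .7, .6), 1:4)$rho, -1)
  # constant pTM: zero variance is NA, not 0
  r <- ptm_rmsd_correlation(rep(.5, 5), 1:5)
  expect_true(is.na(r$rho))
  expect_equal(r$n, 5L)
  expect_error(ptm_rmsd_correlation(c(.1, .2), c(1, 2)), "at least 3")
  # 5-point toy with one tie, hand-ranked: ptm ranks (1,2.5,2.5,4,5)
  ptm <- c(.1, .2, .2, .3, .4); rmsd <- c(5, 3, 4, 2, 1)
  rx <- c(1, 2.5, 2.5, 4, 5); ry <- c(5, 3, 4, 2, 1)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(ptm_rmsd_correlation(ptm, rmsd)$rho, hand, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(ptm_rmsd_correlation(exp(ptm), rmsd^3)$rho, hand,
               tolerance = 1e-12)
  expect_true(abs(hand) <= 1)
})

test_that("kinase features classify to the nearest labelled exemplar", {
  klib <- make_kinase_reference_library()
  exemplar_in <- klib$by_label[["in/in"]]
  cls <- classify_kinase_conformation(exemplar_in, klib$segments, klib$library)
  expect_equal(cls$a_loop, "in")
  expect_equal(cls$ac_helix, "in")
  expect_gt(cls$margin_a_loop, 0)
  out_out <- klib$by_label[["out/out"]]
  cls2 <- classify_kinase_conformation(out_out, klib$segments, klib$library)
  expect_equal(cls2$a_loop, "out")
  expect_equal(cls2$ac_helix, "out")
  # midpoint structure: equidistant, tie flagged, earlier exemplar wins
  mid <- structure_coords(exemplar_in$residue_ids,
                          (exemplar_in$ca + klib$by_label[["out/in"]]$ca) / 2)
  expect_warning(cm <- classify_kinase_conformation(mid, klib$segments,
                                                    klib$library),
                 "tie")
  expect_equal(cm$a_loop, "in")
})

test_that("structure files round-trip through PDB", {
  fx <- shared_fixture()
  ref <- read_structure(fx$active_ref)
  f <- tempfile(fileext = ".pdb")
  write_structure(ref, f)
  again <- read_structure(f)
  expect_equal(again$residue_ids, ref$residue_ids)
  expect_equal(again$ca, ref$ca, tolerance = 1e-3)  # PDB has 3 decimals
})
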