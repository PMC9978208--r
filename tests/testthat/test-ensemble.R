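# Mock predictor contract and ensemble orchestration.

template_set_from <- function(records) {
  q <- state_query("gpcr", gpcr_state = records$gpcr_state[1],
                   k = nrow(records), exclude_same_subfamily = FALSE)
  plan_template_sets(records, q, 1)[[1]]
}

test_that("a single noiseless template is reproduced exactly", {
  fx <- shared_fixture()
  recs <- fx$records[fx$records$gpcr_state == "Active", ][1, , drop = FALSE]
  tset <- template_set_from(recs)
  m <- mock_predictor(fx$gpcr_query_seq, msa = NULL, template_set = tset,
                      seed = 1, sigma = 0)
  tmpl <- read_structure(recs$coords_path[1])
  fit <- kabsch_superpose(m$coords, tmpl)
  expect_equal(fit$rmsd, 0, tolerance = 1e-3)
  expect_true(all(m$plddt >= 99))
  expect_gt(m$ptm, 0.95)
})

test_that("rigid-body copies of one structure give a zero-RMSD consensus", {
  fx <- shared_fixture()
  base <- read_structure(fx$active_ref)
  d <- tempfile("copies"); dir.create(d)
  R <- random_rotation(5)
  moved <- structure_coords(base$residue_ids,
                            base$ca %*% t(R) + matrix(c(10, -4, 2), nrow(base$ca), 3, byrow = TRUE))
  p1 <- file.path(d, "c1.pdb"); p2 <- file.path(d, "c2.pdb")
  write_structure(base, p1); write_structure(moved, p2)
  recs <- template_records(data.frame(
    pdb_id = c("9C01", "9C02"), chain_id = "A", sequence = "ACD",
    rank_score = c(2, 1), seq_identity = 50, family = "f", subfamily = "s",
    gpcr_state = "Active", coords_path = c(p1, p2)))
  m <- mock_predictor(fx$gpcr_query_seq, NULL, template_set_from(recs),
                      seed = 1, sigma = 0)
  expect_equal(kabsch_superpose(m$coords, base)$rmsd, 0, tolerance = 1e-2)
})

test_that("the mock predictor is deterministic and honors its error contract", {
  fx <- shared_fixture()
  recs <- fx$records[fx$records$gpcr_state == "Active", ][1:2, ]
  tset <- template_set_from(recs)
  a <- mock_predictor(fx$gpcr_query_seq, NULL, tset, seed = 7)
  b <- mock_predictor(fx$gpcr_query_seq, NULL, tset, seed = 7)
  expect_identical(a$coords$ca, b$coords$ca)
  expect_identical(a$plddt, b$plddt)
  c_ <- mock_predictor(fx$gpcr_query_seq, NULL, tset, seed = 8)
  expect_false(identical(a$coords$ca, c_$coords$ca))
  # empty template set with a no-MSA recipe: nothing to build from
  nomsa <- msa_remove_over_templates(make_toy_msa(20, 4, seed = 1), 1:20)
  expect_error(mock_predictor(strrep("A", 20), nomsa, NULL), "nothing to build")
  expect_error(mock_predictor(strrep("A", 20), NULL, NULL), "nothing to build")
  # confidence ranges respect the contract
  expect_true(all(a$plddt >= 0 & a$plddt <= 100))
  expect_gte(a$ptm, 0); expect_lte(a$ptm, 1)
})

test_that("state-opposed template sets steer the consensus as intended", {
  # templates from two toy states 4 A apart: each consensus lands nearer
  # its own state's reference
  fx <- shared_fixture()
  act <- fx$records[fx$records$gpcr_state == "Active", ][1:3, ]
  ina <- fx$records[fx$records$gpcr_state == "Inactive", ][1:3, ]
  segs <- fetch_segment_map(fx$segment_maps, "GPCR_QUERY")
  ref_a <- read_structure(fx$active_ref)
  ma <- mock_predictor(fx$gpcr_query_seq, NULL, template_set_from(act), seed = 3)
  mi <- mock_predictor(fx$gpcr_query_seq, NULL, template_set_from(ina), seed = 3)
  ra <- segment_rmsd(ma$coords, ref_a, segs)$tm_rmsd
  ri <- segment_rmsd(mi$coords, ref_a, segs)$tm_rmsd
  expect_lt(ra, ri)
})

test_that("run_ensemble dispatches one recipe per model with derived seeds", {
  fx <- shared_fixture()
  q <- state_query("gpcr", gpcr_state = "Active", k = 4,
                   exclude_same_subfamily = FALSE)
  m <- make_toy_msa(nchar(fx$gpcr_query_seq), depth = 40, seed = 2)
  run <- run_ensemble(fx$gpcr_query_seq, m, fx$records, q,
                      n_models = 50, seed = 11)
  expect_length(run$models, 50L)
  expect_equal(nrow(run$manifest), 50L)
  expect_equal(run$manifest$model_index, 0:49)
  expect_true(all(run$manifest$status == "ok"))
  # audit trail: every model carries the recipe that rebuilds it
  m0 <- run$models[[1]]
  expect_equal(m0$recipe$model_index, 0L)
  rebuilt <- mock_predictor(fx$gpcr_query_seq,
                            NULL, m0$recipe$template_set,
                            recycles = m0$recipe$recycles,
                            seed = m0$recipe$seed, model_index = 0L)
  expect_identical(rebuilt$coords$ca, m0$coords$ca)
  # full-run determinism
  run2 <- run_ensemble(fx$gpcr_query_seq, m, fx$records, q,
                       n_models = 3, seed = 11)
  expect_identical(run2$models[[2]]$coords$ca, run$models[[2]]$coords$ca)
})

test_that("randomized runs reference several distinct template sets", {
  fx <- shared_fixture()
  q <- state_query("gpcr", gpcr_state = "Active", k = 4,
                   exclude_same_subfamily = FALSE, randomize = TRUE, seed = 5)
  m <- make_toy_msa(nchar(fx$gpcr_query_seq), depth = 40, seed = 2)
  run <- run_ensemble(fx$gpcr_query_seq, m, fx$records, q,
                      n_models = 12, seed = 5)
  sets <- unique(vapply(run$models, function(x)
    paste(x$recipe$template_set$records$pdb_id, collapse = ","), ""))
  expect_gt(length(sets), 1L)
})

test_that("predictor failures are logged and the run continues", {
  fx <- shared_fixture()
  q <- state_query("gpcr", gpcr_state = "Active", k = 2,
                   exclude_same_subfamily = FALSE)
  flaky <- function(query_seq, msa, template_set, recycles, seed, model_index) {
    if (model_index == 1L) stop("synthetic failure")
    mock_predictor(query_seq, msa, template_set, recycles, seed,
                   model_index = model_index)
  }
  run <- run_ensemble(fx$gpcr_query_seq, NULL, fx$records, q,
                      n_models = 4, seed = 1, msa_mode = "full",
                      predictor = flaky)
  expect_length(run$models, 3L)
  expect_equal(run$manifest$status, c("ok", "failed", "ok", "ok"))
  expect_match(run$manifest$message[2], "synthetic failure")
  always_fail <- function(...) stop("no")
  expect_error(run_ensemble(fx$gpcr_query_seq, NULL, fx$records, q,
                            n_models = 2, seed = 1, msa_mode = "full",
                            predictor = always_fail), "all 2 models failed")
})

test_that("the unfolded filter removes extended chains and low confidence", {
  n <- 60
  compact <- structure_coords(1:n, random_cloud(n, 1, scale = 3))
  line <- structure_coords(1:n, cbind(3.8 * (1:n), 0, 0))
  # straight-line Rg is analytic: d * sqrt((n^2-1)/12)
  expect_equal(radius_of_gyration(line), 3.8 * sqrt((n^2 - 1) / 12),
               tolerance = 1e-9)
  expect_gt(radius_of_gyration(line) / globular_rg(n), 2.5)
  models <- list(
    predicted_model(0, compact, rep(90, n), .8),
    predicted_model(1, line, rep(90, n), .8),       # unfolded by geometry
    predicted_model(2, compact, rep(20, n), .2))    # unfolded by confidence
  kept <- discard_unfolded(models)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$model_index, 0L)
  disc <- attr(kept, "discarded")
  expect_equal(nrow(disc), 2L)
  expect_match(disc$reason[1], "globular")
  expect_match(disc$reason[2], "pLDDT")
  # no-op bounds give the identity; the filter is idempotent
  all_kept <- discard_unfolded(models, plddt_floor = 0, rg_ceiling = Inf)
  expect_length(all_kept, 3L)
  again <- discard_unfolded(kept)
  expect_length(again, length(kept))
  expect_lte(length(kept), length(models))
})
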