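# Ensemble orchestration: one prediction recipe per model (MSA variant x
# template set), dispatch to a pluggable predictor, and post-hoc filtering
# of unfolded models.

#' Run a biased prediction ensemble
#'
#' For each of `n_models` models the driver assembles a recipe: the
#' template set planned by [plan_template_sets()] (identical top-k sets,
#' or an independent random draw per model when the query randomizes
#' templates) and an MSA variant according to `msa_mode`:
#' \describe{
#'   \item{`shallow`}{a fresh subsample per model (`n_clusters` +
#'     `n_extra` rows, seeded per model) — the default protocol;}
#'   \item{`none`}{rows gapped over the query columns covered by the
#'     model's templates (noMSA);}
#'   \item{`speach`}{sliding-window masked variants, cycled across
#'     models;}
#'   \item{`full`}{the alignment untouched.}
#' }
#' Per-model seeds derive from `(seed, model_index)`, so any model can be
#' reproduced in isolation. A predictor failure on one model is logged in
#' the manifest and the run continues; a run where every model failed is
#' an error.
#'
#' @param query_seq query amino-acid sequence.
#' @param msa_obj an [msa()] (may be `NULL` for template-only recipes with
#'   `msa_mode = "none"`... the templates then carry the model).
#' @param records `template_records` of annotated candidates.
#' @param query a [state_query()].
#' @param n_models ensemble size (protocol default 50).
#' @param msa_mode one of `"shallow"`, `"none"`, `"speach"`, `"full"`.
#' @param n_clusters,n_extra shallow-MSA subsample sizes (protocol
#'   defaults 8 and 16).
#' @param speach_window window width for `msa_mode = "speach"`.
#' @param recycles recycle count recorded in recipes (default 0).
#' @param seed run seed.
#' @param predictor a function obeying the predictor contract; defaults to
#'   [mock_predictor()].
#' @param query_subfamily passed to template filtering.
#' @param sigma mock-predictor noise level (ignored by external predictors
#'   unless they accept it).
#' @return an `ensemble_run`: list with `models` (the successful
#'   `predicted_model`s) and `manifest` (a data.frame with one row per
#'   recipe: model index, seeds, template ids, MSA variant, status, pTM
#'   and mean pLDDT).
#' @export
run_ensemble <- function(query_seq, msa_obj, records, query,
                         n_models = 50L,
                         msa_mode = c("shallow", "none", "speach", "full"),
                         n_clusters = 8L, n_extra = 16L,
                         speach_window = 10L,
                         recycles = 0L, seed = 0L,
                         predictor = NULL, query_subfamily = "",
                         sigma = 0.5) {
  msa_mode <- match.arg(msa_mode)
  stopifnot(is_count(n_models), n_models >= 1)
  predictor <- predictor %||%
    function(query_seq, msa, template_set, recycles, seed, model_index)
      mock_predictor(query_seq, msa, template_set, recycles, seed,
                     sigma = sigma, model_index = model_index)
  sets <- plan_template_sets(records, query, n_models, query_subfamily)
  speach_variants <- if (msa_mode == "speach") {
    if (is.null(msa_obj)) stop("msa_mode 'speach' requires an MSA")
    msa_speach_variants(msa_obj, window = speach_window)
  } else NULL

  models <- vector("list", n_models)
  manifest <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    idx <- i - 1L
    model_seed <- derive_seed(seed, idx)
    tset <- sets[[i]]
    msa_i <- switch(msa_mode,
      shallow = if (is.null(msa_obj)) NULL else
        msa_subsample(msa_obj, n_clusters, n_extra, seed = model_seed)$clusters,
      none = if (is.null(msa_obj)) NULL else
        msa_remove_over_templates(msa_obj, template_coverage(tset, nchar(query_seq))),
      speach = speach_variants[[(idx %% length(speach_variants)) + 1L]],
      full = msa_obj)
    recipe <- list(model_index = idx, seed = model_seed,
                   msa_mode = msa_mode,
                   msa_provenance = if (is.null(msa_i)) list(kind = "none")
                                    else msa_i$provenance,
                   template_set = tset, recycles = as.integer(recycles))
    res <- tryCatch({
      m <- predictor(query_seq, msa_i, tset, recycles, model_seed,
                     model_index = idx)
      m$recipe <- recipe
      m
    }, error = function(e) e)
    failed <- inherits(res, "error")
    if (!failed) models[[i]] <- res
    df <- as.data.frame(tset$records)
    manifest[[i]] <- data.frame(
      model_index = idx, seed = model_seed, msa_mode = msa_mode,
      templates = paste(paste0(df$pdb_id, "_", df$chain_id), collapse = ","),
      status = if (failed) "failed" else "ok",
      message = if (failed) conditionMessage(res) else "",
      ptm = if (failed) NA_real_ else res$ptm,
      mean_plddt = if (failed) NA_real_ else mean(res$plddt))
  }
  manifest <- do.call(rbind, manifest)
  models <- models[!vapply(models, is.null, logical(1))]
  if (!length(models))
    stop("all ", n_models, " models failed; first error: ",
         manifest$message[1])
  structure(list(models = models, manifest = manifest), class = "ensemble_run")
}

# query columns covered by >= 1 template of the set: the alignment
# footprint used by the noMSA intervention.  With the fixture templates
# (query numbering) this is the union of template residue ids within the
# query range.
template_coverage <- function(template_set, query_length) {
  recs <- as.data.frame(template_set$records)
  if (nrow(recs) == 0L) return(integer(0))
  ids <- unlist(lapply(seq_len(nrow(recs)), function(i) {
    s <- read_structure(recs$coords_path[i], chain = recs$chain_id[i])
    s$residue_ids
  }))
  sort(unique(ids[ids >= 1L & ids <= query_length]))
}

#' Radius of gyration of a C-alpha trace
#'
#' @param x a [structure_coords()].
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x) {
  stopifnot(inherits(x, "structure_coords"))
  c0 <- sweep(x$ca, 2, colMeans(x$ca))
  sqrt(mean(rowSums(c0^2)))
}

#' Expected radius of gyration of a globular chain
#'
#' The empirical scaling `Rg = 2.2 * N^0.38` Angstrom for folded
#' single-domain proteins of `N` residues, used as the yardstick of the
#' unfolded-model filter.
#'
#' @param n_residues chain length.
#' @return expected Rg in Angstrom.
#' @export
globular_rg <- function(n_residues) 2.2 * n_residues^0.38

#' Discard unfolded models from an ensemble
#'
#' A model survives when its mean pLDDT is at least `plddt_floor` and its
#' radius of gyration is at most `rg_ceiling` times the globular
#' expectation for its length. The operation never enlarges the ensemble
#' and is idempotent; discarded models are reported with the reason.
#'
#' @param models list of `predicted_model` (or an `ensemble_run`).
#' @param plddt_floor minimum acceptable mean pLDDT (default 40).
#' @param rg_ceiling compactness ceiling as a multiple of [globular_rg()]
#'   (default 2.5).
#' @return the surviving models, with a `discarded` attribute: data.frame
#'   of model index, mean pLDDT, Rg ratio and reason.
#' @export
discard_unfolded <- function(models, plddt_floor = 40, rg_ceiling = 2.5) {
  if (inherits(models, "ensemble_run")) models <- models$models
  stopifnot(length(models) >= 1L)
  info <- lapply(models, function(m) {
    rg <- radius_of_gyration(m$coords)
    ratio <- rg / globular_rg(nrow(m$coords$ca))
    mp <- mean(m$plddt)
    keep <- mp >= plddt_floor && ratio <= rg_ceiling
    reason <- if (keep) "" else if (mp < plddt_floor)
      sprintf("mean pLDDT %.1f < floor %.1f", mp, plddt_floor)
    else sprintf("Rg %.1f A is %.2fx the globular expectation (ceiling %.2fx)",
                 rg, ratio, rg_ceiling)
    list(keep = keep,
         row = data.frame(model_index = m$model_index, mean_plddt = mp,
                          rg_ratio = ratio, reason = reason))
  })
  keep <- vapply(info, `[[`, logical(1), "keep")
  tab <- do.call(rbind, lapply(info, `[[`, "row"))
  out <- models[keep]
  attr(out, "discarded") <- tab[!keep, , drop = FALSE]
  out
}
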