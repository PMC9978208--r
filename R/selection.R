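# Template filtering, ranking and selection against a user-defined
# conformational-state query: top-k and per-model randomized draws.

#' Specify the conformational state a template set must satisfy
#'
#' In GPCR mode the query names an activation state; templates whose
#' annotation matches it survive. By default a record annotated
#' `"G protein"` or `"Arrestin"` (bound to a signaling protein) also
#' satisfies an `"Active"` query, since complexes with a transducer are in
#' the active conformation; set `signaling_as_active = FALSE` for literal
#' matching only. In kinase mode the query fixes up to three structural
#' criteria — DFG, alphaC-helix and K-E salt bridge — each of which may be
#' `"all"` (no filtering on that feature).
#'
#' @param mode `"gpcr"` or `"kinase"`.
#' @param gpcr_state activation state label (GPCR mode).
#' @param dfg,ac_helix,salt_bridge kinase feature values, `"all"` = no-op.
#' @param k number of templates per model (GPCR protocol default 4,
#'   kinase 20).
#' @param exclude_same_subfamily drop templates from the query's own
#'   subfamily (defaults on in GPCR mode, off in kinase mode).
#' @param randomize draw a fresh random template set per model instead of
#'   reusing the top-k set.
#' @param min_rank_score,min_seq_identity floors applied during filtering.
#' @param signaling_as_active see Description.
#' @param seed run seed used for randomized draws.
#' @return a `state_query` object.
#' @export
state_query <- function(mode = c("gpcr", "kinase"),
                        gpcr_state = NULL,
                        dfg = "all", ac_helix = "all", salt_bridge = "all",
                        k = if (mode[1] == "kinase") 20L else 4L,
                        exclude_same_subfamily = (mode[1] == "gpcr"),
                        randomize = FALSE,
                        min_rank_score = 0, min_seq_identity = 0,
                        signaling_as_active = TRUE,
                        seed = 0L) {
  mode <- match.arg(mode)
  if (mode == "gpcr") {
    if (is.null(gpcr_state) ||
        !(gpcr_state %in% setdiff(gpcr_state_levels(), "unknown")))
      stop("gpcr mode requires gpcr_state, one of: ",
           paste(setdiff(gpcr_state_levels(), "unknown"), collapse = ", "))
  } else {
    if (!(dfg %in% c(setdiff(dfg_levels(), "unknown"), "all")))
      stop("dfg must be one of out, in, out-like, all")
    if (!(ac_helix %in% c("out", "in", "all")))
      stop("ac_helix must be one of out, in, all")
    if (!(salt_bridge %in% c("yes", "no", "all")))
      stop("salt_bridge must be one of yes, no, all")
  }
  stopifnot(is_count(k), k >= 1, is_count(abs(seed)),
            min_rank_score >= 0, min_seq_identity >= 0)
  structure(list(mode = mode,
                 gpcr_state = if (mode == "gpcr") gpcr_state else NULL,
                 dfg = dfg, ac_helix = ac_helix, salt_bridge = salt_bridge,
                 k = as.integer(k),
                 exclude_same_subfamily = isTRUE(exclude_same_subfamily),
                 randomize = isTRUE(randomize),
                 min_rank_score = min_rank_score,
                 min_seq_identity = min_seq_identity,
                 signaling_as_active = isTRUE(signaling_as_active),
                 seed = as.integer(seed)),
            class = "state_query")
}

matches_query <- function(records, query, query_subfamily = "") {
  df <- as.data.frame(records)
  if (query$mode == "gpcr") {
    ok <- df$gpcr_state == query$gpcr_state
    if (query$gpcr_state == "Active" && query$signaling_as_active)
      ok <- ok | df$gpcr_state %in% c("G protein", "Arrestin")
  } else {
    # only kinase-typed records can satisfy a kinase query, wildcards or not
    ok <- df$dfg != "unknown"
    if (query$dfg != "all") ok <- ok & df$dfg == query$dfg
    if (query$ac_helix != "all") ok <- ok & df$ac_helix == query$ac_helix
    if (query$salt_bridge != "all") ok <- ok & df$salt_bridge == query$salt_bridge
  }
  if (query$exclude_same_subfamily && nzchar(query_subfamily))
    ok <- ok & df$subfamily != query_subfamily
  ok <- ok & df$rank_score >= query$min_rank_score
  ok <- ok & df$seq_identity >= query$min_seq_identity
  ok
}

#' Filter template candidates against a state query
#'
#' Keeps the subsequence of `records` satisfying every active criterion of
#' `query` (state match or its signaling-protein extension in GPCR mode;
#' all three feature criteria with `"all"` wildcards in kinase mode;
#' subfamily exclusion; rank-score and identity floors). Input order — the
#' upstream template-search ranking — is preserved.
#'
#' @param records a `template_records` data.frame.
#' @param query a [state_query()].
#' @param query_subfamily the query protein's own subfamily (used by the
#'   subfamily exclusion; `""` disables it).
#' @return the surviving `template_records`, in input order.
#' @export
filter_candidates <- function(records, query, query_subfamily = "") {
  validate_template_records(records)
  stopifnot(inherits(query, "state_query"))
  ok <- matches_query(records, query, query_subfamily)
  out <- records[ok, , drop = FALSE]
  if (nrow(out) == 0L) {
    active <- if (query$mode == "gpcr") {
      paste0("gpcr_state=", query$gpcr_state)
    } else {
      paste0("dfg=", query$dfg, ", ac_helix=", query$ac_helix,
             ", salt_bridge=", query$salt_bridge)
    }
    stop("no templates satisfy the query (active filters: ", active,
         if (query$exclude_same_subfamily && nzchar(query_subfamily))
           paste0(", exclude subfamily '", query_subfamily, "'") else "",
         ", min_rank_score=", query$min_rank_score,
         ", min_seq_identity=", query$min_seq_identity, ")")
  }
  rownames(out) <- NULL
  out
}

# Order survivors by rank_score descending, ties by (pdb_id, chain_id).
rank_order <- function(records) {
  df <- as.data.frame(records)
  order(-df$rank_score, df$pdb_id, df$chain_id)
}

new_template_set <- function(records, query, draw_index = 0L) {
  structure(list(records = records, query = query,
                 draw_index = as.integer(draw_index)),
            class = "template_set")
}

#' Select the top-k templates from the filtered survivors
#'
#' Survivors are taken in the upstream ranking order carried by
#' `rank_score` (descending; ties broken by PDB id and chain for
#' determinism). A warning is issued when fewer than `k` survive.
#'
#' @param survivors filtered `template_records` (see [filter_candidates()]).
#' @param k number of templates wanted.
#' @param query the originating [state_query()] (kept for the audit trail).
#' @return a `template_set` with at most `k` records.
#' @export
select_top_k <- function(survivors, k, query = NULL) {
  stopifnot(is_count(k), k >= 1)
  ord <- rank_order(survivors)
  if (nrow(survivors) < k)
    warning("only ", nrow(survivors), " templates satisfy the query; ",
            "requested k=", k)
  take <- ord[seq_len(min(k, nrow(survivors)))]
  out <- survivors[take, , drop = FALSE]
  rownames(out) <- NULL
  new_template_set(out, query, draw_index = 0L)
}

#' Draw a random template set (template shuffling)
#'
#' A uniform sample without replacement of size `min(k, n)` from the
#' survivors. The draw is fully reproducible from `(seed, draw_index)` and
#' draws with different `draw_index` are independent, so the template set
#' behind any single model of a shuffled ensemble can be regenerated.
#'
#' @inheritParams select_top_k
#' @param seed run seed.
#' @param draw_index which model this set is drawn for.
#' @return a `template_set`.
#' @export
select_random_k <- function(survivors, k, seed = 0L, draw_index = 0L,
                            query = NULL) {
  stopifnot(is_count(k), k >= 1, nrow(survivors) >= 1L)
  n <- nrow(survivors)
  take <- with_seed(derive_seed(seed, draw_index),
                    sort(sample.int(n, min(k, n))))
  out <- survivors[take, , drop = FALSE]
  rownames(out) <- NULL
  new_template_set(out, query, draw_index = draw_index)
}

#' Plan the template set for every model of an ensemble
#'
#' Non-randomized mode replicates the top-k set across all models (the
#' standard protocol); randomized mode draws an independent set per model
#' (template shuffling), indexed `0..n_models-1`.
#'
#' @param records annotation records (filtered internally).
#' @param query a [state_query()]; its `randomize`, `k` and `seed` fields
#'   control the plan.
#' @param n_models ensemble size.
#' @param query_subfamily passed to [filter_candidates()].
#' @return list of `template_set`, one per model.
#' @export
plan_template_sets <- function(records, query, n_models,
                               query_subfamily = "") {
  stopifnot(is_count(n_models), n_models >= 1)
  survivors <- filter_candidates(records, query, query_subfamily)
  if (query$randomize) {
    lapply(seq_len(n_models) - 1L, function(i)
      select_random_k(survivors, query$k, seed = query$seed,
                      draw_index = i, query = query))
  } else {
    top <- select_top_k(survivors, query$k, query = query)
    lapply(seq_len(n_models) - 1L, function(i) {
      s <- top; s$draw_index <- i; s
    })
  }
}

#' @export
format.template_set <- function(x, ...) {
  df <- as.data.frame(x$records)
  paste0("template_set (draw ", x$draw_index, "): ",
         paste(paste0(df$pdb_id, "_", df$chain_id), collapse = ", "))
}

#' @export
print.template_set <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Log a plan of template sets as a TSV table
#'
#' One row per (model, template): model index, PDB id, chain, rank score,
#' identity and state labels — the audit trail of which templates steer
#' which model.
#'
#' @param sets list of `template_set` from [plan_template_sets()].
#' @param path optional output TSV.
#' @return the table, invisibly if `path` is given.
#' @export
template_plan_table <- function(sets, path = NULL) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    df <- as.data.frame(s$records)
    cbind(model_index = s$draw_index,
          df[, c("pdb_id", "chain_id", "rank_score", "seq_identity",
                 "gpcr_state", "dfg", "ac_helix", "salt_bridge", "a_loop")])
  }))
  rownames(rows) <- NULL
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
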