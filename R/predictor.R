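# The predictor contract and its deterministic mock implementation.
#
# A predictor is any function with signature
#   function(query_seq, msa, template_set, recycles, seed) -> predicted_model
# that is deterministic given identical inputs and seed.  The mock
# predictor below realizes the premise the whole protocol rests on —
# that a prediction fed state-matched templates lands near those
# templates — by building a consensus of the superposed template traces.
# It exists so the pipeline, the bias properties and the evaluation stack
# are fully testable offline; it does not emulate a neural network.

#' Construct a predicted model
#'
#' @param model_index index of the model within its ensemble run.
#' @param coords a [structure_coords()] C-alpha trace.
#' @param plddt per-residue confidence in `[0, 100]`.
#' @param ptm global confidence in `[0, 1]`.
#' @param recipe the `prediction_recipe` that produced the model
#'   (audit trail; may be `NULL` for externally produced models).
#' @return a `predicted_model` object.
#' @export
predicted_model <- function(model_index, coords, plddt, ptm, recipe = NULL) {
  stopifnot(inherits(coords, "structure_coords"),
            length(plddt) == nrow(coords$ca),
            all(plddt >= 0 & plddt <= 100),
            ptm >= 0, ptm <= 1)
  structure(list(model_index = as.integer(model_index), coords = coords,
                 plddt = as.numeric(plddt), ptm = as.numeric(ptm),
                 recipe = recipe),
            class = "predicted_model")
}

# ideal alpha-helix C-alpha trace: radius 2.3 A, rise 1.5 A, 100 deg/res
ideal_helix <- function(n, start = 1L) {
  i <- seq.int(start, length.out = n) - 1L
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
}

# continue a trace beyond its last built residue as an ideal helix laid
# along the direction of the last two points (3.8 A spacing fallback when
# fewer than 2 points exist)
extend_helix <- function(ca_known, n_more) {
  if (n_more <= 0L) return(NULL)
  ca_known <- ca_known[stats::complete.cases(ca_known), , drop = FALSE]
  n <- nrow(ca_known)
  dirv <- if (n >= 2L) {
    d <- ca_known[n, ] - ca_known[n - 1L, ]
    d / max(sqrt(sum(d^2)), 1e-9)
  } else c(0, 0, 1)
  anchor <- if (n >= 1L) ca_known[n, ] else c(0, 0, 0)
  helix <- ideal_helix(n_more + 1L)
  # lay the helix axis (z) along dirv, anchored at the last known point
  axis_from <- c(0, 0, 1)
  v <- pracma_cross(axis_from, dirv)
  R <- if (sqrt(sum(v^2)) < 1e-9) diag(3) * sign(sum(axis_from * dirv)) else
    rotation_about(v / sqrt(sum(v^2)), acos(max(-1, min(1, sum(axis_from * dirv)))))
  pts <- helix %*% t(R)
  off <- matrix(anchor - pts[1, ], n_more + 1L, 3, byrow = TRUE)
  (pts + off)[-1, , drop = FALSE]
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_about <- function(u, theta) {
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Deterministic mock predictor
#'
#' Builds a C-alpha model as the per-residue average of the aligned
#' template traces after mutual superposition, plus seeded Gaussian noise
#' (`sigma` per coordinate, default 0.5 Angstrom). Residues covered by no
#' template are extrapolated as an ideal helix continuation. Per-residue
#' confidence is a monotone rescaling of the realized deviation (template
#' spread plus the drawn noise displacement):
#' `plddt = 100 * exp(-deviation / 4)` with deviation in Angstrom, and
#' `ptm = 1 / (1 + (mean_deviation / 1.24)^2)` is a monotone function of
#' the mean deviation, so confidence varies across an ensemble the way it
#' is later rank-correlated with accuracy. With a single noiseless template the model reproduces
#' that template exactly.
#'
#' @param query_seq query amino-acid sequence (its length fixes the model
#'   length).
#' @param msa an [msa()] or `NULL`; only its provenance participates (a
#'   `"nomsa"` alignment together with an empty template set is an error —
#'   there is nothing to build the model from).
#' @param template_set a `template_set` whose records carry readable
#'   `coords_path` files, or `NULL`/empty for MSA-only recipes.
#' @param recycles nonnegative integer, kept for the contract (the mock
#'   ignores it beyond recording it).
#' @param seed noise seed; identical inputs and seed give bitwise
#'   identical models.
#' @param sigma noise standard deviation per coordinate (Angstrom).
#' @param model_index index recorded in the output.
#' @return a `predicted_model`.
#' @export
mock_predictor <- function(query_seq, msa = NULL, template_set = NULL,
                           recycles = 0L, seed = 0L, sigma = 0.5,
                           model_index = 0L) {
  L <- nchar(query_seq)
  stopifnot(L >= 3L)
  recs <- if (is.null(template_set)) NULL else as.data.frame(template_set$records)
  n_templ <- if (is.null(recs)) 0L else nrow(recs)
  msa_kind <- if (is.null(msa)) "none" else msa$provenance$kind %||% "raw"
  if (n_templ == 0L && (is.null(msa) || msa_kind == "nomsa"))
    stop("empty template set with a no-MSA recipe: nothing to build the model from")

  if (n_templ == 0L) {
    # MSA-only recipe: an ideal-helix baseline with mid confidence
    ca <- ideal_helix(L)
    noise <- with_seed(derive_seed(seed, 1L),
                       matrix(stats::rnorm(L * 3, 0, sigma), L, 3))
    return(predicted_model(model_index,
                           structure_coords(seq_len(L), ca + noise,
                                            source = "mock:msa-only"),
                           plddt = rep(50, L), ptm = 0.5))
  }

  templates <- lapply(seq_len(n_templ), function(i)
    read_structure(recs$coords_path[i], chain = recs$chain_id[i]))
  # mutual superposition onto the first template over shared residues
  ref <- templates[[1]]
  aligned <- c(list(ref), lapply(templates[-1], function(t) {
    fit <- kabsch_superpose(t, ref)
    apply_transform(t, fit)
  }))
  ca <- matrix(NA_real_, L, 3)
  spread <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    pts <- do.call(rbind, lapply(aligned, function(a) {
      j <- match(i, a$residue_ids)
      if (is.na(j)) NULL else a$ca[j, , drop = FALSE]
    }))
    if (!is.null(pts) && nrow(pts) > 0L) {
      mu <- colMeans(pts)
      ca[i, ] <- mu
      spread[i] <- if (nrow(pts) == 1L) 0
      else sqrt(mean(rowSums(sweep(pts, 2, mu)^2)))
    }
  }
  covered <- which(!is.na(spread))
  if (!length(covered)) stop("templates share no residues with the query numbering")
  # leading gap: extend backward from the first covered stretch
  if (covered[1] > 1L) {
    anchor <- ca[covered[1]:min(covered[1] + 1L, covered[length(covered)]), , drop = FALSE]
    anchor <- anchor[rev(seq_len(nrow(anchor))), , drop = FALSE]
    lead <- extend_helix(anchor, covered[1] - 1L)
    ca[(covered[1] - 1L):1L, ] <- lead
  }
  # internal/trailing gaps: extend forward from the preceding residues
  miss <- which(is.na(ca[, 1]))
  while (length(miss)) {
    i <- miss[1]
    run_end <- i
    while ((run_end + 1L) %in% miss) run_end <- run_end + 1L
    ca[i:run_end, ] <- extend_helix(ca[seq_len(i - 1L), , drop = FALSE],
                                    run_end - i + 1L)
    miss <- which(is.na(ca[, 1]))
  }
  spread[is.na(spread)] <- 4  # uncovered: low confidence
  noise <- with_seed(derive_seed(seed, 1L),
                     matrix(stats::rnorm(L * 3, 0, sigma), L, 3))
  ca <- ca + noise
  # per-residue deviation actually realized: template disagreement plus
  # the noise displacement drawn for this model
  deviation <- spread + sqrt(rowSums(noise^2))
  plddt <- 100 * exp(-deviation / 4)
  ptm <- 1 / (1 + (mean(deviation) / 1.24)^2)
  predicted_model(model_index,
                  structure_coords(seq_len(L), ca, source = "mock:consensus"),
                  plddt = plddt, ptm = ptm)
}
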