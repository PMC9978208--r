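# C-alpha coordinate handling: PDB/mmCIF IO via bio3d, Kabsch
# superposition, segment-restricted RMSD, ensemble summaries and
# conformational-feature classification.

#' C-alpha coordinate traces
#'
#' A `structure_coords` holds an ordered C-alpha trace: strictly increasing
#' 1-based residue ids and an `n x 3` coordinate matrix in Angstrom.
#'
#' @param residue_ids integer vector, strictly increasing.
#' @param ca numeric `n x 3` matrix of coordinates (Angstrom).
#' @param source free-form locator (file + chain) for provenance.
#' @return a `structure_coords` object.
#' @export
structure_coords <- function(residue_ids, ca, source = "") {
  residue_ids <- as.integer(residue_ids)
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  if (ncol(ca) != 3L) stop("ca must be an n x 3 coordinate matrix")
  if (length(residue_ids) != nrow(ca))
    stop("residue_ids and ca disagree in length")
  if (any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  structure(list(residue_ids = residue_ids, ca = ca, source = source),
            class = "structure_coords")
}

#' Read a C-alpha trace from a PDB or mmCIF file
#'
#' mmCIF is chosen by a `.cif` extension. Altloc `A` (or blank) is taken;
#' residues with insertion codes are rejected with an error, since the
#' 1-based author-numbering convention used throughout cannot represent
#' them.
#'
#' @param path coordinate file (`.pdb` or `.cif`).
#' @param chain author chain id; `NULL` takes the first chain present.
#' @return a [structure_coords()].
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read coordinate file: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path, verbose = FALSE)
  else bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$elety == "CA" & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (is.null(chain)) chain <- at$chain[keep][1]
  keep <- keep & at$chain == chain
  if (!any(keep)) stop("no CA atoms for chain '", chain, "' in ", path)
  ins <- at$insert[keep]
  if (any(!is.na(ins) & nzchar(ins)))
    stop("insertion codes present in ", path,
         " (chain ", chain, "); renumber the structure first")
  structure_coords(at$resno[keep],
                   cbind(at$x[keep], at$y[keep], at$z[keep]),
                   source = paste0(path, ":", chain))
}

#' Write a C-alpha trace as a PDB file
#'
#' @param x a [structure_coords()].
#' @param path output PDB path.
#' @param chain chain id to write.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, chain = "A") {
  stopifnot(inherits(x, "structure_coords"))
  n <- length(x$residue_ids)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(x$ca)),
                   resno = x$residue_ids, resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep(chain, n))
  invisible(path)
}

# rows of each ca matrix for the shared residue ids (optionally restricted)
match_residues <- function(a, b, selection = NULL) {
  ids <- intersect(a$residue_ids, b$residue_ids)
  if (!is.null(selection)) ids <- intersect(ids, as.integer(selection))
  ids <- sort(ids)
  list(ids = ids,
       a = a$ca[match(ids, a$residue_ids), , drop = FALSE],
       b = b$ca[match(ids, b$residue_ids), , drop = FALSE])
}

#' Kabsch least-squares superposition
#'
#' Closed-form optimal rigid alignment of the mobile structure onto the
#' fixed one over a residue selection, via SVD of the cross-covariance
#' matrix with the determinant correction that enforces a proper rotation
#' (no reflection).
#'
#' @param mobile,fixed [structure_coords()] objects.
#' @param selection residue ids to superpose on (default: all shared).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3;
#'   the transform is `x %*% rotation + translation`), `rmsd` over the
#'   selection after the transform, and `n` residues used.
#' @export
kabsch_superpose <- function(mobile, fixed, selection = NULL) {
  m <- match_residues(mobile, fixed, selection)
  if (length(m$ids) < 3L)
    stop("need at least 3 common residues to superpose, got ", length(m$ids))
  P <- m$a; Q <- m$b
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12))
    stop("degenerate (collinear) selection: superposition is not unique")
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t_vec <- as.numeric(cq - cp %*% R)
  moved <- P %*% R + matrix(t_vec, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))), n = length(m$ids))
}

#' @rdname kabsch_superpose
#' @param x a [structure_coords()] to transform.
#' @param fit a fit returned by `kabsch_superpose`.
#' @export
apply_transform <- function(x, fit) {
  structure_coords(x$residue_ids,
                   x$ca %*% fit$rotation +
                     matrix(fit$translation, nrow(x$ca), 3, byrow = TRUE),
                   source = x$source)
}

rmsd_over <- function(a, b, ids) {
  pa <- a$ca[match(ids, a$residue_ids), , drop = FALSE]
  pb <- b$ca[match(ids, b$residue_ids), , drop = FALSE]
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Segment-restricted RMSD report
#'
#' Computes the three accuracy measures used to score a model against an
#' experimental reference: `tm_rmsd`, the C-alpha RMSD over the union of
#' transmembrane segments (names matching `TM<d>`) after superposing on
#' that union; `loop_rmsd`, the RMSD over the remaining shared residues
#' scored in the TM-superposed frame (so it reports loop placement
#' relative to the helical bundle; set `loop_frame = "independent"` for a
#' separate loop superposition); and `global_rmsd`, over all shared
#' residues after a global superposition. For maps without TM segments
#' (kinase motif maps), the union of all segments takes the TM role.
#'
#' @param model,reference [structure_coords()] objects.
#' @param segments a [segment_map()] in query numbering.
#' @param loop_frame `"tm"` (default) or `"independent"`.
#' @return an `rmsd_report`: list with `tm_rmsd`, `loop_rmsd`,
#'   `global_rmsd`, `n_tm`, `n_loop`, `n_global`.
#' @export
segment_rmsd <- function(model, reference, segments, loop_frame = c("tm", "independent")) {
  loop_frame <- match.arg(loop_frame)
  stopifnot(inherits(segments, "segment_map"))
  tm_names <- grep("^TM[0-9]+$", names(segments), value = TRUE)
  core_pattern <- if (length(tm_names)) "^TM[0-9]+$" else "."
  core_ids <- segment_residues(segments, core_pattern)
  shared <- intersect(model$residue_ids, reference$residue_ids)
  tm_ids <- intersect(core_ids, shared)
  if (length(tm_ids) == 0L)
    stop("no shared residues in segment selection '",
         paste(grep(core_pattern, names(segments), value = TRUE), collapse = ","), "'")
  fit_tm <- kabsch_superpose(model, reference, tm_ids)
  model_tm <- apply_transform(model, fit_tm)
  loop_ids <- setdiff(shared, core_ids)
  loop_rmsd <- if (length(loop_ids) == 0L) NA_real_
  else if (loop_frame == "tm") rmsd_over(model_tm, reference, loop_ids)
  else kabsch_superpose(model, reference, loop_ids)$rmsd
  fit_all <- kabsch_superpose(model, reference, shared)
  structure(list(tm_rmsd = fit_tm$rmsd, loop_rmsd = loop_rmsd,
                 global_rmsd = fit_all$rmsd,
                 n_tm = length(tm_ids), n_loop = length(loop_ids),
                 n_global = length(shared)),
            class = "rmsd_report")
}

#' Summarise an ensemble against a reference structure
#'
#' @param models list of `predicted_model` (see [mock_predictor()]) or of
#'   [structure_coords()].
#' @param reference the reference [structure_coords()].
#' @param segments a [segment_map()].
#' @return list with `table` (one row per model: index, TM/loop/global
#'   RMSD, pTM, mean pLDDT, ordered by model index) and `best`, the model
#'   index with minimal TM-RMSD (ties broken by model index).
#' @export
ensemble_summary <- function(models, reference, segments) {
  stopifnot(length(models) >= 1L)
  rows <- lapply(models, function(m) {
    coords <- if (inherits(m, "structure_coords")) m else m$coords
    rep_ <- segment_rmsd(coords, reference, segments)
    data.frame(model_index = if (inherits(m, "structure_coords")) NA_integer_ else m$model_index,
               tm_rmsd = rep_$tm_rmsd, loop_rmsd = rep_$loop_rmsd,
               global_rmsd = rep_$global_rmsd,
               ptm = if (inherits(m, "structure_coords")) NA_real_ else m$ptm,
               mean_plddt = if (inherits(m, "structure_coords")) NA_real_ else mean(m$plddt))
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$model_index))) tab$model_index <- seq_len(nrow(tab)) - 1L
  tab <- tab[order(tab$model_index), , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab$model_index[which.min(tab$tm_rmsd)]
  list(table = tab, best = best)
}

#' Spearman correlation between pTM and RMSD
#'
#' Rank correlation with average ranks for ties, the standard diagnostic
#' of whether a predictor's global confidence tracks accuracy within an
#' ensemble.
#'
#' @param ptm,rmsd numeric vectors of equal length (>= 3 finite pairs).
#' @return list with `rho` in `[-1, 1]` (NA when either variable has zero
#'   variance) and `n`, the number of pairs used.
#' @export
ptm_rmsd_correlation <- function(ptm, rmsd) {
  stopifnot(length(ptm) == length(rmsd))
  ok <- is.finite(ptm) & is.finite(rmsd)
  if (sum(ok) < 3L)
    stop("need at least 3 models with finite pTM and RMSD, got ", sum(ok))
  x <- ptm[ok]; y <- rmsd[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, n = sum(ok)))
  list(rho = stats::cor(x, y, method = "spearman"), n = sum(ok))
}

#' Classify kinase conformational features by nearest reference
#'
#' Assigns the activation-loop (`a_loop`) and alphaC-helix (`ac_helix`)
#' in/out labels of a model by nearest-reference motif RMSD: the model is
#' superposed onto each labelled exemplar over the kinase core (all shared
#' residues outside the motif segments), the RMSD over the feature's motif
#' segment is measured in that frame, and the feature takes the label of
#' the closest exemplar. Ties are flagged with a warning and resolved
#' toward the earlier exemplar in the library.
#'
#' @param model a [structure_coords()].
#' @param motif_segments [segment_map()] naming at least `a_loop` and
#'   `ac_helix` (a `DFG` segment, when present, counts as part of the
#'   non-core motif region).
#' @param reference_library list of exemplars, each
#'   `list(coords = structure_coords, a_loop = "in"|"out", ac_helix = ...)`.
#' @return list with `a_loop`, `ac_helix` labels, per-feature `margin`
#'   (second-best minus best RMSD, Angstrom) and the per-exemplar RMSD
#'   tables.
#' @export
classify_kinase_conformation <- function(model, motif_segments, reference_library) {
  stopifnot(inherits(motif_segments, "segment_map"), length(reference_library) >= 1L)
  features <- c("a_loop", "ac_helix")
  if (!all(features %in% names(motif_segments)))
    stop("motif_segments must name segments: ", paste(features, collapse = ", "))
  motif_ids <- segment_residues(motif_segments)
  details <- list(); out <- list()
  for (feat in features) {
    feat_ids <- segment_residues(motif_segments,
                                 paste0("^", feat, "$"))
    labels <- vapply(reference_library, function(r) r[[feat]] %||% "unknown",
                     character(1))
    usable <- which(labels %in% c("in", "out"))
    if (!length(usable))
      stop("reference library has no exemplar labelled for ", feat)
    d <- vapply(usable, function(i) {
      ref <- reference_library[[i]]$coords
      shared <- intersect(model$residue_ids, ref$residue_ids)
      core <- setdiff(shared, motif_ids)
      ids <- intersect(feat_ids, shared)
      if (!length(ids))
        stop("motif residues '", feat, "' missing from model or reference")
      fit <- kabsch_superpose(model, ref, core)
      rmsd_over(apply_transform(model, fit), ref, ids)
    }, numeric(1))
    tol <- 1e-6
    # nearest exemplar; numerical near-ties resolve to the earlier one
    best <- which(d <= min(d) + tol)[1]
    margin <- NA_real_
    other <- which(labels[usable] != labels[usable][best])
    if (length(other)) margin <- min(d[other]) - d[best]
    if (!is.na(margin) && abs(margin) < tol)
      warning("tie in ", feat, " classification; keeping earlier exemplar")
    out[[feat]] <- labels[usable][best]
    out[[paste0("margin_", feat)]] <- margin
    details[[feat]] <- data.frame(exemplar = usable, label = labels[usable],
                                  rmsd = d)
  }
  c(out, list(details = details))
}
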