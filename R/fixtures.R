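# Synthetic test fixtures: toy GPCR and kinase conformer structures with
# known state differences, annotation tables, segment maps and toy
# alignments.  Everything here is a deliberate cartoon — ideal-helix
# C-alpha geometry, rigid segment displacements — sufficient to exercise
# selection, prediction and evaluation, and reproducible from (spec, seed).
# All generated structures are synthetic and labelled as such in their
# REMARKs-free minimal PDB files and file names.

#' Specification of a toy conformer pair
#'
#' @param mode `"gpcr"` (seven-TM helical bundle; activation is a rigid
#'   outward swing of TM6) or `"kinase"` (two-lobe cartoon; the state flip
#'   is a rigid relocation of the DFG motif plus activation loop).
#' @param helix_len,loop_len residues per helix and per connecting loop.
#' @param state_displacement Angstrom displacement applied to the
#'   designated segment in state B (default 4 for GPCR, 6 for kinase).
#' @param noise_sigma optional Gaussian jitter (Angstrom) applied to both
#'   states identically (keeps the A/B difference a pure rigid shift).
#' @param seed RNG seed for the jitter.
#' @return a `conformer_spec` list.
#' @export
conformer_spec <- function(mode = c("gpcr", "kinase"),
                           helix_len = 24L, loop_len = 5L,
                           state_displacement = if (mode[1] == "kinase") 6 else 4,
                           noise_sigma = 0, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(state_displacement >= 0, noise_sigma >= 0)
  structure(list(mode = mode, helix_len = as.integer(helix_len),
                 loop_len = as.integer(loop_len),
                 state_displacement = state_displacement,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "conformer_spec")
}

# straight-line interpolation between two points, n interior residues
loop_trace <- function(from, to, n) {
  if (n == 0L) return(NULL)
  f <- seq_len(n) / (n + 1)
  cbind(from[1] + f * (to[1] - from[1]),
        from[2] + f * (to[2] - from[2]),
        from[3] + f * (to[3] - from[3]))
}

# seven-TM helical bundle on a circle; returns list(ca, segments)
build_gpcr_bundle <- function(helix_len, loop_len) {
  n_helices <- 7L
  radius <- 14
  ca <- NULL
  seg <- list()
  pos <- 0L
  for (h in seq_len(n_helices)) {
    ang <- 2 * pi * (h - 1) / n_helices
    hx <- ideal_helix(helix_len)
    if (h %% 2L == 0L) hx[, 3] <- max(hx[, 3]) - hx[, 3]  # alternate direction
    hx[, 1] <- hx[, 1] + radius * cos(ang)
    hx[, 2] <- hx[, 2] + radius * sin(ang)
    if (!is.null(ca)) {
      lp <- loop_trace(ca[nrow(ca), ], hx[1, ], loop_len)
      ca <- rbind(ca, lp)
      pos <- pos + loop_len
    }
    seg[[paste0("TM", h)]] <- c(pos + 1L, pos + helix_len)
    ca <- rbind(ca, hx)
    pos <- pos + helix_len
  }
  list(ca = ca, segments = segment_map(seg))
}

# two-lobe kinase cartoon: helix1 - loop - aC helix - loop - helix3 -
# DFG + activation loop - helix4
build_kinase_cartoon <- function(helix_len = 18L, loop_len = 4L,
                                 a_loop_len = 12L) {
  seg <- list(); pieces <- list(); pos <- 0L
  place <- function(name, block) {
    if (!is.null(name)) seg[[name]] <<- c(pos + 1L, pos + nrow(block))
    pieces[[length(pieces) + 1L]] <<- block
    pos <<- pos + nrow(block)
  }
  h <- function(dx, dy) {
    b <- ideal_helix(helix_len); b[, 1] <- b[, 1] + dx; b[, 2] <- b[, 2] + dy; b
  }
  joined <- function(block) {
    prev <- do.call(rbind, pieces)
    lp <- loop_trace(prev[nrow(prev), ], block[1, ], loop_len)
    place(NULL, lp)
    block
  }
  place(NULL, h(0, 0))                       # N-lobe helix
  place("ac_helix", joined(h(10, 6)))        # alphaC helix
  place(NULL, joined(h(20, 0)))              # C-lobe helix
  prev <- do.call(rbind, pieces)
  start <- prev[nrow(prev), ]
  dfg <- rbind(start + c(2.5, 2.5, 0), start + c(5.0, 3.5, 0),
               start + c(7.5, 2.5, 0))
  place("DFG", dfg)
  al <- loop_trace(dfg[3, ], dfg[3, ] + c(3.8 * (a_loop_len + 1), 0, 0),
                   a_loop_len)
  place("a_loop", al)
  place(NULL, joined(h(55, 0)))              # C-terminal helix
  list(ca = do.call(rbind, pieces), segments = segment_map(seg))
}

#' Build a toy conformer pair with a known state difference
#'
#' State A is the base geometry; state B differs ONLY by a rigid
#' translation of the designated segment (TM6 for GPCRs, DFG + activation
#' loop for kinases) by `state_displacement` Angstrom, so the
#' segment-restricted RMSD between the two states (without superposition)
#' equals the displacement exactly.
#'
#' @param spec a [conformer_spec()].
#' @param dir optional directory; when given, `state_a.pdb`,
#'   `state_b.pdb` and `segments.json` are written there.
#' @return list with `state_a`, `state_b` ([structure_coords()]),
#'   `segments` ([segment_map()]), the displaced segment name, and file
#'   paths when `dir` was given.
#' @export
make_conformer_pair <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "conformer_spec"))
  base <- if (spec$mode == "gpcr")
    build_gpcr_bundle(spec$helix_len, spec$loop_len)
  else build_kinase_cartoon()
  ca <- base$ca
  if (spec$noise_sigma > 0)
    ca <- ca + with_seed(derive_seed(spec$seed, 7L),
                         matrix(stats::rnorm(length(ca), 0, spec$noise_sigma),
                                nrow(ca), 3))
  seg_name <- if (spec$mode == "gpcr") "TM6" else "a_loop"
  moved <- segment_residues(base$segments,
                            if (spec$mode == "gpcr") "^TM6$" else "^(DFG|a_loop)$")
  if (max(moved) > nrow(ca)) stop("displacement segment outside the chain")
  # outward = radially away from the bundle center of mass
  centroid <- colMeans(ca)
  seg_cen <- colMeans(ca[moved, , drop = FALSE])
  dirv <- seg_cen - centroid
  dirv[3] <- 0
  dirv <- dirv / max(sqrt(sum(dirv^2)), 1e-9)
  ca_b <- ca
  ca_b[moved, ] <- ca[moved, , drop = FALSE] +
    matrix(spec$state_displacement * dirv, length(moved), 3, byrow = TRUE)
  ids <- seq_len(nrow(ca))
  out <- list(state_a = structure_coords(ids, ca, source = "synthetic:state_a"),
              state_b = structure_coords(ids, ca_b, source = "synthetic:state_b"),
              segments = base$segments, displaced_segment = seg_name)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$state_a_path <- file.path(dir, "synthetic_state_a.pdb")
    out$state_b_path <- file.path(dir, "synthetic_state_b.pdb")
    out$segments_path <- file.path(dir, "segments.json")
    write_structure(out$state_a, out$state_a_path)
    write_structure(out$state_b, out$state_b_path)
    write_segment_map(out$segments, out$segments_path)
  }
  out
}

random_aa_seq <- function(n, seed = 0L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(derive_seed(seed, 11L),
            paste(sample(aa, n, replace = TRUE), collapse = ""))
}

# jittered copy of a conformer, written as a PDB template file
write_noisy_template <- function(coords, path, sigma, seed) {
  ca <- coords$ca + with_seed(seed, matrix(stats::rnorm(length(coords$ca), 0, sigma),
                                           nrow(coords$ca), 3))
  write_structure(structure_coords(coords$residue_ids, ca,
                                   source = "synthetic:template"), path)
  path
}

#' Generate a complete annotation fixture
#'
#' Builds a self-contained directory holding: a toy conformer pair per
#' mode, per-record jittered template structures (Active records derive
#' from state A, Inactive from state B; kinase records cycle through the
#' DFG/alphaC label combinations with matching geometry), an annotation
#' TSV in the documented dialect, reference structures for evaluation, a
#' segment map JSON keyed by query id, and the query sequence.
#'
#' @param dir output directory.
#' @param n_active,n_inactive GPCR record counts per state.
#' @param n_kinase kinase record count (0 for a pure GPCR fixture).
#' @param seed master seed; every file is reproducible from it.
#' @param noise_sigma jitter applied to each template copy (Angstrom).
#' @param gpcr_displacement,kinase_displacement state differences (Angstrom).
#' @return list with `tsv`, `records`, `segments` / `kinase_segments`
#'   maps and reference paths, query ids and sequences.
#' @export
make_annotation_fixture <- function(dir, n_active = 10L, n_inactive = 10L,
                                    n_kinase = 0L, seed = 0L,
                                    noise_sigma = 0.3,
                                    gpcr_displacement = 4,
                                    kinase_displacement = 6) {
  stopifnot(n_active >= 0, n_inactive >= 0, n_kinase >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); out <- list(dir = dir)

  if (n_active + n_inactive > 0L) {
    pair <- make_conformer_pair(
      conformer_spec("gpcr", state_displacement = gpcr_displacement,
                     seed = seed), dir = dir)
    out$gpcr_segments <- pair$segments
    out$active_ref <- pair$state_a_path
    out$inactive_ref <- pair$state_b_path
    out$gpcr_query_seq <- random_aa_seq(length(pair$state_a$residue_ids), seed)
    states <- c(rep("Active", n_active), rep("Inactive", n_inactive))
    scores <- with_seed(derive_seed(seed, 21L),
                        round(sort(stats::runif(length(states), 10, 100),
                                   decreasing = TRUE), 1))
    idents <- with_seed(derive_seed(seed, 22L),
                        round(stats::runif(length(states), 15, 45), 1))
    for (i in seq_along(states)) {
      pdb_id <- sprintf("9G%02d", i)
      src <- if (states[i] == "Active") pair$state_a else pair$state_b
      path <- file.path(dir, sprintf("synthetic_tmpl_%s.pdb", pdb_id))
      write_noisy_template(src, path, noise_sigma, derive_seed(seed, 100L + i))
      rows[[length(rows) + 1L]] <- data.frame(
        pdb_id = pdb_id, chain_id = "A", sequence = out$gpcr_query_seq,
        rank_score = scores[i], seq_identity = idents[i],
        family = "ClassA", subfamily = c("synthA", "synthB")[(i %% 2L) + 1L],
        gpcr_state = states[i], dfg = "unknown", ac_helix = "unknown",
        salt_bridge = "unknown", a_loop = "unknown", coords_path = path)
    }
    # segment map JSON keyed by query id
    out$gpcr_query_id <- "GPCR_QUERY"
    segfile <- file.path(dir, "segment_maps.json")
    jsonlite::write_json(stats::setNames(list(unclass(pair$segments)),
                                         out$gpcr_query_id),
                         segfile, auto_unbox = FALSE)
    out$segment_maps <- segfile
  }

  if (n_kinase > 0L) {
    klib <- make_kinase_reference_library(dir, displacement = kinase_displacement,
                                          seed = seed)
    out$kinase_segments <- klib$segments
    out$kinase_library <- klib$library
    out$kinase_query_seq <- random_aa_seq(
      length(klib$library[[1]]$coords$residue_ids), seed + 1L)
    combos <- data.frame(
      dfg = c("in", "in", "out", "out-like"),
      ac_helix = c("in", "out", "out", "in"),
      salt_bridge = c("yes", "no", "no", "no"),
      a_loop = c("in", "in", "out", "out"))
    scores <- with_seed(derive_seed(seed, 31L),
                        round(sort(stats::runif(n_kinase, 10, 100),
                                   decreasing = TRUE), 1))
    idents <- with_seed(derive_seed(seed, 32L),
                        round(stats::runif(n_kinase, 15, 45), 1))
    for (i in seq_len(n_kinase)) {
      cmb <- combos[((i - 1L) %% nrow(combos)) + 1L, ]
      pdb_id <- sprintf("9K%02d", i)
      src <- klib$by_label[[paste0(cmb$a_loop, "/", cmb$ac_helix)]]
      path <- file.path(dir, sprintf("synthetic_tmpl_%s.pdb", pdb_id))
      write_noisy_template(src, path, noise_sigma, derive_seed(seed, 200L + i))
      rows[[length(rows) + 1L]] <- data.frame(
        pdb_id = pdb_id, chain_id = "A", sequence = out$kinase_query_seq,
        rank_score = scores[i], seq_identity = idents[i],
        family = "STE", subfamily = "synthK",
        gpcr_state = "unknown", dfg = cmb$dfg, ac_helix = cmb$ac_helix,
        salt_bridge = cmb$salt_bridge, a_loop = cmb$a_loop,
        coords_path = path)
    }
  }

  records <- template_records(do.call(rbind, rows))
  out$tsv <- file.path(dir, "annotations.tsv")
  write_annotations(records, out$tsv)
  out$records <- records
  out
}

#' Toy kinase reference library
#'
#' Four exemplars covering the `a_loop` x `ac_helix` in/out combinations,
#' built from the kinase cartoon by rigid displacement of the DFG +
#' activation loop (a_loop out) and of the alphaC helix (ac_helix out).
#'
#' @param dir optional directory for the exemplar PDB files.
#' @param displacement Angstrom shift defining "out" (default 6).
#' @param seed reserved for future jitter; exemplars are noise-free.
#' @return list with `library` (exemplars as
#'   `list(coords, a_loop, ac_helix, path)`), `by_label` (coords indexed
#'   by `"a_loop/ac_helix"`), and `segments`.
#' @export
make_kinase_reference_library <- function(dir = NULL, displacement = 6,
                                          seed = 0L) {
  base <- build_kinase_cartoon()
  seg <- base$segments
  aloop_ids <- segment_residues(seg, "^(DFG|a_loop)$")
  ach_ids <- segment_residues(seg, "^ac_helix$")
  shift <- function(ca, ids, v) {
    ca[ids, ] <- ca[ids, , drop = FALSE] + matrix(v, length(ids), 3, byrow = TRUE)
    ca
  }
  variants <- list(
    `in/in` = base$ca,
    `in/out` = shift(base$ca, ach_ids, c(0, displacement, 0)),
    `out/in` = shift(base$ca, aloop_ids, c(0, -displacement, 0)),
    `out/out` = shift(shift(base$ca, aloop_ids, c(0, -displacement, 0)),
                      ach_ids, c(0, displacement, 0)))
  ids <- seq_len(nrow(base$ca))
  library <- lapply(names(variants), function(nm) {
    lab <- strsplit(nm, "/", fixed = TRUE)[[1]]
    coords <- structure_coords(ids, variants[[nm]],
                               source = paste0("synthetic:kinase_", nm))
    path <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(dir, sprintf("synthetic_kinase_aloop_%s_ach_%s.pdb",
                                     lab[1], lab[2]))
      write_structure(coords, path)
    }
    list(coords = coords, a_loop = lab[1], ac_helix = lab[2], path = path)
  })
  by_label <- stats::setNames(lapply(library, `[[`, "coords"), names(variants))
  list(library = library, by_label = by_label, segments = seg)
}

#' Generate a toy A3M alignment
#'
#' The query is a random sequence; each homolog keeps every query residue
#' with probability `identity` and substitutes a uniformly random
#' different residue otherwise (no gaps, no insertions: a minimal valid
#' A3M).
#'
#' @param query_length residues in the query.
#' @param depth number of rows including the query.
#' @param identity expected per-position identity of homologs.
#' @param seed RNG seed.
#' @param path optional A3M output file.
#' @param query_seq optional explicit query sequence.
#' @return an [msa()]; written to `path` when given.
#' @export
make_toy_msa <- function(query_length = 100L, depth = 50L, identity = 0.9,
                         seed = 0L, path = NULL, query_seq = NULL) {
  stopifnot(depth >= 1L, identity >= 0, identity <= 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  q <- query_seq %||% random_aa_seq(query_length, seed)
  qch <- strsplit(q, "")[[1]]
  rows <- with_seed(derive_seed(seed, 41L), {
    c(q, vapply(seq_len(depth - 1L), function(i) {
      keep <- stats::runif(length(qch)) < identity
      mut <- vapply(qch, function(a) sample(setdiff(aa, a), 1L), character(1))
      paste(ifelse(keep, qch, mut), collapse = "")
    }, character(1)))
  })
  m <- msa(rows, ids = c("query", paste0("hom", seq_len(depth - 1L))),
           query_id = "query")
  if (!is.null(path)) write_a3m(m, path)
  m
}
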