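# A3M alignments and the three MSA interventions that let templates steer
# a prediction: shallow subsampling, removal over template-covered regions
# (noMSA) and sliding-window masking.

#' Query-anchored multiple sequence alignments (A3M)
#'
#' An `msa` holds a query-anchored alignment in the A3M convention: the
#' query is row 1 (uppercase, no gaps); match states in other rows are
#' uppercase letters or `-`; insertions relative to the query are lowercase
#' and do not count as columns. All rows therefore span exactly
#' `query length` match columns.
#'
#' @param rows character vector of aligned sequences, query first.
#' @param ids sequence identifiers (same length as `rows`).
#' @param query_id identifier of the query (defaults to `ids[1]`).
#' @param provenance list tagging how this alignment was derived
#'   (`kind` one of `"raw"`, `"subsampled"`, `"nomsa"`, `"speach_masked"`,
#'   plus the parameters used).
#' @return an `msa` object.
#' @export
msa <- function(rows, ids = NULL, query_id = NULL,
                provenance = list(kind = "raw")) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows) - 1L)
  stopifnot(length(ids) == length(rows))
  if (grepl("-", rows[1], fixed = TRUE))
    stop("query row must contain no gaps after A3M normalization")
  widths <- match_width(rows)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged alignment: row '", ids[bad], "' spans ", widths[bad],
         " match columns, query spans ", widths[1])
  }
  structure(list(query_id = query_id %||% ids[1], ids = ids, rows = rows,
                 provenance = provenance),
            class = "msa")
}

# number of match columns (uppercase or gap) per row
match_width <- function(rows) {
  vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    sum(ch == "-" | (ch %in% LETTERS))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname msa
#' @param x an `msa`.
#' @export
msa_depth <- function(x) length(x$rows)

#' @rdname msa
#' @export
msa_query_length <- function(x) nchar(gsub("[a-z]", "", x$rows[1]))

#' Read and write A3M files
#'
#' Files are FASTA-framed; `read_a3m(write_a3m(x, f))` is the identity on
#' normalized content, lowercase insertion states included.
#'
#' @param path an A3M file.
#' @return `read_a3m` returns an [msa()]; `write_a3m` returns `path`
#'   invisibly.
#' @export
read_a3m <- function(path) {
  if (!file.exists(path)) stop("cannot read A3M file: ", path)
  set <- Biostrings::readBStringSet(path)
  rows <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  msa(unname(rows), ids = ids)
}

#' @rdname read_a3m
#' @param x an `msa`.
#' @export
write_a3m <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  set <- Biostrings::BStringSet(x$rows)
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

#' Subsample an alignment to a shallow MSA
#'
#' Draws the two row subsets handed to the predictor as "sequence clusters"
#' and "extra cluster sequences". The cluster block holds the query plus
#' `n_clusters - 1` uniformly drawn rows; the extra block holds `n_extra`
#' rows drawn from the remainder, so the two blocks are disjoint.
#' Shortfalls (alignment shallower than requested) are taken as-is.
#' The GPCR protocol default is 8 clusters + 16 extra; the MSA-only
#' variant uses 16 + 32.
#'
#' @param x an [msa()].
#' @param n_clusters cluster block size (query included).
#' @param n_extra extra block size.
#' @param seed draw seed; the draw is reproducible from it.
#' @return list with elements `clusters` (an `msa`, query first) and
#'   `extra` (an `msa`-shaped block without the query; may be empty).
#' @export
msa_subsample <- function(x, n_clusters, n_extra = 0L, seed = 0L) {
  stopifnot(inherits(x, "msa"), is_count(n_clusters), n_clusters >= 1,
            is_count(n_extra))
  n <- msa_depth(x)
  pool <- setdiff(seq_len(n), 1L)
  idx <- with_seed(derive_seed(seed, 0L), {
    cl_extra <- sort(sample(pool, min(n_clusters - 1L, length(pool))))
    rest <- setdiff(pool, cl_extra)
    ex <- sort(sample(rest, min(n_extra, length(rest))))
    list(cl = c(1L, cl_extra), ex = ex)
  })
  prov <- list(kind = "subsampled", n_clusters = n_clusters,
               n_extra = n_extra, seed = seed)
  clusters <- msa(x$rows[idx$cl], ids = x$ids[idx$cl],
                  query_id = x$query_id, provenance = prov)
  extra <- structure(list(query_id = x$query_id, ids = x$ids[idx$ex],
                          rows = x$rows[idx$ex],
                          provenance = c(prov, list(query_included = FALSE))),
                     class = "msa")
  list(clusters = clusters, extra = extra)
}

# replace match-state characters at the given query columns with gaps,
# in all rows except the query; insertions are untouched.
gap_columns <- function(x, columns, kind, extra_prov = list()) {
  ql <- msa_query_length(x)
  columns <- as.integer(columns)
  if (length(columns) && (min(columns) < 1L || max(columns) > ql))
    stop("column index out of range [1, ", ql, "]")
  cols <- logical(ql)
  cols[columns] <- TRUE
  rows <- x$rows
  if (length(rows) > 1L && any(cols)) {
    for (i in seq_along(rows)[-1]) {
      ch <- strsplit(rows[i], "", fixed = TRUE)[[1]]
      is_match <- ch == "-" | ch %in% LETTERS
      at <- which(is_match)[cols]
      ch[at] <- "-"
      rows[i] <- paste(ch, collapse = "")
    }
  }
  msa(rows, ids = x$ids, query_id = x$query_id,
      provenance = c(list(kind = kind), extra_prov))
}

#' Remove alignment rows over template-covered regions (noMSA)
#'
#' Gaps out every non-query row at the query columns covered by the
#' selected templates' alignment footprint, making the prediction
#' template-driven there. The query row, columns outside the footprint,
#' and the alignment depth are unchanged; the operation is idempotent.
#'
#' @param x an [msa()].
#' @param covered_columns integer vector of 1-based query positions covered
#'   by at least one selected template.
#' @return an `msa` with provenance `"nomsa"`.
#' @export
msa_remove_over_templates <- function(x, covered_columns) {
  stopifnot(inherits(x, "msa"))
  gap_columns(x, covered_columns, "nomsa",
              list(covered = as.integer(covered_columns)))
}

#' Sliding-window masked alignment variants
#'
#' Generates one alignment variant per window placement; in each variant a
#' block of `window` consecutive query columns is masked (all rows but the
#' query gapped there), perturbing the prediction toward conformations
#' less represented in the alignment. The protocol default window is 10
#' residues; the stride defaults to the window (non-overlapping), with the
#' final window right-aligned so the placements cover every column.
#'
#' @param x an [msa()].
#' @param window number of masked columns per variant (positive).
#' @param stride distance between window starts (default `window`).
#' @return list of `msa` variants; each carries its window in
#'   `provenance$window_start/window_end`.
#' @export
msa_speach_variants <- function(x, window = 10L, stride = window) {
  stopifnot(inherits(x, "msa"))
  if (!is_count(window) || window < 1L) stop("window must be a positive integer")
  stopifnot(is_count(stride), stride >= 1L)
  window <- as.integer(window); stride <- as.integer(stride)
  ql <- msa_query_length(x)
  if (window > ql) stop("window (", window, ") exceeds query length (", ql, ")")
  starts <- seq.int(1L, ql, by = stride)
  starts <- starts[starts + window - 1L <= ql | starts == starts[1]]
  last <- ql - window + 1L
  if (max(starts + window - 1L) < ql) starts <- c(starts, last)
  starts <- unique(pmin(starts, last))
  lapply(starts, function(s) {
    gap_columns(x, seq.int(s, s + window - 1L), "speach_masked",
                list(window_start = s, window_end = s + window - 1L,
                     window = window, stride = stride))
  })
}
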