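# Template annotation store: a uniform record model for state-annotated
# GPCR and kinase template chains, a TSV fixture store, and remote-API
# adapters that normalize to the same records.

#' @name annotations
#' @title Template annotation records
#' @description
#' A template record describes one annotated template chain: PDB id, author
#' chain, sequence, the upstream template-search ranking score, percent
#' sequence identity to the query, family/subfamily, the GPCR activation
#' state label, the kinase conformational feature labels (DFG, alphaC-helix,
#' K-E salt bridge, activation loop), and a locator for its coordinate file.
#' Records are held as a `data.frame` of class `template_records`, one row
#' per chain, in source order.
#'
#' Label vocabularies follow the GPCRdb and KLIFS conventions:
#' activation state one of `"Active"`, `"Inactive"`, `"Intermediate"`,
#' `"G protein"`, `"Arrestin"` (or `"unknown"`); DFG one of `"out"`, `"in"`,
#' `"out-like"`; alphaC-helix `"out"`/`"in"`; salt bridge `"yes"`/`"no"`;
#' activation loop `"in"`/`"out"`. Absent labels are stored as `"unknown"`,
#' never dropped.
NULL

gpcr_state_levels <- function() c("Active", "Inactive", "Intermediate", "G protein", "Arrestin", "unknown")
dfg_levels        <- function() c("out", "in", "out-like", "unknown")
ac_helix_levels   <- function() c("out", "in", "unknown")
salt_bridge_levels <- function() c("yes", "no", "unknown")
a_loop_levels     <- function() c("in", "out", "unknown")

template_record_columns <- function() {
  c("pdb_id", "chain_id", "sequence", "rank_score", "seq_identity",
    "family", "subfamily", "gpcr_state", "dfg", "ac_helix", "salt_bridge",
    "a_loop", "coords_path")
}

#' Construct and validate a table of template records
#'
#' @param df data.frame carrying the columns named by the documented TSV
#'   header (see [load_annotations()]); missing label columns are filled
#'   with `"unknown"`, a missing `coords_path` with `NA`.
#' @return a validated `template_records` data.frame.
#' @export
template_records <- function(df) {
  stopifnot(is.data.frame(df))
  for (lab in c("family", "subfamily")) if (is.null(df[[lab]])) df[[lab]] <- ""
  for (lab in c("gpcr_state", "dfg", "ac_helix", "salt_bridge", "a_loop"))
    if (is.null(df[[lab]])) df[[lab]] <- "unknown"
  if (is.null(df$coords_path)) df$coords_path <- NA_character_
  need <- setdiff(template_record_columns(), names(df))
  if (length(need))
    stop("template_records: missing required column(s): ", paste(need, collapse = ", "))
  df <- df[, template_record_columns(), drop = FALSE]
  for (lab in c("gpcr_state", "dfg", "ac_helix", "salt_bridge", "a_loop")) {
    v <- as.character(df[[lab]])
    v[is.na(v) | v == ""] <- "unknown"
    df[[lab]] <- v
  }
  df$rank_score <- as.numeric(df$rank_score)
  df$seq_identity <- as.numeric(df$seq_identity)
  validate_template_records(df)
  class(df) <- c("template_records", "data.frame")
  df
}

#' @rdname template_records
#' @param records object to validate.
#' @export
validate_template_records <- function(records) {
  df <- as.data.frame(records)
  bad_id <- !grepl("^[0-9][A-Za-z0-9]{3}$", df$pdb_id)
  if (any(bad_id))
    stop("invalid pdb_id (must be a 4-character PDB code): ",
         paste(unique(df$pdb_id[bad_id]), collapse = ", "))
  check_enum <- function(field, levels) {
    v <- as.character(df[[field]])
    bad <- !(v %in% levels)
    if (any(bad))
      stop("unrecognized value for field '", field, "': ",
           paste(unique(v[bad]), collapse = ", "),
           " (allowed: ", paste(levels, collapse = ", "), ")")
  }
  check_enum("gpcr_state", gpcr_state_levels())
  check_enum("dfg", dfg_levels())
  check_enum("ac_helix", ac_helix_levels())
  check_enum("salt_bridge", salt_bridge_levels())
  check_enum("a_loop", a_loop_levels())
  if (any(is.na(df$rank_score)) || any(df$rank_score < 0))
    stop("rank_score must be a nonnegative number for every record")
  if (any(is.na(df$seq_identity)) || any(df$seq_identity < 0 | df$seq_identity > 100))
    stop("seq_identity must lie in [0, 100] for every record")
  untyped <- df$gpcr_state == "unknown" & df$dfg == "unknown"
  if (any(untyped))
    stop("record(s) ", paste(df$pdb_id[untyped], collapse = ", "),
         " carry neither a GPCR activation state nor a kinase DFG label; ",
         "a record is typed by which label block is populated")
  invisible(records)
}

#' Describe where annotations come from
#'
#' @param kind one of `"fixture"` (local TSV), `"gpcrdb_api"`, `"klifs_api"`.
#' @param location file path (fixture) or URL (API kinds).
#' @param cache_dir optional directory for cached API responses.
#' @param transport for API kinds, a function `function(url) -> JSON string`;
#'   defaults to an HTTP GET. Injectable so adapters are testable offline.
#' @return an `annotation_source` object.
#' @export
annotation_source <- function(kind = c("fixture", "gpcrdb_api", "klifs_api"),
                              location, cache_dir = NULL, transport = NULL) {
  kind <- match.arg(kind)
  stopifnot(is_string(location))
  if (kind == "fixture" && !file.exists(location))
    stop("annotation source not readable: ", location)
  structure(list(kind = kind, location = location, cache_dir = cache_dir,
                 transport = transport),
            class = "annotation_source")
}

#' Load template annotations from a source
#'
#' The fixture dialect is tab-separated with a fixed header
#' (`pdb_id  chain_id  sequence  rank_score  seq_identity  family  subfamily
#' gpcr_state  dfg  ac_helix  salt_bridge  a_loop  coords_path`); label
#' columns may be omitted and default to `"unknown"`. Row order is
#' preserved: it carries the upstream template-search ranking.
#'
#' API sources go through small adapters that map the remote JSON payload
#' onto the same records (see [gpcrdb_adapter()], [klifs_adapter()]).
#'
#' @param source an [annotation_source()] or a path to a fixture TSV.
#' @return a `template_records` data.frame.
#' @export
load_annotations <- function(source) {
  if (is_string(source)) source <- annotation_source("fixture", source)
  stopifnot(inherits(source, "annotation_source"))
  switch(source$kind,
    fixture = load_annotations_tsv(source$location),
    gpcrdb_api = gpcrdb_adapter(source),
    klifs_api = klifs_adapter(source))
}

load_annotations_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop("malformed annotation TSV '", path, "': ",
                             conditionMessage(e)))
  if (!("pdb_id" %in% names(df)))
    stop("malformed annotation TSV '", path, "': missing 'pdb_id' header")
  n_field <- lengths(strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE))
  bad <- which(n_field != n_field[1])
  if (length(bad))
    stop("malformed annotation TSV '", path, "': row ", bad[1],
         " has ", n_field[bad[1]], " fields, expected ", n_field[1])
  template_records(df)
}

#' Write template records as a fixture TSV
#'
#' `load_annotations(write_annotations(x, f))` is the identity on `x`.
#'
#' @param records a `template_records` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  validate_template_records(records)
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- remote adapters ------------------------------------------------------

# The adapters accept a minimal JSON schema (an array of objects using the
# same field names as the TSV header); live endpoint field mapping is the
# adapter's concern and is documented here, not asserted of any remote
# schema. `transport` is injectable for offline testing.

default_transport <- function(url) {
  paste(readLines(url, warn = FALSE), collapse = "\n")
}

#' @rdname load_annotations
#' @param source an `annotation_source` of the matching API kind.
#' @export
gpcrdb_adapter <- function(source) {
  payload <- fetch_json(source)
  records_from_json(payload)
}

#' @rdname load_annotations
#' @export
klifs_adapter <- function(source) {
  payload <- fetch_json(source)
  records_from_json(payload)
}

fetch_json <- function(source) {
  tr <- source$transport %||% default_transport
  txt <- tryCatch(tr(source$location),
                  error = function(e) stop("cannot reach annotation source ",
                                           source$location, ": ",
                                           conditionMessage(e)))
  if (!is.null(source$cache_dir)) {
    dir.create(source$cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache <- file.path(source$cache_dir,
                       paste0(gsub("[^A-Za-z0-9]", "_", source$location), ".json"))
    writeLines(txt, cache)
  }
  jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)
}

records_from_json <- function(payload) {
  df <- as.data.frame(payload, stringsAsFactors = FALSE)
  template_records(df)
}

# ---- segment maps ---------------------------------------------------------

#' Named residue-range maps
#'
#' A segment map names non-overlapping, 1-based inclusive residue ranges in
#' query numbering: `TM1`..`TM7` for a GPCR (residues outside them are
#' loops), or the kinase motifs `DFG`, `ac_helix`, `a_loop`.
#'
#' @param segments named list, each element `c(start, end)`.
#' @return a `segment_map` object.
#' @export
segment_map <- function(segments) {
  stopifnot(is.list(segments), length(segments) >= 1L,
            !is.null(names(segments)), all(nzchar(names(segments))))
  segs <- lapply(segments, function(x) {
    x <- as.integer(x)
    if (length(x) != 2L || any(is.na(x)) || x[1] < 1L || x[2] < x[1])
      stop("each segment must be c(start, end) with 1 <= start <= end")
    x
  })
  ord <- order(vapply(segs, `[`, integer(1), 1L))
  so <- segs[ord]
  for (i in seq_along(so)[-1]) {
    if (so[[i]][1] <= so[[i - 1]][2])
      stop("segments overlap: ", names(so)[i - 1], " [",
           so[[i - 1]][1], ",", so[[i - 1]][2], "] and ",
           names(so)[i], " [", so[[i]][1], ",", so[[i]][2], "]")
  }
  structure(segs, class = "segment_map")
}

#' @rdname segment_map
#' @param map a `segment_map`.
#' @param pattern regular expression selecting segment names.
#' @return integer vector of residue positions in the selected segments.
#' @export
segment_residues <- function(map, pattern = ".") {
  stopifnot(inherits(map, "segment_map"))
  keep <- grepl(pattern, names(map))
  sort(unique(unlist(lapply(unclass(map)[keep],
                            function(x) seq.int(x[1], x[2])))))
}

#' Read or write a segment map as JSON
#'
#' The JSON form is `{"segment": [start, end], ...}`; a file may hold maps
#' for several queries keyed by query id, which is the form
#' [fetch_segment_map()] expects.
#'
#' @param map a `segment_map`.
#' @param path JSON file.
#' @return `write_segment_map` returns `path` invisibly; `read_segment_map`
#'   returns a `segment_map`.
#' @export
write_segment_map <- function(map, path) {
  stopifnot(inherits(map, "segment_map"))
  jsonlite::write_json(unclass(map), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_segment_map
#' @export
read_segment_map <- function(path) {
  if (!file.exists(path)) stop("cannot read segment map: ", path)
  segment_map(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Fetch the segment map for one query from a source
#'
#' The fixture form is a JSON object keyed by query id, each value a
#' `{"segment": [start, end]}` map — the shape GPCRdb's segment endpoints
#' reduce to.
#'
#' @param source an [annotation_source()] or path to the JSON file.
#' @param query_id identifier to look up.
#' @return a `segment_map`.
#' @export
fetch_segment_map <- function(source, query_id) {
  path <- if (inherits(source, "annotation_source")) source$location else source
  if (!file.exists(path)) stop("cannot read segment map source: ", path)
  all_maps <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(all_maps[[query_id]]))
    stop("query '", query_id, "' not present in segment map source ", path)
  segment_map(all_maps[[query_id]])
}
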