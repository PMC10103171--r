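# Readers and writers for the package's standard formats: multi-model
# PDB ensembles, peptide maps, uptake tables and frame-weight tables.
# All tables are plain comma-separated UTF-8 with '.' decimals.

#' Construct and validate a peptide segment map
#'
#' A peptide map lists the proteolytic peptides over which HDX-MS uptake
#' is averaged. Residue numbering is 1-based and ranges are inclusive,
#' following the usual HDX convention ("peptide 31-40" covers residues
#' 31 through 40).
#'
#' @param peptide_id character vector of unique peptide identifiers.
#' @param start,end integer vectors of 1-based inclusive residue bounds.
#' @param sequence one-letter amino-acid strings, one per peptide; the
#'   length of each must equal `end - start + 1`.
#' @return A `data.frame` of class `peptide_map` with columns
#'   `peptide_id`, `start`, `end`, `sequence`.
#' @export
peptide_map <- function(peptide_id, start, end, sequence) {
  peptide_id <- as.character(peptide_id)
  start <- as.integer(start)
  end <- as.integer(end)
  sequence <- toupper(as.character(sequence))
  n <- length(peptide_id)
  if (length(start) != n || length(end) != n || length(sequence) != n)
    stop_hdx("validation", "peptide map columns have unequal lengths")
  if (anyDuplicated(peptide_id))
    stop_hdx("validation", "duplicate peptide_id in peptide map")
  if (any(start < 1L))
    stop_hdx("validation", "peptide start indices must be >= 1")
  if (any(end < start))
    stop_hdx("validation", "peptide end must be >= start")
  if (any(nchar(sequence) != end - start + 1L))
    stop_hdx("validation",
             "peptide sequence length does not match start/end span (%s)",
             paste(peptide_id[nchar(sequence) != end - start + 1L],
                   collapse = ", "))
  bad <- !vapply(strsplit(sequence, ""),
                 function(ch) all(ch %in% AA1), logical(1))
  if (any(bad))
    stop_hdx("validation", "non-canonical residue code in peptide %s",
             paste(peptide_id[bad], collapse = ", "))
  structure(
    data.frame(peptide_id = peptide_id, start = start, end = end,
               sequence = sequence, stringsAsFactors = FALSE),
    class = c("peptide_map", "data.frame")
  )
}

#' @rdname peptide_map
#' @param path file path of a CSV with columns
#'   `peptide_id,start,end,sequence`.
#' @export
read_peptides_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("peptide_id", "start", "end", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_hdx("format", "peptide map is missing column(s): %s",
             paste(miss, collapse = ", "))
  peptide_map(df$peptide_id, df$start, df$end, df$sequence)
}

#' @rdname peptide_map
#' @param peptides a `peptide_map`.
#' @export
write_peptides_csv <- function(peptides, path) {
  utils::write.csv(as.data.frame(peptides), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct and validate an uptake table
#'
#' Holds replicate deuterium-uptake measurements per peptide, state and
#' exposure time. A table is either in daltons (raw) or unitless MaxD-
#' normalized fractions; the `normalized` attribute records which.
#' Normalized values are allowed outside \[0, 1\]: experimental noise can
#' produce negative or >1 fractions, which are preserved here and
#' handled by [filter_peptides()].
#'
#' @param records data.frame with columns `peptide_id`, `state`,
#'   `exposure_s`, `replicate`, `uptake`.
#' @param peptides a [peptide_map()] covering every peptide in `records`.
#' @param normalized logical; `TRUE` for MaxD-normalized fractions.
#' @return data.frame of class `uptake_table` with attributes
#'   `normalized` and `peptides`.
#' @export
uptake_table <- function(records, peptides, normalized = FALSE) {
  need <- c("peptide_id", "state", "exposure_s", "replicate", "uptake")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_hdx("format", "uptake table is missing column(s): %s",
             paste(miss, collapse = ", "))
  records <- records[need]
  records$peptide_id <- as.character(records$peptide_id)
  records$state <- as.character(records$state)
  records$exposure_s <- as.numeric(records$exposure_s)
  records$replicate <- as.integer(records$replicate)
  records$uptake <- as.numeric(records$uptake)
  if (any(!is.finite(records$exposure_s)) || any(records$exposure_s <= 0))
    stop_hdx("validation", "exposure_s must be positive and finite")
  key <- with(records, paste(peptide_id, state, exposure_s, replicate))
  if (anyDuplicated(key))
    stop_hdx("validation",
             "duplicate (peptide, state, exposure, replicate) rows: %s",
             key[duplicated(key)][1])
  unknown <- setdiff(unique(records$peptide_id), peptides$peptide_id)
  if (length(unknown))
    stop_hdx("validation", "peptide(s) absent from peptide map: %s",
             paste(unknown, collapse = ", "))
  structure(records,
            peptides = peptides,
            normalized = isTRUE(normalized),
            class = c("uptake_table", "data.frame"))
}

#' @rdname uptake_table
#' @param x an `uptake_table`.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @rdname uptake_table
#' @export
peptides_of <- function(x) attr(x, "peptides")

#' Read an uptake CSV
#'
#' Expects a header `peptide_id,state,start,end,sequence,exposure_s,
#' replicate,uptake`; an optional leading comment line `# units: Da` or
#' `# units: fraction` records whether the table is raw or
#' MaxD-normalized (default raw Da).
#'
#' @param path CSV file path.
#' @return an [uptake_table()]; the implied [peptide_map()] is attached
#'   as the `peptides` attribute.
#' @export
read_uptake_csv <- function(path) {
  first <- readLines(path, n = 1L)
  normalized <- FALSE
  if (startsWith(first, "#")) {
    if (grepl("units:\\s*fraction", first)) normalized <- TRUE
    else if (!grepl("units:\\s*Da", first))
      stop_hdx("format", "unrecognized metadata line: %s", first)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("peptide_id", "state", "start", "end", "sequence",
            "exposure_s", "replicate", "uptake")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_hdx("format", "uptake CSV is missing column(s): %s",
             paste(miss, collapse = ", "))
  pep_rows <- !duplicated(df$peptide_id)
  peptides <- peptide_map(df$peptide_id[pep_rows], df$start[pep_rows],
                          df$end[pep_rows], df$sequence[pep_rows])
  # every row must agree with its peptide's map entry
  m <- match(df$peptide_id, peptides$peptide_id)
  if (any(df$start != peptides$start[m] | df$end != peptides$end[m] |
          toupper(df$sequence) != peptides$sequence[m]))
    stop_hdx("validation", "inconsistent start/end/sequence for a peptide_id")
  uptake_table(df, peptides, normalized = normalized)
}

#' Write an uptake table as CSV
#'
#' Emits the same layout [read_uptake_csv()] expects, including the
#' `# units:` metadata line, at full double precision so that
#' `read_uptake_csv(write_uptake_csv(x)) == x`.
#'
#' @param table an [uptake_table()].
#' @param path output file path.
#' @export
write_uptake_csv <- function(table, path) {
  peptides <- peptides_of(table)
  m <- match(table$peptide_id, peptides$peptide_id)
  out <- data.frame(
    peptide_id = table$peptide_id,
    state = table$state,
    start = peptides$start[m],
    end = peptides$end[m],
    sequence = peptides$sequence[m],
    exposure_s = format_full(table$exposure_s),
    replicate = table$replicate,
    uptake = format_full(table$uptake),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s",
                     if (is_normalized(table)) "fraction" else "Da"), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------
# Multi-model PDB ensembles

#' Read a structural ensemble from a multi-model PDB file
#'
#' Each `MODEL`/`ENDMDL` block becomes one ensemble frame; a file with
#' no `MODEL` records is a single frame. Residue numbering is taken from
#' the PDB residue sequence numbers. HETATM records and alternate
#' locations other than ' '/'A' are dropped with a warning; insertion
#' codes are rejected. Initial frame weights are uniform.
#'
#' @param path PDB file path.
#' @param state_label conformational state label attached to every frame
#'   (e.g. `"OF"` or `"IF"`).
#' @return an [hdx_ensemble()] carrying per-frame atomic coordinates.
#' @export
read_ensemble_pdb <- function(path, state_label) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ")
  is_het <- startsWith(lines, "HETATM")
  atom_idx <- which(is_atom)
  if (!length(atom_idx))
    stop_hdx("parse", "no ATOM records in %s", path)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop_hdx("parse", "malformed ATOM record at line %d (truncated)", i)
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop_hdx("parse", "malformed ATOM record at line %d (bad coordinates)", i)
    if (substr(ln, 27, 27) != " ")
      stop_hdx("parse", "insertion code at line %d is not supported", i)
  }
  if (any(is_het))
    warning(sprintf("dropping %d HETATM record(s)", sum(is_het)))

  model_starts <- which(startsWith(lines, "MODEL"))
  alt <- substr(lines[atom_idx], 17, 17)
  if (any(!alt %in% c(" ", "A")))
    warning("dropping alternate-location atoms other than altloc 'A'")

  parse_atoms <- function(idx) {
    ln <- lines[idx]
    alt <- substr(ln, 17, 17)
    keep <- alt %in% c(" ", "A")
    ln <- ln[keep]
    elety <- trimws(substr(ln, 13, 16))
    resid <- trimws(substr(ln, 18, 20))
    resno <- as.integer(trimws(substr(ln, 23, 26)))
    elesy <- trimws(substr(ln, 77, 78))
    noel <- elesy == ""
    if (any(noel)) { # derive element from atom name (strip leading digits)
      nm <- sub("^[0-9]*", "", elety[noel])
      elesy[noel] <- substr(nm, 1, 1)
    }
    data.frame(
      elety = elety, resno = resno, resid = resid, element = elesy,
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      stringsAsFactors = FALSE
    )
  }

  if (length(model_starts)) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop_hdx("structural", "unbalanced MODEL/ENDMDL records")
    frames <- lapply(seq_along(model_starts), function(k) {
      idx <- atom_idx[atom_idx > model_starts[k] & atom_idx < model_ends[k]]
      parse_atoms(idx)
    })
  } else {
    frames <- list(parse_atoms(atom_idx))
  }

  sig <- vapply(frames, function(f) paste(f$elety, f$resno, collapse = "|"),
                character(1))
  if (length(unique(vapply(frames, nrow, integer(1)))) != 1L ||
      length(unique(sig)) != 1L)
    stop_hdx("structural",
             "models differ in atom content; all MODELs must share one topology")

  # cross-check frame count against bio3d's multi-model reader
  nref <- tryCatch({
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nrow(pdb$xyz)
  }, error = function(e) length(frames))
  if (!is.null(nref) && nref != length(frames) && length(model_starts) > 0)
    warning("bio3d model count differs from MODEL/ENDMDL block count")

  hdx_ensemble(
    frame_id = sprintf("%s_%04d", state_label, seq_along(frames)),
    state = rep(state_label, length(frames)),
    coords = frames
  )
}

#' Structural ensemble container
#'
#' An ensemble is an ordered set of frames, each with a state label and
#' either atomic coordinates (from [read_ensemble_pdb()]) or precomputed
#' per-residue features (from [make_feature_ensemble()]). Initial frame
#' weights are non-negative and sum to 1; they default to uniform.
#'
#' @param frame_id character vector of unique, stable frame identifiers.
#' @param state per-frame state label.
#' @param coords optional list of per-frame atom data.frames with
#'   columns `elety,resno,resid,element,x,y,z`.
#' @param features optional precomputed feature table with columns
#'   `frame_id,residue,N_C,N_H`.
#' @param weights optional initial weights; default uniform.
#' @export
hdx_ensemble <- function(frame_id, state, coords = NULL, features = NULL,
                         weights = NULL) {
  frame_id <- as.character(frame_id)
  n <- length(frame_id)
  if (anyDuplicated(frame_id))
    stop_hdx("validation", "frame_id values must be unique")
  if (length(state) != n)
    stop_hdx("validation", "one state label per frame is required")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0))
    stop_hdx("validation", "weights must be non-negative, one per frame")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_hdx("validation", "initial weights must sum to 1 (within 1e-9)")
  if (!is.null(coords)) {
    if (length(coords) != n)
      stop_hdx("validation", "coords must hold one atom table per frame")
    resnos <- lapply(coords, function(f) sort(unique(f$resno)))
    if (length(unique(vapply(resnos, paste, character(1), collapse = ","))) != 1L)
      stop_hdx("structural", "frames do not share one residue numbering")
  }
  if (!is.null(features)) {
    need <- c("frame_id", "residue", "N_C", "N_H")
    if (!all(need %in% names(features)))
      stop_hdx("format", "feature table needs columns %s",
               paste(need, collapse = ", "))
    if (!all(unique(features$frame_id) %in% frame_id))
      stop_hdx("validation", "feature table references unknown frames")
  }
  structure(list(frame_id = frame_id, state = as.character(state),
                 weights = weights, coords = coords, features = features),
            class = "hdx_ensemble")
}

#' @export
print.hdx_ensemble <- function(x, ...) {
  cat(sprintf("hdx_ensemble: %d frames (%s); %s\n",
              length(x$frame_id),
              paste(sprintf("%s: %d", names(table(x$state)),
                            as.integer(table(x$state))), collapse = ", "),
              if (!is.null(x$coords)) "atomic coordinates"
              else "precomputed features"))
  invisible(x)
}

#' @export
length.hdx_ensemble <- function(x) length(x$frame_id)

# ---------------------------------------------------------------------
# Frame-weight tables

#' Write / read reweighting frame weights
#'
#' The weight CSV has columns `frame_id,state_label,initial_weight,
#' final_weight`, written at full double precision so that values
#' round-trip bit-exactly.
#'
#' @param result a [reweight()] result (class `hdx_reweight`), or any
#'   list with `frame_id`, `state`, `initial_weights`, `weights`.
#' @param path output CSV path.
#' @export
write_weights <- function(result, path) {
  df <- data.frame(
    frame_id = result$frame_id %||% character(0),
    state_label = result$state %||% character(0),
    initial_weight = format_full(result$initial_weights %||% numeric(0)),
    final_weight = format_full(result$weights %||% numeric(0)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame_id = "character"))
  need <- c("frame_id", "state_label", "initial_weight", "final_weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_hdx("format", "weights CSV is missing column(s): %s",
             paste(miss, collapse = ", "))
  if (nrow(df) && abs(sum(df$final_weight) - 1) > 1e-9)
    stop_hdx("validation", "final weights do not sum to 1 within 1e-9")
  df
}
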