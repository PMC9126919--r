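#' On-disk formats
#'
#' Everything the pipeline exchanges on disk is plain TSV with mandatory
#' headers (times in seconds, 0-based, half-open intervals `[onset,
#' offset)`); NIfTI volumes are supported as an ingestion convenience for
#' parcel time series and as an optional rendering target for parcel maps.
#' Empty fields are the missing-value sentinel in numeric output.
#'
#' @name io-formats
NULL

SEGMENTATION_COLS <- c("segment_id", "scene_id", "onset_s", "offset_s", "annotation")
TRANSCRIPT_COLS <- c(
  "subject_id", "utterance_id", "onset_s", "offset_s", "text",
  "start_segment", "end_segment", "label"
)
NETWORKS <- c(
  "Default", "Frontoparietal", "Visual", "VentAttn",
  "DorsAttn", "SomMot", "Limbic"
)
LABELS <- c("PRECISE", "SUMMARY", "OTHER")

#' Validate a movie segmentation table
#'
#' A segmentation is a tibble of micro-segments (`segment_id`, `scene_id`,
#' `onset_s`, `offset_s`, `annotation`) partitioning the movie timeline:
#' contiguous, non-overlapping, ordered by onset, each micro-segment inside
#' exactly one scene (scene ids form contiguous blocks in time, so the
#' coarse scene boundaries are a subset of the micro-segment boundaries).
#'
#' @param seg Data frame of micro-segments.
#' @param tol Numeric tolerance for contiguity checks (seconds).
#' @return The validated segmentation, sorted by onset, invisibly usable in
#'   a pipe.
#' @export
validate_segmentation <- function(seg, tol = 1e-6) {
  miss <- setdiff(SEGMENTATION_COLS, names(seg))
  if (length(miss) > 0) {
    stop("segmentation is missing column(s): ", paste(miss, collapse = ", "))
  }
  seg <- dplyr::arrange(tibble::as_tibble(seg), .data$onset_s)
  if (anyDuplicated(seg$segment_id)) {
    stop("segmentation: duplicated segment_id ",
         seg$segment_id[duplicated(seg$segment_id)][1])
  }
  bad <- which(seg$offset_s <= seg$onset_s)
  if (length(bad) > 0) {
    stop("segmentation row ", bad[1], " (segment ", seg$segment_id[bad[1]],
         "): offset_s must exceed onset_s")
  }
  if (nrow(seg) > 1) {
    gap <- seg$onset_s[-1] - seg$offset_s[-nrow(seg)]
    bad <- which(abs(gap) > tol)
    if (length(bad) > 0) {
      i <- bad[1] + 1L
      what <- if (gap[bad[1]] < 0) "overlaps" else "leaves a gap after"
      stop("segmentation row ", i, " (segment ", seg$segment_id[i], "): ",
           what, " segment ", seg$segment_id[i - 1L])
    }
    # a scene must be one contiguous block of micro-segments
    runs <- rle(seg$scene_id)$values
    if (anyDuplicated(runs)) {
      dup <- runs[duplicated(runs)][1]
      i <- which(seg$scene_id == dup)
      stop("segmentation row ", max(i), " (segment ", seg$segment_id[max(i)],
           "): scene ", dup, " is split by another scene ",
           "(micro-segment crosses a scene boundary)")
    }
  }
  seg
}

#' Read / write a movie segmentation TSV
#'
#' @param path Path to a TSV with columns `segment_id`, `scene_id`,
#'   `onset_s`, `offset_s`, `annotation`.
#' @return [read_segmentation()]: a validated segmentation tibble sorted by
#'   onset. [write_segmentation()]: `path`, invisibly.
#' @seealso [validate_segmentation()], [scene_table()]
#' @export
read_segmentation <- function(path) {
  seg <- readr::read_tsv(
    path,
    col_types = readr::cols(
      segment_id = readr::col_integer(),
      scene_id = readr::col_integer(),
      onset_s = readr::col_double(),
      offset_s = readr::col_double(),
      annotation = readr::col_character()
    )
  )
  validate_segmentation(seg)
}

#' @rdname read_segmentation
#' @param seg Segmentation tibble.
#' @export
write_segmentation <- function(seg, path) {
  seg <- validate_segmentation(seg)
  readr::write_tsv(seg, path)
  invisible(path)
}

#' Coarse scene intervals of a segmentation
#'
#' @param seg Segmentation tibble.
#' @return Tibble with one row per scene: `scene_id`, `onset_s`,
#'   `offset_s`, `duration_s`, `n_segments`.
#' @export
scene_table <- function(seg) {
  seg |>
    dplyr::group_by(.data$scene_id) |>
    dplyr::summarise(
      onset_s = min(.data$onset_s),
      offset_s = max(.data$offset_s),
      duration_s = .data$offset_s - .data$onset_s,
      n_segments = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$onset_s)
}

#' Validate a recall transcript table
#'
#' Utterances are ordered speech chunks with movie-segment spans. `PRECISE`
#' and `SUMMARY` utterances must carry a segment range with
#' `end_segment >= start_segment`; `OTHER` utterances (inaccurate or
#' off-task speech) may have a missing range. Onsets must be non-decreasing
#' and utterance ids unique within subject.
#'
#' @param transcript Data frame of utterances (one or more subjects).
#' @return The validated transcript tibble with uppercase labels.
#' @export
validate_transcript <- function(transcript) {
  miss <- setdiff(TRANSCRIPT_COLS, names(transcript))
  if (length(miss) > 0) {
    stop("transcript is missing column(s): ", paste(miss, collapse = ", "))
  }
  tr <- tibble::as_tibble(transcript)
  tr$label <- toupper(as.character(tr$label))
  bad <- which(!tr$label %in% LABELS)
  if (length(bad) > 0) {
    stop("transcript row ", bad[1], ": unknown label '", tr$label[bad[1]],
         "' (expected PRECISE, SUMMARY or OTHER)")
  }
  bad <- which(tr$offset_s <= tr$onset_s)
  if (length(bad) > 0) {
    stop("transcript row ", bad[1], ": offset_s must exceed onset_s")
  }
  coded <- tr$label != "OTHER"
  bad <- which(coded & (is.na(tr$start_segment) | is.na(tr$end_segment)))
  if (length(bad) > 0) {
    stop("transcript row ", bad[1], " (", tr$label[bad[1]],
         "): segment range is required for non-OTHER utterances")
  }
  has_range <- !is.na(tr$start_segment) & !is.na(tr$end_segment)
  bad <- which(coded & has_range & tr$end_segment < tr$start_segment)
  if (length(bad) > 0) {
    stop("transcript row ", bad[1], ": end_segment < start_segment")
  }
  for (sid in unique(tr$subject_id)) {
    sub <- tr[tr$subject_id == sid, ]
    if (anyDuplicated(sub$utterance_id)) {
      stop("transcript: duplicated utterance_id for subject ", sid)
    }
    if (is.unsorted(sub$onset_s)) {
      stop("transcript: utterance onsets not non-decreasing for subject ", sid)
    }
  }
  tr
}

#' Read / write a recall transcript TSV
#'
#' @param path Path to a TSV with columns `subject_id`, `utterance_id`,
#'   `onset_s`, `offset_s`, `text`, `start_segment`, `end_segment`,
#'   `label`. Labels are parsed case-insensitively; empty segment fields
#'   are allowed only for OTHER utterances.
#' @return [read_transcript()]: validated transcript tibble.
#' @export
read_transcript <- function(path) {
  tr <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      utterance_id = readr::col_integer(),
      onset_s = readr::col_double(),
      offset_s = readr::col_double(),
      text = readr::col_character(),
      start_segment = readr::col_integer(),
      end_segment = readr::col_integer(),
      label = readr::col_character()
    )
  )
  validate_transcript(tr)
}

#' @rdname read_transcript
#' @param transcript Transcript tibble.
#' @export
write_transcript <- function(transcript, path) {
  tr <- validate_transcript(transcript)
  readr::write_tsv(tr, path, na = "")
  invisible(path)
}

#' Read / write a parcellation table
#'
#' A parcellation maps `parcel_id` to one of the seven canonical
#' resting-state networks (Default, Frontoparietal, Visual, VentAttn,
#' DorsAttn, SomMot, Limbic) plus a free-text name.
#'
#' @param path Path to a TSV with columns `parcel_id`, `network`, `name`.
#' @return Validated parcellation tibble.
#' @export
read_parcellation <- function(path) {
  p <- readr::read_tsv(
    path,
    col_types = readr::cols(
      parcel_id = readr::col_integer(),
      network = readr::col_character(),
      name = readr::col_character()
    )
  )
  validate_parcellation(p)
}

#' @rdname read_parcellation
#' @param parcellation Parcellation tibble.
#' @export
write_parcellation <- function(parcellation, path) {
  p <- validate_parcellation(parcellation)
  readr::write_tsv(p, path)
  invisible(path)
}

#' @rdname read_parcellation
#' @export
validate_parcellation <- function(parcellation) {
  miss <- setdiff(c("parcel_id", "network", "name"), names(parcellation))
  if (length(miss) > 0) {
    stop("parcellation is missing column(s): ", paste(miss, collapse = ", "))
  }
  p <- tibble::as_tibble(parcellation)
  if (anyDuplicated(p$parcel_id)) stop("parcellation: duplicated parcel_id")
  bad <- setdiff(unique(p$network), NETWORKS)
  if (length(bad) > 0) {
    stop("parcellation: unknown network '", bad[1], "' (expected one of ",
         paste(NETWORKS, collapse = ", "), ")")
  }
  p
}

#' Parcel-wise time series container
#'
#' One subject, one run (`MOVIE` or `RECALL`): a named list of
#' features-by-TRs matrices, one per parcel, sampled every `tr_s` seconds.
#' All parcels must share the TR count within a run.
#'
#' @param subject_id Subject identifier.
#' @param run `"MOVIE"` or `"RECALL"`.
#' @param tr_s Repetition time in seconds (> 0).
#' @param data Named list (names = parcel ids) of numeric matrices, each
#'   features x TRs.
#' @return An object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(subject_id, run, tr_s, data) {
  run <- toupper(run)
  if (!run %in% c("MOVIE", "RECALL")) stop("run must be MOVIE or RECALL")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be a positive number")
  if (!is.list(data) || is.null(names(data)) || any(names(data) == "")) {
    stop("data must be a named list of parcel matrices")
  }
  ntr <- vapply(data, ncol, integer(1))
  if (length(unique(ntr)) > 1) {
    stop("all parcels must have the same TR count within a run")
  }
  structure(
    list(subject_id = subject_id, run = run, tr_s = tr_s, data = data),
    class = "parcel_timeseries"
  )
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  nf <- vapply(x$data, nrow, integer(1))
  cat("<parcel_timeseries> subject ", x$subject_id, ", run ", x$run,
      ", TR ", x$tr_s, " s\n", sep = "")
  cat("  ", length(x$data), " parcels, ",
      if (length(x$data)) ncol(x$data[[1]]) else 0, " TRs, ",
      "features per parcel: ", paste(range(nf), collapse = "-"), "\n",
      sep = "")
  invisible(x)
}

#' Write / read a parcel time series TSV
#'
#' Wide plain-text exchange format: comment lines carry the metadata
#' (`subject_id`, `run`, `tr_s`), then one row per (parcel, feature) with
#' columns `parcel_id`, `feature`, `t1` ... `tT`.
#'
#' @param ts A [parcel_timeseries()] object.
#' @param path Output path.
#' @return [write_timeseries()]: `path` invisibly; [read_timeseries()]: a
#'   `parcel_timeseries`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  writeLines(c(
    paste0("# subject_id: ", ts$subject_id),
    paste0("# run: ", ts$run),
    paste0("# tr_s: ", format(ts$tr_s, digits = 15))
  ), path)
  tab <- purrr::imap(ts$data, function(m, pid) {
    out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE),
                             .name_repair = ~ paste0("t", seq_along(.x)))
    dplyr::bind_cols(
      tibble::tibble(parcel_id = as.integer(pid), feature = seq_len(nrow(m))),
      out
    )
  }) |> dplyr::bind_rows()
  readr::write_tsv(tab, path, progress = FALSE, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  head_lines <- readLines(path, n = 10)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), meta_lines, value = TRUE)
    if (length(ln) == 0) stop("time series file lacks '# ", key, ":' header")
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  tr_cols <- grep("^t[0-9]+$", names(tab), value = TRUE)
  data <- split(tab, tab$parcel_id) |>
    purrr::map(function(d) {
      d <- dplyr::arrange(d, .data$feature)
      as.matrix(d[tr_cols])
    })
  names(data) <- as.character(sort(unique(tab$parcel_id)))
  data <- purrr::map(data, `dimnames<-`, NULL)
  parcel_timeseries(
    subject_id = get_meta("subject_id"),
    run = get_meta("run"),
    tr_s = as.numeric(get_meta("tr_s")),
    data = data
  )
}

#' Extract parcel time series from a 4-D NIfTI volume
#'
#' Each parcel's feature vector is the ordered set of voxel values whose
#' integer atlas label equals `parcel_id` (array storage order, so
#' repeated reads give identical feature ordering). Atlas label 0 and
#' labels outside the parcellation are ignored.
#'
#' @param data_path Path to a 4-D NIfTI data volume.
#' @param atlas_path Path to a 3-D integer-labelled atlas on the same grid.
#' @param parcellation Parcellation tibble; parcels absent from the atlas
#'   yield a warning and an empty (0-feature) parcel.
#' @param subject_id,run Metadata for the returned object.
#' @param tr_s TR in seconds; if `NULL`, taken from the NIfTI header.
#' @return A [parcel_timeseries()].
#' @export
read_timeseries_nifti <- function(data_path, atlas_path, parcellation,
                                  subject_id, run, tr_s = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_timeseries_nifti() requires the RNifti package")
  }
  vol <- RNifti::readNifti(data_path)
  atlas <- RNifti::readNifti(atlas_path)
  dv <- dim(vol)
  da <- dim(atlas)
  if (length(dv) != 4) stop("data volume must be 4-D, got ", length(dv), "-D")
  pad3 <- function(d) {            # trailing singleton dims may be dropped
    d <- as.integer(d[seq_len(min(3, length(d)))])
    c(d, rep(1L, 3 - length(d)))
  }
  if (!identical(pad3(dv), pad3(da))) {
    stop("atlas grid (", paste(pad3(da), collapse = "x"),
         ") does not match data grid (", paste(pad3(dv), collapse = "x"),
         ")")
  }
  if (is.null(tr_s)) {
    tr_s <- RNifti::pixdim(vol)[4]
    if (!is.finite(tr_s) || tr_s <= 0) {
      stop("TR not present in NIfTI header; pass tr_s explicitly")
    }
  }
  n_tr <- dv[4]
  flat <- matrix(as.numeric(vol), nrow = prod(dv[1:3]), ncol = n_tr)
  labels <- as.integer(round(as.numeric(atlas)))
  p <- validate_parcellation(parcellation)
  data <- purrr::map(p$parcel_id, function(pid) {
    idx <- which(labels == pid)
    if (length(idx) == 0) {
      warning("parcel ", pid, " absent from atlas; returning empty parcel")
      return(matrix(numeric(0), nrow = 0, ncol = n_tr))
    }
    flat[idx, , drop = FALSE]
  })
  names(data) <- as.character(p$parcel_id)
  parcel_timeseries(subject_id, run, tr_s, data)
}

#' Write / read a parcel-wise scalar map
#'
#' Emits a TSV (`parcel_id`, `network`, `value`) in parcellation order and,
#' when an atlas volume is supplied, a NIfTI volume with every voxel set to
#' its parcel's value (non-parcel voxels get `missing`).
#'
#' @param values Named numeric vector (names = parcel ids) or a data frame
#'   with columns `parcel_id`, `value`. Every parcel must exist in the
#'   parcellation.
#' @param parcellation Parcellation tibble.
#' @param path Output TSV path.
#' @param atlas_path Optional path to a 3-D integer atlas NIfTI.
#' @param nifti_path Output NIfTI path (required with `atlas_path`).
#' @param missing Fill value for voxels outside the mapped parcels.
#' @return `path`, invisibly.
#' @export
write_parcel_map <- function(values, parcellation, path,
                             atlas_path = NULL, nifti_path = NULL,
                             missing = NA_real_) {
  p <- validate_parcellation(parcellation)
  if (is.data.frame(values)) {
    vals <- stats::setNames(values$value, values$parcel_id)
  } else {
    vals <- values
  }
  ids <- as.integer(names(vals))
  unknown <- setdiff(ids, p$parcel_id)
  if (length(unknown) > 0) {
    stop("write_parcel_map(): unknown parcel_id ", unknown[1])
  }
  tab <- p |>
    dplyr::filter(.data$parcel_id %in% ids) |>
    dplyr::mutate(value = unname(vals[as.character(.data$parcel_id)])) |>
    dplyr::select("parcel_id", "network", "value")
  readr::write_tsv(tab, path, na = "")
  if (!is.null(atlas_path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI output requires the RNifti package")
    }
    if (is.null(nifti_path)) stop("nifti_path required when atlas_path given")
    atlas <- RNifti::readNifti(atlas_path)
    labels <- as.integer(round(as.numeric(atlas)))
    out <- rep(missing, length(labels))
    for (i in seq_along(vals)) out[labels == ids[i]] <- vals[i]
    img <- array(out, dim = dim(atlas))
    RNifti::writeNifti(RNifti::asNifti(img, reference = atlas), nifti_path)
  }
  invisible(path)
}

#' @rdname write_parcel_map
#' @export
read_parcel_map <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      parcel_id = readr::col_integer(),
      network = readr::col_character(),
      value = readr::col_double()
    )
  )
}
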