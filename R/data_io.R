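## Reading and validating object-level feature tables and subject outcomes,
## and JSON serialization of fitted models.

#' Construct a validated tubule table
#'
#' A tubule table holds one row per segmented object (e.g., renal tubule) with
#' a subject identifier, an object identifier unique within subject, and q
#' numeric image features. It is the ragged per-subject predictor: subject i
#' contributes p_i rows, and p_i may differ across subjects while q is common.
#'
#' @param df data.frame with columns `subject_id`, `object_id`, and at least
#'   one numeric feature column.
#' @return A `tubule_table` (a validated data.frame) whose feature columns are
#'   all columns except `subject_id` and `object_id`.
#' @export
tubule_table <- function(df) {
  if (!is.data.frame(df)) stop_clusso("tubule table must be a data.frame")
  need <- c("subject_id", "object_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_clusso("tubule table missing column(s): %s", paste(miss, collapse = ", "))
  feat <- setdiff(names(df), need)
  if (!length(feat)) stop_clusso("tubule table has no feature columns")
  for (fc in feat) {
    v <- df[[fc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) & !is.na(v))[1]
      stop_clusso("non-numeric value in feature column '%s' (row %s)", fc,
                  if (is.na(bad)) "?" else bad)
    }
    if (anyNA(v)) {
      stop_clusso("missing feature value in column '%s' (row %d)", fc, which(is.na(v))[1])
    }
  }
  df$subject_id <- as.character(df$subject_id)
  df$object_id <- as.character(df$object_id)
  if (anyDuplicated(df[, need])) {
    stop_clusso("(subject_id, object_id) pairs must be unique")
  }
  ## stable subject ordering: sorted by id, objects kept in file order within subject
  df <- df[order(df$subject_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, feature_names = feat, class = c("tubule_table", "data.frame"))
}

#' Feature names of a tubule table
#' @param x a `tubule_table`.
#' @return Character vector of the q feature column names.
#' @export
feature_names <- function(x) attr(x, "feature_names")

## numeric feature matrix (sum(p_i) x q) of a tubule table
feature_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, feature_names(x), drop = FALSE])
}

#' Construct a validated outcome vector
#'
#' @param df data.frame with columns `subject_id` and numeric scalar outcome `y`.
#' @return A validated data.frame sorted by `subject_id`.
#' @export
outcome_vector <- function(df) {
  if (!is.data.frame(df) || !all(c("subject_id", "y") %in% names(df))) {
    stop_clusso("outcomes must be a data.frame with columns subject_id, y")
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop_clusso("duplicated subject_id in outcomes: %s",
                paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  if (!is.numeric(df$y) || anyNA(df$y)) stop_clusso("outcome y must be numeric with no missing values")
  df <- df[order(df$subject_id), c("subject_id", "y"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load and pair an object-level feature table with subject outcomes
#'
#' Reads the long-format tubule CSV (`subject_id,object_id,<feature...>`) and
#' the outcome CSV (`subject_id,y`), validates both, and pairs them on
#' `subject_id`. Subjects present in only one file are excluded with a warning.
#'
#' @param tubule_path path to the object-level feature CSV.
#' @param outcome_path path to the subject outcome CSV.
#' @return A list with components `tubules` (a [tubule_table()]), `outcomes`
#'   (sorted outcome data.frame), and `excluded` (character vector of subject
#'   ids dropped for lacking a match).
#' @export
load_paired_dataset <- function(tubule_path, outcome_path) {
  if (!file.exists(tubule_path)) stop_clusso("tubule file not found: %s", tubule_path)
  if (!file.exists(outcome_path)) stop_clusso("outcome file not found: %s", outcome_path)
  tub <- tubule_table(read.csv(tubule_path, stringsAsFactors = FALSE, check.names = FALSE))
  out <- outcome_vector(read.csv(outcome_path, stringsAsFactors = FALSE))
  pair_dataset(tub, out)
}

#' Pair an in-memory tubule table with outcomes on subject_id
#' @inheritParams load_paired_dataset
#' @param tubules a [tubule_table()].
#' @param outcomes an [outcome_vector()] data.frame.
#' @return Same structure as [load_paired_dataset()].
#' @export
pair_dataset <- function(tubules, outcomes) {
  tub_ids <- unique(tubules$subject_id)
  out_ids <- outcomes$subject_id
  common <- sort(intersect(tub_ids, out_ids))
  if (!length(common)) stop_clusso("no subjects shared between tubule table and outcomes")
  excluded <- sort(union(setdiff(tub_ids, common), setdiff(out_ids, common)))
  if (length(excluded)) {
    warn_clusso("excluding %d subject(s) missing from one input: %s",
                length(excluded), paste(excluded, collapse = ", "))
  }
  tub <- tubules[tubules$subject_id %in% common, , drop = FALSE]
  rownames(tub) <- NULL
  tub <- structure(tub, feature_names = feature_names(tubules),
                   class = c("tubule_table", "data.frame"))
  out <- outcomes[match(common, outcomes$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  list(tubules = tub, outcomes = out, excluded = excluded)
}

## ---- model archive (JSON) ----------------------------------------------

ARCHIVE_SCHEMA <- 1L

## Recursively prepare an R list for lossless JSON writing: matrices/arrays are
## stored as row-major flattened vectors with explicit dims.
archive_pack <- function(x) {
  if (is.null(x)) {
    NULL
  } else if (is.array(x) || is.matrix(x)) {
    list(.array = as.vector(aperm(x)), .dim = dim(x))
  } else if (is.data.frame(x)) {
    list(.df = lapply(as.list(x), archive_pack))
  } else if (is.list(x)) {
    lapply(x, archive_pack)
  } else if (is.atomic(x) && length(x) == 0L) {
    list(.empty = class(x)[1])
  } else x
}

archive_unpack <- function(x) {
  if (is.list(x) && !is.null(x$.array)) {
    aperm(array(unlist(x$.array), dim = rev(unlist(x$.dim))))
  } else if (is.list(x) && !is.null(x$.df)) {
    as.data.frame(lapply(x$.df, archive_unpack), stringsAsFactors = FALSE)
  } else if (is.list(x) && !is.null(x$.empty)) {
    vector(x$.empty, 0L)
  } else if (is.list(x)) {
    lapply(x, archive_unpack)
  } else x
}

#' Save a fitted model to a JSON archive
#'
#' All numeric fields round-trip exactly (full-precision decimal encoding);
#' matrices are stored as flattened row-major arrays with explicit shapes.
#'
#' @param model a fitted `clusso` model object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_clusso_model <- function(model, path) {
  if (!inherits(model, "clusso")) stop_clusso("model must be a 'clusso' fit object")
  payload <- list(schema = ARCHIVE_SCHEMA, class = class(model),
                  fields = archive_pack(unclass(model)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), null = "null",
                       na = "null", always_decimal = TRUE)
  invisible(path)
}

#' Load a fitted model from a JSON archive
#' @param path archive path written by [save_clusso_model()].
#' @return The restored `clusso` model object.
#' @export
load_clusso_model <- function(path) {
  if (!file.exists(path)) stop_clusso("model archive not found: %s", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                                          simplifyDataFrame = FALSE),
                      error = function(e) stop_clusso("cannot parse model archive: %s", conditionMessage(e)))
  if (is.null(payload$schema) || payload$schema != ARCHIVE_SCHEMA) {
    stop_clusso("unknown or missing model archive schema version")
  }
  fields <- archive_unpack(payload$fields)
  if (is.null(fields$method) || !fields$method %in% c("clusso", "full_info", "naive")) {
    stop_clusso("model archive has unknown method tag '%s'", fields$method %||% "<missing>")
  }
  structure(fields, class = unlist(payload$class))
}
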