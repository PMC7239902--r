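#' Feature matrix container
#'
#' A `feature_matrix` bundles a samples-by-features numeric matrix with class
#' labels, sample identifiers and per-feature metadata (modality, block,
#' condition, base measure, statistic). It is the common currency passed
#' between extraction, preprocessing, selection and evaluation.
#'
#' @param values numeric matrix, samples in rows, features in columns. Column
#'   names must be the feature identifiers.
#' @param labels factor (or character) of per-sample class labels; analysis
#'   entry points require exactly two classes.
#' @param feature_meta data frame with columns `feature_id`, `modality`,
#'   `block`, `condition`, `measure`, `statistic`, one row per feature, in
#'   column order. If `NULL`, metadata is parsed from the feature identifiers
#'   (see [feature_id()]).
#' @param sample_ids character vector of sample identifiers; defaults to row
#'   names or `s1...sn`.
#'
#' @return An object of class `feature_matrix`: a list with elements
#'   `values`, `labels`, `feature_meta`, `sample_ids`.
#' @export
feature_matrix <- function(values, labels, feature_meta = NULL,
                           sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (is.null(colnames(values))) stop("`values` must have feature ids as column names")
  if (anyDuplicated(colnames(values))) stop("feature identifiers must be unique")
  if (length(labels) != nrow(values)) {
    stop("length(labels) must equal nrow(values)")
  }
  labels <- factor(labels)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  rownames(values) <- sample_ids
  if (is.null(feature_meta)) {
    feature_meta <- parse_feature_ids(colnames(values))
  } else {
    feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
    need <- c("feature_id", "modality", "block", "condition", "measure", "statistic")
    if (!all(need %in% names(feature_meta))) {
      stop("feature_meta must have columns: ", paste(need, collapse = ", "))
    }
    if (!identical(feature_meta$feature_id, colnames(values))) {
      stop("feature_meta$feature_id must match column names and order")
    }
  }
  structure(
    list(values = values, labels = labels, feature_meta = feature_meta,
         sample_ids = sample_ids),
    class = "feature_matrix"
  )
}

#' Build or parse canonical feature identifiers
#'
#' Identifiers have the form
#' `"<modality>.<block>.<condition>.<measure>.<statistic>"`, e.g.
#' `"kinematic.general.elevated.vertical_amplitude.mean"`.
#'
#' @param modality,block,condition,measure,statistic components; vectors are
#'   recycled as usual.
#' @return character vector of identifiers.
#' @export
feature_id <- function(modality, block, condition, measure, statistic) {
  paste(modality, block, condition, measure, statistic, sep = ".")
}

#' @rdname feature_id
#' @param ids character vector of identifiers to parse back into metadata.
#' @export
parse_feature_ids <- function(ids) {
  parts <- strsplit(ids, ".", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) {
    stop("malformed feature id(s): ", paste(head(ids[bad], 3), collapse = ", "))
  }
  m <- do.call(rbind, parts)
  data.frame(
    feature_id = ids, modality = m[, 1], block = m[, 2], condition = m[, 3],
    measure = m[, 4], statistic = m[, 5], stringsAsFactors = FALSE
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples x %d features (%s)\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s: %d", levels(x$labels), tabulate(x$labels)),
          collapse = ", ")
  ))
  mods <- table(x$feature_meta$modality)
  cat("  modalities:", paste(sprintf("%s=%d", names(mods), mods), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix
#'
#' @param x a [feature_matrix()].
#' @param i sample (row) index.
#' @param j feature (column) index: integer, logical, or feature ids.
#' @param ... ignored.
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(j)) j <- match(j, colnames(x$values))
  if (anyNA(j)) stop("unknown feature id in subset")
  feature_matrix(
    x$values[i, j, drop = FALSE],
    x$labels[i],
    x$feature_meta[j, , drop = FALSE],
    x$sample_ids[i]
  )
}

#' Combine feature matrices column-wise (e.g. kinematic + eye)
#'
#' Samples must match by identifier and label.
#' @param ... feature matrices.
#' @return a combined [feature_matrix()].
#' @export
combine_features <- function(...) {
  fms <- list(...)
  base <- fms[[1]]
  for (fm in fms[-1]) {
    if (!identical(fm$sample_ids, base$sample_ids)) {
      stop("sample ids differ between feature matrices")
    }
    if (!identical(as.character(fm$labels), as.character(base$labels))) {
      stop("labels differ between feature matrices")
    }
  }
  feature_matrix(
    do.call(cbind, lapply(fms, `[[`, "values")),
    base$labels,
    do.call(rbind, lapply(fms, `[[`, "feature_meta")),
    base$sample_ids
  )
}

#' Read and write the feature-matrix CSV dialect
#'
#' The file carries a 5-row metadata header (modality, block, condition,
#' measure, statistic) above a conventional header row
#' (`sample_id,group,<feature ids>`) and the data rows.
#'
#' @param fm a [feature_matrix()].
#' @param path file path.
#' @export
write_feature_csv <- function(fm, path) {
  meta <- fm$feature_meta
  con <- file(path, "w")
  on.exit(close(con))
  for (field in c("modality", "block", "condition", "measure", "statistic")) {
    writeLines(paste(c(paste0("#", field), "", meta[[field]]), collapse = ","), con)
  }
  writeLines(paste(c("sample_id", "group", meta$feature_id), collapse = ","), con)
  vals <- fm$values
  for (r in seq_len(nrow(vals))) {
    writeLines(paste(c(fm$sample_ids[r], as.character(fm$labels[r]),
                       format(vals[r, ], digits = 15, trim = TRUE, scientific = FALSE)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not a feature-matrix CSV: too few rows in ", path)
  hdr <- strsplit(lines[1:6], ",", fixed = TRUE)
  fields <- vapply(hdr[1:5], `[[`, "", 1L)
  if (!identical(fields, paste0("#", c("modality", "block", "condition",
                                       "measure", "statistic")))) {
    stop("malformed metadata header in ", path,
         ": expected rows #modality..#statistic, found ",
         paste(fields, collapse = ", "))
  }
  ids <- hdr[[6]][-(1:2)]
  meta <- data.frame(
    feature_id = ids,
    modality = hdr[[1]][-(1:2)], block = hdr[[2]][-(1:2)],
    condition = hdr[[3]][-(1:2)], measure = hdr[[4]][-(1:2)],
    statistic = hdr[[5]][-(1:2)], stringsAsFactors = FALSE
  )
  body <- read.csv(text = lines[-(1:6)], header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(body) != length(ids) + 2) {
    stop("data rows have ", ncol(body), " columns but header names ",
         length(ids) + 2)
  }
  vals <- as.matrix(body[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(body[-(1:2)], is.numeric, TRUE))[1]
    stop("non-numeric values in feature column '", ids[bad], "'")
  }
  colnames(vals) <- ids
  feature_matrix(vals, body[[2]], meta, sample_ids = as.character(body[[1]]))
}
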