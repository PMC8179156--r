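# Feature-table data model: aligned feature x sample intensity matrix
# plus the experimental design.

.TREATMENTS <- c("control", "unlabeled_tracer", "labeled_tracer")
.ION_MODES <- c("positive", "negative")

#' Construct a feature table
#'
#' An aligned untargeted LC-MS data set: one row per detected feature
#' (id, m/z, retention time in minutes, ion mode) and one column per
#' sample, with intensities as area-under-curve. Missing measurements
#' are `NA` and are distinct from zero until [floor_noise()] materializes
#' them at the noise floor.
#'
#' @param features data.frame with columns `id`, `mz` (Da, > 0), `rt`
#'   (minutes, finite, >= 0), `ion_mode` (`"positive"`/`"negative"`).
#' @param design data.frame with columns `sample_id`, `treatment`
#'   (`"control"`, `"unlabeled_tracer"`, `"labeled_tracer"`), `time_h`,
#'   `replicate`, `batch`.
#' @param intensities Numeric matrix, features x samples, non-negative
#'   or `NA`.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(features, design, intensities) {
  need_f <- c("id", "mz", "rt", "ion_mode")
  need_d <- c("sample_id", "treatment", "time_h", "replicate", "batch")
  if (!all(need_f %in% names(features))) {
    stop("features must have columns: ", paste(need_f, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_d %in% names(design))) {
    stop("design must have columns: ", paste(need_d, collapse = ", "),
         call. = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  features$id <- as.character(features$id)
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(features$id)) {
    stop("duplicate feature ids: ",
         paste(unique(features$id[duplicated(features$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  key <- paste(design$treatment, design$time_h, design$replicate)
  if (anyDuplicated(key)) {
    stop("(treatment, time_h, replicate) must be unique in the design",
         call. = FALSE)
  }
  if (!all(features$ion_mode %in% .ION_MODES)) {
    stop("ion_mode must be one of: ", paste(.ION_MODES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(design$treatment %in% .TREATMENTS)) {
    stop("treatment must be one of: ", paste(.TREATMENTS, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(features$mz)) || any(features$mz <= 0)) {
    stop("feature mz must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(features$rt)) || any(features$rt < 0)) {
    stop("feature rt must be finite and >= 0", call. = FALSE)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(design)) {
    stop("intensity matrix dimensions (", nrow(intensities), " x ",
         ncol(intensities), ") do not match ", nrow(features),
         " features x ", nrow(design), " samples", call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  rownames(intensities) <- features$id
  colnames(intensities) <- design$sample_id
  structure(
    list(features = features, design = design, intensities = intensities,
         floored = FALSE, normalized = FALSE, noise_floor = NA_real_,
         raw_intensities = NULL, is_info = NULL),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  nm <- table(factor(x$features$ion_mode, levels = .ION_MODES))
  cat("feature_table:", nrow(x$features), "features (",
      nm[["positive"]], "positive /", nm[["negative"]], "negative ) x",
      nrow(x$design), "samples\n")
  cat("  treatments:", paste(sort(unique(x$design$treatment)), collapse = ", "),
      "| time points (h):", paste(sort(unique(x$design$time_h)), collapse = ", "),
      "\n")
  cat("  floored:", x$floored,
      if (x$floored) paste0("(floor ", x$noise_floor, ")") else "",
      "| normalized:", x$normalized, "\n")
  invisible(x)
}

.read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    quote = "\"", comment.char = "")
}

#' Read a feature table from matrix and design files
#'
#' The matrix file carries the feature metadata columns followed by one
#' intensity column per sample; the design file describes each sample.
#' Empty cells are read as missing (`NA`), distinct from zero. Because
#' deposited matrices vary in their column headers, `col_map` renames
#' file columns onto the standard `id`/`mz`/`rt`/`ion_mode` names.
#'
#' @param matrix_path CSV/TSV file: columns `id`, `mz`, `rt`, `ion_mode`
#'   (after `col_map`), then one column per sample id.
#' @param design_path CSV/TSV file: columns `sample_id`, `treatment`,
#'   `time_h`, `replicate`, `batch`.
#' @param col_map Named character vector mapping standard names to the
#'   file's column names, e.g. `c(id = "peak", mz = "m.z")`.
#' @param sep Field separator; default inferred from the file extension
#'   (`.tsv`/`.txt` = tab, else comma).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(matrix_path, design_path,
                               col_map = c(id = "id", mz = "mz", rt = "rt",
                                           ion_mode = "ion_mode"),
                               sep = NULL) {
  mat <- .read_delim_auto(matrix_path, sep)
  design <- .read_delim_auto(design_path, sep)
  std <- c("id", "mz", "rt", "ion_mode")
  col_map <- col_map[std]
  missing_cols <- col_map[!col_map %in% names(mat)]
  if (length(missing_cols) > 0) {
    stop("matrix file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta_idx <- match(col_map, names(mat))
  features <- mat[, meta_idx, drop = FALSE]
  names(features) <- std
  sample_cols <- setdiff(names(mat)[-meta_idx], character(0))
  sample_cols <- names(mat)[-meta_idx]
  unknown <- setdiff(sample_cols, design$sample_id)
  if (length(unknown) > 0) {
    stop("sample column(s) in matrix absent from design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  inten <- mat[, sample_cols, drop = FALSE]
  for (j in seq_along(inten)) {
    col <- inten[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop("non-numeric intensity in column '", sample_cols[j],
             "', row ", bad[1], " (feature '", features$id[bad[1]], "')",
             call. = FALSE)
      }
      inten[[j]] <- num
    }
  }
  design <- design[match(sample_cols, design$sample_id), , drop = FALSE]
  feature_table(features, design, as.matrix(inten))
}

#' Write a feature table to matrix and design files
#'
#' Emits the same CSV dialect [read_feature_table()] consumes; missing
#' intensities are written as empty cells, so a write/read round trip
#' reproduces the table.
#'
#' @param table A `feature_table`.
#' @param matrix_path,design_path Output CSV paths.
#' @export
write_feature_table <- function(table, matrix_path, design_path) {
  stopifnot(inherits(table, "feature_table"))
  out <- cbind(table$features,
               as.data.frame(table$intensities, check.names = FALSE))
  # full double precision so a write/read round trip is bit-stable
  for (j in which(vapply(out, is.double, logical(1)))) {
    v <- sprintf("%.17g", out[[j]])
    v[is.na(out[[j]])] <- NA_character_
    out[[j]] <- v
  }
  utils::write.csv(out, matrix_path, row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(table$design, design_path, row.names = FALSE, na = "")
  invisible(NULL)
}

# Group key "treatment@timeh" for each design row.
.group_keys <- function(design) paste0(design$treatment, "@", design$time_h, "h")

#' Per-feature group means over the experimental design
#'
#' Arithmetic mean intensity of each feature within each
#' (treatment, time point) group, averaging over replicates.
#'
#' @param table A `feature_table`.
#' @param matrix Optional intensity matrix to average instead of
#'   `table$intensities` (used internally to evaluate thresholds on
#'   pre-normalization values).
#' @return Numeric matrix features x groups; the attribute `"groups"`
#'   is a data.frame with the `key`, `treatment` and `time_h` of each
#'   column.
#' @export
group_means <- function(table, matrix = NULL) {
  stopifnot(inherits(table, "feature_table"))
  m <- if (is.null(matrix)) table$intensities else matrix
  keys <- .group_keys(table$design)
  groups <- unique(data.frame(key = keys,
                              treatment = table$design$treatment,
                              time_h = table$design$time_h,
                              stringsAsFactors = FALSE))
  groups <- groups[order(match(groups$treatment, .TREATMENTS), groups$time_h), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  gm <- vapply(groups$key, function(k) {
    cols <- which(keys == k)
    if (length(cols) == 0) stop("empty group: ", k, call. = FALSE)
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) gm <- matrix(gm, nrow = 1, dimnames = list(rownames(m), groups$key))
  attr(gm, "groups") <- groups
  gm
}

# Sample ids per treatment, ordered by (time_h, replicate). Errors if the
# (time, replicate) layout differs between treatments, since the
# co-behavior correlation pairs samples positionally across treatments.
.samples_by_treatment <- function(table) {
  d <- table$design
  out <- lapply(.TREATMENTS, function(tr) {
    di <- d[d$treatment == tr, , drop = FALSE]
    di <- di[order(di$time_h, di$replicate), , drop = FALSE]
    di
  })
  names(out) <- .TREATMENTS
  layouts <- lapply(out, function(di) paste(di$time_h, di$replicate))
  if (length(unique(vapply(layouts, paste, "", collapse = ";"))) != 1L) {
    stop("incomplete design: treatments do not share the same ",
         "(time point, replicate) layout", call. = FALSE)
  }
  lapply(out, function(di) di$sample_id)
}
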