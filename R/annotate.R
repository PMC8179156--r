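# Exact-mass annotation of screened records against a compound library.

#' Read a compound library
#'
#' The library is a CSV with columns `name` and `formula` (and
#' optionally `printed_adduct`/`printed_mz` reference values). Formulas
#' are validated and neutral monoisotopic masses computed on load.
#'
#' @param path CSV file path.
#' @return data.frame with `name`, `formula`, `neutral_mass` and any
#'   extra columns from the file.
#' @export
read_compound_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!all(c("name", "formula") %in% names(lib))) {
    stop("compound library must have 'name' and 'formula' columns",
         call. = FALSE)
  }
  lib$neutral_mass <- vapply(lib$formula, monoisotopic_mass, numeric(1),
                             USE.NAMES = FALSE)
  lib
}

#' Bundled compound library
#'
#' A small curated library of the glucosinolate-catabolism
#' intermediates (isothiocyanate-thiol conjugates, raphanusamic acid,
#' glutathione, the amine) plus common glucosinolates, for exact-mass
#' annotation. Entries with a `printed_mz` carry the instrument-measured
#' reference m/z of the stated adduct.
#'
#' @return data.frame (see [read_compound_library()]).
#' @export
compound_library <- function() {
  read_compound_library(system.file("extdata", "compound_library.csv",
                                    package = "tracerscreen",
                                    mustWork = TRUE))
}

# Precursor adduct per ion mode used for annotation.
.precursor_adduct <- c(positive = "[M+H]+", negative = "[M-H]-")

#' Annotate one m/z against a compound library
#'
#' Matches the observed m/z against the theoretical precursor-ion m/z
#' (`[M+H]+` for positive mode, `[M-H]-` for negative) of every library
#' compound, within an absolute Da tolerance.
#'
#' @param mz Observed m/z.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param compounds Compound library data.frame; defaults to the
#'   bundled [compound_library()].
#' @param tol_da Absolute tolerance in Da (default 0.01).
#' @return data.frame of hits sorted by absolute mass error: `name`,
#'   `formula`, `adduct`, `theoretical_mz`, `error_da`.
#' @export
annotate_mz <- function(mz, ion_mode, compounds = compound_library(),
                        tol_da = 0.01) {
  stopifnot(length(mz) == 1L, mz > 0, tol_da > 0,
            ion_mode %in% names(.precursor_adduct))
  adduct <- .precursor_adduct[[ion_mode]]
  theo <- vapply(compounds$formula, function(f) adduct_mz(f, adduct),
                 numeric(1), USE.NAMES = FALSE)
  err <- mz - theo
  hit <- which(abs(err) <= tol_da)
  out <- data.frame(name = compounds$name[hit],
                    formula = compounds$formula[hit],
                    adduct = rep(adduct, length(hit)),
                    theoretical_mz = theo[hit],
                    error_da = err[hit], stringsAsFactors = FALSE)
  out[order(abs(out$error_da)), , drop = FALSE]
}

#' Annotate a table of records
#'
#' Applies [annotate_mz()] to each row of a record table (e.g. the
#' output of [consolidate_records()] or [screen_cobehavior()]).
#'
#' @param records data.frame with an id column, `mz` and `ion_mode`.
#' @param compounds Compound library.
#' @param tol_da Tolerance in Da.
#' @param id_col Name of the id column (default: first of `record_id`,
#'   `feature_id`, `id` present).
#' @return data.frame of hits with the record id prepended; records
#'   without a hit contribute no rows.
#' @export
annotate_records <- function(records, compounds = compound_library(),
                             tol_da = 0.01, id_col = NULL) {
  if (is.null(id_col)) {
    id_col <- intersect(c("record_id", "feature_id", "id"), names(records))[1]
  }
  if (is.na(id_col)) stop("no id column found in records", call. = FALSE)
  hits <- lapply(seq_len(nrow(records)), function(i) {
    h <- annotate_mz(records$mz[i], records$ion_mode[i], compounds, tol_da)
    if (nrow(h) == 0) return(NULL)
    cbind(record_id = records[[id_col]][i], h, stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0) {
    return(data.frame(record_id = character(0), name = character(0),
                      formula = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), error_da = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
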