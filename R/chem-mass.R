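# Monoisotopic mass arithmetic: formulas, adducts, isotope label shifts.

# Monoisotopic atomic masses in Da (CIAAW/AME atomic mass evaluation,
# >= 6 decimal places). "D" is deuterium (2H); "S34" is 34S. Embedded as
# constants so results are identical on every platform.
.ELEMENT_MASSES <- c(
  C   = 12.000000000,
  H   = 1.007825032,
  D   = 2.014101778,
  N   = 14.003074004,
  O   = 15.994914620,
  S   = 31.972071174,
  S34 = 33.967867012,
  P   = 30.973761998
)

# Mass of a proton (Da); relates neutral monoisotopic mass to singly
# protonated/deprotonated ion m/z.
.PROTON_MASS <- 1.007276467

#' Supported element symbols and their monoisotopic masses
#'
#' @return Named numeric vector of monoisotopic atomic masses in Da.
#'   Heavy isotopes used as labels appear under their own symbols:
#'   `D` for deuterium and `S34` for sulfur-34.
#' @export
element_masses <- function() .ELEMENT_MASSES

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas over C, H, N, O, S, P plus the heavy-label
#' symbols `D` (or `[2H]`) and `[34S]`, e.g. `"C16H28N4O7S3"` or
#' `"C5H8D5NOS"`. Repeated symbols are summed.
#'
#' @param formula Formula string, or an already-parsed `molecular_formula`.
#' @return Named integer vector of element counts with class
#'   `molecular_formula`.
#' @examples
#' parse_formula("C10H17N3O6S")
#' @export
parse_formula <- function(formula) {
  if (inherits(formula, "molecular_formula")) return(formula)
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || !nzchar(formula)) {
    stop("empty molecular formula is invalid", call. = FALSE)
  }
  pat <- "(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop("cannot parse molecular formula: '", formula, "'", call. = FALSE)
  }
  sym <- sub(pat, "\\1", tokens, perl = TRUE)
  cnt <- sub(pat, "\\2", tokens, perl = TRUE)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  sym[sym == "[2H]"] <- "D"
  sym[sym == "[34S]"] <- "S34"
  bad <- setdiff(unique(sym), names(.ELEMENT_MASSES))
  if (length(bad) > 0) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (any(counts < 1L)) stop("element counts must be >= 1", call. = FALSE)
  structure(counts, class = "molecular_formula")
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' @param formula Formula string or `molecular_formula`.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(.ELEMENT_MASSES[names(f)] * as.numeric(f))
}

#' Built-in adduct definitions
#'
#' The three singly charged adduct forms used throughout:
#' `[M+H]+`, `[M-H]-` and `[2M+H]+`. Users may extend the table with
#' additional singly charged adducts in the same layout.
#'
#' @return data.frame with columns `name`, `ion_mode`, `multimer`
#'   (number of neutral molecules M in the ion) and `proton_delta`
#'   (signed proton-mass offset in Da).
#' @export
adduct_table <- function() {
  data.frame(
    name = c("[M+H]+", "[M-H]-", "[2M+H]+"),
    ion_mode = c("positive", "negative", "positive"),
    multimer = c(1L, 1L, 2L),
    proton_delta = c(.PROTON_MASS, -.PROTON_MASS, .PROTON_MASS),
    stringsAsFactors = FALSE
  )
}

.lookup_adduct <- function(adduct, adducts = adduct_table()) {
  i <- match(adduct, adducts$name)
  if (is.na(i)) {
    stop("unknown adduct: '", adduct, "'; known: ",
         paste(adducts$name, collapse = ", "), call. = FALSE)
  }
  adducts[i, , drop = FALSE]
}

#' Theoretical m/z of an adduct ion
#'
#' @param formula Formula string or `molecular_formula` of the neutral
#'   molecule.
#' @param adduct Adduct name, one of `adduct_table()$name` (or of a
#'   user-supplied `adducts` table).
#' @param adducts Adduct definition table; defaults to [adduct_table()].
#' @return m/z in Da (singly charged ions only).
#' @examples
#' adduct_mz("C16H28N4O7S3", "[M+H]+")
#' @export
adduct_mz <- function(formula, adduct, adducts = adduct_table()) {
  a <- .lookup_adduct(adduct, adducts)
  a$multimer * monoisotopic_mass(formula) + a$proton_delta
}

#' Neutral monoisotopic mass implied by an observed m/z under an adduct
#'
#' Inverse of [adduct_mz()]: `neutral_mass_from_mz(adduct_mz(f, a), a)`
#' equals `monoisotopic_mass(f)`.
#'
#' @param mz Observed m/z in Da.
#' @param adduct Adduct name.
#' @param adducts Adduct definition table.
#' @return Neutral mass hypothesis in Da.
#' @export
neutral_mass_from_mz <- function(mz, adduct, adducts = adduct_table()) {
  a <- .lookup_adduct(adduct, adducts)
  (mz - a$proton_delta) / a$multimer
}

#' Define an isotope label mass-shift specification
#'
#' Describes the mass shift produced by incorporating `n` heavy atoms of
#' one isotope label. When a `printed_deltas` table is supplied, those
#' shifts are used verbatim (they must agree with `n * per_atom_delta`
#' within 200 ppm); otherwise shifts are computed from the isotope mass
#' table.
#'
#' @param label Label name, e.g. `"2H"` or `"34S"`.
#' @param per_atom_delta Mass shift per heavy atom in Da (> 0).
#' @param allowed_counts Integer vector of label counts the screen
#'   considers.
#' @param printed_deltas Optional named numeric vector mapping count to
#'   shift in Da, overriding computed values.
#' @return Object of class `label_shift_spec`.
#' @export
label_shift_spec <- function(label, per_atom_delta, allowed_counts,
                             printed_deltas = NULL) {
  stopifnot(is.numeric(per_atom_delta), per_atom_delta > 0,
            length(allowed_counts) >= 1, all(allowed_counts >= 1))
  allowed_counts <- sort(unique(as.integer(allowed_counts)))
  if (!is.null(printed_deltas)) {
    if (is.null(names(printed_deltas)) ||
        !all(names(printed_deltas) %in% as.character(allowed_counts))) {
      stop("printed_deltas must be named by allowed counts", call. = FALSE)
    }
    n <- as.integer(names(printed_deltas))
    rel <- abs(printed_deltas - n * per_atom_delta) / (n * per_atom_delta)
    if (any(rel > 200e-6)) {
      stop("printed_deltas deviate from computed shifts by more than 200 ppm",
           call. = FALSE)
    }
  }
  structure(
    list(label = label, per_atom_delta = per_atom_delta,
         allowed_counts = allowed_counts, printed_deltas = printed_deltas),
    class = "label_shift_spec"
  )
}

#' Deuterium (2H) label shift specification
#'
#' By default uses the verbatim shift table 2.0126, 3.0189, 5.0314 and
#' 10.0628 Da for 2, 3, 5 and 10 deuterium atoms. With
#' `printed = FALSE` the shifts are computed from the isotope mass
#' table (`n * (m(2H) - m(1H))`).
#'
#' @param printed Use the tabulated shift values (default) or compute
#'   per-atom products.
#' @return `label_shift_spec` object.
#' @export
deuterium_shift <- function(printed = TRUE) {
  per_atom <- .ELEMENT_MASSES[["D"]] - .ELEMENT_MASSES[["H"]]
  printed_deltas <- if (printed) {
    c("2" = 2.0126, "3" = 3.0189, "5" = 5.0314, "10" = 10.0628)
  }
  label_shift_spec("2H", per_atom, c(2L, 3L, 5L, 10L), printed_deltas)
}

#' Sulfur-34 label shift specification
#'
#' Shifts of approximately +2 and +4 Da for one and two 34S atoms,
#' computed from the isotope mass table.
#'
#' @param allowed_counts Label counts considered (default 1 and 2).
#' @return `label_shift_spec` object.
#' @export
sulfur34_shift <- function(allowed_counts = c(1L, 2L)) {
  per_atom <- .ELEMENT_MASSES[["S34"]] - .ELEMENT_MASSES[["S"]]
  label_shift_spec("34S", per_atom, allowed_counts)
}

#' Mass shift for n heavy-label atoms
#'
#' @param spec `label_shift_spec` object.
#' @param n Number of heavy atoms; must be one of `spec$allowed_counts`.
#' @return Shift in Da.
#' @examples
#' label_delta(deuterium_shift(), 5) # 5.0314
#' @export
label_delta <- function(spec, n) {
  stopifnot(inherits(spec, "label_shift_spec"))
  n <- as.integer(n)
  if (length(n) != 1L || !(n %in% spec$allowed_counts)) {
    stop("label count ", n, " not in allowed counts {",
         paste(spec$allowed_counts, collapse = ", "), "}", call. = FALSE)
  }
  key <- as.character(n)
  if (!is.null(spec$printed_deltas) && key %in% names(spec$printed_deltas)) {
    unname(spec$printed_deltas[[key]])
  } else {
    n * spec$per_atom_delta
  }
}

#' Mass error in parts per million
#'
#' @param observed Observed mass or mass difference in Da.
#' @param expected Expected mass or mass difference in Da.
#' @param reference_mz Reference m/z the tolerance is scaled to (> 0),
#'   typically the query ion's m/z.
#' @return Absolute error in ppm.
#' @export
ppm_error <- function(observed, expected, reference_mz) {
  stopifnot(all(reference_mz > 0))
  1e6 * abs(observed - expected) / reference_mz
}
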