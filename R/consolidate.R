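# Cross-mode / cross-adduct consolidation: merge screened records that
# plausibly represent the same neutral metabolite observed as different
# adduct forms, keeping the most intense representative.

#' Neutral-mass hypotheses for an observed m/z
#'
#' Positive-mode features are interpreted as `[M+H]+` or `[2M+H]+`,
#' negative-mode features as `[M-H]-`; each interpretation implies a
#' neutral monoisotopic mass.
#'
#' @param mz Observed m/z in Da.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param adducts Adduct definition table; defaults to [adduct_table()].
#' @return data.frame with columns `adduct` and `neutral_mass`.
#' @export
neutral_hypotheses <- function(mz, ion_mode, adducts = adduct_table()) {
  stopifnot(length(mz) == 1L, ion_mode %in% .ION_MODES)
  a <- adducts[adducts$ion_mode == ion_mode, , drop = FALSE]
  data.frame(
    adduct = a$name,
    neutral_mass = vapply(a$name, function(nm) neutral_mass_from_mz(mz, nm, adducts),
                          numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Consolidate records into one entry per putative metabolite
#'
#' Builds a graph over the input entries, linking two entries when any
#' of their neutral-mass hypotheses agree within `mass_tol_da` and
#' their retention times agree within `rt_tol_min`; connected
#' components become consolidated records. The representative of each
#' record is its most intense member (ties broken by lower m/z, then
#' lexicographic id). Transitive (connected-component) merging is used
#' because it is the only order-independent reading of "organizing"
#' related records.
#'
#' @param entries data.frame with columns `id`, `mz`, `rt`, `ion_mode`,
#'   `max_intensity` (one row per record; for pairs use the unlabeled
#'   member's m/z).
#' @param mass_tol_da Neutral-mass agreement tolerance in Da.
#' @param rt_tol_min Retention-time agreement tolerance in minutes
#'   (applied across ion modes: both modes come from the same run).
#' @param adducts Adduct definition table.
#' @return data.frame with one row per consolidated record:
#'   `record_id`, `representative_id`, `mz`, `rt`, `ion_mode`,
#'   `max_intensity`, `n_members`, and a list column `members` of
#'   member ids. Ordered by representative m/z within ion mode.
#' @export
consolidate_records <- function(entries, mass_tol_da = 0.01,
                                rt_tol_min = 0.05,
                                adducts = adduct_table()) {
  need <- c("id", "mz", "rt", "ion_mode", "max_intensity")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(mass_tol_da > 0, rt_tol_min > 0)
  n <- nrow(entries)
  empty <- data.frame(record_id = character(0),
                      representative_id = character(0),
                      mz = numeric(0), rt = numeric(0),
                      ion_mode = character(0), max_intensity = numeric(0),
                      n_members = integer(0), stringsAsFactors = FALSE)
  empty$members <- list()
  if (n == 0) return(empty)
  if (anyDuplicated(entries$id)) {
    stop("duplicate entry ids in consolidation input", call. = FALSE)
  }
  # hypothesis table: one row per (entry, adduct interpretation)
  hyp <- do.call(rbind, lapply(seq_len(n), function(i) {
    h <- neutral_hypotheses(entries$mz[i], entries$ion_mode[i], adducts)
    h$entry <- i
    h
  }))
  # pairwise agreement on neutral mass and RT
  dm <- abs(outer(hyp$neutral_mass, hyp$neutral_mass, "-")) <= mass_tol_da
  same <- outer(hyp$entry, hyp$entry, "==")
  agree_mass <- dm & !same
  drt <- abs(outer(entries$rt, entries$rt, "-")) <= rt_tol_min
  edge_idx <- which(agree_mass, arr.ind = TRUE)
  edges <- unique(cbind(hyp$entry[edge_idx[, 1]], hyp$entry[edge_idx[, 2]]))
  if (nrow(edges) > 0) {
    edges <- edges[drt[edges], , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  recs <- lapply(sort(unique(comp)), function(cid) {
    idx <- which(comp == cid)
    # representative: highest intensity, then lower m/z, then id
    ord <- order(-entries$max_intensity[idx], entries$mz[idx],
                 entries$id[idx])
    idx <- idx[ord]
    rep_i <- idx[1]
    data.frame(representative_id = entries$id[rep_i],
               mz = entries$mz[rep_i], rt = entries$rt[rep_i],
               ion_mode = entries$ion_mode[rep_i],
               max_intensity = entries$max_intensity[rep_i],
               n_members = length(idx),
               members = I(list(entries$id[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(match(out$ion_mode, .ION_MODES), out$mz), , drop = FALSE]
  out <- cbind(record_id = sprintf("R%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consolidate isotopologue pair candidates
#'
#' Reduces the output of [screen_pairs()] to one pair per putative
#' metabolite. Linkage is evaluated on the unlabeled member of each
#' pair; the record's intensity is the larger of the two members'
#' maximal group means. After merging, the labeled members of each
#' merged component are checked for consistent merging under the same
#' rule, with a warning when they do not agree.
#'
#' @param pairs Output of [screen_pairs()].
#' @param mass_tol_da,rt_tol_min Consolidation tolerances.
#' @param adducts Adduct definition table.
#' @return Consolidated record data.frame (see [consolidate_records()])
#'   with an extra `labeled_id` column for the representative pair.
#' @export
consolidate_pairs <- function(pairs, mass_tol_da = 0.01, rt_tol_min = 0.05,
                              adducts = adduct_table()) {
  entries <- data.frame(id = pairs$unlabeled_id, mz = pairs$unlabeled_mz,
                        rt = pairs$rt, ion_mode = pairs$ion_mode,
                        max_intensity = pmax(pairs$unlabeled_max_intensity,
                                             pairs$labeled_max_intensity),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(entries$id)) {
    # one feature may head several candidate pairs (e.g. two label
    # counts); keep the most intense pairing per unlabeled feature and
    # let the graph handle cross-adduct merging
    ord <- order(-entries$max_intensity)
    keep <- !duplicated(entries$id[ord])
    sel <- sort(ord[keep])
    entries <- entries[sel, , drop = FALSE]
    pairs <- pairs[sel, , drop = FALSE]
  }
  out <- consolidate_records(entries, mass_tol_da, rt_tol_min, adducts)
  out$labeled_id <- pairs$labeled_id[match(out$representative_id,
                                           pairs$unlabeled_id)]
  # consistency: within a merged component, the labeled members should
  # merge under the same rule
  for (i in which(out$n_members > 1)) {
    mem <- out$members[[i]]
    sel <- match(mem, pairs$unlabeled_id)
    lab <- data.frame(id = pairs$labeled_id[sel], mz = pairs$labeled_mz[sel],
                      rt = pairs$rt[sel], ion_mode = pairs$ion_mode[sel],
                      max_intensity = pairs$labeled_max_intensity[sel],
                      stringsAsFactors = FALSE)
    lab <- lab[!duplicated(lab$id), , drop = FALSE]
    if (nrow(lab) > 1) {
      sub <- consolidate_records(lab, mass_tol_da, rt_tol_min, adducts)
      if (nrow(sub) > 1) {
        warning("labeled members of consolidated record ",
                out$record_id[i], " do not merge consistently",
                call. = FALSE)
      }
    }
  }
  out
}
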