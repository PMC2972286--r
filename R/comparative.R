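#' Cross-study significance table
#'
#' Aggregates per-study significance calls into one row per item (gene or
#' pathway) with a status per study — `significant`, `not_significant`, or
#' `untested` when the item was absent from that study (e.g. not on the
#' platform, or size-filtered) — plus the count of studies where it was
#' significant. Sorted by that count (descending), then by item name, so
#' the table is invariant to study input order.
#'
#' @param per_study_results named list (one element per study, unique
#'   names) of data.frames: `pathway_result`s (uses `pathway` +
#'   `gfwer_reject`), `gene_score_table`s (uses `gene_id` + `significant`),
#'   or any frame with columns `item_id` and `significant`.
#' @param item_type `"pathway"` or `"gene"`.
#' @return data.frame: `item_id`, one status column per study,
#'   `n_studies_significant`.
#' @export
build_cross_table <- function(per_study_results,
                              item_type = c("pathway", "gene")) {
  item_type <- match.arg(item_type)
  .assert(length(per_study_results) >= 2, "need results from >= 2 studies")
  nms <- names(per_study_results)
  .assert(!is.null(nms) && all(nzchar(nms)), "per_study_results must be named")
  .assert(!anyDuplicated(nms), "duplicate study names")
  id_col <- if (item_type == "pathway") "pathway" else "gene_id"
  sig_col <- if (item_type == "pathway") "gfwer_reject" else "significant"
  std <- lapply(per_study_results, function(df) {
    if (all(c("item_id", "significant") %in% names(df)))
      df[, c("item_id", "significant")]
    else setNames(df[, c(id_col, sig_col)], c("item_id", "significant"))
  })
  items <- sort(unique(unlist(lapply(std, `[[`, "item_id"))))
  status <- sapply(std, function(df) {
    s <- rep("untested", length(items))
    hit <- match(items, df$item_id)
    s[!is.na(hit)] <- ifelse(df$significant[hit[!is.na(hit)]],
                             "significant", "not_significant")
    s
  })
  status <- matrix(status, nrow = length(items),
                   dimnames = list(NULL, nms))
  n_sig <- rowSums(status == "significant")
  out <- data.frame(item_id = items, status, n_studies_significant = n_sig,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(-out$n_studies_significant, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection-pattern counts across study significant sets
#'
#' Counts, for every nonempty subset of studies, the items significant in
#' exactly those studies (the disjoint Venn regions), plus per-study
#' totals. The region sizes sum to the size of the union.
#'
#' @param per_study_significant_sets named list (2-5 studies) of character
#'   vectors of significant item identifiers.
#' @return list with `patterns` (data.frame `pattern`, `n`) and `totals`
#'   (named per-study counts).
#' @export
overlap_counts <- function(per_study_significant_sets) {
  k <- length(per_study_significant_sets)
  .assert(k >= 2 && k <= 5, "expected 2-5 studies")
  nms <- names(per_study_significant_sets)
  .assert(!is.null(nms) && !anyDuplicated(nms), "sets must be uniquely named")
  sets <- lapply(per_study_significant_sets, unique)
  items <- unique(unlist(sets))
  membership <- vapply(sets, function(s) items %in% s,
                       logical(length(items)))
  if (length(items) == 1) membership <- matrix(membership, nrow = 1,
                                               dimnames = list(NULL, nms))
  pat <- apply(membership, 1, function(r) paste(nms[r], collapse = "+"))
  combos <- unlist(lapply(seq_len(k), function(size)
    combn(nms, size, FUN = paste, collapse = "+")))
  n <- vapply(combos, function(cb) sum(pat == cb), numeric(1))
  list(patterns = data.frame(pattern = combos, n = unname(n),
                             stringsAsFactors = FALSE),
       totals = vapply(sets, length, integer(1)))
}
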