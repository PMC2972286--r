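#' Construct an expression study
#'
#' Bundles one study's expression matrix (genes x samples) with the
#' per-sample clinical/survival table, enforcing the alignment invariants
#' every downstream stage assumes: identical sample order in both parts,
#' unique gene identifiers, nonnegative times and 0/1 event indicators.
#'
#' @param study_name study label.
#' @param expression numeric matrix, rows = genes (rownames = gene IDs),
#'   columns = samples (colnames = sample IDs).
#' @param clinical data.frame with columns `sample_id`, `time`, `event` and
#'   optionally `er_status` (`"positive"`/`"negative"`/NA), `tumor_size`,
#'   `grade`, `age`.
#' @param endpoint_name survival endpoint label (e.g. overall survival vs
#'   disease-specific survival).
#' @return object of class `expression_study`.
#' @export
expression_study <- function(study_name, expression, clinical,
                             endpoint_name = "overall survival") {
  .assert(is.matrix(expression) && is.numeric(expression),
          "expression must be a numeric matrix")
  .assert(!is.null(rownames(expression)) && !is.null(colnames(expression)),
          "expression needs gene rownames and sample colnames")
  .assert(!anyDuplicated(rownames(expression)), "duplicate gene identifiers")
  .assert(!anyDuplicated(colnames(expression)), "duplicate sample identifiers")
  .assert(all(c("sample_id", "time", "event") %in% names(clinical)),
          "clinical table needs sample_id, time, event")
  .assert(ncol(expression) == nrow(clinical),
          "expression column count must equal clinical record count")
  .assert(identical(colnames(expression), as.character(clinical$sample_id)),
          "sample order differs between expression and clinical")
  .assert(all(clinical$time >= 0, na.rm = TRUE), "negative survival time")
  .assert(all(clinical$event %in% c(0, 1)), "event must be 0/1")
  structure(list(study_name = study_name, expression = expression,
                 clinical = clinical, endpoint_name = endpoint_name),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study '%s': %d genes x %d samples, %d events (%s)\n",
              x$study_name, nrow(x$expression), ncol(x$expression),
              sum(x$clinical$event), x$endpoint_name))
  invisible(x)
}

#' Construct a pathway database
#'
#' @param pathways named list of character vectors (gene identifiers).
#' @param source_note free-text provenance note.
#' @return object of class `pathway_db`.
#' @export
pathway_db <- function(pathways, source_note = "") {
  .assert(length(pathways) == 0 || !is.null(names(pathways)),
          "pathways must be named")
  .assert(!anyDuplicated(names(pathways)), "duplicate pathway names")
  .assert(all(lengths(pathways) > 0), "empty pathway set")
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  structure(list(pathways = pathways, source_note = source_note),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  sz <- lengths(x$pathways)
  cat(sprintf("pathway_db: %d sets (sizes %s-%s)%s\n", length(sz),
              if (length(sz)) min(sz) else "-", if (length(sz)) max(sz) else "-",
              if (nzchar(x$source_note)) paste0(" [", x$source_note, "]") else ""))
  invisible(x)
}

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Duplicate gene rows (e.g. several probes mapped to one gene)
#' are collapsed by their mean. Ragged rows, duplicate sample IDs and
#' non-numeric data cells are format errors reported with their line number.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames and sample colnames; attribute
#'   `collapsed` lists gene IDs that had duplicate rows.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 2, "expression file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  samples <- header[-1]
  .assert(!anyDuplicated(samples), "duplicate sample IDs in header")
  nfield <- length(header)
  for (i in seq_along(parts)[-1]) {
    if (length(parts[[i]]) != nfield)
      stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                   i, path, length(parts[[i]]), nfield), call. = FALSE)
  }
  genes <- vapply(parts[-1], `[[`, character(1), 1)
  vals <- lapply(seq_along(parts)[-1], function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (anyNA(v) && any(is.na(v) != (parts[[i]][-1] %in% c("NA", "NaN"))))
      stop(sprintf("non-numeric data cell at line %d of %s", i, path),
           call. = FALSE)
    v
  })
  mat <- do.call(rbind, vals)
  rownames(mat) <- genes
  colnames(mat) <- samples
  collapsed <- character(0)
  if (anyDuplicated(genes)) {
    collapsed <- unique(genes[duplicated(genes)])
    mat <- rowsum(mat, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  attr(mat, "collapsed") <- collapsed
  mat
}

#' Write an expression matrix as TSV
#'
#' Full float precision (`%.17g`), so a write/read round trip is the
#' identity.
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  body <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(paste(c("gene_id", colnames(mat)), collapse = "\t"),
               paste(rownames(mat), body, sep = "\t")), path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Required columns: `sample_id`, `time`, `event`; optional: `er_status`,
#' `tumor_size`, `grade`, `age`. ER status strings are normalized
#' (`positive`/`pos`/`1` and `negative`/`neg`/`0`); anything else becomes
#' missing. Negative times and event values outside \{0,1\} are rejected.
#'
#' @param path TSV path.
#' @param endpoint_name endpoint label stored alongside the records.
#' @return data.frame with attribute `endpoint_name`.
#' @export
read_clinical <- function(path, endpoint_name = "overall survival") {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(c("sample_id", "time", "event"), names(df))
  .assert(length(miss) == 0,
          "clinical table missing required column(s): ",
          paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$time <- as.numeric(df$time)
  .assert(all(df$time >= 0, na.rm = TRUE), "negative survival time")
  .assert(all(df$event %in% c(0, 1)), "event outside {0,1}")
  df$event <- as.integer(df$event)
  if ("er_status" %in% names(df)) df$er_status <- normalize_er(df$er_status)
  for (col in intersect(c("tumor_size", "age"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  attr(df, "endpoint_name") <- endpoint_name
  df
}

#' Normalize ER-status strings
#'
#' `positive`/`pos`/`1` map to `"positive"`, `negative`/`neg`/`0` to
#' `"negative"`, anything else to `NA`.
#' @param x character vector.
#' @return character vector of `"positive"`, `"negative"` or `NA`.
#' @export
normalize_er <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("positive", "pos", "1")] <- "positive"
  out[x %in% c("negative", "neg", "0")] <- "negative"
  out
}

#' Write a clinical table as TSV
#' @param clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  num <- vapply(clinical, is.numeric, logical(1))
  out <- clinical
  for (col in names(out)[num]) out[[col]] <- sprintf("%.17g", out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT pathway file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are deduplicated; duplicate set names and
#' lines with fewer than three fields are format errors.
#'
#' @param path GMT file path.
#' @param source_note provenance note stored in the database.
#' @return [pathway_db()] preserving file order.
#' @export
read_gmt <- function(path, source_note = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts))
    if (length(parts[[i]]) < 3)
      stop(sprintf("GMT line %d of %s has fewer than 3 fields", i, path),
           call. = FALSE)
  nms <- vapply(parts, `[[`, character(1), 1)
  .assert(!anyDuplicated(nms), "duplicate pathway name in GMT: ",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  pathway_db(sets, source_note = source_note)
}

#' Write a pathway database as GMT
#' @param db [pathway_db()].
#' @param path output path.
#' @param description description field for every line.
#' @export
write_gmt <- function(db, path, description = "na") {
  writeLines(vapply(names(db$pathways), function(nm) {
    paste(c(nm, description, db$pathways[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Align expression, clinical records and pathways into one study
#'
#' Restricts to samples present in both tables (kept in clinical order) and
#' intersects every pathway with the study's gene universe. Dropped samples
#' and pathway members are counted in the `alignment_log` attribute.
#'
#' @param expression numeric matrix as from [read_expression()].
#' @param clinical data.frame as from [read_clinical()].
#' @param db optional [pathway_db()] to restrict to the study's genes.
#' @param study_name study label.
#' @param endpoint_name endpoint label.
#' @return list with `study` (an [expression_study()]) and `db` (restricted
#'   pathway database, or NULL).
#' @export
align_study <- function(expression, clinical, db = NULL,
                        study_name = "study",
                        endpoint_name = attr(clinical, "endpoint_name") %||%
                          "overall survival") {
  shared <- intersect(clinical$sample_id, colnames(expression))
  .assert(length(shared) > 0, "no samples shared between expression and clinical")
  clin <- clinical[clinical$sample_id %in% shared, , drop = FALSE]
  expr <- expression[, clin$sample_id, drop = FALSE]
  log <- list(samples_dropped_expression = ncol(expression) - ncol(expr),
              samples_dropped_clinical = nrow(clinical) - nrow(clin))
  rdb <- NULL
  if (!is.null(db)) {
    sets <- lapply(db$pathways, intersect, y = rownames(expr))
    log$pathway_members_dropped <- sum(lengths(db$pathways)) - sum(lengths(sets))
    sets <- sets[lengths(sets) > 0]
    rdb <- pathway_db(sets, source_note = db$source_note)
  }
  study <- expression_study(study_name, expr, clin, endpoint_name)
  attr(study, "alignment_log") <- log
  list(study = study, db = rdb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an expression study to a directory
#'
#' Emits `expression.tsv` and `clinical.tsv` in the formats read back by
#' [read_expression()] / [read_clinical()].
#' @param study [expression_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(study$expression, file.path(dir, "expression.tsv"))
  write_clinical(study$clinical, file.path(dir, "clinical.tsv"))
  invisible(dir)
}

#' Read an expression study from a directory written by [write_study()]
#' @param dir directory containing `expression.tsv` and `clinical.tsv`.
#' @param study_name study label (default: directory basename).
#' @param endpoint_name endpoint label.
#' @return [expression_study()].
#' @export
read_study <- function(dir, study_name = basename(dir),
                       endpoint_name = "overall survival") {
  expr <- read_expression(file.path(dir, "expression.tsv"))
  clin <- read_clinical(file.path(dir, "clinical.tsv"), endpoint_name)
  align_study(expr, clin, study_name = study_name,
              endpoint_name = endpoint_name)$study
}
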