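#' Read an expression matrix from TSV
#'
#' Expects a header line of sample ids (an optional leading label for the
#' feature-id column is allowed) and one row per feature, first field the
#' feature id. Malformed files are rejected with an error naming the line.
#' Duplicate feature ids are rejected here: collapsing multiple probes per
#' gene is the preprocessing stage's job and requires an annotation table.
#'
#' @param path Path to a tab-separated file.
#' @param cohort Cohort label attached to the dataset.
#' @param detection_path Optional path to a detection p-value matrix of the
#'   same layout; values must lie in \[0, 1\].
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, cohort = NA_character_,
                                detection_path = NULL) {
  values <- parse_matrix_tsv(path)
  detp <- NULL
  if (!is.null(detection_path)) {
    detp <- parse_matrix_tsv(detection_path)
    if (!identical(dimnames(detp), dimnames(values)))
      tb_stop("detection matrix %s does not match expression matrix layout",
              detection_path)
  }
  expression_dataset(values, detection_p = detp, cohort = cohort)
}

# Strict TSV matrix parser with located errors.
parse_matrix_tsv <- function(path) {
  if (!file.exists(path)) tb_stop("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) tb_stop("%s: need a header and at least one row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  widths <- lengths(body)
  # header may or may not carry a label for the feature-id column
  expected <- widths[1]
  if (length(header) == expected - 1) {
    samples <- header
  } else if (length(header) == expected) {
    samples <- header[-1]
  } else {
    tb_stop("%s: header has %d fields but line 2 has %d", path,
            length(header), expected)
  }
  bad <- which(widths != expected)
  if (length(bad))
    tb_stop("%s: ragged row at line %d (%d fields, expected %d)", path,
            bad[1] + 1L, widths[bad[1]], expected)
  if (anyDuplicated(samples))
    tb_stop("%s: duplicate sample ids in header: %s", path,
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  feats <- vapply(body, `[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(expected - 1)))
  if (expected == 2) vals <- matrix(vals, nrow = 1)
  na_col <- which(colSums(is.na(vals)) > 0)  # vals is samples x rows here
  if (length(na_col))
    tb_stop("%s: non-numeric cell at line %d", path, na_col[1] + 1L)
  m <- t(vals)
  dimnames(m) <- list(feats, samples)
  if (anyDuplicated(feats))
    tb_stop("%s: duplicate feature ids (first: %s); collapse probes via annotation",
            path, feats[duplicated(feats)][1])
  m
}

#' Write an expression matrix (or its detection p-values) to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces them to full double precision.
#'
#' @param ds An `ExpressionDataset`.
#' @param path Output path.
#' @param what `"values"` or `"detection_p"`.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(ds, path, what = c("values", "detection_p")) {
  what <- match.arg(what)
  m <- ds[[what]]
  if (is.null(m)) tb_stop("dataset has no %s matrix", what)
  write_matrix_tsv(m, path)
}

write_matrix_tsv <- function(m, path, id_label = "feature_id") {
  header <- paste(c(id_label, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"), "")
  ok <- tryCatch({
    writeLines(c(header, rows), path); TRUE
  }, error = function(e) FALSE)
  if (!ok) tb_stop("failed to write %s", path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Duplicated members within a line are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets, each a list with `name`,
#'   `description` and a character vector `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) tb_stop("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character()))
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      tb_stop("%s: line %d has %d fields; GMT needs name, description and members",
              path, i, length(f))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("%s: duplicate members in set '%s' deduplicated",
                      path, f[1]), call. = FALSE)
      members <- unique(members)
    }
    list(name = f[1], description = f[2], members = members)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene sets (as returned by [read_gmt()]), or a
#'   named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) s <- list(name = names(sets)[i], description = "", members = s)
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated with a `sample_id` column; used for cohort labels, IHC
#' status, storage times and true subtypes of fixtures.
#'
#' @param path Path to TSV.
#' @return A data.frame keyed by `sample_id`.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) tb_stop("file not found: %s", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(ann))
    tb_stop("%s: annotation needs a 'sample_id' column", path)
  if (anyDuplicated(ann$sample_id))
    tb_stop("%s: duplicate sample ids in annotation", path)
  ann
}

#' Read a probe annotation table
#'
#' Two tab-separated columns, `probe_id` and `symbol`; every probe maps to
#' exactly one symbol (symbols may repeat).
#'
#' @param path Path to TSV.
#' @return Named character vector, probe id -> gene symbol.
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "symbol") %in% names(tab)))
    tb_stop("%s: probe annotation needs columns probe_id, symbol", path)
  if (anyDuplicated(tab$probe_id))
    tb_stop("%s: probes mapping to multiple symbols: %s", path,
            paste(unique(tab$probe_id[duplicated(tab$probe_id)]), collapse = ", "))
  stats::setNames(as.character(tab$symbol), tab$probe_id)
}

#' Read a run configuration (YAML or JSON)
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) tb_stop("file not found: %s", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
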