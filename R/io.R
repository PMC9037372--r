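#' Read a gene-level count matrix from TSV
#'
#' The file must be tab-separated with a header row of sample IDs and the
#' first column named `gene_id`. Lines starting with `#` are ignored. Rows
#' whose gene ID is absent from `annotation` are dropped with a warning, so
#' the returned matrix is always consistent with its annotation table.
#'
#' @param path path to the TSV file.
#' @param annotation gene annotation tibble as returned by
#'   [read_annotation()]; must contain `gene_id`.
#' @param strip_versions if `TRUE`, versioned Ensembl-style IDs
#'   ("ENSG...X.2") are matched to the annotation on the unversioned stem.
#'   Default matches the full versioned string.
#' @return an [exlr_matrix()] with unit `"counts"`.
#' @export
read_counts <- function(path, annotation, strip_versions = FALSE) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "gene_id") {
    abort("first column of a count matrix must be named 'gene_id'.")
  }
  ids <- as.character(df$gene_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate gene_id in counts file: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) abort("count columns must be numeric.")
  rownames(values) <- ids
  ann_ids <- annotation$gene_id
  match_ids <- if (strip_versions) strip_gene_version(ids) else ids
  match_ann <- if (strip_versions) strip_gene_version(ann_ids) else ann_ids
  keep <- match_ids %in% match_ann
  if (!all(keep)) {
    warn(sprintf("%d gene(s) absent from annotation dropped (e.g. %s).",
                 sum(!keep), ids[!keep][1]))
  }
  if (!any(keep)) abort("no genes in common with the annotation.")
  exlr_matrix(values[keep, , drop = FALSE], unit = "counts")
}

strip_gene_version <- function(ids) sub("\\.\\d+$", "", ids)

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, na.strings = "NA",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort(sprintf("no data rows in %s", path))
  df
}

#' Read a gene annotation table from TSV
#'
#' Requires columns `gene_id`, `symbol`, `biotype` and `length_bp`
#' (union-exon length in base pairs). Biotypes outside
#' protein_coding/lncRNA/pseudogene are recoded to `"other"`.
#'
#' @param path path to the TSV file.
#' @return a tibble with one row per gene.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path)
  required <- c("gene_id", "symbol", "biotype", "length_bp")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) abort("duplicate gene_id in annotation.")
  if (any(df$length_bp < 1 | df$length_bp != round(df$length_bp))) {
    abort("length_bp must be a positive integer for every gene.")
  }
  df$biotype <- ifelse(df$biotype %in% BIOTYPE_LEVELS, df$biotype, "other")
  as_tibble(df[required])
}

#' Read a sample metadata (cohort design) table from TSV
#'
#' Requires `sample_id` and `cohort` (CRC / CRA / healthy). Optional columns:
#' `stage` (I-IV), `cea_status` (negative/positive), `os_time`, `os_event`,
#' `dfs_time`, `dfs_event`, `split` (train/validation/independent). Missing
#' optional values are written and read as the literal token `NA`.
#'
#' @param path path to the TSV file.
#' @return a tibble with one row per sample.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path)
  validate_design(as_tibble(df))
}

validate_design <- function(design) {
  if (!all(c("sample_id", "cohort") %in% names(design))) {
    abort("design needs columns 'sample_id' and 'cohort'.")
  }
  if (anyDuplicated(design$sample_id)) abort("duplicate sample_id in design.")
  bad <- setdiff(unique(design$cohort), c("CRC", "CRA", "healthy"))
  if (length(bad)) {
    abort(paste0("unknown cohort label(s): ", paste(bad, collapse = ", ")))
  }
  for (col in c("os", "dfs")) {
    tcol <- paste0(col, "_time"); ecol <- paste0(col, "_event")
    if (ecol %in% names(design)) {
      ev <- design[[ecol]]
      if (!tcol %in% names(design)) abort(sprintf("'%s' requires '%s'.", ecol, tcol))
      if (any(ev %in% c(TRUE, 1) & is.na(design[[tcol]]))) {
        abort(sprintf("%s = TRUE with missing %s.", ecol, tcol))
      }
      if (any(design[[tcol]] < 0, na.rm = TRUE)) {
        abort(sprintf("negative %s.", tcol))
      }
    }
  }
  as_tibble(design)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene IDs. Duplicate members within a set are collapsed.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file.")
  sets <- vector("list", length(lines))
  names_out <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields.", i))
    }
    names_out[i] <- fields[1]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) abort(sprintf("GMT line %d has no members.", i))
    sets[[i]] <- members
  }
  if (anyDuplicated(names_out)) {
    abort(paste0("duplicate set name in GMT: ",
                 names_out[duplicated(names_out)][1]))
  }
  setNames(sets, names_out)
}

#' Write a gene-set list to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Align an expression matrix with a design table
#'
#' Restricts both to the samples present in both, in matrix column order,
#' and reports samples dropped from either side.
#'
#' @param matrix an `exlr_matrix`.
#' @param design a design tibble ([read_design()]).
#' @return a list with elements `matrix`, `design` (row order matching the
#'   matrix columns) and `dropped` (character vector of sample IDs present on
#'   only one side).
#' @export
join_design <- function(matrix, design) {
  design <- validate_design(design)
  common <- intersect(colnames(matrix), design$sample_id)
  if (!length(common)) abort("no samples in common between matrix and design.")
  dropped <- union(setdiff(colnames(matrix), common),
                   setdiff(design$sample_id, common))
  if (length(dropped)) {
    inform(sprintf("join_design: dropped %d sample(s): %s",
                   length(dropped),
                   paste(head(dropped, 5), collapse = ", ")))
  }
  keep <- colnames(matrix)[colnames(matrix) %in% common]
  unit <- if (inherits(matrix, "exlr_matrix")) expr_unit(matrix) else NULL
  sub <- unclass(matrix)[, keep, drop = FALSE]
  attr(sub, "unit") <- NULL
  if (!is.null(unit)) sub <- exlr_matrix(sub, unit = unit)
  list(
    matrix = sub,
    design = design[match(keep, design$sample_id), , drop = FALSE],
    dropped = dropped
  )
}

#' Write an expression matrix (or any result tibble) to TSV
#'
#' @param x an `exlr_matrix` or a data frame.
#' @param path output path.
#' @export
write_tsv_out <- function(x, path) {
  if (inherits(x, "exlr_matrix")) {
    df <- data.frame(gene_id = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read back a TSV expression matrix written by [write_tsv_out()]
#'
#' @param path path to the TSV file.
#' @param unit expression unit the values are in.
#' @return an [exlr_matrix()].
#' @export
read_expression <- function(path, unit = c("tpm", "log2tpm", "counts")) {
  unit <- match.arg(unit)
  df <- read_tsv_checked(path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  exlr_matrix(values, unit = unit)
}
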