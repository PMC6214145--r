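# Expression tables: a tibble whose first column is `gene_id` and whose
# remaining columns are one numeric intensity column per sample (linear
# scale). Sample group labels and detection flags travel as attributes
# ("sample_info", "flags") so the table itself stays pipe-friendly.

#' Build an expression table
#'
#' Constructs and validates the tabular expression container used throughout
#' the package: one row per gene, one numeric column per sample, linear-scale
#' intensities, with group labels attached as the `sample_info` attribute.
#'
#' @param values A matrix or data frame of strictly positive intensities
#'   (genes in rows, samples in columns), or a tibble already carrying a
#'   `gene_id` column.
#' @param gene_ids Character vector of unique gene identifiers (ignored when
#'   `values` already has a `gene_id` column).
#' @param sample_info Optional tibble with columns `sample_id` and `group`.
#' @param flags Optional detection-flag tibble (same genes and samples,
#'   values in `Present`, `Marginal`, `Absent`).
#' @return A tibble of class `cernet_expr`.
#' @export
expression_table <- function(values, gene_ids = NULL, sample_info = NULL,
                             flags = NULL) {
  if (is.matrix(values)) {
    gene_ids <- gene_ids %||% rownames(values) %||%
      (if (nrow(values) == 0) character())
    x <- tibble(gene_id = gene_ids, as_tibble(values, .name_repair = "minimal"))
  } else {
    x <- as_tibble(values)
    if (!"gene_id" %in% names(x)) {
      x <- tibble(gene_id = gene_ids, x)
    }
  }
  x <- new_expr(x, sample_info = sample_info, flags = flags)
  validate_expression(x)
  x
}

new_expr <- function(x, sample_info = NULL, flags = NULL, template = NULL) {
  x <- as_tibble(x)
  class(x) <- unique(c("cernet_expr", class(x)))
  attr(x, "sample_info") <- sample_info %||% attr(template, "sample_info")
  attr(x, "flags") <- flags %||% attr(template, "flags")
  x
}

#' @export
print.cernet_expr <- function(x, ...) {
  si <- attr(x, "sample_info")
  cat(sprintf("# Expression table: %d genes x %d samples\n",
              nrow(x), ncol(x) - 1L))
  if (!is.null(si)) {
    tab <- table(si$group)
    cat("# Groups: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  NextMethod()
}

#' Sample metadata of an expression table
#'
#' @param x An expression table.
#' @return A tibble with columns `sample_id` and `group`, or `NULL`.
#' @export
sample_groups <- function(x) attr(x, "sample_info")

#' @rdname sample_groups
#' @param value A tibble with columns `sample_id` and `group`.
#' @export
`sample_groups<-` <- function(x, value) {
  stopifnot(all(c("sample_id", "group") %in% names(value)))
  attr(x, "sample_info") <- as_tibble(value)
  x
}

#' Detection flags of an expression table
#' @param x An expression table.
#' @return The parallel flag tibble, or `NULL`.
#' @export
detection_flags <- function(x) attr(x, "flags")

# numeric genes-by-samples matrix view (rownames = gene ids)
expr_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- x$gene_id
  m
}

validate_expression <- function(x, arg = "values") {
  if (!"gene_id" %in% names(x) || ncol(x) < 2) {
    abort("an expression table needs a `gene_id` column plus >= 1 sample column")
  }
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(sprintf("duplicate gene ids: %s", paste(head(dup, 5), collapse = ", ")))
  }
  m <- expr_matrix(x)
  if (anyNA(m) || any(!is.finite(m))) {
    abort(sprintf("%s contain missing or non-finite entries", arg))
  }
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("intensities must be strictly positive (gene %s, sample %s)",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  si <- attr(x, "sample_info")
  if (!is.null(si) && !setequal(si$sample_id, colnames(m))) {
    abort("sample_info sample ids do not match the table's sample columns")
  }
  fl <- attr(x, "flags")
  if (!is.null(fl)) {
    if (!identical(dim(fl), dim(x)) ||
        !identical(fl$gene_id, x$gene_id)) {
      abort("flags must parallel the expression table (same genes, same samples)")
    }
    fv <- as.matrix(fl[, -1])
    if (!all(fv %in% c("Present", "Marginal", "Absent"))) {
      abort("flags must be one of Present, Marginal, Absent")
    }
  }
  invisible(x)
}

#' Read an expression table from TSV
#'
#' Reads the tab-separated layout written by [write_expression_table()]: a
#' header row of sample ids, a second header row of group labels (A/B/C, led
#' by the word `group`), then one row per gene. An optional parallel flag
#' file uses the same layout with cells in `Present`/`Marginal`/`Absent`.
#'
#' @param path Path to the expression TSV.
#' @param flags_path Optional path to the parallel detection-flag TSV.
#' @return A `cernet_expr` tibble with `sample_info` (and `flags`) attached.
#' @export
read_expression_table <- function(path, flags_path = NULL) {
  lines <- readLines(path, n = 2L)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  grp <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2 || hdr[1] != "gene_id" || grp[1] != "group" ||
      length(grp) != length(hdr)) {
    abort(sprintf("%s: expected 'gene_id' + sample-id header and a 'group' row", path))
  }
  sample_ids <- hdr[-1]
  raw <- read.table(path, skip = 2L, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) != length(hdr)) {
    abort(sprintf("%s: rows have %d fields, header has %d", path, ncol(raw), length(hdr)))
  }
  names(raw) <- hdr
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("%s: non-numeric value '%s' for gene %s in sample %s",
                    path, raw[i, j + 1L], raw$gene_id[i], sample_ids[j]))
    }
    vals[[j]] <- v
  }
  si <- tibble(sample_id = sample_ids, group = grp[-1])
  flags <- if (!is.null(flags_path)) read_flag_table(flags_path, raw$gene_id, sample_ids)
  x <- new_expr(tibble(gene_id = raw$gene_id, as_tibble(vals)),
                sample_info = si, flags = flags)
  validate_expression(x)
  x
}

read_flag_table <- function(path, gene_ids, sample_ids) {
  lines <- readLines(path, n = 2L)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  raw <- read.table(path, skip = 2L, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  names(raw) <- hdr
  if (!identical(raw$gene_id, gene_ids) || !identical(hdr[-1], sample_ids)) {
    abort(sprintf("%s: flag table does not parallel the expression table", path))
  }
  as_tibble(raw)
}

#' Write an expression table (and optional flags) to TSV
#'
#' @param x A `cernet_expr` tibble.
#' @param path Output TSV path.
#' @param flags_path Optional output path for the detection-flag table.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, flags_path = NULL) {
  validate_expression(x)
  si <- sample_groups(x)
  sample_ids <- names(x)[-1]
  groups <- if (is.null(si)) rep(NA_character_, length(sample_ids)) else {
    si$group[match(sample_ids, si$sample_id)]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", sample_ids), collapse = "\t"), con)
  writeLines(paste(c("group", groups), collapse = "\t"), con)
  body <- cbind(x$gene_id, vapply(x[-1], function(v) sprintf("%.17g", v),
                                  character(nrow(x))))
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fl <- detection_flags(x)
  if (!is.null(flags_path) && !is.null(fl)) {
    fcon <- file(flags_path, "w")
    on.exit(close(fcon), add = TRUE)
    writeLines(paste(c("gene_id", sample_ids), collapse = "\t"), fcon)
    writeLines(paste(c("group", groups), collapse = "\t"), fcon)
    write.table(as.data.frame(fl), fcon, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Quantile normalization
#'
#' Forces every sample to share one empirical intensity distribution: each
#' gene's value becomes the cross-sample mean of the values occupying its
#' within-sample rank. Rank ties receive the average of the tied ranks' row
#' means. After normalization the sorted value vector of every sample is
#' identical, and the operation is idempotent.
#'
#' @param x An expression table (no missing values).
#' @return The normalized expression table.
#' @export
quantile_normalize <- function(x) {
  validate_expression(x)
  m <- expr_matrix(x)
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- new_expr(tibble(gene_id = x$gene_id,
                         as_tibble(qn, .name_repair = "minimal")),
                  template = x)
  out
}

#' Median scaling normalization
#'
#' Scales each sample so that the medians of a high-intensity reference gene
#' set agree across samples. The reference set holds every gene whose
#' intensity is at least `ref_min_intensity` in all samples (default 30, the
#' usual expressed-probe floor for miRNA arrays). Each sample is multiplied
#' by (grand mean of reference medians) / (its own reference median), which
#' keeps values on the original intensity scale and preserves within-sample
#' rank order.
#'
#' @param x An expression table.
#' @param ref_min_intensity Reference-set intensity floor.
#' @return The normalized expression table, with the per-sample scale factors
#'   in the `scale_factors` attribute.
#' @export
median_normalize <- function(x, ref_min_intensity = 30) {
  validate_expression(x)
  m <- expr_matrix(x)
  ref <- rowSums(m >= ref_min_intensity) == ncol(m)
  if (!any(ref)) {
    abort(sprintf("no gene has intensity >= %g in every sample: empty reference set",
                  ref_min_intensity))
  }
  med <- apply(m[ref, , drop = FALSE], 2, median)
  scale <- mean(med) / med
  out_m <- sweep(m, 2, scale, `*`)
  out <- new_expr(tibble(gene_id = x$gene_id,
                         as_tibble(out_m, .name_repair = "minimal")),
                  template = x)
  attr(out, "scale_factors") <- scale
  out
}

#' Detection-call filtering
#'
#' Keeps genes flagged `Present` or `Marginal` in at least
#' `min_flagged_samples` samples; everything else is dropped. The default of
#' 3 follows the common "detected in at least three arrays" rule for a
#' 12-sample three-group design.
#'
#' @param x An expression table with detection flags (attribute or argument).
#' @param min_flagged_samples Minimum number of Present/Marginal calls.
#' @param flags Flag tibble overriding the attached attribute.
#' @return The filtered expression table (flags filtered in step).
#' @export
filter_detected <- function(x, min_flagged_samples = 3, flags = NULL) {
  validate_expression(x)
  fl <- flags %||% detection_flags(x)
  if (is.null(fl)) abort("no detection flags available for filter_detected()")
  fv <- as.matrix(fl[, -1])
  n_ok <- rowSums(fv == "Present" | fv == "Marginal")
  keep <- n_ok >= min_flagged_samples
  new_expr(x[keep, , drop = FALSE],
           sample_info = sample_groups(x),
           flags = as_tibble(fl[keep, , drop = FALSE]))
}
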