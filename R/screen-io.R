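#' Screen library annotation
#'
#' A `screen_library` is a data frame with one row per shRNA and columns
#' `shrna_id` (unique), `barcode` (nucleotide string), `gene`, and `role`
#' (one of `"target"`, `"killing"`, `"ntc"`). Every screen stage joins
#' against it; controls are identified by role, never by name.
#'
#' @param df A data frame with the four required columns.
#' @return A validated `screen_library`.
#' @export
screen_library <- function(df) {
  required <- c("shrna_id", "barcode", "gene", "role")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("library is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$shrna_id <- as.character(df$shrna_id)
  df$barcode <- as.character(df$barcode)
  df$gene <- as.character(df$gene)
  df$role <- as.character(df$role)
  dup <- unique(df$shrna_id[duplicated(df$shrna_id)])
  if (length(dup)) {
    stop("duplicate shrna_id in library: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- !df$role %in% c("target", "killing", "ntc")
  if (any(bad_role)) {
    stop("unknown role in library row(s) ",
         paste(which(bad_role), collapse = ", "), ": ",
         paste(unique(df$role[bad_role]), collapse = ", "), call. = FALSE)
  }
  empty_gene <- df$role == "target" & (is.na(df$gene) | !nzchar(df$gene))
  if (any(empty_gene)) {
    stop("target record(s) with empty gene: row(s) ",
         paste(which(empty_gene), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("screen_library", "data.frame")
  df
}

#' Read / write a screen library as TSV
#'
#' @param path Path to a tab-separated file with columns `shrna_id`,
#'   `barcode`, `gene`, `role`.
#' @return `read_library` returns a [screen_library()]; `write_library`
#'   invisibly returns `path`.
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  screen_library(df)
}

#' @rdname read_library
#' @param lib A [screen_library()].
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "screen_library"))
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Barcode count matrix with sample metadata
#'
#' Bundles a non-negative integer shRNA x sample count matrix with its sample
#' metadata (`sample_id`, `cell_line`, `timepoint` in `{"input", "final"}`,
#' `replicate`). Row names must be library shRNA ids and every column must
#' have a metadata row.
#'
#' @param counts Integer matrix, shRNAs in rows (rownames = shrna ids),
#'   samples in columns.
#' @param meta Data frame of sample metadata.
#' @param library A [screen_library()] used to validate row ids.
#' @return An object of class `screen_counts`: a list with elements `counts`
#'   and `meta`.
#' @export
screen_counts <- function(counts, meta, library = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have shRNA row names and sample column names",
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  meta <- as.data.frame(meta)
  req <- c("sample_id", "cell_line", "timepoint", "replicate")
  missing <- setdiff(req, names(meta))
  if (length(missing)) {
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$replicate <- as.integer(meta$replicate)
  if (!all(meta$timepoint %in% c("input", "final"))) {
    stop("timepoint must be 'input' or 'final'", call. = FALSE)
  }
  key <- interaction(meta$cell_line, meta$timepoint, meta$replicate, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("(cell_line, timepoint, replicate) must be unique", call. = FALSE)
  }
  orphan <- setdiff(colnames(counts), meta$sample_id)
  if (length(orphan)) {
    stop("sample(s) without metadata: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!is.null(library)) {
    unknown <- setdiff(rownames(counts), library$shrna_id)
    if (length(unknown)) {
      stop("count rows absent from library: ",
           paste(utils::head(unknown, 5L), collapse = ", "),
           if (length(unknown) > 5L) ", ...", call. = FALSE)
    }
  }
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero)) {
    message(length(zero), " shRNA(s) with all-zero counts retained")
  }
  structure(list(counts = counts, meta = meta), class = "screen_counts")
}

#' Read barcode counts and sample metadata from TSV
#'
#' @param path Counts TSV: first column `shrna_id`, remaining columns one per
#'   sample.
#' @param meta_path Sample metadata TSV with columns `sample_id`,
#'   `cell_line`, `timepoint`, `replicate`.
#' @param library A [screen_library()] for row-id validation.
#' @return A [screen_counts()] object.
#' @export
read_counts <- function(path, meta_path, library) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "shrna_id") {
    stop("counts file must have 'shrna_id' as its first column", call. = FALSE)
  }
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$shrna_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  screen_counts(counts, meta, library)
}

#' @rdname read_counts
#' @param x A [screen_counts()] object.
#' @export
write_counts <- function(x, path, meta_path) {
  stopifnot(inherits(x, "screen_counts"))
  out <- data.frame(shrna_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write newline-delimited gene lists
#'
#' Signature files hold one gene id per line; blank lines and lines starting
#' with `#` are ignored on read.
#'
#' @param path File path.
#' @return `read_gene_list` returns a character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_gene_list
#' @param genes Character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
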