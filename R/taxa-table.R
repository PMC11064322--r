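RANK_PREFIXES <- c("k", "p", "c", "o", "f", "g", "s")
RANK_NAMES <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

#' Parse a taxonomy string into a rank path
#'
#' Taxonomy strings are semicolon-delimited, ordered kingdom to species.
#' Two dialects are supported: `"greengenes"` strings carry single-letter
#' rank prefixes (`k__Bacteria;p__Firmicutes;...`), `"bare"` strings are
#' plain names (`Bacteria;Firmicutes`). An empty rank (e.g. `s__`)
#' terminates the path; non-empty ranks after an empty one are an error,
#' which keeps every feature's position in the taxonomy unambiguous.
#'
#' @param s a single taxonomy string.
#' @param dialect `"auto"` (default), `"greengenes"` or `"bare"`.
#' @return character vector of rank names; its length is the depth (1-7).
#' @examples
#' parse_taxonomy("k__Bacteria;p__Firmicutes")
#' parse_taxonomy("k__Bacteria;p__;c__")  # truncates to depth 1
#' @export
parse_taxonomy <- function(s, dialect = c("auto", "greengenes", "bare")) {
  dialect <- match.arg(dialect)
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("taxonomy string must be a single non-empty string")
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  if (length(parts) > 7L)
    stop("taxonomy string has more than 7 ranks: ", s)
  if (dialect == "auto")
    dialect <- if (any(grepl("^[kpcofgs]__", parts))) "greengenes" else "bare"
  if (dialect == "greengenes") {
    for (i in seq_along(parts)) {
      pref <- substr(parts[i], 1L, 3L)
      expected <- paste0(RANK_PREFIXES[i], "__")
      if (pref != expected)
        stop("malformed taxonomy prefix at rank ", i, " (", RANK_NAMES[i],
             "): expected '", expected, "' in '", s, "'")
    }
    parts <- sub("^[kpcofgs]__", "", parts)
  }
  empty <- !nzchar(parts)
  if (any(empty)) {
    first_empty <- which(empty)[1L]
    if (any(!empty[first_empty:length(parts)]))
      stop("non-empty rank after an empty rank in '", s,
           "': ambiguous taxonomy")
    parts <- parts[seq_len(first_empty - 1L)]
  }
  if (length(parts) == 0L)
    stop("taxonomy string '", s, "' has no named ranks")
  parts
}

#' Construct a taxa abundance table
#'
#' @param values numeric matrix, samples in rows, taxonomic features in
#'   columns. Row names are sample ids; column names are taxonomy strings.
#' @param value_kind `"raw"` (counts / relative input, non-negative),
#'   `"relative"` or `"log_processed"`.
#' @param dialect taxonomy dialect passed to [parse_taxonomy()].
#' @return an object of class `taxa_table`: the validated matrix with
#'   canonical (bare, semicolon-joined) feature paths as column names and a
#'   `value_kind` attribute.
#' @export
taxa_table <- function(values, value_kind = c("raw", "relative",
                                              "log_processed"),
                       dialect = "auto") {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample ids (rownames) and taxonomy strings ",
         "(colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("abundance values must be finite and non-missing")
  if (value_kind == "raw" && any(values < 0))
    stop("negative abundance in raw table")
  paths <- vapply(colnames(values),
                  function(s) paste(parse_taxonomy(s, dialect),
                                    collapse = ";"),
                  character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(paths))
    stop("duplicate feature path: ",
         paste(unique(paths[duplicated(paths)]), collapse = ", "))
  colnames(values) <- paths
  structure(list(values = values, value_kind = value_kind),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat("Taxa table:", nrow(x$values), "samples x", ncol(x$values),
      "features (", x$value_kind, "values )\n")
  d <- path_depth(colnames(x$values))
  cat("Feature depths:",
      paste(names(table(d)), table(d), sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$values)

path_depth <- function(paths) {
  lengths(strsplit(paths, ";", fixed = TRUE))
}

path_parent <- function(path) {
  parts <- strsplit(path, ";", fixed = TRUE)[[1L]]
  if (length(parts) <= 1L) return(NA_character_)
  paste(parts[-length(parts)], collapse = ";")
}

#' Read a taxa table from CSV/TSV
#'
#' The delimiter is taken from the file extension (`.tsv`/`.txt` tab,
#' otherwise comma) unless `sep` is given. One axis holds sample ids, the
#' other taxonomy strings; `orientation` declares which.
#'
#' @param path file path.
#' @param orientation `"samples_rows"` (default) or `"samples_cols"`.
#' @param sep optional field separator overriding the extension rule.
#' @param dialect taxonomy dialect, see [parse_taxonomy()].
#' @return a [taxa_table()] with `value_kind = "raw"`.
#' @export
read_taxa_table <- function(path, orientation = c("samples_rows",
                                                  "samples_cols"),
                            sep = NULL, dialect = "auto") {
  orientation <- match.arg(orientation)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in taxa table ", path)
  if (orientation == "samples_cols") m <- t(m)
  taxa_table(m, value_kind = "raw", dialect = dialect)
}

#' Write a taxa table as TSV (full float precision)
#'
#' @param table a [taxa_table()].
#' @param path output file.
#' @export
write_taxa_table <- function(table, path) {
  stopifnot(inherits(table, "taxa_table"))
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

guess_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a per-sample label vector
#'
#' @param values vector of labels, named by sample id (or `sample_ids`
#'   given separately). Exactly two distinct values are treated as a binary
#'   label and mapped to 0/1 (lexicographically smaller value is 0 unless
#'   `positive` names the class mapped to 1); anything else is continuous.
#' @param sample_ids optional sample ids when `values` is unnamed.
#' @param positive optional label value to map to 1 (binary only).
#' @return object of class `label_vector`: list with numeric `values`
#'   (named by sample), `kind` (`"binary"`/`"continuous"`) and, for binary
#'   labels, the original `levels` in 0/1 order.
#' @export
label_vector <- function(values, sample_ids = NULL, positive = NULL) {
  if (!is.null(sample_ids)) names(values) <- sample_ids
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("labels must be uniquely named by sample id")
  if (anyNA(values))
    stop("missing label for sample(s): ",
         paste(names(values)[is.na(values)], collapse = ", "))
  ids <- names(values)
  uv <- sort(unique(as.character(values)))
  if (length(uv) < 2L) stop("label has fewer than two distinct values")
  if (length(uv) == 2L) {
    if (!is.null(positive)) {
      if (!positive %in% uv)
        stop("positive class '", positive, "' not found among labels")
      uv <- c(setdiff(uv, positive), positive)
    }
    num <- as.numeric(as.character(values) == uv[2L])
    names(num) <- ids
    out <- list(values = num, kind = "binary", levels = uv)
  } else {
    num <- suppressWarnings(as.numeric(values))
    if (anyNA(num)) stop("non-binary labels must be numeric (continuous)")
    names(num) <- ids
    out <- list(values = num, kind = "continuous", levels = NULL)
  }
  structure(out, class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat("Label vector:", length(x$values), "samples,", x$kind, "\n")
  if (x$kind == "binary")
    cat("  classes:", x$levels[1L], "-> 0 (", sum(x$values == 0), "),",
        x$levels[2L], "-> 1 (", sum(x$values == 1), ")\n")
  invisible(x)
}

#' Read per-sample metadata and extract a label
#'
#' @param path CSV/TSV file with a sample-id column and a label column.
#' @param label_col name of the label column.
#' @param sample_col name of the sample-id column; default first column.
#' @param sep optional separator override (extension rule otherwise).
#' @param positive optional class to map to 1 for binary labels.
#' @return a [label_vector()].
#' @export
read_metadata <- function(path, label_col, sample_col = NULL, sep = NULL,
                          positive = NULL) {
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  sample_col <- sample_col %||% colnames(df)[1L]
  if (!label_col %in% colnames(df))
    stop("label column '", label_col, "' not found in ", path)
  if (!sample_col %in% colnames(df))
    stop("sample column '", sample_col, "' not found in ", path)
  vals <- df[[label_col]]
  if (anyNA(vals))
    stop("missing label in column '", label_col, "' for sample(s): ",
         paste(df[[sample_col]][is.na(vals)], collapse = ", "))
  label_vector(stats::setNames(vals, df[[sample_col]]), positive = positive)
}

#' Join a taxa table and a label vector on shared samples
#'
#' Samples present in only one input are dropped with a warning; the
#' result preserves the taxa table's sample order.
#'
#' @param table a [taxa_table()].
#' @param labels a [label_vector()].
#' @return list with the aligned `table` and `labels`.
#' @export
join_samples <- function(table, labels) {
  stopifnot(inherits(table, "taxa_table"), inherits(labels, "label_vector"))
  shared <- intersect(rownames(table$values), names(labels$values))
  if (length(shared) == 0L) stop("no shared samples between table and labels")
  dropped <- c(setdiff(rownames(table$values), shared),
               setdiff(names(labels$values), shared))
  if (length(dropped) > 0L)
    warning("dropping ", length(dropped),
            " sample(s) absent from one input: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  keep <- rownames(table$values)[rownames(table$values) %in% shared]
  tab <- table
  tab$values <- table$values[keep, , drop = FALSE]
  lab <- labels
  lab$values <- labels$values[keep]
  if (lab$kind == "binary" && length(unique(lab$values)) < 2L)
    stop("binary label has an empty class after the join")
  list(table = tab, labels = lab)
}
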