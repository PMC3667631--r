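# CSV readers/writers for every table dialect the pipeline exchanges.
# Numerics are written with 17 significant digits so read(write(x)) == x
# exactly; metadata (seed, config hash) goes in leading `# key=value`
# comment lines that readers skip but expose.

#' Write a screen table as CSV
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param header optional named list written as `# key=value` comment
#'   lines before the column header (e.g. seed and config hash).
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(df, path, header = NULL) {
  pre <- character(0)
  if (!is.null(header) && length(header) > 0L)
    pre <- sprintf("# %s=%s", names(header),
                   vapply(header, as.character, character(1)))
  cells <- lapply(df, function(col) {
    if (is.double(col)) ifelse(is.na(col), "NA", sprintf("%.17g", col))
    else ifelse(is.na(col), "NA", as.character(col))
  })
  body <- if (nrow(df) > 0L) do.call(paste, c(cells, sep = ",")) else character(0)
  writeLines(c(pre, paste(names(df), collapse = ","), body), path)
  invisible(path)
}

#' Read a screen table from CSV
#'
#' Strict reader for the package's CSV dialects: required columns must be
#' present, every row must have the full field count, and type coercion
#' failures are reported with the offending file line number.
#'
#' @param path CSV file.
#' @param col_types named character vector mapping required column names
#'   to one of `"integer"`, `"numeric"`, `"character"`, `"logical"`.
#' @param allow_extra keep columns beyond `col_types` (as character)?
#' @return data.frame; comment-line metadata in attribute `meta`.
#' @export
read_screen_table <- function(path, col_types, allow_extra = TRUE) {
  raw <- readLines(path)
  is_comment <- grepl("^#", raw)
  meta <- list()
  if (any(is_comment)) {
    kv <- sub("^#\\s*", "", raw[is_comment])
    ok <- grepl("=", kv, fixed = TRUE)
    meta <- stats::setNames(as.list(sub("^[^=]*=", "", kv[ok])),
                            sub("=.*$", "", kv[ok]))
  }
  keep <- which(!is_comment & nzchar(trimws(raw)))
  if (length(keep) < 1L) stop("no header line in ", path, call. = FALSE)
  hdr_line <- keep[1L]
  cols <- strsplit(raw[hdr_line], ",", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(names(col_types), cols)
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data_lines <- keep[-1L]
  n <- length(data_lines)
  parts <- strsplit(raw[data_lines], ",", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad) > 0L)
    stop("malformed row at line ", data_lines[bad[1L]], " of ", path,
         ": expected ", length(cols), " fields, found ",
         lengths(parts)[bad[1L]], call. = FALSE)
  m <- if (n > 0L) matrix(unlist(parts), nrow = n, byrow = TRUE)
       else matrix(character(0), 0L, length(cols))
  out <- list()
  for (j in seq_along(cols)) {
    nm <- cols[j]
    ty <- if (nm %in% names(col_types)) col_types[[nm]]
          else if (allow_extra) "character" else next
    v <- m[, j]
    coerced <- switch(ty,
      integer = suppressWarnings(as.integer(v)),
      numeric = suppressWarnings(as.numeric(v)),
      logical = as.logical(v),
      character = v)
    if (ty != "character") {
      bad <- which(is.na(coerced) & !(v %in% c("NA", "")))
      if (length(bad) > 0L)
        stop("cannot parse field `", nm, "` as ", ty, " at line ",
             data_lines[bad[1L]], " of ", path, " (value: '",
             v[bad[1L]], "')", call. = FALSE)
    }
    if (ty == "character") coerced <- ifelse(v == "NA", NA_character_, v)
    out[[nm]] <- coerced
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  out
}

well_col_types <- c(replicate = "integer", plate = "integer",
                    row = "character", col = "integer",
                    well_type = "character", gene_id = "character",
                    signal = "numeric")

#' Read / write well-record tables
#'
#' The long-format plate dialect: header
#' `replicate,plate,row,col,well_type,gene_id,signal`, rows as letters
#' (A-H on a 96-well plate), columns 1-based. Coordinates outside the
#' stated geometry and unknown well types are validation errors.
#'
#' @param path CSV file.
#' @param n_rows,n_cols plate geometry used for coordinate validation.
#' @return data.frame of well records.
#' @export
read_well_table <- function(path, n_rows = 8L, n_cols = 12L) {
  out <- read_screen_table(path, well_col_types)
  validate_well_table(out, n_rows = n_rows, n_cols = n_cols, where = path)
  out
}

#' @rdname read_well_table
#' @param wells well-record data.frame.
#' @param header optional metadata for comment lines.
#' @export
write_well_table <- function(wells, path, header = NULL) {
  validate_well_table(wells, where = "well table")
  write_screen_table(wells[, names(well_col_types)], path, header = header)
}

validate_well_table <- function(w, n_rows = 8L, n_cols = 12L, where = "table") {
  ok_types <- c("sample", "mock_plusPMA", "mock_minusPMA", "empty")
  bad_type <- which(!(w$well_type %in% ok_types))
  if (length(bad_type) > 0L)
    stop("unknown well_type '", w$well_type[bad_type[1L]], "' in ", where,
         call. = FALSE)
  ri <- row_index(w$row)
  bad <- which(is.na(ri) | ri > n_rows | w$col < 1L | w$col > n_cols)
  if (length(bad) > 0L)
    stop("well coordinate '", w$row[bad[1L]], w$col[bad[1L]],
         "' outside the ", n_rows, "x", n_cols, " geometry in ", where,
         call. = FALSE)
  invisible(w)
}

#' Readers and writers for the remaining pipeline dialects
#'
#' Truth tables (`gene_id,true_class,effect`), b-score tables
#' (`gene_id,replicate,plate,b_score`), rank-product tables, primary and
#' validation hit tables, annotation tables (`gene_id,category`) and
#' expression tables.
#'
#' @param path CSV file.
#' @param x table to write.
#' @param header optional comment-line metadata.
#' @name dialects
NULL

#' @rdname dialects
#' @export
read_truth_table <- function(path) {
  out <- read_screen_table(path, c(gene_id = "character",
                                   true_class = "character",
                                   effect = "numeric"))
  bad <- which(!(out$true_class %in% c("hypo", "hyper", "null")))
  if (length(bad) > 0L)
    stop("unknown true_class '", out$true_class[bad[1L]], "' in ", path,
         call. = FALSE)
  out
}

#' @rdname dialects
#' @export
write_truth_table <- function(x, path, header = NULL)
  write_screen_table(x[, c("gene_id", "true_class", "effect")], path, header)

#' @rdname dialects
#' @export
read_b_table <- function(path)
  read_screen_table(path, c(gene_id = "character", replicate = "integer",
                            plate = "integer", b_score = "numeric"))

#' @rdname dialects
#' @export
write_b_table <- function(x, path, header = NULL)
  write_screen_table(x[, c("gene_id", "replicate", "plate", "b_score")],
                     path, header)

#' @rdname dialects
#' @export
read_rankprod_table <- function(path)
  read_screen_table(path, c(gene_id = "character",
                            rp_down = "numeric", rp_up = "numeric",
                            p_down = "numeric", p_up = "numeric",
                            pfp_down = "numeric", pfp_up = "numeric"))

#' @rdname dialects
#' @export
write_rankprod_table <- function(x, path, header = NULL)
  write_screen_table(x[, c("gene_id", "rp_down", "rp_up", "p_down", "p_up",
                           "pfp_down", "pfp_up")], path, header)

#' @rdname dialects
#' @export
read_annotation_table <- function(path)
  read_screen_table(path, c(gene_id = "character", category = "character"))

#' @rdname dialects
#' @export
read_expression_table <- function(path)
  read_screen_table(path, c(gene_id = "character", condition = "character",
                            replicate = "integer",
                            gene_intensity = "numeric",
                            housekeeping_intensity = "numeric"))

#' @rdname dialects
#' @export
read_intensity_table <- function(path)
  read_screen_table(path, c(sample_id = "character", condition = "character",
                            replicate = "integer",
                            target_signal = "numeric",
                            control_signal = "numeric"))
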