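#' Read a delimited table with schema validation
#'
#' Reads a comma-delimited UTF-8 table with a mandatory header row and "."
#' decimal separator. Lines starting with `#` (provenance headers) are
#' skipped. Missing values may be encoded as empty fields or `"NA"`; they
#' are counted in the `"n_missing"` attribute.
#'
#' @param path file to read.
#' @param schema optional named character vector mapping required column
#'   names to `"numeric"` or `"character"`; missing columns or non-numeric
#'   values in numeric columns raise validation errors naming the file,
#'   column and row.
#' @param key optional character vector of columns whose combination must
#'   be unique (e.g. `c("country", "cohort")`).
#' @return The data frame, with attribute `"n_missing"`.
#' @export
read_table <- function(path, schema = NULL, key = NULL) {
  if (!file.exists(path))
    np_error(sprintf("file not found: %s", path), "validation_error")
  dat <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  na.strings = c("NA", ""), encoding = "UTF-8")
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(dat))
    if (length(miss))
      np_error(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
               "validation_error")
    for (col in names(schema)) {
      if (schema[[col]] == "numeric") {
        raw <- dat[[col]]
        if (!is.numeric(raw)) {
          num <- suppressWarnings(as.numeric(raw))
          bad <- which(!is.na(raw) & is.na(num))
          if (length(bad))
            np_error(sprintf("%s: non-numeric value '%s' in numeric column '%s' (row %d)",
                             path, raw[bad[1]], col, bad[1]), "validation_error")
          dat[[col]] <- num
        }
      } else {
        dat[[col]] <- as.character(dat[[col]])
      }
    }
  }
  if (!is.null(key)) {
    kv <- do.call(paste, c(dat[key], sep = "\r"))
    d <- anyDuplicated(kv)
    if (d)
      np_error(sprintf("%s: duplicated key (%s) at row %d", path,
                       paste(unlist(dat[d, key]), collapse = ", "), d),
               "validation_error")
  }
  attr(dat, "n_missing") <- sum(is.na(dat))
  dat
}

#' Write a delimited table with a provenance header
#'
#' Writes comma-delimited UTF-8 text with a header row; numeric columns
#' are rendered with 17 significant digits so that a write/read round trip
#' reproduces the values exactly. A `#`-prefixed provenance line records
#' the generating seed. Missing values are written as `NA`, never as
#' sentinel numbers.
#'
#' @param x data frame to write.
#' @param path destination file.
#' @param seed optional seed recorded in the provenance header.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, seed = NULL) {
  if (!is.data.frame(x)) np_error("x must be a data frame", "validation_error")
  xx <- as.data.frame(x)
  for (col in names(xx)) {
    if (is.numeric(xx[[col]]) && !is.integer(xx[[col]])) {
      v <- sprintf("%.17g", xx[[col]])
      v[is.na(xx[[col]])] <- NA_character_
      xx[[col]] <- v
    }
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# npheight table%s",
                     if (is.null(seed)) "" else sprintf("; seed: %s", format(seed))),
             con)
  write.table(xx, con, sep = ",", row.names = FALSE, quote = TRUE,
              qmethod = "double", na = "NA")
  invisible(path)
}
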