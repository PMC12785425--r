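#' Read / write an expression table CSV
#'
#' The expression table is a plain data.frame with metadata columns
#' `animal_id`, `sex` (`"M"`/`"F"`), `group` (`"CRS0"` ... `"CRS35"`),
#' followed by one numeric column per marker holding percent-of-control
#' values. Empty CSV cells encode missing values; no sentinel numbers are
#' used. `read_expression_csv` validates labels against the panel and the
#' canonical group set and reports the offending row on failure.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param panel a [marker_panel]; marker columns in the file must be a
#'   subset of the panel (default [default_panel()]).
#' @param table an expression table to write.
#' @return `read_expression_csv` returns the validated data.frame;
#'   `write_expression_csv` returns `path` invisibly. A write-then-read
#'   round trip reproduces the table exactly (values, missingness, order).
#' @export
read_expression_csv <- function(path, panel = default_panel()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(animal_id = "character"),
                         na.strings = "")
  meta <- c("animal_id", "sex", "group")
  if (!all(meta %in% names(tab)))
    stop("expression CSV must have columns ", paste(meta, collapse = ", "))
  extra <- setdiff(names(tab), c(meta, panel$marker))
  if (length(extra))
    stop("unknown marker column(s): ", paste(extra, collapse = ", "))
  validate_expression(tab)
  tab
}

#' @rdname read_expression_csv
#' @export
write_expression_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

## shared row-level checks; 'where' gives CSV-style row numbers (header = 1)
validate_expression <- function(tab) {
  bad <- which(!tab$group %in% crs_groups())
  if (length(bad))
    stop("unknown group label '", tab$group[bad[1]], "' at row ", bad[1] + 1L)
  bad <- which(!tab$sex %in% crs_sexes())
  if (length(bad))
    stop("unknown sex label '", tab$sex[bad[1]], "' at row ", bad[1] + 1L)
  dup <- which(duplicated(tab$animal_id))
  if (length(dup))
    stop("duplicate animal_id '", tab$animal_id[dup[1]], "' at row ",
         dup[1] + 1L)
  invisible(tab)
}

## marker columns of an expression table
marker_columns <- function(table) {
  setdiff(names(table), c("animal_id", "sex", "group"))
}
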