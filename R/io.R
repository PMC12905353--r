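#' Read and write gridded fields as long-format CSV
#'
#' Fields travel as plain long-format tables -- one row per (cell, variable)
#' with the cell's coordinates -- so every stage's inputs and outputs are
#' inspectable with any spreadsheet or data.frame tool. Generation
#' parameters (seed etc.) can be recorded alongside in the run manifest.
#'
#' @param X Matrix/data.frame of fields (columns = variables, rows = cells).
#' @param grid The matching [fire_grid()].
#' @param path CSV path.
#' @return `read_field_csv()` returns a matrix with cells in `cell_id`
#'   order; `write_field_csv()` returns `path` invisibly.
#' @export
write_field_csv <- function(X, grid, path) {
  X <- as.matrix(X)
  long <- data.frame(
    cell_id = rep(grid$cells$cell_id, ncol(X)),
    lon = rep(grid$cells$lon, ncol(X)),
    lat = rep(grid$cells$lat, ncol(X)),
    variable = rep(colnames(X), each = nrow(X)),
    value = as.vector(X)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  long <- utils::read.csv(path)
  vars <- unique(long$variable)
  ids <- sort(unique(long$cell_id))
  out <- sapply(vars, function(v) {
    sub <- long[long$variable == v, ]
    sub$value[match(ids, sub$cell_id)]
  })
  rownames(out) <- ids
  out
}

#' Write a threshold-skill table as CSV
#'
#' Column order mirrors the reference skill table: percentile, threshold,
#' TSS, sensitivity, specificity, maxTSS.
#'
#' @param curve A [tss_curve()] data.frame.
#' @param path CSV path.
#' @export
write_tss_csv <- function(curve, path) {
  cols <- c("percentile", "threshold", "TSS", "sensitivity", "specificity",
            "maxTSS")
  utils::write.csv(curve[, cols], path, row.names = FALSE)
  invisible(path)
}
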