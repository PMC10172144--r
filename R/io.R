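## Plain-text interchange: vertex x frame matrices as TSV with a JSON
## sidecar for run metadata; geometry as JSON; tables as TSV.

#' Read and write BOLD runs, strips and result tables
#'
#' `writeBoldRun()` writes the vertex x frame matrix as TSV (vertex ids in
#' the first column, frame ids in the header) plus a JSON sidecar
#' `<path>.json` holding `tr` and `runType`; `readBoldRun()` reverses it.
#' `writeStrip()`/`readStrip()` serialize a \linkS4class{CorticalStrip} as
#' JSON. `writeResultTable()` writes any result data.frame as TSV.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param path file path (TSV); the sidecar is `<path>.json`.
#' @return `readBoldRun()` a BoldRun; `readStrip()` a CorticalStrip;
#'   writers return the path invisibly.
#' @export
writeBoldRun <- function(run, path) {
  m <- boldMatrix(run)
  df <- data.frame(vertex = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = tr(run), runType = runType(run)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeBoldRun
#' @export
readBoldRun <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .newBoldRun(m, tr = meta$tr, runType = meta$runType)
}

#' @rdname writeBoldRun
#' @param strip a \linkS4class{CorticalStrip}.
#' @export
writeStrip <- function(strip, path) {
  jsonlite::write_json(list(
    coords = unname(as.data.frame(coords(strip))),
    vertex = rownames(coords(strip)),
    axisLine = axisLine(strip),
    regionLabels = as.character(regionLabels(strip)),
    hemisphere = strip@hemisphere), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBoldRun
#' @export
readStrip <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- as.matrix(as.data.frame(j$coords))
  dimnames(cm) <- list(j$vertex, c("x", "y"))
  labs <- j$regionLabels
  new("CorticalStrip", coords = cm, axisLine = as.integer(j$axisLine),
      regionLabels = factor(labs, levels = .allRegions[.allRegions %in%
                                                         unique(labs)]),
      hemisphere = j$hemisphere)
}

#' @rdname writeBoldRun
#' @param table a data.frame.
#' @export
writeResultTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
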