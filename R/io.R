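#' Read a colony-size table
#'
#' Reads the tab-separated colony table dialect shared by all pipeline
#' stages: one row per spot with columns `screen_id`, `experiment_id`,
#' `condition`, `temperature`, `plate_id`, `row`, `col`, `gene`,
#' `replicate`, `size` and optionally `size_normalized`. Lines starting
#' with `#` are comments. Format violations (missing columns, negative
#' sizes, duplicated grid positions) are reported with the offending
#' line numbers.
#'
#' @param path file to read.
#' @param plateRows,plateCols grid dimensions the positions are validated
#'   against.
#' @return a [ColonyScreen-class] object.
#' @seealso [writeColonyTable()]
#' @export
readColonyTable <- function(path, plateRows = 16L, plateCols = 24L) {
  if (!file.exists(path))
    .formatError(paste0("no such file: ", path))
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", quote = "",
                         stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  required <- setdiff(.COLONY_COLS, "size_normalized")
  missing_cols <- setdiff(required, colnames(d))
  if (length(missing_cols))
    .formatError(paste0("missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  # data line numbers for error messages (header is line 1 if no comments)
  n_comment <- 0L
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    n_comment <- n_comment + 1L
  }
  line_no <- seq_len(nrow(d)) + n_comment + 1L
  bad_size <- which(!is.finite(d$size) | d$size < 0)
  if (length(bad_size))
    .formatError(paste0("negative or non-finite size at line(s) ",
                        paste(line_no[bad_size], collapse = ", ")))
  key <- paste(d$experiment_id, d$condition, d$plate_id, d$row, d$col,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    .formatError(paste0("duplicated (plate,row,col) at line(s) ",
                        paste(line_no[dup], collapse = ", ")))
  ColonyScreen(d, plateRows = plateRows, plateCols = plateCols)
}

#' Write a colony-size table
#'
#' Inverse of [readColonyTable()]; the pair round-trips losslessly.
#' Numeric sizes are written with full precision.
#'
#' @param screen a [ColonyScreen-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeColonyTable <- function(screen, path) {
  stopifnot(is(screen, "ColonyScreen"))
  d <- as.data.frame(measurements(screen))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene annotations from BED
#'
#' Reads a BED4 file (chrom, start, end, name; 0-based half-open) into a
#' `GRanges` keyed by gene name. Internally all coordinates follow the
#' usual Bioconductor 1-based closed convention; the 0-based BED
#' convention is converted at this boundary.
#'
#' @param path BED file.
#' @return a named `GRanges`, one range per gene.
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) && (is.null(gr$name) || anyNA(gr$name)))
    .formatError("BED file must carry a gene name in column 4")
  names(gr) <- gr$name
  gr
}

#' Write gene annotations to BED
#'
#' @param annotations a named `GRanges` (names are gene ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(annotations, path) {
  gr <- annotations
  gr$name <- names(gr)
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene sets from GMT
#'
#' One set per line: set id, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return a named list of character vectors (empty list for an empty file).
#' @export
readGmt <- function(path) {
  if (file.size(path) == 0) return(setNames(list(), character()))
  fgsea::gmtPathways(path)
}

#' Write gene sets to GMT
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set ids).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read a planted-interaction truth table
#'
#' The truth table records, for every simulated gene, its planted
#' interaction class (`sick`, `rescue` or `none`) and the multiplicative
#' effect applied to its double-mutant colony size. `writeTruth()` /
#' `readTruth()` round-trip losslessly.
#'
#' @param truth a data.frame/DataFrame with columns `gene`, `class`,
#'   `effect`.
#' @param path TSV file.
#' @return `writeTruth()`: `path` invisibly; `readTruth()`: a `DataFrame`.
#' @export
writeTruth <- function(truth, path) {
  d <- as.data.frame(truth)[, c("gene", "class", "effect"), drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
  S4Vectors::DataFrame(d)
}
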