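#' Linkage windows around query and marker loci
#'
#' During the cross, genes physically near the query mutation (or near a
#' selection-marker locus) cannot recombine away from it, which biases
#' double-mutant recovery. Genes within a fixed physical window — 500 kb
#' by default — of such loci are therefore flagged and excluded from
#' multiple-testing adjustment and hit calling.
#'
#' @param chromosome character vector of chromosome names.
#' @param center numeric vector of window centers (bp, 0-based).
#' @param halfWidth window half-width in bp (default 500,000), recycled.
#' @return a data.frame of class `LinkageWindows`.
#' @examples
#' linkageWindows(c("II", "I"), c(2.2e6, 4.0e6))
#' @export
linkageWindows <- function(chromosome, center, halfWidth = 5e5) {
  stopifnot(length(chromosome) == length(center),
            all(halfWidth > 0), all(center >= 0))
  structure(data.frame(chromosome = as.character(chromosome),
                       center = as.numeric(center),
                       half_width = as.numeric(halfWidth)),
            class = c("LinkageWindows", "data.frame"))
}

#' Flag genes linked to query/marker loci
#'
#' A gene is linked when it lies on the same chromosome as a window and
#' the minimum distance from the window center to any point of the gene's
#' interval is at most the window half-width (boundary inclusive; distance
#' 0 when the center falls inside the gene). Distance is measured to the
#' nearest point of the interval, not the gene midpoint, so long genes
#' cannot escape a window on a technicality.
#'
#' @param annotations a named `GRanges` of gene coordinates (1-based,
#'   as returned by [readBed()]).
#' @param windows a [linkageWindows()] object.
#' @return named logical vector, `TRUE` for linked genes, in the order of
#'   `annotations`.
#' @export
flagLinked <- function(annotations, windows) {
  stopifnot(is(annotations, "GRanges"), inherits(windows, "LinkageWindows"))
  chr <- as.character(GenomicRanges::seqnames(annotations))
  if (!all(windows$chromosome %in% chr))
    warning("linkage window chromosome(s) absent from annotation: ",
            paste(setdiff(windows$chromosome, chr), collapse = ", "))
  # back to 0-based half-open for the distance arithmetic
  start0 <- GenomicRanges::start(annotations) - 1
  end0 <- GenomicRanges::end(annotations)
  linked <- rep(FALSE, length(annotations))
  for (w in seq_len(nrow(windows))) {
    same <- chr == windows$chromosome[w]
    ctr <- windows$center[w]
    dist <- ifelse(ctr >= start0 & ctr < end0, 0,
                   ifelse(ctr < start0, start0 - ctr, ctr - (end0 - 1)))
    linked <- linked | (same & dist <= windows$half_width[w])
  }
  names(linked) <- names(annotations)
  linked
}

#' Apply linkage flags to scored results
#'
#' Sets the `linked` column of a [scoreScreen()] result. Genes without
#' coordinates are flagged with a warning and excluded from the
#' adjustment universe via `status = "unknown_position"`; they remain in
#' the table for auditability but can never be called.
#'
#' @param results a result `DataFrame` from [scoreScreen()].
#' @param annotations a named `GRanges`.
#' @param windows a [linkageWindows()] object.
#' @return `results` with `linked` (and, for unannotated genes, `status`)
#'   updated.
#' @export
applyLinkageFilter <- function(results, annotations, windows) {
  flags <- flagLinked(annotations, windows)
  idx <- match(results$gene, names(flags))
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) lack coordinates; excluded from the ",
            "adjustment universe")
    results$status[unknown] <- "unknown_position"
    results$linked[unknown] <- TRUE
  }
  results$linked[!unknown] <- unname(flags[idx[!unknown]])
  results
}
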