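#' 2x2 contingency table of phenotype counts
#'
#' Event counts out of totals for two strains — e.g. anaphases with
#' lagging chromosomes out of anaphases scored, for a mutant versus a
#' reference strain.
#'
#' @param strain_a,strain_b strain labels.
#' @param a_event,a_total,b_event,b_total nonnegative counts with
#'   `event <= total` and `total >= 1`.
#' @return a list of class `ContingencyTable`.
#' @examples
#' contingencyTable("WT", "mutant", 2, 100, 13, 100)
#' @export
contingencyTable <- function(strain_a, strain_b,
                             a_event, a_total, b_event, b_total) {
  counts <- c(a_event, a_total, b_event, b_total)
  if (any(counts < 0) || a_event > a_total || b_event > b_total ||
      a_total < 1 || b_total < 1)
    .formatError("invalid contingency counts")
  structure(list(strain_a = strain_a, strain_b = strain_b,
                 a_event = as.integer(a_event), a_total = as.integer(a_total),
                 b_event = as.integer(b_event), b_total = as.integer(b_total)),
            class = "ContingencyTable")
}

#' Fisher's exact test on a 2x2 phenotype table
#'
#' Exact hypergeometric-tail p-value over tables with fixed margins, as
#' used to compare lagging-chromosome frequencies between strains. The
#' two-sided p-value sums the probabilities of all tables no more likely
#' than the observed one (minimum-likelihood convention). Tables with a
#' zero margin (no events or all events in both strains, or an empty
#' strain) are degenerate: p = 1.
#'
#' @param table a [contingencyTable()].
#' @param sided `"two"` (default), `"less"` or `"greater"`; the one-sided
#'   alternatives refer to the event rate of strain A relative to B.
#' @return a list with `p`, `odds_ratio`, `degenerate`.
#' @examples
#' fisherExact2x2(contingencyTable("WT", "mut", 2, 100, 13, 100))
#' @export
fisherExact2x2 <- function(table, sided = c("two", "less", "greater")) {
  sided <- match.arg(sided)
  stopifnot(inherits(table, "ContingencyTable"))
  m <- matrix(c(table$a_event, table$a_total - table$a_event,
                table$b_event, table$b_total - table$b_event),
              nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(p = 1, odds_ratio = NA_real_, degenerate = TRUE))
  alt <- switch(sided, two = "two.sided", less = "less",
                greater = "greater")
  ft <- stats::fisher.test(m, alternative = alt)
  list(p = unname(ft$p.value), odds_ratio = unname(ft$estimate),
       degenerate = FALSE)
}

#' Per-strain event percentages with exact binomial confidence intervals
#'
#' Summarizes phenotype penetrance (e.g. percent lagging anaphases) as
#' `100 * event / total` with a 95% Clopper-Pearson interval.
#'
#' @param events,totals integer vectors (same length).
#' @param strains optional strain labels.
#' @param conf confidence level (default 0.95).
#' @return a data.frame with `strain`, `events`, `total`, `percent`,
#'   `ci_lower`, `ci_upper` (percent scale).
#' @examples
#' rateSummary(c(13, 2), c(100, 100), c("eso1-G799D", "rescue"))
#' @export
rateSummary <- function(events, totals, strains = NULL, conf = 0.95) {
  stopifnot(length(events) == length(totals))
  if (any(totals < 1)) .formatError("totals must be >= 1")
  if (any(events < 0 | events > totals))
    .formatError("events must lie in [0, total]")
  if (is.null(strains)) strains <- sprintf("strain%d", seq_along(events))
  ci <- t(vapply(seq_along(events), function(i)
    stats::binom.test(events[i], totals[i],
                      conf.level = conf)$conf.int, numeric(2)))
  data.frame(strain = strains, events = events, total = totals,
             percent = 100 * events / totals,
             ci_lower = 100 * ci[, 1], ci_upper = 100 * ci[, 2])
}

#' Fisher tests of each strain against a reference
#'
#' Convenience wrapper for panels of strains compared with a common
#' reference (e.g. each double mutant's lagging-chromosome rate versus
#' the query single mutant).
#'
#' @param counts data.frame with columns `strain`, `events`, `total`.
#' @param reference name of the reference strain in `counts`.
#' @param sided passed to [fisherExact2x2()].
#' @return `counts` with added `percent` and `p_vs_reference` (NA for the
#'   reference row).
#' @export
laggingTest <- function(counts, reference, sided = "two") {
  stopifnot(all(c("strain", "events", "total") %in% colnames(counts)))
  ref <- counts[counts$strain == reference, ]
  if (nrow(ref) != 1L)
    .formatError(paste0("reference strain not found: ", reference))
  counts$percent <- 100 * counts$events / counts$total
  counts$p_vs_reference <- vapply(seq_len(nrow(counts)), function(i) {
    if (counts$strain[i] == reference) return(NA_real_)
    tb <- contingencyTable(ref$strain, counts$strain[i],
                           ref$events, ref$total,
                           counts$events[i], counts$total[i])
    fisherExact2x2(tb, sided = sided)$p
  }, numeric(1))
  counts
}
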