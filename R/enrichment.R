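#' Hypergeometric gene-set overrepresentation
#'
#' Tests each gene set for overrepresentation in a hit list by the
#' hypergeometric upper tail: with a universe of `N` scored genes, `K` of
#' which belong to the set, and `n` hits, the p-value is
#' `P(X >= k)` for the observed overlap `k`,
#' `X ~ Hypergeometric(N, K, n)`. Set members outside the universe are
#' ignored; sets with fewer than `minSetSize` in-universe members are
#' skipped. P-values are BH-adjusted across the tested sets.
#'
#' The universe should be the genes that could have been hits — i.e. the
#' genes scored after linkage filtering — not the whole genome.
#'
#' @param hits character vector of hit genes; must be a subset of
#'   `universe`.
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of all scored genes.
#' @param minSetSize smallest in-universe set size tested (default 3).
#' @return a `DataFrame` with one row per tested set: `set_id`,
#'   `universe_size`, `set_size`, `hits_size`, `overlap`, `p_hyper`,
#'   `p_adjusted`, ordered by `p_hyper`.
#' @examples
#' hypergeometricEnrich(hits = c("g1", "g2"),
#'                      sets = list(s = c("g1", "g2", "g3")),
#'                      universe = paste0("g", 1:10), minSetSize = 2)
#' @export
hypergeometricEnrich <- function(hits, sets, universe, minSetSize = 3L) {
  universe <- unique(universe)
  hits <- unique(hits)
  offenders <- setdiff(hits, universe)
  if (length(offenders))
    .formatError(paste0("hits not in universe: ",
                        paste(offenders, collapse = ", ")))
  N <- length(universe)
  n <- length(hits)
  members <- lapply(sets, intersect, universe)
  keep <- vapply(members, length, integer(1)) >= minSetSize
  members <- members[keep]
  K <- vapply(members, length, integer(1))
  k <- vapply(members, function(s) length(intersect(s, hits)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- S4Vectors::DataFrame(
    set_id = names(members), universe_size = N, set_size = unname(K),
    hits_size = n, overlap = unname(k), p_hyper = unname(p),
    p_adjusted = unname(stats::p.adjust(p, method = "BH")))
  out[order(out$p_hyper), ]
}
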