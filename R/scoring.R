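#' Paired t-test on matched control/test colony sizes
#'
#' The screen's interaction statistic: for a gene with replicate spots at
#' matched grid positions on the control (single-mutant) and test
#' (double-mutant) plates, the paired differences
#' `d_i = control_i - test_i` give
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom. A
#' positive mean difference means the double mutant grows worse
#' (synthetic sick direction); a negative one means it grows better
#' (rescue direction).
#'
#' Degenerate inputs are flagged rather than dropped: if all differences
#' are identical the t-statistic is undefined; the p-value is set to 1
#' when the common difference is 0 and to 0 otherwise (a constant nonzero
#' shift is unambiguous evidence of a difference), with
#' `status = "degenerate"`. Fewer than 2 pairs gives
#' `status = "insufficient"` and `NA` statistics.
#'
#' @param control,test numeric vectors of equal length; element `i` of
#'   each is the same replicate spot under the two conditions.
#' @param sided `"two"` (default) or `"one"`; one-sided tests the
#'   control > test (sick) direction.
#' @return a list with `t_stat`, `p_raw`, `diff` (mean difference),
#'   `n_pairs`, `status` (`"ok"`, `"degenerate"`, `"insufficient"`).
#' @examples
#' pairedT(c(110, 95, 105, 100), c(60, 55, 70, 50))
#' @export
pairedT <- function(control, test, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(control) != length(test))
    .formatError("control and test must have equal length")
  keep <- is.finite(control) & is.finite(test)
  d <- control[keep] - test[keep]
  n <- length(d)
  if (n < 2L)
    return(list(t_stat = NA_real_, p_raw = NA_real_,
                diff = if (n == 1L) d else NA_real_,
                n_pairs = n, status = "insufficient"))
  dbar <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t_stat = if (dbar == 0) 0 else sign(dbar) * Inf,
                p_raw = if (dbar == 0) 1 else 0,
                diff = dbar, n_pairs = n, status = "degenerate"))
  }
  t <- dbar / (s / sqrt(n))
  p <- if (sided == "two") 2 * stats::pt(-abs(t), df = n - 1)
  else stats::pt(t, df = n - 1, lower.tail = FALSE)
  list(t_stat = t, p_raw = p, diff = dbar, n_pairs = n, status = "ok")
}

#' Combine p-values across independent experiments (Fisher's method)
#'
#' `X2 = -2 * sum(log(p_i))` follows a chi-square distribution with `2k`
#' degrees of freedom under the joint null; the combined p-value is the
#' upper tail at `X2`. A single p-value passes through unchanged. Zero
#' p-values are clamped to the smallest positive double with a warning.
#'
#' @param p numeric vector of `k >= 1` p-values in (0, 1].
#' @return a list with `X2`, `df = 2k`, `p_combined`.
#' @examples
#' fisherCombine(c(0.05, 0.05))  # p_combined ~ 0.0175
#' @export
fisherCombine <- function(p) {
  p <- p[!is.na(p)]
  k <- length(p)
  if (k < 1L) .insufficientData("no p-values to combine")
  if (any(p < 0 | p > 1)) .formatError("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  if (k == 1L)
    return(list(X2 = -2 * log(p), df = 2L, p_combined = p))
  X2 <- -2 * sum(log(p))
  list(X2 = X2, df = 2L * k,
       p_combined = stats::pchisq(X2, df = 2L * k, lower.tail = FALSE))
}

#' Multiple-testing adjustment over the screen universe
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the methods the
#' pipeline exposes. The universe passed here must already exclude
#' linkage-flagged and unscorable genes.
#'
#' @param p numeric vector of combined p-values.
#' @param method `"BH"` (default), `"bonferroni"` or `"none"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjustP <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = method)
}

#' Scoring thresholds and options
#'
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param diffThreshold minimum absolute mean colony-size difference, in
#'   normalized arbitrary area units (default 25).
#' @param adjustMethod multiple-testing adjustment (default `"BH"`).
#' @param sided sidedness of the paired t-test.
#' @return a list of class `ScoringConfig`.
#' @export
ScoringConfig <- function(alpha = 0.05, diffThreshold = 25,
                          adjustMethod = c("BH", "bonferroni", "none"),
                          sided = c("two", "one")) {
  stopifnot(alpha > 0, alpha < 1, diffThreshold > 0)
  structure(list(alpha = alpha, diffThreshold = diffThreshold,
                 adjustMethod = match.arg(adjustMethod),
                 sided = match.arg(sided)),
            class = "ScoringConfig")
}

#' Score a screen gene by gene
#'
#' Runs the per-gene paired t-test within each experiment (pairing test to
#' control spots by replicate index), pools all pairs across experiments
#' for a single reported t-statistic and mean difference, and combines the
#' per-experiment p-values with Fisher's method. Pairs whose control spot
#' is dead (size 0) are excluded — a failed single mutant is
#' uninformative — while dead test spots are kept as genuine size-0 double
#' mutants.
#'
#' Genes whose per-experiment t-statistics disagree in sign are marked
#' `sign_consistent = FALSE` and are never called as hits, preventing two
#' opposite-direction experiments from combining into a spurious hit.
#'
#' @param screen a normalized [ColonyScreen-class] (see
#'   [normalizePlates()]); set `useNormalized = FALSE` to score raw sizes.
#' @param config a [ScoringConfig()].
#' @param useNormalized score `size_normalized` (default) or raw `size`.
#' @return a `DataFrame` with one row per gene: `gene`, `n_pairs`,
#'   `mean_control`, `mean_test`, `diff`, `t_stat`, per-experiment
#'   `t_exp*` / `p_exp*` columns, `sign_consistent`, `p_combined`,
#'   `status`, plus placeholder columns `linked`, `p_adjusted` and `call`
#'   filled by [flagLinked()]/[callHits()].
#' @seealso [callHits()], [flagLinked()], [intersectScreens()]
#' @export
scoreScreen <- function(screen, config = ScoringConfig(),
                        useNormalized = TRUE) {
  stopifnot(is(screen, "ColonyScreen"))
  m <- measurements(screen)
  size_col <- if (useNormalized) "size_normalized" else "size"
  if (useNormalized && all(is.na(m$size_normalized)))
    .configError("screen is not normalized; run normalizePlates() first")
  m$value <- m[[size_col]]
  m <- m[m$gene != "blank", ]
  experiments <- sort(unique(m$experiment_id))
  genes <- sort(unique(m$gene))

  # per (gene, experiment, replicate) control/test values
  ctrl <- m[m$condition == "control", ]
  test <- m[m$condition == "test", ]
  key_c <- paste(ctrl$gene, ctrl$experiment_id, ctrl$replicate, sep = "\r")
  key_t <- paste(test$gene, test$experiment_id, test$replicate, sep = "\r")
  test_val <- setNames(test$value, key_t)

  per_exp <- lapply(experiments, function(e) {
    sel <- ctrl$experiment_id == e
    d <- data.frame(gene = ctrl$gene[sel],
                    control = ctrl$value[sel],
                    test = unname(test_val[key_c[sel]]))
    # drop pairs with a dead or unnormalizable control spot
    d <- d[!is.na(d$control) & d$control > 0 & !is.na(d$test), ]
    split(d, factor(d$gene, levels = genes))
  })
  names(per_exp) <- experiments

  res <- lapply(genes, function(g) {
    exps <- lapply(per_exp, `[[`, g)
    tt <- lapply(exps, function(d) pairedT(d$control, d$test,
                                           sided = config$sided))
    pooled_c <- unlist(lapply(exps, `[[`, "control"))
    pooled_t <- unlist(lapply(exps, `[[`, "test"))
    pooled <- pairedT(pooled_c, pooled_t, sided = config$sided)
    p_exp <- vapply(tt, `[[`, numeric(1), "p_raw")
    t_exp <- vapply(tt, `[[`, numeric(1), "t_stat")
    ok <- !is.na(p_exp)
    comb <- if (any(ok)) fisherCombine(p_exp[ok])
    else list(p_combined = NA_real_)
    signs <- sign(t_exp[ok & is.finite(t_exp)])
    sign_consistent <- length(signs) < 2L ||
      all(signs >= 0) || all(signs <= 0)
    status <- if (pooled$status == "insufficient") "insufficient"
    else if (all(vapply(tt, `[[`, character(1), "status") ==
                 "degenerate")) "degenerate"
    else "ok"
    c(list(gene = g, n_pairs = pooled$n_pairs,
           mean_control = if (length(pooled_c)) mean(pooled_c) else NA_real_,
           mean_test = if (length(pooled_t)) mean(pooled_t) else NA_real_,
           diff = pooled$diff, t_stat = pooled$t_stat),
      setNames(as.list(t_exp), paste0("t_", experiments)),
      setNames(as.list(p_exp), paste0("p_", experiments)),
      list(sign_consistent = sign_consistent,
           p_combined = unname(comb$p_combined), status = status))
  })
  out <- S4Vectors::DataFrame(do.call(rbind,
                                      lapply(res, function(r)
                                        as.data.frame(r,
                                                      stringsAsFactors = FALSE))))
  out$linked <- FALSE
  out$p_adjusted <- NA_real_
  out$call <- "none"
  S4Vectors::metadata(out) <- list(config = config,
                                   experiments = experiments)
  out
}

#' Call synthetic sick and rescue interactions
#'
#' Applies the dual-threshold rule to scored results: a gene is called
#' `sick` when its adjusted p-value is below `alpha` AND its mean
#' colony-size difference (control minus test, normalized units) exceeds
#' `diffThreshold`, and `rescue` when the adjusted p is below `alpha` AND
#' the difference is below `-diffThreshold`. Linkage-flagged genes, genes
#' with inconsistent t-statistic signs across experiments, and genes with
#' degenerate or insufficient data are never called.
#'
#' The adjustment universe is the set of genes that are not linked and
#' have a valid combined p-value; adjusted p-values of excluded genes are
#' `NA`.
#'
#' @param results the `DataFrame` from [scoreScreen()], optionally with
#'   `linked` set by [flagLinked()].
#' @param config a [ScoringConfig()] (defaults match the screen design:
#'   adjusted p < 0.05 and |difference| > 25).
#' @return `results` with `p_adjusted` and `call` filled in.
#' @export
callHits <- function(results, config = ScoringConfig()) {
  universe <- !results$linked & !is.na(results$p_combined) &
    results$status != "insufficient"
  results$p_adjusted <- NA_real_
  results$p_adjusted[universe] <- adjustP(results$p_combined[universe],
                                          method = config$adjustMethod)
  callable <- universe & results$sign_consistent &
    !is.na(results$p_adjusted) & results$p_adjusted < config$alpha
  results$call <- "none"
  results$call[callable & results$diff > config$diffThreshold] <- "sick"
  results$call[callable & results$diff < -config$diffThreshold] <- "rescue"
  results
}

#' Intersect the hit lists of two screens
#'
#' Genes called in the same direction in both screens, with both screens'
#' statistics attached (suffixes `_a`, `_b`).
#'
#' @param results_a,results_b scored and called result `DataFrame`s.
#' @param call `"sick"` (default) or `"rescue"`.
#' @return a `DataFrame` of shared hits (possibly empty).
#' @export
intersectScreens <- function(results_a, results_b, call = "sick") {
  if (!length(intersect(results_a$gene, results_b$gene)))
    warning("screens have disjoint gene universes")
  hits_a <- results_a[results_a$call == call, ]
  hits_b <- results_b[results_b$call == call, ]
  shared <- intersect(hits_a$gene, hits_b$gene)
  a <- hits_a[match(shared, hits_a$gene), ]
  b <- hits_b[match(shared, hits_b$gene), ]
  keep <- c("n_pairs", "mean_control", "mean_test", "diff", "t_stat",
            "p_combined", "p_adjusted")
  out <- S4Vectors::DataFrame(gene = shared, call = rep(call,
                                                        length(shared)))
  for (k in keep) {
    out[[paste0(k, "_a")]] <- a[[k]]
    out[[paste0(k, "_b")]] <- b[[k]]
  }
  out
}

#' Write scored results to TSV
#'
#' Stable column order, one row per gene; round-trips with
#' [readResults()].
#'
#' @param results a result `DataFrame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  S4Vectors::DataFrame(utils::read.table(path, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE))
}
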