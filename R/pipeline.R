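#' Run the full screen-scoring pipeline on a simulated screen
#'
#' Chains every stage on generated data: simulate plates, normalize
#' (edge correction then plate scaling), score genes with the paired
#' t-test and Fisher combination across experiments, flag linkage around
#' the configured query loci, BH-adjust and call sick/rescue hits, and
#' test gene sets for overrepresentation among the sick hits.
#'
#' @param config a [SimulationConfig-class].
#' @param scoring a [ScoringConfig()].
#' @param windows linkage windows; by default 500 kb windows around the
#'   configuration's query loci.
#' @param outDir optional directory; when given, all intermediate and
#'   final tables (colonies, normalization report, truth, BED, GMT,
#'   results, enrichment) are written there as plain text.
#' @return a list with `sim` (the [simulateScreen()] output), `normalized`
#'   (screen + report), `results` (scored, flagged, called `DataFrame`),
#'   `hits` (character vector of sick calls), `enrichment` (`DataFrame`),
#'   and `qc` (t-statistic normality summary or NULL).
#' @examples
#' out <- runScreenPipeline(SimulationConfig(nGenes = 64,
#'                                           replicatesPerGene = 4,
#'                                           nExperiments = 1, seed = 3))
#' table(out$results$call)
#' @export
runScreenPipeline <- function(config = SimulationConfig(),
                              scoring = ScoringConfig(),
                              windows = NULL, outDir = NULL) {
  sim <- simulateScreen(config)
  norm <- normalizePlates(sim$screen)
  results <- scoreScreen(norm$screen, config = scoring)
  if (is.null(windows))
    windows <- linkageWindows(config@queryLoci$chromosome,
                              config@queryLoci$position)
  results <- applyLinkageFilter(results, sim$annotations, windows)
  results <- callHits(results, config = scoring)
  universe <- results$gene[!results$linked &
                             results$status %in% c("ok", "degenerate")]
  hits <- results$gene[results$call == "sick"]
  enrichment <- if (length(hits) && length(sim$geneSets))
    hypergeometricEnrich(hits, sim$geneSets, universe)
  else NULL
  qc <- tryCatch(qcTstatNormality(results$t_stat[!results$linked]),
                 error = function(e) NULL)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeColonyTable(norm$screen, file.path(outDir, "colonies.tsv"))
    utils::write.table(as.data.frame(norm$report),
                       file.path(outDir, "normalization_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeTruth(sim$truth, file.path(outDir, "truth.tsv"))
    writeBed(sim$annotations, file.path(outDir, "genes.bed"))
    writeGmt(sim$geneSets, file.path(outDir, "gene_sets.gmt"))
    writeResults(results, file.path(outDir, "results.tsv"))
    if (!is.null(enrichment))
      utils::write.table(as.data.frame(enrichment),
                         file.path(outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sim = sim, normalized = norm, results = results, hits = hits,
       enrichment = enrichment, qc = qc)
}
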