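#' Simulate an arrayed genetic interaction screen
#'
#' Generates paired control (single-mutant selection) and test
#' (double-mutant selection) plates with the statistical structure the
#' scoring pipeline assumes: each library gene occupies the same grid
#' positions on the control and the test plate of an experiment, spots on
#' the outermost two rows/columns grow larger by a fixed edge factor, each
#' physical plate carries an independent multiplicative batch effect, and
#' per-spot noise is lognormal with a configured coefficient of variation.
#' A configurable fraction of genes carries a planted synthetic-sick
#' (multiplier < 1) or synthetic-rescue (multiplier > 1) interaction that
#' scales the test-plate colony size only.
#'
#' The expected size of a spot is
#' `baseline * effect(gene) * plateEffect * edgeFactor`, with
#' `effect(gene) = 1` on control plates and for non-interacting genes.
#' Plate effects and spot noise are mean-one lognormal so that configured
#' baselines are recovered in expectation. A fraction `missingRate` of
#' spots is set to size 0 (dead spots are encoded as zeros, never dropped).
#'
#' Gene coordinates are drawn uniformly over the configured chromosomes,
#' except that one gene is placed inside the 500 kb window around each
#' query locus so linkage filtering always has work to do. Gene sets are
#' generated with planted enrichment: one set contains half of the planted
#' sick genes (plus as many null genes), alongside random decoy sets.
#'
#' @param config a [SimulationConfig-class].
#' @param nDecoySets number of random decoy gene sets in the generated
#'   annotation (the planted set comes on top of these).
#' @param truth optional truth table from a previous [simulateScreen()]
#'   call; when supplied, its planted classes and effects are reused
#'   instead of sampling new ones, so that two independently noised
#'   screens (different seeds) share the same true interactions — as two
#'   query screens over one library would.
#' @return a list with elements
#'   \describe{
#'     \item{screen}{a [ColonyScreen-class] holding all plates of all
#'       experiments and both conditions.}
#'     \item{truth}{`DataFrame` of planted classes/effects per gene.}
#'     \item{annotations}{named `GRanges` of gene coordinates.}
#'     \item{geneSets}{named list of gene sets (`planted_set` first).}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' sim <- simulateScreen(SimulationConfig(nGenes = 32, replicatesPerGene = 4,
#'                                        nExperiments = 1, seed = 7))
#' sim$screen
#' table(sim$truth$class)
#' @export
simulateScreen <- function(config, nDecoySets = 20L, truth = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  n_genes <- config@nGenes
  reps <- config@replicatesPerGene
  rows <- config@plateRows
  cols <- config@plateCols
  spots_per_plate <- rows * cols
  n_sets <- ceiling(n_genes / spots_per_plate)
  n_plates <- n_sets * reps
  if (n_genes > n_sets * spots_per_plate)
    .configError("library does not fit on the computed number of plates")

  genes <- sprintf("gene%04d", seq_len(n_genes))

  # planted interaction classes (or a shared truth table from a sibling
  # screen over the same library)
  if (is.null(truth)) {
    n_sick <- round(config@sickFraction * n_genes)
    n_rescue <- round(config@rescueFraction * n_genes)
    planted <- sample(genes, n_sick + n_rescue)
    truth <- S4Vectors::DataFrame(gene = genes,
                                  class = "none", effect = 1)
    truth$class[match(planted[seq_len(n_sick)], genes)] <- "sick"
    truth$effect[match(planted[seq_len(n_sick)], genes)] <- config@sickEffect
    if (n_rescue > 0) {
      resc <- planted[n_sick + seq_len(n_rescue)]
      truth$class[match(resc, genes)] <- "rescue"
      truth$effect[match(resc, genes)] <- config@rescueEffect
    }
  } else {
    truth <- S4Vectors::DataFrame(truth)
    if (!identical(truth$gene, genes))
      .configError("supplied truth table does not match the gene universe")
  }
  effect_of <- setNames(truth$effect, truth$gene)

  # arrayed-library layout: the library fills n_sets plates row-major
  # (partial last plate padded with unscored baseline "blank" spots), and
  # each replicate is a complete pinned copy of that arrangement on its
  # own plate; a gene therefore sits at the same grid position on every
  # replicate plate and on the matched control/test plates
  set_gene <- c(genes, rep("blank", n_sets * spots_per_plate - n_genes))
  idx <- seq_along(set_gene) - 1L
  set_layout <- data.frame(
    set = idx %/% spots_per_plate + 1L,
    row = (idx %% spots_per_plate) %/% cols + 1L,
    col = (idx %% spots_per_plate) %% cols + 1L,
    gene = set_gene)
  layout <- do.call(rbind, lapply(seq_len(reps), function(r)
    cbind(set_layout, replicate = r)))
  layout$plate <- (layout$replicate - 1L) * n_sets + layout$set
  edge <- .isEdge(layout$row, layout$col, rows, cols)
  edge_factor <- ifelse(edge, config@edgeBoost, 1)

  sigma_noise <- sqrt(log(1 + config@noiseCv^2))
  n_layout <- nrow(layout)

  measurement_blocks <- vector("list", config@nExperiments * 2L)
  b <- 0L
  for (e in seq_len(config@nExperiments)) {
    for (cond in c("control", "test")) {
      # one independent batch effect per physical plate
      plate_mult <- if (config@plateEffectSd > 0)
        exp(stats::rnorm(n_plates, -config@plateEffectSd^2 / 2,
                         config@plateEffectSd))
      else rep(1, n_plates)
      noise <- if (sigma_noise > 0)
        exp(stats::rnorm(n_layout, -sigma_noise^2 / 2, sigma_noise))
      else rep(1, n_layout)
      gene_effect <- if (cond == "test")
        ifelse(layout$gene == "blank", 1, effect_of[layout$gene])
      else rep(1, n_layout)
      size <- config@baselineSize * gene_effect *
        plate_mult[layout$plate] * edge_factor * noise
      if (config@missingRate > 0)
        size[stats::runif(n_layout) < config@missingRate] <- 0
      b <- b + 1L
      measurement_blocks[[b]] <- data.frame(
        screen_id = "synthetic",
        experiment_id = sprintf("exp%d", e),
        condition = cond,
        temperature = "25C",
        plate_id = sprintf("exp%d_%s_p%02d", e, cond, layout$plate),
        row = layout$row, col = layout$col,
        gene = layout$gene, replicate = layout$replicate,
        size = size, size_normalized = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  screen <- ColonyScreen(do.call(rbind, measurement_blocks),
                         plateRows = rows, plateCols = cols)

  annotations <- .simulateCoordinates(genes, config)
  geneSets <- .simulateGeneSets(truth, nDecoySets)

  list(screen = screen, truth = truth, annotations = annotations,
       geneSets = geneSets, config = config)
}

# uniform gene placement with one gene forced into each query window
.simulateCoordinates <- function(genes, config, geneLength = 2000,
                                 windowHalfWidth = 5e5) {
  chroms <- names(config@chromosomeLengths)
  lens <- config@chromosomeLengths
  chr <- sample(chroms, length(genes), replace = TRUE,
                prob = lens / sum(lens))
  start0 <- floor(stats::runif(length(genes)) *
                    pmax(1, lens[chr] - geneLength))
  ql <- config@queryLoci
  for (q in seq_len(nrow(ql))) {
    if (q > length(genes)) break
    qchr <- ql$chromosome[q]
    lo <- max(0, ql$position[q] - windowHalfWidth / 2)
    hi <- min(lens[qchr] - geneLength, ql$position[q] + windowHalfWidth / 2)
    chr[q] <- qchr
    start0[q] <- floor(stats::runif(1, lo, hi))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chr,
    ranges = IRanges::IRanges(start = start0 + 1, width = geneLength))
  names(gr) <- genes
  gr
}

# planted set = half the sick genes + as many nulls; decoys random
.simulateGeneSets <- function(truth, nDecoySets, decoySize = NULL) {
  genes <- truth$gene
  sick <- genes[truth$class == "sick"]
  nulls <- genes[truth$class == "none"]
  n_half <- ceiling(length(sick) / 2)
  planted <- character()
  if (n_half > 0)
    planted <- c(sick[seq_len(n_half)],
                 sample(nulls, min(n_half, length(nulls))))
  size <- if (is.null(decoySize)) max(4L, length(planted)) else decoySize
  sets <- lapply(seq_len(nDecoySets), function(i)
    sample(genes, min(size, length(genes))))
  names(sets) <- sprintf("decoy_set_%02d", seq_len(nDecoySets))
  if (length(planted))
    sets <- c(list(planted_set = planted), sets)
  sets
}
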