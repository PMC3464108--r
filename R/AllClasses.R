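#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.CONDITIONS <- c("control", "test")
.TEMPERATURES <- c("25C", "37C")

#' Colony measurement table columns
#'
#' Column order of the on-disk colony table dialect and of the
#' `measurements` slot of a [ColonyScreen-class] object.
#' @keywords internal
.COLONY_COLS <- c("screen_id", "experiment_id", "condition", "temperature",
                  "plate_id", "row", "col", "gene", "replicate",
                  "size", "size_normalized")

#' ColonyScreen: arrayed colony-size measurements
#'
#' An S4 container for one or more plates of colony-size measurements from
#' an arrayed genetic screen. Each row of the `measurements` DataFrame is a
#' single spot: its plate, grid position, the deletion-library gene arrayed
#' there, the replicate index, the experimental condition
#' (`"control"` = single-mutant selection, `"test"` = double-mutant
#' selection), the incubation temperature, the raw colony size in arbitrary
#' area units, and (after [normalizePlates()]) the normalized size.
#'
#' All plates in one object share the same grid dimensions. Dead or missing
#' spots are encoded as size 0, never as absent rows: every grid position of
#' every plate must be present exactly once.
#'
#' @slot measurements a `DataFrame` with columns `screen_id`,
#'   `experiment_id`, `condition`, `temperature`, `plate_id`, `row`, `col`,
#'   `gene`, `replicate`, `size`, `size_normalized`.
#' @slot plateRows,plateCols integer grid dimensions (defaults describe a
#'   384-format plate, 16 rows by 24 columns).
#'
#' @seealso [ColonyScreen()] constructor, [readColonyTable()],
#'   [normalizePlates()]
#' @aliases ColonyScreen-class
#' @exportClass ColonyScreen
setClass("ColonyScreen",
  representation(measurements = "DataFrame",
                 plateRows = "integer",
                 plateCols = "integer"),
  prototype(measurements = S4Vectors::DataFrame(),
            plateRows = 16L, plateCols = 24L))

setValidity("ColonyScreen", function(object) {
  m <- object@measurements
  msgs <- character()
  if (length(object@plateRows) != 1L || length(object@plateCols) != 1L ||
      object@plateRows < 1L || object@plateCols < 1L)
    return("plateRows and plateCols must be single positive integers")
  if (nrow(m) == 0L)
    return(TRUE)
  missing_cols <- setdiff(.COLONY_COLS, colnames(m))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("missing measurement columns: ",
                           paste(missing_cols, collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (!all(m$condition %in% .CONDITIONS))
    msgs <- c(msgs, "condition must be 'control' or 'test'")
  if (!all(m$temperature %in% .TEMPERATURES))
    msgs <- c(msgs, "temperature must be '25C' or '37C'")
  if (any(!is.finite(m$size)) || any(m$size < 0))
    msgs <- c(msgs, "size must be finite and >= 0")
  if (any(m$row < 1L) || any(m$row > object@plateRows) ||
      any(m$col < 1L) || any(m$col > object@plateCols))
    msgs <- c(msgs, "grid positions outside plate dimensions")
  key <- paste(m$experiment_id, m$condition, m$plate_id, m$row, m$col,
               sep = "\r")
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicated (experiment, condition, plate, row, col)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ColonyScreen
#'
#' @param measurements a `DataFrame` or `data.frame` of spot measurements
#'   (see [ColonyScreen-class] for the required columns; `size_normalized`
#'   is added as `NA` if absent).
#' @param plateRows,plateCols plate grid dimensions.
#' @return a validated `ColonyScreen` object.
#' @examples
#' m <- data.frame(screen_id = "s", experiment_id = "e1",
#'                 condition = "control", temperature = "25C",
#'                 plate_id = "p1", row = 1:2, col = 1L,
#'                 gene = c("g1", "g1"), replicate = 1:2, size = c(100, 90))
#' ColonyScreen(m, plateRows = 16L, plateCols = 24L)
#' @export
ColonyScreen <- function(measurements = S4Vectors::DataFrame(),
                         plateRows = 16L, plateCols = 24L) {
  m <- S4Vectors::DataFrame(measurements)
  if (nrow(m) > 0L) {
    if (!"size_normalized" %in% colnames(m))
      m$size_normalized <- NA_real_
    m$row <- as.integer(m$row)
    m$col <- as.integer(m$col)
    m$replicate <- as.integer(m$replicate)
    m$size <- as.numeric(m$size)
    m$size_normalized <- as.numeric(m$size_normalized)
    m <- m[, .COLONY_COLS]
  }
  new("ColonyScreen", measurements = m,
      plateRows = as.integer(plateRows), plateCols = as.integer(plateCols))
}

setMethod("show", "ColonyScreen", function(object) {
  m <- object@measurements
  cat("ColonyScreen:", nrow(m), "spots on",
      length(unique(paste(m$condition, m$plate_id))), "plate(s) of",
      object@plateRows, "x", object@plateCols, "\n")
  if (nrow(m)) {
    cat("  conditions:", paste(sort(unique(m$condition)), collapse = ", "),
        "| experiments:",
        paste(sort(unique(m$experiment_id)), collapse = ", "), "\n")
    cat("  genes:", length(setdiff(unique(m$gene), "blank")),
        "| normalized:",
        if (all(is.na(m$size_normalized))) "no" else "yes", "\n")
  }
  invisible(object)
})

#' SimulationConfig: parameters of the synthetic screen generator
#'
#' Holds every generative parameter of [simulateScreen()]. The defaults
#' describe the screen design the pipeline targets: 384-format plates
#' (16 x 24), 12 replicate spots per gene, colonies with a baseline size of
#' 100 arbitrary area units, multiplicative per-plate batch effects,
#' enhanced growth (factor 1.3) on the outermost two rows and columns,
#' lognormal colony-size noise, and a small three-chromosome genome with
#' query loci around which linkage can be exercised.
#'
#' @slot nGenes number of library genes.
#' @slot plateRows,plateCols plate grid dimensions.
#' @slot replicatesPerGene replicate spots per gene (screens use 4 or 12).
#' @slot nExperiments independent experiments (1 or 2); p-values from two
#'   experiments are combined by Fisher's method downstream.
#' @slot baselineSize expected colony size of a non-interacting spot in the
#'   plate middle, arbitrary area units.
#' @slot plateEffectSd log-scale sd of the per-plate multiplier (each
#'   physical plate is an independent batch; control and test plates do not
#'   share plate effects).
#' @slot edgeBoost multiplier applied to spots in the outermost two rows
#'   and two columns (nutrient-access edge effect).
#' @slot noiseCv coefficient of variation of the lognormal per-spot noise.
#' @slot sickFraction,rescueFraction proportions of genes with planted
#'   synthetic-sick / synthetic-rescue interactions.
#' @slot sickEffect,rescueEffect multiplicative effect on double-mutant
#'   (test) colony size for planted genes (< 1 sick, > 1 rescue).
#' @slot missingRate proportion of spots set to size 0 (random dropout).
#' @slot chromosomeLengths named numeric vector of chromosome lengths (bp).
#' @slot queryLoci data.frame with columns `chromosome`, `position` giving
#'   query/marker loci; at least one gene is always placed within 500 kb of
#'   each.
#' @slot seed integer random seed.
#' @aliases SimulationConfig-class
#' @seealso [SimulationConfig()], [simulateScreen()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nGenes = "integer", plateRows = "integer",
                 plateCols = "integer", replicatesPerGene = "integer",
                 nExperiments = "integer", baselineSize = "numeric",
                 plateEffectSd = "numeric", edgeBoost = "numeric",
                 noiseCv = "numeric", sickFraction = "numeric",
                 rescueFraction = "numeric", sickEffect = "numeric",
                 rescueEffect = "numeric", missingRate = "numeric",
                 chromosomeLengths = "numeric", queryLoci = "data.frame",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  counts <- c(nGenes = object@nGenes, plateRows = object@plateRows,
              plateCols = object@plateCols,
              replicatesPerGene = object@replicatesPerGene,
              nExperiments = object@nExperiments)
  if (any(counts < 1L))
    msgs <- c(msgs, paste0("counts must be >= 1: ",
                           paste(names(counts)[counts < 1L], collapse = ", ")))
  pos <- c(baselineSize = object@baselineSize, edgeBoost = object@edgeBoost,
           sickEffect = object@sickEffect, rescueEffect = object@rescueEffect)
  if (any(pos <= 0))
    msgs <- c(msgs, "baselineSize, edgeBoost, sickEffect, rescueEffect must be > 0")
  if (object@plateEffectSd < 0 || object@noiseCv < 0)
    msgs <- c(msgs, "plateEffectSd and noiseCv must be >= 0")
  props <- c(object@sickFraction, object@rescueFraction, object@missingRate)
  if (any(props < 0) || any(props > 1))
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (object@sickFraction + object@rescueFraction > 1)
    msgs <- c(msgs, "sickFraction + rescueFraction must be <= 1")
  if (object@plateRows < 5L || object@plateCols < 5L)
    msgs <- c(msgs, "plates need >= 5 rows and columns (a middle must exist)")
  if (any(object@chromosomeLengths <= 0) ||
      is.null(names(object@chromosomeLengths)))
    msgs <- c(msgs, "chromosomeLengths must be a named vector of positive bp")
  ql <- object@queryLoci
  if (!all(c("chromosome", "position") %in% colnames(ql)))
    msgs <- c(msgs, "queryLoci needs columns chromosome, position")
  else if (!all(ql$chromosome %in% names(object@chromosomeLengths)))
    msgs <- c(msgs, "queryLoci chromosome not in chromosomeLengths")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' See [SimulationConfig-class] for the meaning of each parameter. The
#' genome defaults are a scaled-down fission-yeast-like karyotype: three
#' chromosomes and two query loci (the query mutation and a selection
#' marker) on different chromosomes.
#'
#' @param nGenes,plateRows,plateCols,replicatesPerGene,nExperiments counts.
#' @param baselineSize,plateEffectSd,edgeBoost,noiseCv generative scales.
#' @param sickFraction,rescueFraction,sickEffect,rescueEffect planted
#'   interactions.
#' @param missingRate random dropout proportion.
#' @param chromosomeLengths named numeric vector (bp).
#' @param queryLoci data.frame(chromosome, position).
#' @param seed integer seed.
#' @return a validated `SimulationConfig`.
#' @examples
#' SimulationConfig(nGenes = 100, replicatesPerGene = 4, seed = 1)
#' @export
SimulationConfig <- function(nGenes = 500L, plateRows = 16L, plateCols = 24L,
                             replicatesPerGene = 12L, nExperiments = 2L,
                             baselineSize = 100, plateEffectSd = 0.1,
                             edgeBoost = 1.3, noiseCv = 0.1,
                             sickFraction = 0.05, rescueFraction = 0.02,
                             sickEffect = 0.5, rescueEffect = 1.5,
                             missingRate = 0.01,
                             chromosomeLengths = c(I = 5.6e6, II = 4.5e6,
                                                   III = 2.5e6),
                             queryLoci = data.frame(
                               chromosome = c("II", "I"),
                               position = c(2.2e6, 4.0e6)),
                             seed = 1L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), plateRows = as.integer(plateRows),
      plateCols = as.integer(plateCols),
      replicatesPerGene = as.integer(replicatesPerGene),
      nExperiments = as.integer(nExperiments),
      baselineSize = baselineSize, plateEffectSd = plateEffectSd,
      edgeBoost = edgeBoost, noiseCv = noiseCv,
      sickFraction = sickFraction, rescueFraction = rescueFraction,
      sickEffect = sickEffect, rescueEffect = rescueEffect,
      missingRate = missingRate, chromosomeLengths = chromosomeLengths,
      queryLoci = queryLoci, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes x",
      object@replicatesPerGene, "replicates,",
      object@nExperiments, "experiment(s),",
      object@plateRows, "x", object@plateCols, "plates\n")
  cat("  baseline", object@baselineSize, "| plate sd", object@plateEffectSd,
      "| edge boost", object@edgeBoost, "| noise CV", object@noiseCv, "\n")
  cat("  planted: sick", object@sickFraction, "x", object@sickEffect,
      "| rescue", object@rescueFraction, "x", object@rescueEffect,
      "| missing", object@missingRate, "| seed", object@seed, "\n")
  invisible(object)
})

#' Accessors for ColonyScreen
#'
#' `measurements()` returns the spot-level `DataFrame`; `plateDims()` the
#' grid dimensions.
#' @param x a `ColonyScreen`.
#' @return `measurements()`: a `DataFrame`; `plateDims()`: named integer
#'   vector `c(rows=, cols=)`.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname measurements
#' @export
setMethod("measurements", "ColonyScreen", function(x) x@measurements)

#' @rdname measurements
#' @export
setGeneric("plateDims", function(x) standardGeneric("plateDims"))

#' @rdname measurements
#' @export
setMethod("plateDims", "ColonyScreen", function(x)
  c(rows = x@plateRows, cols = x@plateCols))
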