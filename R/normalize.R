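#' Partition a plate grid into edge and middle positions
#'
#' The edge is the outermost two rows and two columns; the middle is the
#' complement. A plate needs at least 5 rows and 5 columns so that a
#' middle exists.
#'
#' @param rows,cols plate grid dimensions.
#' @return a list with data.frames `edge` and `middle` (columns `row`,
#'   `col`); together they partition the grid exactly.
#' @examples
#' p <- partitionEdgeMiddle(8, 8)
#' nrow(p$edge)    # 48
#' nrow(p$middle)  # 16
#' @export
partitionEdgeMiddle <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 5L || cols < 5L)
    .configError("plate must have >= 5 rows and >= 5 columns")
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols),
                   KEEP.OUT.ATTRS = FALSE)
  e <- .isEdge(g$row, g$col, rows, cols)
  list(edge = g[e, , drop = FALSE], middle = g[!e, , drop = FALSE])
}

#' Two-step plate normalization of colony sizes
#'
#' Corrects the two dominant systematic effects of arrayed colony screens.
#' Step 1 (edge correction): on each plate, spots in the outermost two
#' rows/columns — which grow larger through better nutrient access — are
#' multiplied by `f_p = m_p / e_p`, where `m_p` is the plate middle mean
#' and `e_p` the edge mean, bringing the edge ring onto the plate middle
#' mean. Middle spots are untouched by this step. Step 2 (plate scaling):
#' every spot on plate `p` is multiplied by `g_p = M / m_p`, where `M` is
#' the median of the middle means across all plates, so that after
#' normalization every plate's middle mean equals the same fixed number
#' `M`.
#'
#' Zero-size (dead) spots participate in `e_p` and `m_p`: a dead middle
#' colony legitimately lowers the plate's growth estimate. A plate whose
#' middle spots are all zero cannot be normalized; it is excluded from the
#' median `M`, its normalized sizes are set to `NA`, and it is flagged in
#' the report.
#'
#' @param screen a [ColonyScreen-class] with raw sizes.
#' @param middleStat statistic used for the plate summary (`"mean"`,
#'   the reference behavior, or `"median"` as a robustness option).
#' @param perRing if `TRUE`, the edge correction uses a separate factor for
#'   the outermost ring and the second ring instead of one factor for the
#'   whole two-deep edge.
#' @return a list with
#'   \describe{
#'     \item{screen}{the input with `size_normalized` filled in.}
#'     \item{report}{per-plate `DataFrame`: middle mean `m_p`, edge mean
#'       `e_p`, edge factor `f_p`, global target `M`, plate scale `g_p`,
#'       and an `excluded` flag.}
#'   }
#' @seealso [partitionEdgeMiddle()]
#' @export
normalizePlates <- function(screen, middleStat = c("mean", "median"),
                            perRing = FALSE) {
  stopifnot(is(screen, "ColonyScreen"))
  middleStat <- match.arg(middleStat)
  stat <- if (middleStat == "mean") mean else stats::median
  m <- measurements(screen)
  if (nrow(m) == 0L) .insufficientData("empty screen")
  dims <- plateDims(screen)
  if (dims["rows"] < 5L || dims["cols"] < 5L)
    .configError("plate must have >= 5 rows and >= 5 columns")

  plate_key <- paste(m$experiment_id, m$condition, m$plate_id, sep = "\r")
  plates <- unique(plate_key)
  is_edge <- .isEdge(m$row, m$col, dims["rows"], dims["cols"])
  outer_ring <- m$row == 1L | m$row == dims["rows"] |
    m$col == 1L | m$col == dims["cols"]

  m_p <- vapply(plates, function(p)
    stat(m$size[plate_key == p & !is_edge]), numeric(1))
  e_p <- vapply(plates, function(p)
    stat(m$size[plate_key == p & is_edge]), numeric(1))
  excluded <- m_p <= 0
  M <- stats::median(m_p[!excluded])

  size_norm <- m$size
  f_p <- ifelse(e_p > 0, m_p / e_p, 1)   # an all-dead edge stays at zero
  g_p <- ifelse(excluded, NA_real_, M / m_p)
  if (perRing) {
    r1_p <- vapply(plates, function(p)
      stat(m$size[plate_key == p & outer_ring]), numeric(1))
    r2_p <- vapply(plates, function(p)
      stat(m$size[plate_key == p & is_edge & !outer_ring]), numeric(1))
    f1 <- ifelse(r1_p > 0, m_p / r1_p, 1)
    f2 <- ifelse(r2_p > 0, m_p / r2_p, 1)
    i <- match(plate_key, plates)
    size_norm <- size_norm *
      ifelse(is_edge, ifelse(outer_ring, f1[i], f2[i]), 1)
  } else {
    size_norm <- size_norm * ifelse(is_edge, f_p[match(plate_key, plates)], 1)
  }
  size_norm <- size_norm * g_p[match(plate_key, plates)]

  mm <- m
  mm$size_normalized <- unname(size_norm)
  out <- screen
  out@measurements <- mm

  first <- match(plates, plate_key)
  report <- S4Vectors::DataFrame(
    experiment_id = m$experiment_id[first],
    condition = m$condition[first],
    plate_id = m$plate_id[first],
    middle_mean = unname(m_p), edge_mean = unname(e_p),
    edge_factor = unname(f_p), target = M, plate_scale = unname(g_p),
    excluded = unname(excluded))
  list(screen = out, report = report)
}

#' Normality QC of screen t-statistics
#'
#' After linkage-biased genes are removed, the per-gene t-statistics of a
#' well-behaved screen are approximately normal apart from the planted
#' tail of true interactions. This advisory summary reports skewness,
#' excess kurtosis and a Shapiro-Wilk p-value; it never blocks the
#' pipeline.
#'
#' @param t_statistics numeric vector of per-gene t-statistics (at least
#'   20 finite values).
#' @return a list with `n`, `skewness`, `excess_kurtosis`, `shapiro_p`.
#' @export
qcTstatNormality <- function(t_statistics) {
  t <- t_statistics[is.finite(t_statistics)]
  n <- length(t)
  if (n < 20L)
    .insufficientData("need >= 20 finite t-statistics for normality QC")
  s <- stats::sd(t)
  if (s == 0)
    .configError("t-statistics have zero variance")
  z <- (t - mean(t)) / (s * sqrt((n - 1) / n))   # population sd for moments
  skew <- mean(z^3)
  kurt <- mean(z^4) - 3
  sh <- stats::shapiro.test(if (n > 5000) sample(t, 5000) else t)
  list(n = n, skewness = skew, excess_kurtosis = kurt,
       shapiro_p = unname(sh$p.value))
}
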