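# shared fixture builders; all data is generated in code

# a single-plate screen with explicit sizes laid out row-major
makePlateScreen <- function(sizes, rows, cols, plate_id = "p1",
                            condition = "control", experiment = "e1") {
  stopifnot(length(sizes) == rows * cols)
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  ColonyScreen(data.frame(
    screen_id = "fix", experiment_id = experiment, condition = condition,
    temperature = "25C", plate_id = plate_id,
    row = g$row, col = g$col,
    gene = sprintf("g%03d", seq_len(rows * cols)), replicate = 1L,
    size = sizes), plateRows = rows, plateCols = cols)
}

# stack several ColonyScreen objects into one
bindScreens <- function(...) {
  screens <- list(...)
  m <- do.call(rbind, lapply(screens, function(s)
    as.data.frame(measurements(s))))
  d <- plateDims(screens[[1]])
  ColonyScreen(m, plateRows = d["rows"], plateCols = d["cols"])
}

# independent closed-form paired t oracle (kept deliberately naive)
oraclePairedT <- function(control, test) {
  d <- control - test
  n <- length(d)
  m <- sum(d) / n
  s2 <- sum((d - m)^2) / (n - 1)
  t <- m / sqrt(s2 / n)
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# brute-force hypergeometric upper tail by direct enumeration with choose()
oracleHyperTail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force two-sided Fisher exact by enumerating all tables with the
# observed margins (minimum-likelihood convention)
oracleFisherTwoSided <- function(a, b, c, d) {
  # margins: row1 = a+b, row2 = c+d, col1 = a+c
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force linkage scan, one gene at a time
oracleLinked <- function(chrom, start0, end0, windows) {
  any(vapply(seq_len(nrow(windows)), function(w) {
    if (chrom != windows$chromosome[w]) return(FALSE)
    ctr <- windows$center[w]
    d <- if (ctr >= start0 && ctr < end0) 0
    else min(abs(ctr - start0), abs(ctr - (end0 - 1)))
    d <= windows$half_width[w]
  }, logical(1)))
}
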