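# Independent oracles used to cross-check the fitting paths.  These are
# deliberately naive (grid search, explicit loops) and share no code with
# the implementation.

# Zooming grid-search minimiser for the two-state intensity model.
oracle_two_state_grid <- function(conc, y, temperature_K,
                                  rounds = 10, npts = 11) {
  RT <- 8.314e-3 * temperature_K
  sse <- function(a, m, d50) {
    pred <- a / (1 + exp(m * (conc - d50) / RT))
    sum((y - pred)^2)
  }
  centre <- c(a = max(y), m = 2, d50 = stats::median(conc))
  width <- c(a = 0.6, m = 3, d50 = max(conc) / 2)
  for (r in seq_len(rounds)) {
    grids <- lapply(names(centre), function(p)
      seq(centre[[p]] - width[[p]], centre[[p]] + width[[p]],
          length.out = npts))
    names(grids) <- names(centre)
    grids$a <- pmax(grids$a, 1e-6)
    grids$m <- pmax(grids$m, 1e-4)
    grids$d50 <- pmax(grids$d50, 1e-6)
    best <- Inf
    for (a in grids$a) for (m in grids$m) for (d in grids$d50) {
      v <- sse(a, m, d)
      if (v < best) { best <- v; centre <- c(a = a, m = m, d50 = d) }
    }
    width <- width * 0.35
  }
  centre
}

# Brute-force recount of restraint range classes with an explicit loop.
oracle_classify_loop <- function(ri, rj) {
  counts <- c(intra = 0L, sequential = 0L, medium = 0L, long = 0L)
  for (k in seq_along(ri)) {
    s <- abs(ri[k] - rj[k])
    if (s == 0) counts["intra"] <- counts["intra"] + 1L
    else if (s == 1) counts["sequential"] <- counts["sequential"] + 1L
    else if (s <= 4) counts["medium"] <- counts["medium"] + 1L
    else counts["long"] <- counts["long"] + 1L
  }
  counts
}

# Convenience: corrected single-peak series from a generated table.
one_corrected_series <- function(tab, peak = NULL) {
  corr <- correct_series(tab)
  if (is.null(peak)) peak <- corr$peak_id[1]
  corr[corr$peak_id == peak, ]
}
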