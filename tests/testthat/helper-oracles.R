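# Shared helpers: an independent brute-force gradient-endpoint oracle
# and direct bundle constructors for capacity/validation edge cases.

# Exhaustive endpoint oracle on the same 0.1 degC grid the planner
# uses, written as a flat enumeration over expand.grid so it shares no
# code with the planner. Default endpoints (the range of the optima) are
# accepted outright when every reaction is within tolerance; otherwise
# the full grid is searched for the lexicographic optimum of
# (max clamped excess, max deviation, t_low, span).
bf_gradient <- function(ta, tol, n_zones = 12, window = 2.0, step = 0.1,
                        max_span = 24) {
  lo0 <- min(ta); hi0 <- max(ta)
  eval_at <- function(lo, hi) {
    zt <- if (n_zones == 1 || hi == lo) rep(lo, n_zones)
      else seq(lo, hi, length.out = n_zones)
    dev <- vapply(ta, function(t) min(abs(t - zt)), numeric(1))
    list(excess = max(pmax(dev - tol, 0)), max_dev = max(dev))
  }
  d0 <- eval_at(lo0, hi0)
  if (d0$excess <= 1e-12) {
    return(list(t_low = lo0, t_high = hi0, excess = d0$excess,
                max_dev = d0$max_dev))
  }
  ks <- seq(-window / step, window / step)
  grid <- expand.grid(i = ks, j = ks)
  lows <- lo0 + grid$i * step
  highs <- hi0 + grid$j * step
  keep <- highs >= lows - 1e-12 & (highs - lows) <= max_span + 1e-9
  lows <- lows[keep]; highs <- highs[keep]
  best <- NULL
  for (m in seq_along(lows)) {
    zt <- if (n_zones == 1 || highs[m] == lows[m]) rep(lows[m], n_zones)
      else seq(lows[m], highs[m], length.out = n_zones)
    dev <- vapply(ta, function(t) min(abs(t - zt)), numeric(1))
    excess <- max(pmax(dev - tol, 0))
    key <- c(round(excess, 9), round(max(dev), 9), round(lows[m], 9),
             round(highs[m] - lows[m], 9))
    take <- FALSE
    if (is.null(best)) take <- TRUE else {
      for (q in seq_along(key)) {
        if (key[q] < best$key[q]) { take <- TRUE; break }
        if (key[q] > best$key[q]) break
      }
    }
    if (take) best <- list(key = key, t_low = lows[m], t_high = highs[m],
                           excess = excess, max_dev = max(dev))
  }
  best
}

# Bundle with an exact combined count of distinct primers + templates:
# one shared template plus (count - 1) oligos paired into reactions.
bundle_with_capacity <- function(count) {
  m <- count - 1L
  n_pcr <- ceiling(m / 2)
  fwd <- paste0("cap_oligo_", 2L * seq_len(n_pcr) - 1L)
  rev <- paste0("cap_oligo_", pmin(2L * seq_len(n_pcr), m))
  oligos <- tibble::tibble(
    name = paste0("cap_oligo_", seq_len(m)),
    sequence = strrep("ACGT", 8), anneal_tm = 60, cost = NA_real_)
  pcrs <- tibble::tibble(
    id = seq_len(n_pcr), template_name = "cap_template",
    fwd_oligo = fwd, rev_oligo = rev,
    product_length = 1000L, ta_opt = 60, delta = NA_real_,
    note = NA_character_)
  pieces <- tibble::tibble(id = seq_len(n_pcr), source_pcr = seq_len(n_pcr),
                           length = 1000L, piece_kind = "homology")
  piece_ids <- if (n_pcr >= 2) list(seq_len(n_pcr)) else list(c(1L, 1L))
  combos <- tibble::tibble(construct_name = "cap_construct",
                           piece_ids = piece_ids)
  design_bundle(oligos, pcrs, pieces, combos, strategy = "aqua")
}

# fixture parsed into a bundle, one call
parsed_fixture <- function(spec, dir = withr::local_tempdir()) {
  fx <- generate_design(spec, dir = dir)
  parse_design(fx$path, strategy = spec$strategy)
}
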