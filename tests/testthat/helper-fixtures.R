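# Shared generators and independent brute-force oracles.

# seeded random tensor of standard shape
rand_tensor <- function(n, seed) {
  set.seed(seed)
  mod_tensor(array(rnorm(n * 48), dim = c(n, 2, 4, 3, 2)))
}

# random coverage track: disjoint sorted intervals on one chromosome
rand_track <- function(chrom, chrom_len, n_intervals, seed) {
  set.seed(seed)
  cuts <- sort(sample.int(chrom_len + 1L, 2L * n_intervals) - 1L)
  start <- cuts[seq(1, length(cuts), by = 2)]
  end <- cuts[seq(2, length(cuts), by = 2)]
  keep <- start < end
  data.frame(chrom = chrom, start = start[keep], end = end[keep],
             value = round(runif(sum(keep), -5, 5), 3),
             stringsAsFactors = FALSE)
}

# per-base accumulation oracle for bin_signal (single-chromosome tracks)
per_base_bin_oracle <- function(track, regions) {
  out <- numeric(nrow(regions))
  for (c in unique(regions$chrom)) {
    len <- max(regions$end[regions$chrom == c])
    base <- numeric(len)
    tr <- track[track$chrom == c, , drop = FALSE]
    for (i in seq_len(nrow(tr)))
      base[(tr$start[i] + 1):tr$end[i]] <-
        base[(tr$start[i] + 1):tr$end[i]] + tr$value[i]
    ri <- which(regions$chrom == c)
    for (r in ri)
      out[r] <- sum(base[(regions$start[r] + 1):regions$end[r]])
  }
  out
}

# interval set <-> per-base boolean mask on a toy chromosome
mask_from_peaks <- function(peaks, len) {
  m <- logical(len)
  for (i in seq_len(nrow(peaks)))
    m[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
  m
}

mask_to_peaks <- function(mask, chrom = "toy") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], stringsAsFactors = FALSE)
}

rand_peaks <- function(len, n_intervals, seed, chrom = "toy") {
  tr <- rand_track(chrom, len, n_intervals, seed)
  tr[, c("chrom", "start", "end")]
}

# quadratic-time step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# textbook Welch t-test oracle
welch_oracle <- function(a, b, alternative = "two.sided") {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), df),
              greater = pt(t, df, lower.tail = FALSE))
  list(t = t, df = df, p = p)
}

# full 48-condition label grid, replicate fastest
full_grid <- function() {
  lv <- condition_levels()
  g <- expand.grid(replicate = lv$replicate, phase = lv$phase,
                   mark = lv$mark, cell_line = lv$cell_line,
                   stringsAsFactors = FALSE)
  g[, c("cell_line", "mark", "phase", "replicate")]
}

recovery_stats <- function(selected_idx, planted) {
  tp <- length(intersect(selected_idx, planted))
  precision <- tp / max(1, length(selected_idx))
  recall <- tp / length(planted)
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}
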