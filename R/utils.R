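# Internal numeric helpers shared by the DSC and IMC signal-processing code.

# centered running mean with reflected ends; width forced odd
.running_mean <- function(y, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L || length(y) < width) return(y)
  half <- (width - 1L) %/% 2L
  ypad <- c(rev(y[seq_len(half) + 1L]), y, rev(y[length(y) - seq_len(half)]))
  as.numeric(stats::filter(ypad, rep(1 / width, width), sides = 2))[
    (half + 1L):(half + length(y))]
}

# local maxima of y with topographic prominence >= min_prom.
# Returns a data.frame(index, value, prominence) ordered by index.
.find_peaks <- function(y, min_prom = 0, min_sep = 1L) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(0), value = numeric(0),
                                prominence = numeric(0)))
  d <- diff(y)
  # strict rise then fall; plateaus resolved to their first point
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(data.frame(index = integer(0), value = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    v <- y[i]
    # walk left to the first higher point (or edge); key col is the min en route
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > v)
    lmin <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    right <- y[(i + 1L):n]
    higher_r <- which(right > v)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else min(right)
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prom
  pk <- data.frame(index = cand[keep], value = y[cand[keep]],
                   prominence = prom[keep])
  if (min_sep > 1L && nrow(pk) > 1L) {
    # greedy: keep the most prominent peak inside each min_sep neighbourhood
    ord <- order(-pk$prominence)
    taken <- logical(0)
    sel <- integer(0)
    for (j in ord) {
      if (!any(abs(pk$index[sel] - pk$index[j]) < min_sep)) sel <- c(sel, j)
    }
    pk <- pk[sort(sel), , drop = FALSE]
  }
  rownames(pk) <- NULL
  pk
}

# robust noise scale: 1.4826 * MAD of first differences / sqrt(2),
# insensitive to smooth trends underlying the signal
.noise_sd <- function(y) {
  stats::mad(diff(y)) / sqrt(2)
}

# linear interpolation of the crossing x where y passes through level
# between indices i and i+1
.cross_x <- function(x, y, i, level) {
  x[i] + (level - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
}
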