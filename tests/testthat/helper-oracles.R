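# Independent brute-force oracles used across tests. These deliberately
# re-derive results from first principles (loops, enumeration) rather than
# calling the package's vectorised implementations.

# Split-and-sum carbon by literal repetition of the stated rule: peel off
# 100 m^2 pieces while more than 200 m^2 remain in total.
oracle_carbon <- function(area, fraction = 0.47) {
  pieces <- if (area > 200) {
    k <- 0L
    rest <- area
    ps <- numeric()
    while (k < floor(area / 100)) {
      ps <- c(ps, 100)
      rest <- rest - 100
      k <- k + 1L
    }
    if (rest > 0) ps <- c(ps, rest)
    ps
  } else area
  total <- 0
  for (p in pieces) {
    total <- total + 3.9448 * p^1.1068 + 0.2693 * p^0.9441 + 0.8339 * p^1.1730
  }
  fraction * total
}

# Maximum-total-overlap one-to-one assignment by exhaustive enumeration
# (feasible only for a handful of crowns per side).
oracle_best_assignment <- function(overlap) {
  n <- nrow(overlap); m <- ncol(overlap)
  best <- -Inf; best_pairs <- NULL
  idx <- seq_len(m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(idx)) {
    tot <- 0
    pairs <- list()
    for (i in seq_len(min(n, m))) {
      if (overlap[i, p[i]] > 0) {
        tot <- tot + overlap[i, p[i]]
        pairs[[length(pairs) + 1L]] <- c(i, p[i])
      }
    }
    if (tot > best) { best <- tot; best_pairs <- pairs }
  }
  list(total = best, pairs = best_pairs)
}

# Percentile by hand: sort and linearly interpolate between order statistics.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Mosaic choice by stable sort over the full documented key.
oracle_select <- function(records) {
  cls <- drylandtrees::priority_class(records$month, records$off_nadir_deg)
  keep <- !is.na(cls)
  if (!any(keep)) return(NULL)
  r <- records[keep, , drop = FALSE]
  cls <- cls[keep]
  ord <- order(cls, r$cloud_pct, -r$sun_elev_deg, abs(r$off_nadir_deg),
               -r$year, r$image_id)
  r[ord[1], , drop = FALSE]
}

make_circle_df <- function(id, x, y, area) {
  data.frame(id = id, x = x, y = y, crown_area_m2 = area)
}
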