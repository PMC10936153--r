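# Independent brute-force oracles used to check the fast implementations.
# These deliberately recompute everything from first principles.

# histogram shared by the threshold oracles; mirrors the package's binning
# (integer-centred unit bins for in-range integer data, equal-width bins
# otherwise) — the exhaustive argmax search is what the oracles verify
oracle_histogram <- function(v, bins) {
  rng <- range(v)
  if (all(v == round(v)) && diff(rng) <= bins - 1) {
    return(list(counts = tabulate(v - rng[1] + 1, nbins = bins),
                centers = rng[1] + seq_len(bins) - 1))
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  list(counts = tabulate(idx, nbins = bins),
       centers = (breaks[-1] + breaks[-(bins + 1L)]) / 2)
}

# exhaustive two-class Otsu: between-class variance w0*w1*(mu0-mu1)^2 for
# every candidate cut, first maximum wins
oracle_otsu <- function(v, bins = 256L) {
  h <- oracle_histogram(v, bins)
  p <- h$counts / sum(h$counts)
  best_val <- -Inf
  best_thr <- NA_real_
  for (k in seq_len(bins - 1L)) {
    w0 <- sum(p[1:k])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:k] * h$centers[1:k]) / w0
    mu1 <- sum(p[(k + 1):bins] * h$centers[(k + 1):bins]) / w1
    val <- w0 * w1 * (mu0 - mu1)^2
    if (val > best_val) {
      best_val <- val
      best_thr <- h$centers[k]
    }
  }
  best_thr
}

# exhaustive three-class multi-Otsu over all ascending bin-center pairs,
# maximizing sum_c w_c (mu_c - mu)^2; lexicographically smallest tie
oracle_multi_otsu <- function(v, bins = 64L) {
  h <- oracle_histogram(v, bins)
  p <- h$counts / sum(h$counts)
  mu <- sum(p * h$centers)
  best_val <- -Inf
  best <- c(NA_real_, NA_real_)
  for (i in seq_len(bins - 2L)) {
    for (j in (i + 1L):(bins - 1L)) {
      cls <- list(1:i, (i + 1):j, (j + 1):bins)
      w <- vapply(cls, function(ix) sum(p[ix]), numeric(1))
      if (any(w <= 0)) next
      mus <- vapply(cls, function(ix) sum(p[ix] * h$centers[ix]), numeric(1)) / w
      val <- sum(w * (mus - mu)^2)
      if (val > best_val) {
        best_val <- val
        best <- h$centers[c(i, j)]
      }
    }
  }
  best
}

# queue-based flood fill, one component at a time
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  l1 <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- as.matrix(offs[switch(as.character(connectivity),
                                "6" = l1 == 1, "18" = l1 <= 2,
                                "26" = rep(TRUE, nrow(offs))), ])
  labels <- array(0L, d)
  nxt <- 0L
  for (lin in which(mask)) {
    if (labels[lin] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(arrayInd(lin, d), ncol = 3)
    labels[lin] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  labels
}

# two labelings are equivalent if they induce the same voxel partition
same_partition <- function(a, b) {
  fa <- a[a > 0]
  fb <- b[b > 0]
  if (length(fa) != length(fb)) return(FALSE)
  identical(unname(tapply(fb, fa, function(x) length(unique(x)))) |>
              (\(x) all(x == 1))(), TRUE) &&
    identical(unname(tapply(fa, fb, function(x) length(unique(x)))) |>
                (\(x) all(x == 1))(), TRUE)
}

# direct two-pass Pearson formula
oracle_pcc <- function(r, g) {
  sum((r - mean(r)) * (g - mean(g))) /
    sqrt(sum((r - mean(r))^2) * sum((g - mean(g))^2))
}

# hand sums-of-squares one-way ANOVA
oracle_anova_F <- function(gl) {
  grand <- mean(unlist(gl))
  ssb <- sum(vapply(gl, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ssw <- sum(vapply(gl, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- length(gl) - 1L
  df_w <- sum(lengths(gl)) - length(gl)
  (ssb / df_b) / (ssw / df_w)
}
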