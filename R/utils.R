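# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# a channel argument may be a plain numeric array or a channel_pair_volume
# component; always return a 3D numeric array (2D input promoted to z = 1)
as_volume3d <- function(x, arg = "volume") {
  if (!is.numeric(x) && !is.logical(x)) stopf("`%s` must be a numeric array", arg)
  d <- dim(x)
  if (is.null(d)) stopf("`%s` must have at least 2 dimensions", arg)
  if (length(d) == 2L) {
    x <- array(x, c(1L, d))
  } else if (length(d) != 3L) {
    stopf("`%s` must be a 2D or 3D array, got %d dimensions", arg, length(d))
  }
  x
}

# pairwise squared distance in um between two matrices of (z,y,x) rows
dist2_um <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}

# shift a 3D array by (dz,dy,dx) voxels, padding with `fill`
shift3 <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
  if (length(src_z) < 1 || length(src_y) < 1 || length(src_x) < 1) return(out)
  out[src_z + dz, src_y + dy, src_x + dx] <- a[src_z, src_y, src_x]
  out
}

# voxel-centre coordinates in um along one axis (0-based voxel convention)
axis_coords_um <- function(n, d) (seq_len(n) - 0.5) * d

# neighbourhood offsets (half-set excluded; full set returned) for 6/18/26
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("connectivity must be one of 6, 18, 26; got %s", connectivity)
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  l1 <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  keep <- switch(as.character(connectivity),
    "6"  = l1 == 1,
    "18" = l1 <= 2,
    "26" = rep(TRUE, nrow(g))
  )
  as.matrix(g[keep, , drop = FALSE])
}
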