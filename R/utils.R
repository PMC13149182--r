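# Internal numerics shared by the imaging modules: seeded RNG scoping,
# separable Gaussian blur, 2D binary morphology, hole filling, 3D connected
# components and bilinear sampling. All operate on plain R arrays.

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Banded convolution matrix for a normalized Gaussian kernel, edge-renormalized
#' @noRd
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])  # truncated-kernel renormalization
  }
  K
}

#' Separable 3D Gaussian blur; sigma_vox per array axis (voxels)
#' @noRd
gaussian_blur3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L)
  d <- dim(arr)
  if (sigma_vox[1] > 0) {
    K <- gauss_band(d[1], sigma_vox[1])
    arr <- array(K %*% matrix(arr, d[1]), d)
  }
  if (sigma_vox[2] > 0) {
    K <- gauss_band(d[2], sigma_vox[2])
    a2 <- aperm(arr, c(2, 1, 3))
    a2 <- array(K %*% matrix(a2, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(a2, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- gauss_band(d[3], sigma_vox[3])
    a3 <- aperm(arr, c(3, 1, 2))
    a3 <- array(K %*% matrix(a3, d[3]), c(d[3], d[1], d[2]))
    arr <- aperm(a3, c(2, 3, 1))
  }
  arr
}

#' Integer offsets of a flat disk structuring element of radius r (voxels)
#' @noRd
disk_offsets <- function(r) {
  r <- as.integer(r)
  if (r <= 0L) return(cbind(0L, 0L))
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[g$di^2 + g$dj^2 <= r^2, ]
  cbind(g$di, g$dj)
}

#' Shift a logical matrix by (di, dj), padding with FALSE
#' @noRd
shift2d <- function(m, di, dj) {
  n <- matrix(FALSE, nrow(m), ncol(m))
  src_i <- max(1L, 1L - di):min(nrow(m), nrow(m) - di)
  src_j <- max(1L, 1L - dj):min(ncol(m), ncol(m) - dj)
  if (length(src_i) == 0L || length(src_j) == 0L) return(n)
  n[src_i + di, src_j + dj] <- m[src_i, src_j]
  n
}

#' @noRd
binary_dilate2d <- function(m, r) {
  if (r <= 0) return(m)
  off <- disk_offsets(r)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) out <- out | shift2d(m, off[k, 1], off[k, 2])
  out
}

#' @noRd
binary_erode2d <- function(m, r) {
  if (r <= 0) return(m)
  !binary_dilate2d(!m, r)
}

#' Morphological closing (dilate then erode) with a disk of radius r
#' @noRd
binary_close2d <- function(m, r) binary_erode2d(binary_dilate2d(m, r), r)

#' Fill interior holes of a 2D mask: background connected (4-conn) to the
#' matrix border stays background, everything else becomes foreground.
#' @noRd
fill_holes2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  outside <- matrix(FALSE, nr, nc)
  # seed queue with all border background pixels
  queue <- integer(nr * nc); qn <- 0L
  push <- function(idx) { qn <<- qn + 1L; queue[qn] <<- idx }
  for (i in seq_len(nr)) for (j in c(1L, nc))
    if (!m[i, j] && !outside[i, j]) { outside[i, j] <- TRUE; push((j - 1L) * nr + i) }
  for (j in seq_len(nc)) for (i in c(1L, nr))
    if (!m[i, j] && !outside[i, j]) { outside[i, j] <- TRUE; push((j - 1L) * nr + i) }
  head <- 1L
  while (head <= qn) {
    idx <- queue[head]; head <- head + 1L
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    if (i > 1L && !m[i - 1L, j] && !outside[i - 1L, j]) { outside[i - 1L, j] <- TRUE; push(idx - 1L) }
    if (i < nr && !m[i + 1L, j] && !outside[i + 1L, j]) { outside[i + 1L, j] <- TRUE; push(idx + 1L) }
    if (j > 1L && !m[i, j - 1L] && !outside[i, j - 1L]) { outside[i, j - 1L] <- TRUE; push(idx - nr) }
    if (j < nc && !m[i, j + 1L] && !outside[i, j + 1L]) { outside[i, j + 1L] <- TRUE; push(idx + nr) }
  }
  !outside
}

#' Label 6-connected components of a 3D logical array.
#' Returns list(labels = integer array, sizes = named integer vector).
#' @noRd
label_components3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nvox <- prod(d)
  queue <- integer(0)
  current <- 0L
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  plane <- nr * nc
  idx_all <- which(mask)
  sizes <- integer(0)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    labels[start] <- current
    queue <- start
    count <- 0L
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      count <- count + length(cur)
      i0 <- ((cur - 1L) %% nr) + 1L
      j0 <- (((cur - 1L) %/% nr) %% nc) + 1L
      k0 <- ((cur - 1L) %/% plane) + 1L
      for (step in 1:6) {
        nb <- switch(step,
          ifelse(i0 > 1L, cur - 1L, NA_integer_),
          ifelse(i0 < nr, cur + 1L, NA_integer_),
          ifelse(j0 > 1L, cur - nr, NA_integer_),
          ifelse(j0 < nc, cur + nr, NA_integer_),
          ifelse(k0 > 1L, cur - plane, NA_integer_),
          ifelse(k0 < ns, cur + plane, NA_integer_))
        nb <- nb[!is.na(nb)]
        nb <- nb[mask[nb] & labels[nb] == 0L]
        if (length(nb)) {
          labels[nb] <- current
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
    sizes <- c(sizes, count)
  }
  list(labels = labels, sizes = sizes)
}

#' Bilinear sampling of a matrix at physical coordinates.
#' Pixel (i, j) center sits at x = (i - 0.5) * dx, y = (j - 0.5) * dy.
#' Out-of-grid coordinates sample as `fill`.
#' @noRd
bilinear_sample <- function(m, x, y, dx, dy, fill = 0) {
  fi <- x / dx + 0.5   # fractional row index
  fj <- y / dy + 0.5
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  nr <- nrow(m); nc <- ncol(m)
  get <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    v <- rep(fill, length(i))
    if (any(ok)) v[ok] <- m[cbind(i[ok], j[ok])]
    v
  }
  v00 <- get(i0, j0); v10 <- get(i0 + 1, j0)
  v01 <- get(i0, j0 + 1); v11 <- get(i0 + 1, j0 + 1)
  (1 - wi) * (1 - wj) * v00 + wi * (1 - wj) * v10 +
    (1 - wi) * wj * v01 + wi * wj * v11
}
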