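# Internal numerical helpers shared across modules.

# Shift a matrix by integer (dr, dc), zero-padding the exposed border.
shift_int <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Bilinear sampling of `m` at (row + dr, col + dc) for every pixel, i.e. the
# image translated by (-dr, -dc).  Border values are replicated.
warp_translate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  c <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  r0 <- floor(r); r1 <- pmin(r0 + 1, nr); fr <- r - r0
  c0 <- floor(c); c1 <- pmin(c0 + 1, nc); fc <- c - c0
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  m[r0, c0] * (1 - wr) * (1 - wc) + m[r1, c0] * wr * (1 - wc) +
    m[r0, c1] * (1 - wr) * wc + m[r1, c1] * wr * wc
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find pass.
label8 <- function(mask) {
  stopifnot(is.logical(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { i <- as.integer(i); while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (d in list(c(1, 1), c(1, -1))) {
    sh <- shift_int(lab, d[1], d[2])
    sel <- lab > 0 & sh > 0 & lab != sh
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], sh[sel]))
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[b] <- a
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, unique(roots))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Pearson correlation that treats zero-variance input as uncorrelated
# instead of propagating NaN (flat pixels must classify as background).
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# Least-squares slope of y on x (n small, no lm() overhead).
ls_slope <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) / sum((x - xm)^2)
}

# Design matrix of a 2-D polynomial surface of given total degree on
# normalised [0,1]^2 coordinates.
poly2d_design <- function(rows, cols, nr, nc, degree) {
  x <- (rows - 1) / max(nr - 1, 1)
  y <- (cols - 1) / max(nc - 1, 1)
  terms <- list()
  for (i in 0:degree) for (j in 0:(degree - i)) terms[[length(terms) + 1]] <- x^i * y^j
  do.call(cbind, terms)
}
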