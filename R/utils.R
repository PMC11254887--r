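#' @useDynLib splitgfr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois qnorm qt rnorm runif var cor sd
#' @importFrom utils write.csv read.csv modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. All stochastic operations in the
# package take explicit seeds and go through this helper (no global state).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying below
# 2^31 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483629
  as.integer(h)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# ---- resampling helpers ------------------------------------------------------

#' Bilinear resize of a numeric matrix
#'
#' Pixel-centre aligned bilinear interpolation, used to upsample 64x64 raw
#' frames to the network input grid.
#'
#' @param m numeric matrix.
#' @param out_dim integer vector (rows, cols) of the target size; a single
#'   number is recycled.
#' @return numeric matrix of size `out_dim`.
#' @keywords internal
resize_bilinear <- function(m, out_dim) {
  out_dim <- rep_len(as.integer(out_dim), 2L)
  nr <- nrow(m); nc <- ncol(m)
  # map output pixel centres to input pixel-centre coordinates (identity when
  # sizes match)
  src_r <- pmin(pmax((seq_len(out_dim[1]) - 0.5) * nr / out_dim[1] + 0.5, 1), nr)
  src_c <- pmin(pmax((seq_len(out_dim[2]) - 0.5) * nc / out_dim[2] + 0.5, 1), nc)
  i0 <- pmax(pmin(floor(src_r), nr - 1L), 1L); i1 <- pmin(i0 + 1L, nr)
  j0 <- pmax(pmin(floor(src_c), nc - 1L), 1L); j1 <- pmin(j0 + 1L, nc)
  fr <- src_r - i0
  fc <- src_c - j0
  a <- m[i0, j0, drop = FALSE]; b <- m[i0, j1, drop = FALSE]
  d <- m[i1, j0, drop = FALSE]; e <- m[i1, j1, drop = FALSE]
  wr <- matrix(fr, out_dim[1], out_dim[2])
  wc <- matrix(fc, out_dim[1], out_dim[2], byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * d + wc * e)
}

# Nearest-neighbour resize (used for binary label masks).
resize_nearest <- function(m, out_dim) {
  out_dim <- rep_len(as.integer(out_dim), 2L)
  ri <- pmin(pmax(floor((seq_len(out_dim[1]) - 0.5) * nrow(m) / out_dim[1]) + 1L, 1L), nrow(m))
  ci <- pmin(pmax(floor((seq_len(out_dim[2]) - 0.5) * ncol(m) / out_dim[2]) + 1L, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Block reduction by an integer factor with `fun` ("mean" or "max").
block_reduce <- function(m, factor, fun = c("mean", "max")) {
  fun <- match.arg(fun)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr %% factor == 0, nc %% factor == 0)
  a <- array(m, dim = c(factor, nr / factor, factor, nc / factor))
  if (fun == "mean") apply(a, c(2, 4), mean) else apply(a, c(2, 4), max)
}

# Length of overlap between raw-pixel intervals and panel-pixel intervals for
# fractional rescaling (rows n_to, cols n_from). Row i of the result holds the
# overlap of target interval i with each source interval, summing to
# n_from/n_to.
overlap_weights <- function(n_from, n_to) {
  s <- n_from / n_to
  w <- matrix(0, n_to, n_from)
  for (i in seq_len(n_to)) {
    lo <- (i - 1) * s; hi <- i * s
    j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
    for (j in j0:min(j1, n_from)) {
      w[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
    }
  }
  w
}

# ---- binary mask helpers -----------------------------------------------------

as_mask <- function(m) {
  if (is.logical(m)) mode(m) <- "integer"
  if (!all(m %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

mask_empty <- function(m) sum(m) == 0

# Shift a matrix by (dr, dc), zero-filling exposed borders.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

# Offsets of a Euclidean disc of radius r (r >= 0); always includes (0,0).
disc_offsets <- function(r) {
  k <- floor(r)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}
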