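# Internal helpers shared across modules.

abort_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_param(field, "must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(field, "must be a single finite number")
  }
  if (integer && x != round(x)) abort_param(field, "must be a whole number")
  if (x < lower || x > upper) {
    abort_param(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(NULL)
}

# Shift a matrix by (dr, dc), padding with `fill`. dr > 0 moves content down,
# dc > 0 moves it right; shift_mat(m, -1, 0)[i, j] is m[i + 1, j].
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Offsets of the 8-neighbourhood, row-major clockwise from north.
NEIGH8 <- cbind(
  dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
  dc = c(0, 1, 1, 1, 0, -1, -1, -1)
)

# Gaussian blur that accepts and returns a plain matrix. The filter radius
# is capped so small windows remain blurable.
gblur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  largest <- min(dim(m))
  if (largest %% 2L == 0L) largest <- largest - 1L
  radius <- min(radius, largest)
  if (radius < 3L) return(m)
  as.matrix(EBImage::imageData(EBImage::gblur(m, sigma = sigma,
                                              radius = radius)))
}

as_logical_mask <- function(m, field = "mask") {
  if (is.null(dim(m)) || length(dim(m)) != 2L) {
    abort_param(field, "must be a 2-D matrix")
  }
  mode(m) <- "logical"
  m & !is.na(m)
}

# Deterministic derived seed kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 104729 + as.double(index) * 7919) %% 2147483629L)
}
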