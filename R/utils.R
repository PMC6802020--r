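# Internal numerical helpers shared across modules.

# Separable Gaussian blur of a matrix; sd in cell units. Edge handling is
# truncation (kernel renormalized per position via blurring a ones-mask),
# so a flat field stays flat.
gaussian_blur <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(4 * sd_cells))
  k <- stats::dnorm(seq(-half, half), sd = sd_cells)
  k <- k / sum(k)
  na_mask <- is.na(m)
  m0 <- m
  m0[na_mask] <- 0
  ones <- matrix(1, nrow(m), ncol(m))
  ones[na_mask] <- 0
  conv1 <- function(mat) {
    # convolve along rows then columns with kernel k
    pad <- half
    nr <- nrow(mat); nc <- ncol(mat)
    out <- matrix(0, nr, nc)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(nc) + off
      ok <- src >= 1L & src <= nc
      out[, ok] <- out[, ok] + k[j] * mat[, src[ok], drop = FALSE]
    }
    out2 <- matrix(0, nr, nc)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(nr) + off
      ok <- src >= 1L & src <= nr
      out2[ok, ] <- out2[ok, ] + k[j] * out[src[ok], , drop = FALSE]
    }
    out2
  }
  num <- conv1(m0)
  den <- conv1(ones)
  res <- num / pmax(den, .Machine$double.eps)
  res[na_mask] <- NA_real_
  res
}

# Stratified fold assignment: returns integer fold id per row, both
# classes spread as evenly as possible across folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Derive a reproducible child seed (< 2^31) from a base seed and a tag.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
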