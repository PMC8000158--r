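## Undecimated (stationary) wavelet transform used by the wavelet
## baseline-removal filter. The transform is shift-invariant, so a
## subband-zeroing bandpass acts as a single linear time-invariant operator
## on the (mirror-extended) record -- repeated beats receive identical
## treatment, which matters for the beat averaging that runs downstream of
## this filter. No wavelet package ships with the environment, so the
## transform is implemented here with Coiflet filter coefficients (4
## vanishing moments, 12 taps) frozen from PyWavelets 1.9.0 as a numeric
## constant.

coif2_filters <- function() {
  dec_lo <- c(-0.000720549445520347, -0.0018232088709110323,
              0.005611434819368834, 0.02368017194684777,
              -0.05943441864643109, -0.07648859907828076,
              0.4170051844232391, 0.8127236354494135,
              0.3861100668227629, -0.0673725547237256,
              -0.04146493678687178, 0.01638733646320364)
  dec_hi <- rev(dec_lo) * (-1)^(seq_along(dec_lo))
  list(dec_lo = dec_lo, dec_hi = dec_hi)
}

## circularly shift matrix columns left by s (s >= 0)
col_rotate <- function(X, s) {
  n <- ncol(X)
  s <- s %% n
  if (s == 0L) return(X)
  X[, c((s + 1L):n, 1L:s), drop = FALSE]
}

## one analysis level: circular correlation of every row with the filter
## upsampled by `up` (a trous); returns list(a=, d=)
swt_level <- function(A, filt, up) {
  a <- d <- matrix(0, nrow(A), ncol(A))
  for (m in seq_along(filt$dec_lo)) {
    S <- col_rotate(A, (m - 1L) * up)
    a <- a + filt$dec_lo[m] * S
    d <- d + filt$dec_hi[m] * S
  }
  list(a = a, d = d)
}

## one synthesis level: adjoint of the analysis pair; for an orthonormal
## filter pair H'H + G'G = 2I, hence the 1/2
iswt_level <- function(a, d, filt, up) {
  out <- matrix(0, nrow(a), ncol(a))
  for (m in seq_along(filt$dec_lo)) {
    out <- out + col_rotate(filt$dec_lo[m] * a + filt$dec_hi[m] * d,
                            -(m - 1L) * up)
  }
  out / 2
}

## Wavelet bandpass of the rows of X: keep detail scales whose nominal band
## [fs/2^(j+1), fs/2^j] lies within [f_lo, f_hi]; drop the approximation
## and all other scales. The record is symmetrically mirror-extended and
## padded to a power of two; `levels` requests the decomposition depth,
## capped at the deepest level the padded record supports (deeper levels
## only re-partition coefficients that are zeroed anyway, so the cap does
## not change the output).
wavelet_bandpass <- function(X, fs_hz, f_lo = 0.5, f_hi = 150, levels = 20) {
  one_row <- is.null(dim(X))
  if (one_row) X <- matrix(X, 1)
  n <- ncol(X)
  N <- 2^ceiling(log2(2 * n))
  refl <- c(seq_len(n), rev(seq_len(n)))
  E <- X[, refl[((seq_len(N) - 1L) %% (2L * n)) + 1L], drop = FALSE]
  filt <- coif2_filters()
  J <- min(levels, as.integer(log2(N)))
  keep <- vapply(seq_len(J), function(j) {
    fs_hz / 2^(j + 1) >= f_lo && fs_hz / 2^j <= f_hi
  }, logical(1))
  if (!any(keep)) return(X * 0)
  ## decomposing past the deepest kept scale is redundant: the level-J
  ## approximation and every non-kept detail are dropped either way
  J <- max(which(keep))
  kept <- vector("list", J)
  A <- E
  for (j in seq_len(J)) {
    lv <- swt_level(A, filt, 2^(j - 1L))
    if (keep[j]) kept[[j]] <- lv$d
    A <- lv$a
  }
  A[] <- 0                                  # approximation dropped
  zero <- matrix(0, nrow(E), ncol(E))
  for (j in rev(seq_len(J))) {
    A <- iswt_level(A, kept[[j]] %||% zero, filt, 2^(j - 1L))
  }
  out <- A[, seq_len(n), drop = FALSE]
  if (one_row) out[1, ] else out
}
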