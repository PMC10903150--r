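# internal helpers shared across modules

# coerce a logical/0-1 array to integer storage for the C++ kernels
as_binary_array <- function(x, arg = "x") {
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    stop(sprintf("`%s` must be a 3D array", arg), call. = FALSE)
  }
  v <- as.vector(x)
  if (is.logical(v)) {
    if (anyNA(v)) stop(sprintf("`%s` contains NA", arg), call. = FALSE)
    iv <- as.integer(v)
  } else if (is.numeric(v)) {
    if (anyNA(v)) stop(sprintf("`%s` contains NA", arg), call. = FALSE)
    if (!all(v %in% c(0, 1))) {
      stop(sprintf("`%s` must be binary (0/1 or logical)", arg), call. = FALSE)
    }
    iv <- as.integer(v)
  } else {
    stop(sprintf("`%s` must be logical or numeric 0/1", arg), call. = FALSE)
  }
  array(iv, dim = dim(x))
}

# voxel volume in litres (1 L = 1e6 mm^3)
voxel_volume_l <- function(spacing_mm) {
  prod(spacing_mm) / 1e6
}

stopifnot_scalar <- function(x, arg, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a scalar in [%s, %s]", arg, lo, hi), call. = FALSE)
  }
  invisible(x)
}

# derive a stream of child seeds from one master seed, staying inside 32-bit
child_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
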