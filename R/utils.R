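# internal helpers shared across modules

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (nonnegative && x < 0) abort(sprintf("`%s` must be nonnegative.", name))
  invisible(x)
}

# physical position (mm) of the centre of 1-based voxel index i at given spacing
index_to_mm <- function(i, spacing) (i - 0.5) * spacing

mm_to_index <- function(mm, spacing) mm / spacing + 0.5
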