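# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministically derive a child seed from a root seed and a stage label.
# Stays below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stopf("voxel spacing must be three strictly positive numbers, got (%s)",
          paste(spacing, collapse = ", "))
  as.numeric(spacing)
}

# Voxel volume in mL (spacing is mm per axis; 1000 mm^3 = 1 mL)
voxel_ml <- function(spacing) prod(spacing) / 1000
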