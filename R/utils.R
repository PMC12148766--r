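# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporarily fixed RNG state; NULL seed = use current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(values, what) {
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(values))
    stop_("%s contains a non-finite value; first offending voxel index (%d, %d, %d)",
          what, idx[1L], idx[2L], idx[3L])
  }
  invisible(TRUE)
}

# linear index from (i, j, k) matrix, 1-based
lin_index <- function(ijk, dm) {
  ijk[, 1L] + (ijk[, 2L] - 1L) * dm[1L] + (ijk[, 3L] - 1L) * dm[1L] * dm[2L]
}

# world coordinates (mm) of voxel centers for 1-based index matrix
world_coords <- function(ijk, spacing, origin) {
  cbind(origin[1L] + (ijk[, 1L] - 1) * spacing[1L],
        origin[2L] + (ijk[, 2L] - 1) * spacing[2L],
        origin[3L] + (ijk[, 3L] - 1) * spacing[3L])
}
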