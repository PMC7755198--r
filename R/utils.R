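#' Round half away from zero
#'
#' Presentation rounding used for all tabular output: exact halves round up
#' (e.g. `round_half_up(0.5) == 1`), unlike [base::round()]'s round-half-even.
#' Applied only when formatting tables, never inside intermediate arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(13101.77, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Write `lines`/data to `path` via a sibling temporary file and an atomic
# rename, so partially written outputs are never observed.
write_atomically <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
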