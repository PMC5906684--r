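# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_VALID <- c(AA20, "X")
AROMATIC <- c("Y", "W", "F", "H")

#' @noRd
stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  seed <- as.integer(seed)  # force the promise before saving RNG state
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

#' @noRd
is_prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1

# Euclidean norm of rows of a matrix (or of a single vector).
#' @noRd
row_norms <- function(m) {
  if (is.null(dim(m))) sqrt(sum(m^2)) else sqrt(rowSums(m^2))
}
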