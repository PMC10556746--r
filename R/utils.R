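# Internal helpers shared across the package.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the ambient stream" (needed so nested stochastic
# steps inside an outer with_seed() stay on one reproducible path).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Stable string hash (polynomial rolling hash mod 2^31 - 1) of the master
#' seed together with any number of labels. Used so that every stage of a
#' pipeline, and every cell of a benchmark, gets its own seed that does not
#' shift when unrelated cells are added or removed.
#'
#' @param seed integer master seed.
#' @param ... character or numeric labels identifying the consumer.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "split")
#' derive_seed(1, "GOS", "cars", 3)
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

stop_nircal <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

as_matrix_x <- function(X) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_nircal("'X' must be a numeric matrix (or a spectra_set)")
  }
  X
}

row_label <- function(X, i) {
  rn <- rownames(X)
  if (is.null(rn)) paste0("row ", i) else paste0("sample '", rn[i], "'")
}
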