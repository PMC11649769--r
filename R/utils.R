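#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded generators never perturb the global random stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
geometric_mean <- function(x) exp(mean(log(x)))

# deterministic base-4 encoding of 1-based indices into nucleotide barcodes;
# unique by construction for i <= 4^width
make_barcodes <- function(n, width = 18L) {
  if (n == 0L) return(character(0))
  alphabet <- c("A", "C", "G", "T")
  v <- seq_len(n) - 1L
  digits <- matrix("A", nrow = n, ncol = width)
  for (j in seq_len(width)) {
    digits[, width - j + 1L] <- alphabet[(v %% 4L) + 1L]
    v <- v %/% 4L
  }
  apply(digits, 1L, paste0, collapse = "")
}
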