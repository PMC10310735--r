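# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# scalar validators; stop with informative messages
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_matrix <- function(x, what = "matrix") {
  assert_that(is.matrix(x) && is.numeric(x), paste(what, "must be a numeric matrix"))
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              paste(what, "must have row and column names"))
  invisible(TRUE)
}

#' Adjusted Rand index between two label vectors
#'
#' Measures agreement between two partitions of the same samples, corrected
#' for chance; 1 means identical partitions (up to relabelling), 0 is the
#' expectation under independent random partitions.
#'
#' @param a,b label vectors of equal length.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < .Machine$double.eps) return(0)
  (sum_ij - expected) / (max_idx - expected)
}
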