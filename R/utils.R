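#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to compare recovered clades with simulator truth (1 = identical
#' partitions up to renumbering, ~0 = random agreement).
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("partitions must have equal length")
  tab <- table(x, y)
  n <- sum(tab)
  choose2 <- function(v) sum(choose(v, 2))
  sum_ij <- choose2(as.vector(tab))
  sum_i <- choose2(rowSums(tab))
  sum_j <- choose2(colSums(tab))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# timestamped logging to stderr; results go to files/stdout only
pp_log_level <- function() {
  lv <- getOption("phaeopop.log_level", "info")
  match(lv, c("quiet", "info", "debug"), nomatch = 2L)
}

pp_log <- function(..., level = "info") {
  if (match(level, c("quiet", "info", "debug")) > pp_log_level()) return(invisible())
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), "[phaeopop] ", ...)
}

# run code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
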