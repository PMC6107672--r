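#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never disturbs the
#' caller's RNG stream. All stochastic stages of the pipeline go through this.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Each pipeline stage consumes its own derived seed so that inserting or
#' removing one stage never shifts the randomness of the others. The
#' derivation is a fixed integer hash of the stage name, kept below 2^31.
#'
#' @param master integer master seed
#' @param stage character stage tag, e.g. `"layout"`, `"panel"`
#' @return an integer seed in `[0, 2^31)`
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 69069 + h * 40503) %% 2147483647)
}

#' Two-class Otsu threshold
#'
#' Maximizes between-class variance over a histogram of the input values.
#' Used to split the averaged, rescaled marker image into low (tm) and high
#' (tam) pixels.
#'
#' @param x numeric vector
#' @param n_bins number of histogram bins
#' @return threshold value; values `> threshold` form the high class
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    stop("otsu_threshold: input is constant, no bimodal structure")
  }
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Min-max rescale to [0, 1]
#' @keywords internal
rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[2] == r[1]) stop("rescale01: constant input")
  (x - r[1]) / (r[2] - r[1])
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index, used to compare segmentation maps with
#' ground-truth region masks.
#'
#' @param a,b label vectors of equal length
#' @return ARI in \[-1, 1\]; 1 means identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

msg <- function(...) message("[msimarkers] ", sprintf(...))
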