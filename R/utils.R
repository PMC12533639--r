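#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats median rnorm runif rbinom rgeom qlnorm plnorm rmultinom
#'   t.test aov anova chisq.test cor cor.test pt setNames complete.cases
#' @importFrom utils read.delim write.table head
#' @importFrom graphics hist
NULL

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

# Format a percentage at 2 significant figures, as printed in cohort reports
# (e.g. 0.31%, 0.075%). Zero renders as "0.0%".
format_pct_2sig <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x))
  if (x == 0) return("0.0%")
  paste0(format(signif(x, 2), scientific = FALSE, trim = TRUE), "%")
}

# Truncated log-normal: sampling by inverse CDF and interval mass.
rlnorm_trunc <- function(n, meanlog, sdlog, min_len, max_len) {
  plo <- plnorm(min_len, meanlog, sdlog)
  phi <- plnorm(max_len, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

plnorm_trunc_mass <- function(lo, hi, meanlog, sdlog, min_len, max_len) {
  lo <- max(lo, min_len); hi <- min(hi, max_len)
  if (hi <= lo) return(0)
  denom <- plnorm(max_len, meanlog, sdlog) - plnorm(min_len, meanlog, sdlog)
  (plnorm(hi, meanlog, sdlog) - plnorm(lo, meanlog, sdlog)) / denom
}
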