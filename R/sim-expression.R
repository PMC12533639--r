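#' Co-simulate marker-gene expression linked to eccDNA burden
#'
#' Generates an expression table whose marker genes depend linearly on
#' per-sample eccDNA burden: `x[g, s] = alpha[g] + beta * burden[s] +
#' N(0, sigma^2)`. With `sigma = 0` every marker correlates perfectly with
#' burden; used to verify that the cohort layer recovers known
#' burden-expression correlations.
#'
#' @param sample_burdens numeric vector of per-sample eccDNA counts
#'   (at least 3 samples).
#' @param beta slope linking burden to expression.
#' @param sigma Gaussian noise standard deviation (`>= 0`).
#' @param seed integer seed.
#' @param markers character vector of marker gene names.
#' @param alpha per-marker intercepts (recycled; default `100 * seq`).
#' @return A data.frame with `sample_id`, `burden` and one column per
#'   marker.
#' @export
cosimulate_expression <- function(sample_burdens, beta, sigma, seed = 1L,
                                  markers = c("marker_1", "marker_2",
                                              "marker_3"),
                                  alpha = NULL) {
  n <- length(sample_burdens)
  if (n < 3L) stop_invalid("need at least 3 samples, got %d", n)
  if (!is.numeric(sigma) || sigma < 0) stop_invalid("`sigma` must be >= 0")
  if (is.null(alpha)) alpha <- 100 * seq_along(markers)
  alpha <- rep_len(alpha, length(markers))
  tab <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                    burden = sample_burdens, stringsAsFactors = FALSE)
  vals <- with_seed(seed, {
    lapply(seq_along(markers), function(g)
      alpha[g] + beta * sample_burdens + rnorm(n, 0, sigma))
  })
  for (g in seq_along(markers)) tab[[markers[g]]] <- vals[[g]]
  tab
}
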