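#' Evaluate a catalog against simulation ground truth
#'
#' Matches calls to true circles on the same chromosome with both
#' breakpoints within `tolerance` bp (each true circle and each call is
#' matched at most once, greedily by total breakpoint distance), then
#' reports recall and precision.
#'
#' @param truth a `true_circles` data.frame (see [sample_circles()]).
#' @param catalog a `circle_catalog` or its call data.frame.
#' @param tolerance breakpoint tolerance, bp.
#' @return List with `recall`, `precision`, `n_truth`, `n_calls`,
#'   `n_matched`, and `matches` (data.frame `circle_id`, `call_id`,
#'   `start_error`, `end_error`).
#' @export
evaluate_calls <- function(truth, catalog, tolerance = 5L) {
  calls <- if (inherits(catalog, "circle_catalog")) catalog$calls
  else catalog
  pairs <- NULL
  if (nrow(truth) > 0 && nrow(calls) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      k <- which(calls$chrom == truth$chrom[i] &
                   abs(calls$start - truth$start[i]) <= tolerance &
                   abs(calls$end - truth$end[i]) <= tolerance)
      if (length(k) == 0L) return(NULL)
      data.frame(ti = i, ci = k,
                 dist = abs(calls$start[k] - truth$start[i]) +
                   abs(calls$end[k] - truth$end[i]))
    }))
    if (!is.null(cand) && nrow(cand) > 0) {
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_t <- logical(nrow(truth)); used_c <- logical(nrow(calls))
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        if (!used_t[cand$ti[r]] && !used_c[cand$ci[r]]) {
          keep[r] <- TRUE
          used_t[cand$ti[r]] <- TRUE
          used_c[cand$ci[r]] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(
        circle_id = truth$circle_id[cand$ti],
        call_id = calls$call_id[cand$ci],
        start_error = calls$start[cand$ci] - truth$start[cand$ti],
        end_error = calls$end[cand$ci] - truth$end[cand$ti],
        stringsAsFactors = FALSE)
    }
  }
  n_matched <- if (is.null(pairs)) 0L else nrow(pairs)
  list(recall = if (nrow(truth) > 0) n_matched / nrow(truth) else NA_real_,
       precision = if (nrow(calls) > 0) n_matched / nrow(calls)
       else NA_real_,
       n_truth = nrow(truth), n_calls = nrow(calls),
       n_matched = n_matched,
       matches = pairs)
}
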