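# Incremental cost-effectiveness synthesis: delta cost, delta QALYs, ICER
# with dominance handling, and net monetary benefit.

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes the incremental cost and effect of \code{new} over \code{ref} and
#' synthesizes them into an ICER, flagging dominance instead of reporting a
#' misleading ratio: \code{"dominant"} when the new strategy is cheaper and
#' more effective, \code{"dominated"} when it is costlier and less effective,
#' \code{"undefined"} when the effect difference is zero.  Net monetary
#' benefit at the willingness-to-pay threshold is always reported.
#'
#' @param ref,new outcome objects with elements \code{cost} and \code{qalys}
#'   (e.g. \code{strategy_outcome}s or the per-dispatched averages from
#'   \code{compare_strategies}); both must be computed under the same
#'   perspective if they carry one
#' @param wtp willingness-to-pay threshold in euros per QALY
#' @param perspective optional label stored in the result
#' @return an object of class \code{cea_result} with \code{delta_cost},
#'   \code{delta_qalys}, \code{icer} (number or NA), \code{dominance} flag,
#'   \code{nmb} and \code{wtp}
#' @examples
#' icer(list(cost = 17923, qalys = 2.23), list(cost = 20471, qalys = 2.29))
#' @export
icer <- function(ref, new, wtp = 47901, perspective = NULL) {
  pr <- ref$perspective; pn <- new$perspective
  if (!is.null(pr) && !is.null(pn) && !identical(pr, pn))
    stop("perspective mismatch: '", pr, "' vs '", pn, "'")
  if (is.null(perspective)) perspective <- if (!is.null(pr)) pr else NA_character_
  stopifnot(is.numeric(ref$cost), is.numeric(new$cost),
            is.numeric(ref$qalys), is.numeric(new$qalys), wtp >= 0)
  dc <- new$cost - ref$cost
  de <- new$qalys - ref$qalys
  dominance <- if (de > 0 && dc < 0) "dominant"
               else if (de < 0 && dc > 0) "dominated"
               else if (de == 0) "undefined"
               else "none"
  ratio <- if (dominance == "none") dc / de else NA_real_
  structure(list(delta_cost = dc, delta_qalys = de, icer = ratio,
                 dominance = dominance, wtp = wtp,
                 nmb = wtp * de - dc, perspective = perspective),
            class = "cea_result")
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' \code{wtp * delta_qalys - delta_cost}; linear and (for positive
#' incremental effect) strictly increasing in the threshold, zero exactly at
#' the ICER.
#'
#' @param result a \code{cea_result}
#' @param wtp threshold(s) in euros per QALY; vectorized
#' @return euros (same length as \code{wtp})
#' @export
nmb <- function(result, wtp = result$wtp) {
  stopifnot(inherits(result, "cea_result"), all(wtp >= 0))
  wtp * result$delta_qalys - result$delta_cost
}

#' @export
print.cea_result <- function(x, ...) {
  icer_txt <- if (x$dominance == "none")
    paste0("EUR ", format(round(x$icer), big.mark = ","), "/QALY")
  else x$dominance
  cat(sprintf("Incremental analysis (%s): dC = EUR %s, dE = %.4f QALYs, ICER = %s, NMB(EUR %s) = EUR %s\n",
              ifelse(is.na(x$perspective), "unspecified perspective", x$perspective),
              format(round(x$delta_cost), big.mark = ","), x$delta_qalys, icer_txt,
              format(x$wtp, big.mark = ","), format(round(x$nmb), big.mark = ",")))
  invisible(x)
}
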