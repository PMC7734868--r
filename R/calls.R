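#' Prediction call categories
#'
#' The common four-category vocabulary used throughout the package for
#' harmonized (Q)SAR mutagenicity calls: `POSITIVE`, `NEGATIVE`,
#' `EQUIVOCAL` and `OOD` (out-of-domain).
#'
#' @format A character vector of length four.
#' @export
CALL_LEVELS <- c("POSITIVE", "NEGATIVE", "EQUIVOCAL", "OOD")

# Severity order used by the consensus rules: the consensus of two calls is
# the more severe one under POSITIVE > EQUIVOCAL > OOD > NEGATIVE.
CALL_SEVERITY <- c(POSITIVE = 4L, EQUIVOCAL = 3L, OOD = 2L, NEGATIVE = 1L)

#' Coerce a character vector to call categories
#'
#' @param x character vector of calls.
#' @return `x`, validated to contain only the four call categories.
#' @keywords internal
as_call <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), CALL_LEVELS)
  if (length(bad) > 0) {
    stop("unknown call categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "),
         " (expected one of ", paste(CALL_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  }
  x
}

#' Factor with the four call categories in canonical order
#' @param x character vector of calls.
#' @keywords internal
call_factor <- function(x) factor(as_call(x), levels = CALL_LEVELS)
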