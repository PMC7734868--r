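# ICH M7 consensus: combine one statistical and one rule-based call.

#' Consensus call from a statistical and a rule-based prediction
#'
#' Applies the consensus rules for two complementary (Q)SAR models:
#' positive if either model is positive; else equivocal if either is
#' equivocal; negative only if both are negative; a negative paired with an
#' out-of-domain result, or two out-of-domain results, give `OOD`. Two
#' equivocal calls resolve to `EQUIVOCAL`. The function is symmetric in its
#' two arguments and equals the maximum under the severity order
#' `POSITIVE > EQUIVOCAL > OOD > NEGATIVE`.
#'
#' @param stat_call,rule_call character vectors of calls (recycled to a
#'   common length).
#' @return Character vector of consensus calls.
#' @export
consensus_call <- function(stat_call, rule_call) {
  a <- as_call(stat_call)
  b <- as_call(rule_call)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- character(n)
  is_pos <- a == "POSITIVE" | b == "POSITIVE"
  is_eqv <- !is_pos & (a == "EQUIVOCAL" | b == "EQUIVOCAL")
  is_neg <- !is_pos & !is_eqv & a == "NEGATIVE" & b == "NEGATIVE"
  out[is_pos] <- "POSITIVE"
  out[is_eqv] <- "EQUIVOCAL"
  out[is_neg] <- "NEGATIVE"
  out[!is_pos & !is_eqv & !is_neg] <- "OOD"
  out
}

resolve_model <- function(table, vendor, model_type, version_label = NULL) {
  mv <- model_versions(table)
  mv <- mv[mv$vendor == vendor & mv$model_type == model_type, ]
  if (nrow(mv) == 0) {
    stop("no ", model_type, " model found for vendor ", vendor,
         call. = FALSE)
  }
  if (!is.null(version_label)) {
    mv <- mv[mv$version_label == version_label, ]
    if (nrow(mv) == 0) {
      stop("version ", version_label, " not found for ", vendor, "/",
           model_type, call. = FALSE)
    }
  }
  mv
}

#' Consensus calls for one statistical/rule-based model pair
#'
#' @param table a [prediction_table()].
#' @param stat_vendor,stat_version vendor and version label of the
#'   statistical model.
#' @param rule_vendor,rule_version vendor and version label of the
#'   rule-based model.
#' @return Tibble `compound_id`, `stat_call`, `rule_call`, `call`, with
#'   attribute `combination` (`"intra"` if both models share a vendor,
#'   `"inter"` otherwise).
#' @export
consensus_table <- function(table, stat_vendor, stat_version,
                            rule_vendor, rule_version) {
  stopifnot(inherits(table, "prediction_table"))
  resolve_model(table, stat_vendor, "statistical", stat_version)
  resolve_model(table, rule_vendor, "rule_based", rule_version)
  ids <- sort(unique(table$compound_id))
  stat <- version_calls(table, stat_vendor, "statistical", stat_version)
  rule <- version_calls(table, rule_vendor, "rule_based", rule_version)
  out <- tibble::tibble(compound_id = ids, stat_call = stat,
                        rule_call = rule,
                        call = consensus_call(stat, rule))
  attr(out, "combination") <-
    if (stat_vendor == rule_vendor) "intra" else "inter"
  out
}
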