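# Structure standardization: validation, contextualization (stereo/isotope
# removal), group I/II counterion stripping, mixture and disallowed-element
# filtering, charge neutralization and canonicalization. All chemistry goes
# through OpenBabel (ChemmineOB); the policy logic lives here.

GROUP_1_2_METALS <- c("Li", "Na", "K", "Rb", "Cs", "Fr",
                      "Be", "Mg", "Ca", "Sr", "Ba", "Ra")

ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Br", "I", "Se")

AROMATIC_ORGANIC <- c(b = "B", c = "C", n = "N", o = "O", p = "P", s = "S",
                      se = "Se", as = "As")

#' Standardization policy
#'
#' Collects the tunable parts of structure standardization: which elements
#' are allowed, whether stereochemistry/isotopes are stripped
#' (contextualization) and whether charges are neutralized.
#'
#' @param allowed_elements elements permitted in the parent structure;
#'   anything else rejects the compound with reason `DISALLOWED_METAL`.
#'   Defaults to the organic subset plus group I/II metals.
#' @param strip_stereo drop stereo bond marks and atom chirality.
#' @param strip_isotopes drop isotope labels.
#' @param neutralize neutralize charges where valence allows.
#' @return An object of class `std_policy`.
#' @export
standardization_policy <- function(allowed_elements = c(ORGANIC_ELEMENTS,
                                                        GROUP_1_2_METALS),
                                   strip_stereo = TRUE,
                                   strip_isotopes = TRUE,
                                   neutralize = TRUE) {
  structure(list(allowed_elements = allowed_elements,
                 strip_stereo = strip_stereo,
                 strip_isotopes = strip_isotopes,
                 neutralize = neutralize),
            class = "std_policy")
}

# Token-level contextualization of a SMILES string: remove stereo bond
# marks, chirality tags and isotope labels. Explicit H counts in bracket
# atoms are preserved, so valence is unaffected.
strip_context <- function(s, stereo = TRUE, isotopes = TRUE) {
  if (stereo) {
    s <- gsub("[/\\\\]", "", s)
    s <- gsub("@", "", s, fixed = TRUE)
  }
  if (isotopes) s <- gsub("\\[[0-9]+", "[", s)
  s
}

# Convert one SMILES to OpenBabel canonical SMILES. Returns NA_character_
# for structures OpenBabel cannot parse.
ob_canonical <- function(smiles, neutralize = FALSE) {
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else
    data.frame(names = character(), args = character())
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, " m\n"),
                              options = opts),
    error = function(e) "")
  if (!nzchar(out)) return(NA_character_)
  sub("[\t\n ].*$", "", out)
}

# Element symbols appearing in a SMILES string (implicit H not reported).
smiles_elements <- function(s) {
  els <- character()
  brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
  for (b in brackets) {
    inner <- sub("^[0-9]+", "", substr(b, 2, nchar(b) - 1))
    inner <- gsub("@", "", inner, fixed = TRUE)
    if (grepl("^(se|as)", inner)) {
      els <- c(els, AROMATIC_ORGANIC[[substr(inner, 1, 2)]])
    } else if (grepl("^[A-Z][a-z]", inner)) {
      els <- c(els, substr(inner, 1, 2))
    } else if (grepl("^[a-z]", inner)) {
      sym <- substr(inner, 1, 1)
      els <- c(els, if (sym %in% names(AROMATIC_ORGANIC))
        AROMATIC_ORGANIC[[sym]] else toupper(sym))
    } else if (nzchar(inner)) {
      els <- c(els, substr(inner, 1, 1))
    }
  }
  rest <- gsub("\\[[^]]*\\]", "", s)
  for (two in c("Cl", "Br")) {
    n <- lengths(regmatches(rest, gregexpr(two, rest, fixed = TRUE)))
    els <- c(els, rep(two, n))
    rest <- gsub(two, "", rest, fixed = TRUE)
  }
  singles <- regmatches(rest, gregexpr("[BCNOPSFIbcnops]", rest))[[1]]
  els <- c(els, vapply(singles, function(ch) {
    if (ch %in% names(AROMATIC_ORGANIC)) AROMATIC_ORGANIC[[ch]]
    else ch
  }, character(1), USE.NAMES = FALSE))
  unique(els)
}

# TRUE for a SMILES component that is a bare group I/II ion or atom,
# e.g. [Na+], [Ca+2], [Mg++], [K].
is_counterion <- function(component) {
  pat <- paste0("^\\[(", paste(GROUP_1_2_METALS, collapse = "|"),
                ")(\\+{1,2}|\\+[0-9])?\\]$")
  grepl(pat, component)
}

standardize_one <- function(raw, policy) {
  rec <- list(smiles_std = NA_character_, status = "REJECTED",
              reject_reason = NA_character_)
  s <- trimws(raw)
  if (!nzchar(s)) {
    rec$reject_reason <- "INVALID"
    return(rec)
  }
  s <- strip_context(s, policy$strip_stereo, policy$strip_isotopes)
  can <- ob_canonical(s)
  if (is.na(can)) {
    rec$reject_reason <- "INVALID"
    return(rec)
  }
  els <- smiles_elements(can)
  if (length(setdiff(els, policy$allowed_elements)) > 0) {
    rec$reject_reason <- "DISALLOWED_METAL"
    return(rec)
  }
  parts <- strsplit(can, ".", fixed = TRUE)[[1]]
  parts <- parts[!is_counterion(parts)]
  if (length(parts) == 0) {
    rec$reject_reason <- "INVALID"
    return(rec)
  }
  if (length(parts) > 1) {
    rec$reject_reason <- "MIXTURE"
    return(rec)
  }
  std <- ob_canonical(parts[[1]], neutralize = policy$neutralize)
  if (is.na(std)) {
    rec$reject_reason <- "INVALID"
    return(rec)
  }
  rec$smiles_std <- std
  rec$status <- "KEPT"
  rec
}

#' Standardize chemical structures
#'
#' Applies the curation standardization policy to raw SMILES: validation
#' (parseability), contextualization (stereochemistry and isotope removal),
#' stripping of bare group I/II counterions, rejection of structures with
#' elements outside the allowed set and of residual multi-component
#' mixtures, charge neutralization and canonicalization. Failures are
#' encoded as `REJECTED` records with the first failing reason in the fixed
#' order `INVALID`, `DISALLOWED_METAL`, `MIXTURE`.
#'
#' @param smiles character vector of raw structure lines.
#' @param compound_id optional ids (unique); defaults to `cmpd_1`, ...
#' @param policy a [standardization_policy()].
#' @return A tibble of compound records with columns `compound_id`,
#'   `smiles_raw`, `smiles_std`, `status` (`KEPT`/`REJECTED`) and
#'   `reject_reason`.
#' @examples
#' \donttest{
#' standardize_structures(c("CCO", "CC(=O)[O-].[Na+]", "CCO.CCN"))
#' }
#' @export
standardize_structures <- function(smiles, compound_id = NULL,
                                   policy = standardization_policy()) {
  stopifnot(is.character(smiles))
  if (is.null(compound_id)) compound_id <- paste0("cmpd_", seq_along(smiles))
  if (anyDuplicated(compound_id)) {
    stop("compound_id values must be unique", call. = FALSE)
  }
  if (length(compound_id) != length(smiles)) {
    stop("compound_id and smiles lengths differ", call. = FALSE)
  }
  recs <- lapply(smiles, standardize_one, policy = policy)
  tibble::tibble(
    compound_id = as.character(compound_id),
    smiles_raw = smiles,
    smiles_std = vapply(recs, `[[`, character(1), "smiles_std"),
    status = vapply(recs, `[[`, character(1), "status"),
    reject_reason = vapply(recs, `[[`, character(1), "reject_reason"))
}

#' Remove structures matching an exclusion set
#'
#' Drops selected compounds whose standardized canonical structure matches
#' any structure in one or more exclusion lists (e.g. model training sets or
#' compounds with existing experimental data). Matching is structural, not
#' id-based; input order is preserved.
#'
#' @param selected character vector of compound ids to filter.
#' @param records compound record tibble (from [standardize_structures()])
#'   providing `smiles_std` for the selected ids.
#' @param exclusion_sets a character vector of structures, or a list of such
#'   vectors; standardized with `policy` before matching.
#' @param policy a [standardization_policy()]; must be the one used for
#'   `records`.
#' @return The subset of `selected`, in order, whose structures match no
#'   exclusion structure.
#' @export
exclude_known <- function(selected, records, exclusion_sets,
                          policy = standardization_policy()) {
  if (!is.list(exclusion_sets)) exclusion_sets <- list(exclusion_sets)
  excl_smiles <- unique(unlist(exclusion_sets, use.names = FALSE))
  if (length(excl_smiles) == 0) return(selected)
  excl <- standardize_structures(excl_smiles, policy = policy)
  excl_std <- excl$smiles_std[excl$status == "KEPT"]
  idx <- match(selected, records$compound_id)
  if (anyNA(idx)) {
    stop("selected ids missing from records: ",
         paste(utils::head(selected[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  selected[!(records$smiles_std[idx] %in% excl_std)]
}
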