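# Vocabularies: the fixed 1098-code diagnosis block and an 830-category
# synthetic drug formulary, plus the code-truncation rules that map raw claim
# codes onto vocabulary rows.

#' Three-digit ICD-9-CM diagnosis vocabulary
#'
#' The 1098 diagnosis categories used as temporal-phenomic-map rows: the 999
#' numeric categories `001`..`999` followed by the 99 supplementary V-code
#' categories `V01`..`V99`. E-codes (external cause) are not part of the
#' vocabulary.
#'
#' @return Character vector of length 1098, ordered numeric block then V block.
#' @export
diagnosis_vocabulary <- function() {
  c(sprintf("%03d", 1:999), sprintf("V%02d", 1:99))
}

#' Synthetic ATC drug-category formulary
#'
#' A deterministic, *synthetic* stand-in for the study drug list (which is not
#' publicly available): exactly 830 ATC categories, mostly 5-character
#' anatomical/therapeutic/pharmacological codes, plus 7-character entries for
#' the "X" (other) pharmacological subgroups, which the truncation rule keeps
#' at full length. A small curated set of dermatology/rheumatology categories
#' (topical vitamin-D analogues, tars, methotrexate, NSAIDs, ...) is always
#' included so the default synthetic-claims generator maps onto it.
#'
#' @return Character vector of length 830 ATC category codes, sorted.
#' @export
atc_formulary <- function() {
  curated <- c(
    "N02BE", "N02BA", "M01AE", "M01AB", "M01AC", "A02BA", "A02BC", "R06AX",
    "D07AC", "D07AB", "D05AA", "D05AX02", "D05AX52", "D05BB", "H02AB",
    "N05BA", "L04AX03", "L04AX01", "L04AD01", "M01CB01", "P01BA02", "A07EC01"
  )
  mains <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")
  base5 <- as.vector(outer(
    as.vector(outer(mains, sprintf("%02d", 1:7), paste0)),
    as.vector(outer(c("A", "B", "C"), c("A", "B", "C"), paste0)),
    paste0
  ))
  x7 <- as.vector(outer(
    paste0(as.vector(outer(mains, c("01", "02", "04"), paste0)), "AX"),
    c("01", "02"), paste0
  ))
  pool <- setdiff(c(x7, base5), curated)
  sort(c(curated, pool[seq_len(830L - length(curated))]))
}

#' Assemble a temporal-phenomic-map vocabulary
#'
#' Rows of the map are the diagnosis block followed by the drug block;
#' `row_index` is a bijection from code to row number `1..n_rows`.
#'
#' @param diagnosis_codes Ordered diagnosis categories (default the full
#'   1098-code block from [diagnosis_vocabulary()]).
#' @param drug_codes Ordered drug categories (default the packaged 830-entry
#'   synthetic formulary from [atc_formulary()]).
#' @return A `tpm_vocab` object: list with `diagnosis_codes`, `drug_codes`,
#'   `row_index` (named integer vector) and `n_rows`.
#' @export
vocabulary <- function(diagnosis_codes = diagnosis_vocabulary(),
                       drug_codes = atc_formulary()) {
  diagnosis_codes <- as.character(diagnosis_codes)
  drug_codes <- as.character(drug_codes)
  if (anyDuplicated(c(diagnosis_codes, drug_codes))) {
    stop("vocabulary codes must be unique across the diagnosis and drug blocks",
         call. = FALSE)
  }
  codes <- c(diagnosis_codes, drug_codes)
  structure(list(
    diagnosis_codes = diagnosis_codes,
    drug_codes = drug_codes,
    row_index = setNames(seq_along(codes), codes),
    n_rows = length(codes)
  ), class = "tpm_vocab")
}

#' Compact vocabulary from observed claims
#'
#' Builds a reduced vocabulary containing only the (truncated) codes that occur
#' in a claims stream. Useful for scaled-down experiments where carrying the
#' full 1928 rows would waste memory and compute; the encoding rules are
#' identical to the full vocabulary.
#'
#' @param claims Claims table (see [simulate_population()] for the schema).
#' @param extra_diagnosis,extra_drugs Additional category codes to include
#'   (e.g. a known-absent code whose row should exist but stay all-zero).
#' @return A `tpm_vocab` object.
#' @export
vocabulary_from_claims <- function(claims, extra_diagnosis = character(),
                                   extra_drugs = character()) {
  claims <- as.data.table(claims)
  dx <- unique(truncate_diagnosis(claims$code[claims$kind == "diagnosis"]))
  rx <- unique(truncate_drug(claims$code[claims$kind == "prescription"]))
  vocabulary(sort(unique(c(dx, extra_diagnosis))),
             sort(unique(c(rx, extra_drugs))))
}

#' @export
print.tpm_vocab <- function(x, ...) {
  cat(sprintf("<tpm_vocab> %d rows (%d diagnosis + %d drug)\n",
              x$n_rows, length(x$diagnosis_codes), length(x$drug_codes)))
  invisible(x)
}

#' Truncate an ICD-9-CM code to its 3-character category
#'
#' Numeric codes keep their first 3 digits (`"696.0"` becomes `"696"`);
#' V-codes keep `"V"` plus 2 digits (`"V82.71"` becomes `"V82"`). E-codes and
#' strings not in ICD-9-CM lexical form are a mapping error.
#'
#' @param code Character vector of ICD-9-CM codes, with or without a decimal
#'   part.
#' @return Character vector of 3-character categories.
#' @export
truncate_diagnosis <- function(code) {
  out <- truncate_diagnosis_safe(code)
  if (anyNA(out)) {
    bad <- unique(code[is.na(out)])
    stop(sprintf("cannot map diagnosis code(s) to a 3-character ICD-9-CM category: %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out
}

# NA instead of error for unmappable codes; used by the TPM builder which
# skips (and counts) such claims rather than failing the run.
truncate_diagnosis_safe <- function(code) {
  code <- as.character(code)
  ok <- grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", code) |
    grepl("^V[0-9]{2}(\\.[0-9]{1,2})?$", code)
  out <- substr(code, 1L, 3L)
  out[!ok] <- NA_character_
  out
}

#' Truncate an ATC code to its vocabulary category
#'
#' The first 5 characters are used, except when the 5th character is `X`
#' (case-insensitive): those "other" pharmacological subgroups are kept at 7
#' characters so distinct medications remain distinguishable
#' (`"L04AX03"` stays `"L04AX03"`, `"N02BA01"` becomes `"N02BA"`).
#'
#' @param code Character vector of ATC codes (7-character or already a
#'   category).
#' @return Character vector of category codes.
#' @export
truncate_drug <- function(code) {
  code <- as.character(code)
  if (any(nchar(code) < 5L)) {
    bad <- unique(code[nchar(code) < 5L])
    stop(sprintf("ATC code(s) shorter than 5 characters: %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  fifth_x <- toupper(substr(code, 5L, 5L)) == "X"
  ifelse(fifth_x, substr(code, 1L, 7L), substr(code, 1L, 5L))
}

truncate_drug_safe <- function(code) {
  code <- as.character(code)
  out <- rep(NA_character_, length(code))
  ok <- nchar(code) >= 5L & grepl("^[A-Z][0-9]{2}[A-Z]", code)
  fifth_x <- toupper(substr(code, 5L, 5L)) == "X"
  out[ok & fifth_x] <- substr(code[ok & fifth_x], 1L, 7L)
  out[ok & !fifth_x] <- substr(code[ok & !fifth_x], 1L, 5L)
  out
}
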