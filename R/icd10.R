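#' Built-in ICD-10 cause-of-death taxonomy
#'
#' The main- and sub-category grouping of causes of death used throughout the
#' package, defined by ICD-10 code ranges at letter-plus-two-digit stem
#' resolution. Sub-categories carry the label of their main category in
#' `parent`; overlap between categories is allowed and expected (intentional
#' self-harm, X60-X84, also falls inside the external-cause block V01-Y98).
#' The "All cause" row has an empty range: all-cause deaths are the total of
#' every record rather than a code-range match.
#'
#' @return A data.frame with columns `label`, `icd10_ranges` (comma-separated
#'   range expression, e.g. `"S,T,V01-Y98"`) and `parent` (`NA` for main
#'   categories).
#' @seealso [parse_icd10_ranges()], [assign_cause()]
#' @export
#' @examples
#' tax <- heat_taxonomy()
#' tax[tax$label == "All cardiovascular", ]
heat_taxonomy <- function() {
  tab <- rbind(
    c("All cause", "", NA),
    c("Accidental causes", "S,T,V01-Y98", NA),
    c("Transport accidents", "V01-V99", "Accidental causes"),
    c("All cardiovascular", "I00-I99", NA),
    c("Ischemic heart disease", "I20-I25", "All cardiovascular"),
    c("Hypertensive diseases", "I10-I15", "All cardiovascular"),
    c("Heart failure", "I50", "All cardiovascular"),
    c("Myocardial infarction", "I20-I23", "All cardiovascular"),
    c("Stroke, cerebrovascular diseases", "I60-I69", "All cardiovascular"),
    c("Chronic ischemic heart disease", "I05-I09", "All cardiovascular"),
    c("Sudden death", "I46", "All cardiovascular"),
    c("Respiratory system", "J00-J99", NA),
    c("Asthma", "J45-J46", "Respiratory system"),
    c("COPD", "J40-J44", "Respiratory system"),
    c("Pneumonia", "J09-J22", "Respiratory system"),
    c("Endocrine, nutritional and metabolic diseases", "E00-E99", NA),
    c("Diabetes mellitus", "E10-E14",
      "Endocrine, nutritional and metabolic diseases"),
    c("Mental and behavioral disorders", "F00-F99", NA),
    c("Organic mental disorders", "F00-F09", "Mental and behavioral disorders"),
    c("Psychoactive substance use disorders", "F10-F19",
      "Mental and behavioral disorders"),
    c("Schizophrenia", "F20", "Mental and behavioral disorders"),
    c("Self-harm", "X60-X84", "Mental and behavioral disorders"),
    c("Digestive system", "K00-K93", NA),
    c("Nervous system", "G00-G99", NA),
    c("Genitourinary system", "N00-N99", NA),
    c("Blood and immune disorders", "D50-D89", NA)
  )
  data.frame(label = tab[, 1], icd10_ranges = tab[, 2], parent = tab[, 3],
             stringsAsFactors = FALSE)
}

# Ordinal encoding of a three-character stem: letter block * 100 + number,
# so lexicographic order on stems equals numeric order on ordinals.
icd10_ordinal <- function(stem) {
  (match(substr(stem, 1, 1), LETTERS) - 1L) * 100L +
    as.integer(substr(stem, 2, 3))
}

#' Truncate an ICD-10 code to its letter-plus-two-digit stem
#'
#' Sub-decimal detail (e.g. `"I63.9"`, `"X60.21"`) is dropped; matching against
#' the taxonomy happens at stem resolution only.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector of three-character stems (e.g. `"I63"`).
#' @export
icd10_stem <- function(code) {
  stem <- toupper(sub("\\..*$", "", trimws(code)))
  bad <- !grepl("^[A-Z][0-9]{2}$", stem)
  if (any(bad)) {
    stop("invalid ICD-10 code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  stem
}

#' Parse an ICD-10 range expression into canonical intervals
#'
#' Accepts comma-separated tokens of three forms: a bare letter (`"S"`,
#' expanded to S00-S99), a single stem (`"I50"`, a degenerate interval), or a
#' stem range (`"V01-Y98"`, which may span letter blocks). The empty string
#' yields zero intervals (used by the "All cause" taxonomy row).
#'
#' @param text A single range expression, e.g. `"S,T,V01-Y98"`.
#' @return A data.frame with columns `start`, `end` (stems) and `start_ord`,
#'   `end_ord` (integer ordinals such that a code stem is a member iff
#'   `start_ord <= ordinal(stem) <= end_ord`).
#' @export
#' @examples
#' parse_icd10_ranges("S,T,V01-Y98")
parse_icd10_ranges <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = character(), end = character(),
                      start_ord = integer(), end_ord = integer(),
                      stringsAsFactors = FALSE)
  text <- trimws(text)
  if (is.na(text) || text == "") return(empty)
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  out <- lapply(tokens, function(tok) {
    if (grepl("^[A-Za-z]$", tok)) {
      s <- paste0(toupper(tok), "00"); e <- paste0(toupper(tok), "99")
    } else if (grepl("^[A-Za-z][0-9]{2}$", tok)) {
      s <- e <- toupper(tok)
    } else if (grepl("^[A-Za-z][0-9]{2}-[A-Za-z][0-9]{2}$", tok)) {
      parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
      s <- toupper(parts[1]); e <- toupper(parts[2])
    } else {
      stop("malformed ICD-10 range token: '", tok, "'")
    }
    so <- icd10_ordinal(s); eo <- icd10_ordinal(e)
    if (so > eo) stop("ICD-10 range runs backwards: '", tok, "'")
    data.frame(start = s, end = e, start_ord = so, end_ord = eo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign an ICD-10 code to cause categories
#'
#' Returns every taxonomy label whose range contains the code's stem. A death
#' can legitimately match both a main category and one or more sub-categories
#' (e.g. `"I63"` is both cardiovascular and cerebrovascular; `"X70"` is both
#' an accidental cause and self-harm). A code outside every listed range
#' returns an empty character vector.
#'
#' @param code A single ICD-10 code (sub-decimal detail allowed and ignored).
#' @param taxonomy Taxonomy data.frame as returned by [heat_taxonomy()] or
#'   [read_taxonomy()].
#' @return Character vector of matching labels (possibly empty).
#' @export
#' @examples
#' assign_cause("I63")
#' assign_cause("X70")
assign_cause <- function(code, taxonomy = heat_taxonomy()) {
  ord <- icd10_ordinal(icd10_stem(code))
  hit <- vapply(taxonomy$icd10_ranges, function(rng) {
    iv <- parsed_ranges(rng)
    nrow(iv) > 0L && any(iv$start_ord <= ord & ord <= iv$end_ord)
  }, logical(1))
  taxonomy$label[hit]
}

# memoized parse, keyed on the range expression; parsing is pure, so caching
# is safe, and it makes whole-codebook sweeps cheap
.range_cache <- new.env(parent = emptyenv())
parsed_ranges <- function(text) {
  key <- paste0("r:", text)
  val <- .range_cache[[key]]
  if (is.null(val)) {
    val <- parse_icd10_ranges(text)
    assign(key, val, envir = .range_cache)
  }
  val
}

#' Read a cause taxonomy from CSV
#'
#' Expects columns `label,icd10_ranges,parent`; every range expression is
#' parsed eagerly so malformed files fail at load time.
#'
#' @param path Path to a CSV file.
#' @return Taxonomy data.frame in the same layout as [heat_taxonomy()].
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("label", "icd10_ranges")
  if (!all(need %in% names(tab))) {
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$parent)) tab$parent <- NA_character_
  tab$parent[!is.na(tab$parent) & tab$parent == ""] <- NA_character_
  if (anyDuplicated(tab$label)) stop("duplicated taxonomy labels")
  for (i in seq_len(nrow(tab))) parse_icd10_ranges(tab$icd10_ranges[i])
  tab[, c("label", "icd10_ranges", "parent")]
}
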