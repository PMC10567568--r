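#' Red List category tokens
#'
#' Categories are represented throughout the package as character tokens:
#' `"LC"`, `"NT"`, `"VU"`, `"EN"`, `"CR"`, `"CR(PE)"`, `"EW"`, `"EX"`,
#' `"DD"`, `"NE"`. The Possibly Extinct tag is only valid on Critically
#' Endangered species and is written `"CR(PE)"`; no other PE spelling is
#' accepted. `NE` (Not Evaluated) records are rejected by every analytical
#' operation, which cover assessed species only.
#'
#' @format A character vector of the ten recognised tokens, ordered from
#'   lowest to highest extinction risk (DD and NE last).
#' @export
rl_categories <- c("LC", "NT", "VU", "EN", "CR", "CR(PE)", "EW", "EX",
                   "DD", "NE")

#' Default assessment epochs
#' @export
rl_epochs_default <- c(1980L, 2004L, 2022L)

#' Biogeographical realm codes
#' @export
rl_realms <- c("Neotropical", "Nearctic", "Palaearctic", "Afrotropical",
               "Indomalayan", "Australasian", "Oceanian", "Antarctic")

# severity ranks: used for change-direction decisions only (never for RLI)
.rl_rank <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L,
              `CR(PE)` = 5L, EW = 6L, EX = 7L)

#' Parse category tokens
#'
#' Normalises free-text category values to canonical tokens. Matching is
#' case-insensitive and whitespace-tolerant; `"CR(PE)"` (any case) parses to
#' the Possibly Extinct tagged state. Anything else is an error naming the
#' offending value.
#'
#' @param x character vector of category strings.
#' @return character vector of canonical tokens.
#' @export
parse_category <- function(x) {
  up <- toupper(gsub("[[:space:]]", "", as.character(x)))
  idx <- match(up, toupper(rl_categories))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown Red List category token(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  rl_categories[idx]
}

#' Build a category state token
#'
#' @param category character vector of base categories (no PE tag).
#' @param possibly_extinct logical vector; `TRUE` is only valid on `"CR"`.
#' @return canonical tokens, `"CR(PE)"` where tagged.
#' @export
cat_state <- function(category, possibly_extinct = FALSE) {
  category <- parse_category(category)
  possibly_extinct <- rep_len(possibly_extinct, length(category))
  if (any(possibly_extinct & category != "CR"))
    stop("possibly_extinct may be TRUE only for category CR", call. = FALSE)
  ifelse(possibly_extinct, "CR(PE)", category)
}

#' Severity rank of a category state
#'
#' Total order used to decide the direction of category changes:
#' LC=0 < NT=1 < VU=2 < EN=3 < CR=4 < CR(PE)=5 < EW=6 < EX=7. A move from CR
#' to CR(PE) is a deterioration, so CR(PE) outranks CR. Ranks are never used
#' as Red List Index weights (see [rli_weight()]); above CR the two scales
#' differ.
#'
#' @param state character vector of category tokens.
#' @return integer ranks.
#' @seealso [rli_weight()]
#' @export
category_rank <- function(state) {
  state <- parse_category(state)
  if (any(state %in% c("DD", "NE")))
    stop("unrankable: DD and NE categories have no severity rank",
         call. = FALSE)
  unname(.rl_rank[state])
}

#' Red List Index weight of a category state
#'
#' Equal-step weights LC=0, NT=1, VU=2, EN=3, CR=4 and CR(PE)=EX=5:
#' Possibly Extinct species are weighted the same as Extinct ones. The
#' weight of Extinct in the Wild is not pinned down by the index anchors;
#' it defaults to the maximum weight 5 (EW sits above CR in the severity
#' ordering) and can be changed via `ew_weight`.
#'
#' Data Deficient species are excluded from the index, so DD (and NE) input
#' is an error here; exclusion with counting happens in [compute_rli()].
#'
#' @param state character vector of category tokens.
#' @param ew_weight weight assigned to EW (default 5).
#' @return numeric weights in `[0, 5]`.
#' @export
rli_weight <- function(state, ew_weight = 5) {
  state <- parse_category(state)
  if (any(state %in% c("DD", "NE")))
    stop("excluded-from-RLI: DD and NE categories carry no RLI weight",
         call. = FALSE)
  stopifnot(ew_weight >= 0, ew_weight <= 5)
  w <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, `CR(PE)` = 5,
         EW = ew_weight, EX = 5)
  unname(w[state])
}

#' Classify breeding strategy from breeding-biology codes
#'
#' Four-way classification used for RLI disaggregation. Live bearers are
#' species coded as giving birth to live young, regardless of whether they
#' also have a free-living larval stage. Egg layers split into larval
#' developers (free-living larval stage) and direct developers (none).
#' If any code needed for the decision is `"unknown"`, the strategy is
#' `"unknown"`. Parthenogenesis and water-breeding codes are recorded in
#' assessments but play no role here.
#'
#' @param lays_eggs,live_young,free_living_larva character vectors with
#'   values `"yes"`, `"no"` or `"unknown"` (recycled to a common length).
#' @return character vector: `"larval"`, `"direct"`, `"live_birth"` or
#'   `"unknown"`.
#' @export
classify_breeding_strategy <- function(lays_eggs, live_young,
                                       free_living_larva) {
  n <- max(length(lays_eggs), length(live_young), length(free_living_larva))
  eggs <- .tri(rep_len(lays_eggs, n), "lays_eggs")
  live <- .tri(rep_len(live_young, n), "live_young")
  larva <- .tri(rep_len(free_living_larva, n), "free_living_larva")
  out <- rep("unknown", n)
  out[live == "yes"] <- "live_birth"
  egg_layer <- live == "no" & eggs == "yes"
  out[egg_layer & larva == "yes"] <- "larval"
  out[egg_layer & larva == "no"] <- "direct"
  # live == "unknown", eggs unknown, or eggs == "no" without live young:
  # no strategy can be assigned
  out
}

.tri <- function(x, what) {
  x <- tolower(as.character(x))
  if (!all(x %in% c("yes", "no", "unknown")))
    stop(what, " must be one of 'yes', 'no', 'unknown'", call. = FALSE)
  x
}

#' Validate an assessment table
#'
#' Structural checks on an assessment table (see [read_assessments()] for
#' the column contract): every configured epoch column present and parseable,
#' PE tags only on CR, realms non-empty unless the species is flagged
#' unmapped, NE absent, and threat codes (when a threat table is supplied)
#' well formed. Issues are returned, never raised, and the input is not
#' modified.
#'
#' @param assessments assessment data frame.
#' @param threats optional threat data frame (`species_id`, `code`, ...).
#' @param epochs integer vector of assessment years.
#' @return data frame with columns `species_id`, `issue`, `detail`;
#'   zero rows when the table is clean.
#' @export
validate_assessments <- function(assessments, threats = NULL,
                                 epochs = rl_epochs_default) {
  issues <- list()
  add <- function(id, issue, detail = "")
    issues[[length(issues) + 1L]] <<- data.frame(
      species_id = as.character(id), issue = issue, detail = detail,
      stringsAsFactors = FALSE)

  cols <- paste0("cat_", epochs)
  for (col in cols) {
    if (!col %in% names(assessments)) {
      add(NA_character_, "missing-epoch", col)
      next
    }
    tok <- tryCatch(parse_category(assessments[[col]]), error = function(e) e)
    if (inherits(tok, "error")) {
      up <- toupper(gsub("[[:space:]]", "", assessments[[col]]))
      bad <- !up %in% toupper(rl_categories)
      # a PE tag on anything but CR is a recognisable invariant violation,
      # not just an unknown token
      pe_wrong <- bad & grepl("^(LC|NT|VU|EN|EW|EX|DD|NE)\\(PE\\)$", up)
      for (id in assessments$species_id[pe_wrong])
        add(id, "PE-on-non-CR", col)
      for (id in assessments$species_id[bad & !pe_wrong])
        add(id, "bad-category", col)
      next
    }
    for (id in assessments$species_id[tok == "NE"])
      add(id, "not-evaluated", col)
  }
  # per-species epoch completeness (NA cells in an existing column)
  present <- cols[cols %in% names(assessments)]
  if (length(present)) {
    miss <- Reduce(`|`, lapply(assessments[present],
                               function(x) is.na(x) | !nzchar(as.character(x))))
    for (id in assessments$species_id[miss])
      add(id, "missing-epoch", "empty category cell")
  }
  if ("realms" %in% names(assessments)) {
    unmapped <- if ("unmapped" %in% names(assessments))
      assessments$unmapped %in% c(1, "1", TRUE) else FALSE
    empty <- !nzchar(trimws(ifelse(is.na(assessments$realms), "",
                                   as.character(assessments$realms))))
    for (id in assessments$species_id[empty & !unmapped])
      add(id, "empty-realms", "no realm codes and not flagged unmapped")
  }
  if (!is.null(threats) && nrow(threats)) {
    ok <- grepl("^[0-9]+(\\.[0-9]+)*$", threats$code)
    for (i in which(!ok))
      add(threats$species_id[i], "malformed-threat-code", threats$code[i])
  }
  if (!length(issues))
    return(data.frame(species_id = character(), issue = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
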