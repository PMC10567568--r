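#' Backcast Red List categories from a current assessment and change ledger
#'
#' Builds the full category timeline for every species from the most recent
#' assessment plus a ledger of declared genuine changes. The rules are:
#'
#' * Data Deficient species are automatically backcast as DD at every epoch.
#' * In the absence of a declaration covering an interval, the later epoch's
#'   state is copied backward unchanged (no evidence of genuine change).
#' * A declaration for interval `(from, to)` sets the species' state at the
#'   interval's start epoch; composition runs backward from the final epoch.
#' * Extinction is absorbing going forward: a timeline in which a species
#'   leaves EX at a later epoch is a "resurrection" error.
#'
#' @param assessments assessment data frame carrying at least `species_id`
#'   and the final epoch's category column `cat_<last epoch>`.
#' @param ledger genuine-change ledger: `species_id`, `epoch_from`,
#'   `epoch_to`, `state_at_from`, and optionally `primary_driver`,
#'   `codriver_count`, `conservation_driven`. May have zero rows.
#' @param epochs ordered integer vector of assessment years.
#' @return the assessment data frame with all `cat_<epoch>` columns filled
#'   with backcast category tokens.
#' @export
apply_backcast <- function(assessments, ledger = empty_ledger(),
                           epochs = rl_epochs_default) {
  stopifnot(length(epochs) >= 2, !is.unsorted(epochs))
  ledger <- .check_ledger(ledger, epochs)
  last <- paste0("cat_", epochs[length(epochs)])
  if (!last %in% names(assessments))
    stop("assessments lack the final epoch column ", sQuote(last),
         call. = FALSE)
  current <- parse_category(assessments[[last]])
  if (any(current == "NE"))
    stop("NE species cannot be backcast; drop them first", call. = FALSE)

  n <- nrow(assessments)
  k <- length(epochs)
  tl <- matrix(NA_character_, n, k, dimnames = list(NULL, paste0("cat_", epochs)))
  tl[, k] <- current
  row_of <- match(ledger$species_id, assessments$species_id)
  if (anyNA(row_of))
    stop("ledger references unknown species: ",
         paste(unique(ledger$species_id[is.na(row_of)]), collapse = ", "),
         call. = FALSE)
  for (j in rev(seq_len(k - 1L))) {
    decl <- ledger$epoch_from == epochs[j] & ledger$epoch_to == epochs[j + 1L]
    tl[, j] <- tl[, j + 1L]                       # no-evidence rule
    tl[row_of[decl], j] <- ledger$state_at_from[decl]
  }
  dd <- current == "DD"
  tl[dd, ] <- "DD"                                # DD at every epoch
  if (any(dd[row_of]))
    stop("ledger declares genuine changes for DD species: ",
         paste(unique(ledger$species_id[dd[row_of]]), collapse = ", "),
         call. = FALSE)
  # EX absorbing forward in time
  for (j in seq_len(k - 1L)) {
    res <- tl[, j] == "EX" & tl[, j + 1L] != "EX"
    if (any(res))
      stop("resurrection: species leave EX after ", epochs[j], ": ",
           paste(assessments$species_id[res], collapse = ", "), call. = FALSE)
  }
  for (col in colnames(tl)) assessments[[col]] <- tl[, col]
  assessments
}

#' An empty genuine-change ledger
#' @return zero-row ledger data frame with the canonical columns.
#' @export
empty_ledger <- function() {
  data.frame(species_id = character(), epoch_from = integer(),
             epoch_to = integer(), state_at_from = character(),
             primary_driver = character(), codriver_count = integer(),
             conservation_driven = logical(), stringsAsFactors = FALSE)
}

.check_ledger <- function(ledger, epochs) {
  needed <- c("species_id", "epoch_from", "epoch_to", "state_at_from")
  if (!all(needed %in% names(ledger)))
    stop("ledger must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!"primary_driver" %in% names(ledger))
    ledger$primary_driver <- rep("undetermined", nrow(ledger))
  if (!"codriver_count" %in% names(ledger))
    ledger$codriver_count <- rep(1L, nrow(ledger))
  if (!"conservation_driven" %in% names(ledger))
    ledger$conservation_driven <- rep(FALSE, nrow(ledger))
  if (!nrow(ledger)) return(ledger)
  ledger$state_at_from <- parse_category(ledger$state_at_from)
  iv <- match(ledger$epoch_from, epochs)
  ok <- !is.na(iv) & iv < length(epochs) & ledger$epoch_to == epochs[iv + 1L]
  if (any(!ok))
    stop("ledger intervals must join consecutive configured epochs",
         call. = FALSE)
  key <- paste(ledger$species_id, ledger$epoch_from)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("conflicting-ledger: multiple declarations for ",
         paste(dup, collapse = "; "), call. = FALSE)
  }
  ledger
}

#' Derive category-change records from backcast timelines
#'
#' Emits one change record per species and interval in which the severity
#' rank changes. Direction is `"deterioration"` when the rank increases and
#' `"improvement"` when it decreases, with one exception: the transition
#' CR(PE) to EX carries direction `"none"` — both states are weighted as
#' Extinct in the RLI, so the move is not a status deterioration — and is
#' flagged `became_extinct` for extinction bookkeeping instead. CR to
#' CR(PE) is a deterioration. A change is genuine iff a ledger declaration
#' covers that species and interval; non-genuine records are excluded from
#' all RLI and driver tabulations downstream.
#'
#' @inheritParams apply_backcast
#' @param crpe_ex_tally `"exclude"` (default) removes CR(PE)->EX from
#'   direction tallies; `"include"` counts it as a deterioration.
#' @return data frame of change records: `species_id`, `epoch_from`,
#'   `epoch_to`, `from_state`, `to_state`, `genuine`, `direction`,
#'   `became_extinct`, `driver_group`, `conservation_driven`.
#' @export
derive_changes <- function(assessments, ledger = empty_ledger(),
                           epochs = rl_epochs_default,
                           crpe_ex_tally = c("exclude", "include")) {
  crpe_ex_tally <- match.arg(crpe_ex_tally)
  ledger <- .check_ledger(ledger, epochs)
  cols <- paste0("cat_", epochs)
  stopifnot(all(cols %in% names(assessments)))
  out <- list()
  for (j in seq_len(length(epochs) - 1L)) {
    from <- parse_category(assessments[[cols[j]]])
    to <- parse_category(assessments[[cols[j + 1L]]])
    movable <- from != "DD" & to != "DD"      # DD timelines never move
    changed <- movable & from != to
    if (!any(changed)) next
    f <- from[changed]; t_ <- to[changed]
    dir <- ifelse(category_rank(t_) > category_rank(f),
                  "deterioration", "improvement")
    became_ex <- t_ == "EX" & f != "EX"
    crpe_ex <- f == "CR(PE)" & t_ == "EX"
    if (crpe_ex_tally == "exclude") dir[crpe_ex] <- "none"
    key <- paste(assessments$species_id[changed], epochs[j])
    lkey <- paste(ledger$species_id, ledger$epoch_from)
    li <- match(key, lkey)
    rec <- data.frame(
      species_id = assessments$species_id[changed],
      epoch_from = epochs[j], epoch_to = epochs[j + 1L],
      from_state = f, to_state = t_,
      genuine = !is.na(li), direction = dir, became_extinct = became_ex,
      driver_group = NA_character_,
      conservation_driven = FALSE, stringsAsFactors = FALSE)
    has <- !is.na(li)
    if (any(has)) {
      rec$driver_group[has] <- group_primary_driver(
        ledger$primary_driver[li[has]], ledger$codriver_count[li[has]])
      rec$conservation_driven[has] <-
        as.logical(ledger$conservation_driven[li[has]])
    }
    out[[length(out) + 1L]] <- rec
  }
  if (!length(out))
    return(data.frame(species_id = character(), epoch_from = integer(),
                      epoch_to = integer(), from_state = character(),
                      to_state = character(), genuine = logical(),
                      direction = character(), became_extinct = logical(),
                      driver_group = character(),
                      conservation_driven = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Primary drivers recognised in genuine-change declarations
#' @export
rl_drivers <- c("agriculture", "mining/energy production",
                "infrastructure development", "human disturbance",
                "timber and plant harvesting", "anthropogenic fire",
                "water management", "native species", "introduced species",
                "pollution", "geological events", "disease",
                "over-exploitation", "climate change effects",
                "undetermined")

#' Group a raw primary driver into the analysis buckets
#'
#' The fifteen raw drivers collapse into six analysis groups. Every driver
#' that operates through the destruction or degradation of habitat —
#' agriculture, mining/energy production, infrastructure development, human
#' disturbance, timber and plant harvesting, anthropogenic fire, water
#' management, native species, pollution, geological events — maps to
#' `habitat_loss_degradation`. Disease (chytridiomycosis only),
#' over-exploitation and climate change effects stay their own groups.
#' `undetermined` passes through, and a change with more than one equally
#' contributing driver is `numerous` regardless of the named driver.
#'
#' Invasive non-native species caused no status deteriorations in amphibians
#' other than via the chytrid fungi (which are coded as disease), so
#' `"introduced species"` as a sole primary driver raises an
#' "unexpected-driver" warning and is recorded as `"undetermined"`.
#'
#' @param raw character vector of raw driver names (see [rl_drivers]).
#' @param n_codrivers integer vector; values greater than 1 mean several
#'   drivers contributed equally.
#' @return character vector of group labels.
#' @export
group_primary_driver <- function(raw, n_codrivers = 1L) {
  raw <- tolower(trimws(as.character(raw)))
  bad <- !raw %in% rl_drivers
  if (any(bad))
    stop("unknown primary driver(s): ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  n_codrivers <- rep_len(as.integer(n_codrivers), length(raw))
  habitat <- c("agriculture", "mining/energy production",
               "infrastructure development", "human disturbance",
               "timber and plant harvesting", "anthropogenic fire",
               "water management", "native species", "pollution",
               "geological events")
  out <- character(length(raw))
  out[raw %in% habitat] <- "habitat_loss_degradation"
  out[raw == "disease"] <- "disease"
  out[raw == "over-exploitation"] <- "over_exploitation"
  out[raw == "climate change effects"] <- "climate_change"
  out[raw == "undetermined"] <- "undetermined"
  intro <- raw == "introduced species"
  if (any(intro & n_codrivers <= 1L)) {
    warning("unexpected-driver: 'introduced species' as sole primary ",
            "driver (chytridiomycosis is coded as disease); ",
            "recorded as undetermined", call. = FALSE)
    out[intro] <- "undetermined"
  }
  out[n_codrivers > 1L] <- "numerous"
  out
}

#' Tabulate genuine changes by interval, direction, driver and destination
#'
#' Cross-tabulates genuine change records by interval, direction, driver
#' group and destination category (CR and CR(PE) kept distinct). The counts
#' partition the genuine change set; marginals by interval reproduce the
#' total deteriorations and improvements.
#'
#' @param changes change-record data frame from [derive_changes()].
#' @return data frame `epoch_from`, `epoch_to`, `direction`, `driver_group`,
#'   `to_state`, `n`, one row per non-empty cell.
#' @export
tabulate_changes <- function(changes) {
  g <- changes[isTRUE_v(changes$genuine), , drop = FALSE]
  if (!nrow(g))
    return(data.frame(epoch_from = integer(), epoch_to = integer(),
                      direction = character(), driver_group = character(),
                      to_state = character(), n = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(g))),
    by = list(epoch_from = g$epoch_from, epoch_to = g$epoch_to,
              direction = g$direction,
              driver_group = ifelse(is.na(g$driver_group), "undetermined",
                                    g$driver_group),
              to_state = g$to_state),
    FUN = sum)
  agg[order(agg$epoch_from, agg$direction, agg$driver_group, agg$to_state), ,
      drop = FALSE]
}

# vectorised isTRUE for logical columns possibly holding NA
isTRUE_v <- function(x) !is.na(x) & x
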