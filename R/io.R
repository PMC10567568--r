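#' Read and write the assessment-table CSV dialect
#'
#' The assessment table is UTF-8 CSV with a header row and columns
#' `species_id`, `binomial`, `order`, `realms` (semicolon-separated realm
#' codes), one `cat_<year>` column per epoch with values
#' `LC|NT|VU|EN|CR|CR(PE)|EW|EX|DD` (case-insensitive), the five breeding
#' code columns (`lays_eggs`, `live_young`, `parthenogenesis`,
#' `free_living_larva`, `water_breeding`; `yes|no|unknown`) and `unmapped`
#' (0/1). Unknown category tokens are a hard error naming the offending
#' rows.
#'
#' @param path file path.
#' @param epochs epochs whose category columns must be present (only the
#'   final epoch's column is required before backcasting).
#' @return data frame of assessments with normalised category tokens.
#' @export
read_assessments <- function(path, epochs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(species_id = "character"))
  cols <- grep("^cat_[0-9]+$", names(df), value = TRUE)
  if (!is.null(epochs)) {
    missing <- setdiff(paste0("cat_", epochs), names(df))
    if (length(missing))
      stop("assessment file lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in cols) {
    tok <- tryCatch(parse_category(df[[col]]), error = function(e) e)
    if (inherits(tok, "error")) {
      bad <- which(!toupper(gsub("[[:space:]]", "", df[[col]])) %in%
                     toupper(rl_categories))
      stop("bad category token(s) in ", col, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), ": ",
           conditionMessage(tok), call. = FALSE)
    }
    df[[col]] <- tok
  }
  df
}

#' @rdname read_assessments
#' @param assessments data frame to write.
#' @export
write_assessments <- function(assessments, path) {
  utils::write.csv(assessments, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a genuine-change ledger CSV
#'
#' Columns: `species_id`, `epoch_from`, `epoch_to`, `state_at_from`,
#' `primary_driver`, `codriver_count`, `conservation_driven`.
#'
#' @param path file path.
#' @return ledger data frame.
#' @export
read_ledger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(species_id = "character"))
  if (nrow(df)) df$state_at_from <- parse_category(df$state_at_from)
  if ("conservation_driven" %in% names(df))
    df$conservation_driven <- df$conservation_driven %in%
      c(TRUE, 1, "1", "TRUE", "true", "yes")
  df
}

#' @rdname read_ledger
#' @param ledger data frame to write.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a threat-record CSV
#'
#' Columns: `species_id`, `code`, `timing` (`past|ongoing|future`),
#' `named_agent` (may be empty), `major` (0/1, optional).
#'
#' @param path file path.
#' @return threat data frame.
#' @export
read_threats <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(species_id = "character",
                                 code = "character"))
}

#' Read a species-by-cell incidence CSV
#'
#' Columns: `species_id`, `cell_id`.
#'
#' @param path file path.
#' @return incidence data frame (deduplicated).
#' @export
read_incidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(species_id = "character",
                                       cell_id = "character"))
  build_incidence(df)
}

#' Run the full assessment pipeline
#'
#' Chains backcasting, change derivation, the RLI with its disaggregations,
#' the summary arithmetic and (when inputs are given) threat tallies and
#' grid summaries, writing every stage's table to `out_dir` together with a
#' run log recording the epochs and paper-gap switches in force.
#'
#' @param assessments assessment data frame or CSV path.
#' @param ledger ledger data frame or CSV path (default empty).
#' @param threats optional threat data frame or CSV path.
#' @param incidence optional incidence data frame or CSV path.
#' @param epochs assessment years.
#' @param ew_weight RLI weight for EW.
#' @param include_ew_as_threatened include EW in threat tallies.
#' @param crpe_ex_tally treatment of CR(PE)->EX in direction tallies.
#' @param groupings RLI disaggregations to compute.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return (invisibly) a report list: `assessments` (backcast), `changes`,
#'   `counts`, `fractions`, `dd`, `extinctions`, `rli`, `driver_shares`,
#'   `improvements`, and optionally `threat_tally`, `richness`,
#'   `dominant_drivers`.
#' @export
run_pipeline <- function(assessments, ledger = empty_ledger(),
                         threats = NULL, incidence = NULL,
                         epochs = rl_epochs_default, ew_weight = 5,
                         include_ew_as_threatened = FALSE,
                         crpe_ex_tally = "exclude",
                         groupings = c("global", "realm", "order",
                                       "breeding_strategy"),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (is.character(assessments))
    assessments <- stage("read", read_assessments(assessments))
  if (is.character(ledger)) ledger <- stage("read", read_ledger(ledger))
  if (is.character(threats)) threats <- stage("read", read_threats(threats))
  if (is.character(incidence))
    incidence <- stage("read", read_incidence(incidence))

  backcast <- stage("backcast", apply_backcast(assessments, ledger, epochs))
  changes <- stage("changes",
                   derive_changes(backcast, ledger, epochs,
                                  crpe_ex_tally = crpe_ex_tally))
  counts <- stage("summarize", category_counts(backcast, epochs))
  fractions <- lapply(stats::setNames(epochs, epochs), function(e)
    stage("summarize", threatened_fraction(counts, e)))
  dd <- stage("summarize", dd_proportion(counts, epochs[length(epochs)]))
  ext <- stage("summarize", extinction_accounting(counts))
  rli <- lapply(stats::setNames(groupings, groupings), function(g)
    stage("rli", rli_series(backcast, g, epochs, ew_weight = ew_weight)))
  shares <- lapply(stats::setNames(utils::head(epochs, -1),
                                   utils::head(epochs, -1)),
                   function(e) stage("summarize",
                                     driver_shares(changes, e)))
  report <- list(assessments = backcast, changes = changes, counts = counts,
                 fractions = fractions, dd = dd, extinctions = ext,
                 rli = rli, driver_shares = shares,
                 improvements = improvement_breakdown(changes))
  if (!is.null(threats))
    report$threat_tally <- stage("threats",
      tally_threats(backcast, threats, epochs[length(epochs)],
                    include_ew = include_ew_as_threatened))
  if (!is.null(incidence)) {
    report$richness <- stage("grid", richness_quantiles(incidence))
    report$dominant_drivers <- lapply(
      stats::setNames(utils::head(epochs, -1), utils::head(epochs, -1)),
      function(e) stage("grid", dominant_driver(incidence, changes, e)))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                         row.names = FALSE)
    w(backcast, "assessments_backcast.csv")
    w(changes, "changes.csv")
    w(counts, "category_counts.csv")
    w(do.call(rbind, lapply(names(report$rli), function(g) report$rli[[g]])),
      "rli_series.csv")
    if (!is.null(report$threat_tally)) w(report$threat_tally,
                                         "threat_tally.csv")
    if (!is.null(report$richness)) w(report$richness, "richness.csv")
    writeLines(c(
      paste("epochs:", paste(epochs, collapse = ",")),
      paste("ew_weight:", ew_weight),
      paste("include_ew_as_threatened:", include_ew_as_threatened),
      paste("crpe_ex_tally:", crpe_ex_tally),
      paste("rlitools_version:",
            as.character(utils::packageVersion("rlitools")))),
      file.path(out_dir, "run_log.txt"))
  }
  invisible(report)
}
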