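#' Compute the Red List Index for one set of category states
#'
#' The index is the complement of the mean category weight relative to the
#' Extinct weight:
#' \deqn{RLI = 1 - \frac{\sum_s W(s)}{W_{EX} \, N}}
#' with equal-step weights LC=0 ... CR=4 and CR(PE)=EW=EX=5 (see
#' [rli_weight()]), \eqn{W_{EX} = 5} and \eqn{N} the number of included
#' species. The index is 1 when every species is Least Concern and 0 when
#' every species carries the Extinct weight. Data Deficient states are
#' excluded (their extinction risk is unknown); the exclusion count is
#' returned as an attribute. NE states are an error.
#'
#' @param states character vector of category tokens.
#' @param ew_weight weight for EW, default 5.
#' @return the index value, with attributes `n_included` and
#'   `n_dd_excluded`.
#' @export
compute_rli <- function(states, ew_weight = 5) {
  states <- parse_category(states)
  if (any(states == "NE"))
    stop("NE states are not assessed and cannot enter the RLI", call. = FALSE)
  dd <- states == "DD"
  inc <- states[!dd]
  if (!length(inc))
    stop("empty-after-exclusion: no non-DD states to index", call. = FALSE)
  value <- 1 - sum(rli_weight(inc, ew_weight = ew_weight)) / (5 * length(inc))
  structure(value, n_included = length(inc), n_dd_excluded = sum(dd))
}

#' Red List Index series with disaggregation
#'
#' Computes the RLI at every epoch for the whole table (`"global"`) or
#' disaggregated by biogeographical realm, taxonomic order or breeding
#' strategy. Realm disaggregation duplicates species occurring in several
#' realms into each realm's series (each species still counts once in the
#' global series); order and breeding strategy partition the table; species
#' with unknown breeding strategy are left out of the breeding
#' disaggregation. Data Deficient species are excluded per group with
#' counts reported — DD status is epoch-constant under the backcasting
#' rule, so the included count is constant within a series (asserted).
#'
#' Per-interval slopes are annualised: \eqn{(RLI_{i+1} - RLI_i) /
#' (year_{i+1} - year_i)}; negative slopes mean deteriorating status.
#'
#' @param assessments backcast assessment data frame (all `cat_<epoch>`
#'   columns filled; see [apply_backcast()]).
#' @param grouping one of `"global"`, `"realm"`, `"order"`,
#'   `"breeding_strategy"`.
#' @param epochs integer vector of assessment years.
#' @param ew_weight weight for EW, default 5.
#' @return a data frame of class `"rli_series"`: `group`, `epoch`, `rli`,
#'   `n_included`, `n_dd_excluded`, `slope_to_next` (NA at the last epoch).
#' @export
rli_series <- function(assessments,
                       grouping = c("global", "realm", "order",
                                    "breeding_strategy"),
                       epochs = rl_epochs_default, ew_weight = 5) {
  grouping <- match.arg(grouping)
  cols <- paste0("cat_", epochs)
  stopifnot(all(cols %in% names(assessments)))
  members <- switch(grouping,
    global = list(global = seq_len(nrow(assessments))),
    order = split(seq_len(nrow(assessments)), assessments$order),
    realm = {
      rl <- strsplit(ifelse(is.na(assessments$realms), "",
                            as.character(assessments$realms)), ";")
      rl <- lapply(rl, trimws)
      idx <- rep(seq_len(nrow(assessments)), lengths(rl))
      split(idx, unlist(rl))
    },
    breeding_strategy = {
      strat <- classify_breeding_strategy(
        assessments$lays_eggs, assessments$live_young,
        assessments$free_living_larva)
      split(seq_len(nrow(assessments)), strat)[
        setdiff(unique(strat), "unknown")]
    })
  members <- members[nzchar(names(members))]
  out <- list()
  for (g in names(members)) {
    rows <- members[[g]]
    states_by_epoch <- lapply(cols, function(col)
      parse_category(assessments[[col]][rows]))
    if (all(states_by_epoch[[1]] == "DD")) {
      warning("group ", sQuote(g), " has no non-DD species; omitted",
              call. = FALSE)
      next
    }
    vals <- vapply(states_by_epoch, function(s)
      as.numeric(compute_rli(s, ew_weight = ew_weight)), numeric(1))
    n_inc <- vapply(states_by_epoch, function(s) sum(s != "DD"), integer(1))
    stopifnot(length(unique(n_inc)) == 1L)   # DD is epoch-constant
    slope <- c(diff(vals) / diff(epochs), NA_real_)
    out[[g]] <- data.frame(
      group = g, epoch = epochs, rli = vals, n_included = n_inc,
      n_dd_excluded = length(rows) - n_inc, slope_to_next = slope,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    stop("no non-empty groups for grouping ", sQuote(grouping), call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rli_series", "data.frame")
  attr(res, "grouping") <- grouping
  res
}

#' Per-interval slope of an RLI series
#'
#' @param values RLI values at the epochs.
#' @param epochs the epoch years.
#' @return annualised slopes, one per interval; negative = deteriorating.
#' @export
rli_slope <- function(values, epochs = rl_epochs_default) {
  stopifnot(length(values) == length(epochs), length(epochs) >= 2)
  diff(values) / diff(epochs)
}

#' @export
print.rli_series <- function(x, digits = 4, ...) {
  cat("Red List Index series (grouping: ",
      attr(x, "grouping") %||% "unknown", ")\n\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.rli_series <- function(x, ...) {
  groups <- unique(x$group)
  graphics::matplot(
    x = unique(x$epoch),
    y = vapply(groups, function(g) x$rli[x$group == g],
               numeric(length(unique(x$epoch)))),
    type = "b", pch = 16, lty = 1, xlab = "Year", ylab = "Red List Index",
    ylim = range(x$rli) + c(-0.02, 0.02), ...)
  graphics::legend("bottomleft", legend = groups, col = seq_along(groups),
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
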