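#' Round half away from zero
#'
#' Display rounding used for every reported percentage: halves round away
#' from zero (so 40.65 -> 40.7), unlike base `round()`'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Category counts per epoch
#'
#' Tabulates a backcast assessment table into per-epoch counts of LC, NT,
#' VU, EN, CR (untagged), CR(PE), EW, EX and DD, plus the total.
#'
#' @param assessments backcast assessment data frame.
#' @param epochs integer vector of assessment years.
#' @return data frame with one row per epoch and one column per category
#'   token (`CR_PE` for the tagged state) plus `epoch` and `total`.
#' @export
category_counts <- function(assessments, epochs = rl_epochs_default) {
  cols <- paste0("cat_", epochs)
  stopifnot(all(cols %in% names(assessments)))
  cats <- c("LC", "NT", "VU", "EN", "CR", "CR(PE)", "EW", "EX", "DD")
  rows <- lapply(seq_along(epochs), function(j) {
    tok <- parse_category(assessments[[cols[j]]])
    if (any(tok == "NE"))
      stop("NE species present; drop them before counting", call. = FALSE)
    n <- vapply(cats, function(cc) sum(tok == cc), integer(1))
    out <- as.data.frame(as.list(n), check.names = FALSE)
    cbind(data.frame(epoch = epochs[j]), out,
          data.frame(total = length(tok)))
  })
  res <- do.call(rbind, rows)
  names(res)[names(res) == "CR(PE)"] <- "CR_PE"
  res
}

.counts_row <- function(counts, epoch) {
  i <- match(epoch, counts$epoch)
  if (is.na(i)) stop("epoch ", epoch, " not present in counts", call. = FALSE)
  counts[i, , drop = FALSE]
}

#' Threatened fraction with Data Deficient uncertainty bounds
#'
#' Threatened species are those in categories VU, EN and CR (including the
#' Possibly Extinct tagged), plus EW, which remains reintroducible. With
#' T = EW + CR + CR(PE) + EN + VU:
#' \deqn{lower = T/(total - EX)}
#' \deqn{best  = T/(total - EX - DD)}
#' \deqn{upper = (T + DD)/(total - EX)}
#' The lower bound assumes no Data Deficient species is threatened, the
#' upper bound that all are.
#'
#' @param counts per-epoch category counts from [category_counts()].
#' @param epoch epoch year to evaluate.
#' @return list with proportions `lower`, `best`, `upper`, the threatened
#'   count `n_threatened`, and `percent` — the three bounds as percentages
#'   rounded to one decimal, half away from zero.
#' @export
threatened_fraction <- function(counts, epoch) {
  r <- .counts_row(counts, epoch)
  T_ <- r$EW + r$CR + r$CR_PE + r$EN + r$VU
  d_lower <- r$total - r$EX
  d_best <- r$total - r$EX - r$DD
  if (d_lower <= 0 || d_best <= 0)
    stop("degenerate-counts: non-positive denominator", call. = FALSE)
  out <- list(lower = T_ / d_lower, best = T_ / d_best,
              upper = (T_ + r$DD) / d_lower, n_threatened = T_)
  out$percent <- round_half_up(100 * unlist(out[c("lower", "best", "upper")]),
                               1)
  out
}

#' Extinction accounting across epochs
#'
#' Cumulative documented extinctions and Possibly Extinct counts per epoch,
#' and the possible extinction total if every CR(PE) species is indeed
#' extinct: `EX` at the final epoch plus `CR(PE)` at the final epoch.
#'
#' @param x either a per-epoch counts table from [category_counts()] or a
#'   backcast assessment data frame.
#' @param epochs integer vector of assessment years (used when `x` is an
#'   assessment table).
#' @return data frame `epoch`, `cumulative_EX`, `CR_PE`, with attribute
#'   `possible_total`.
#' @export
extinction_accounting <- function(x, epochs = rl_epochs_default) {
  counts <- if (all(c("epoch", "EX", "CR_PE") %in% names(x))) x
            else category_counts(x, epochs)
  if (is.unsorted(counts$epoch)) counts <- counts[order(counts$epoch), ]
  if (any(diff(counts$EX) < 0))
    stop("EX counts decrease across epochs; timelines violate absorption",
         call. = FALSE)
  res <- data.frame(epoch = counts$epoch, cumulative_EX = counts$EX,
                    CR_PE = counts$CR_PE)
  attr(res, "possible_total") <-
    counts$EX[nrow(counts)] + counts$CR_PE[nrow(counts)]
  res
}

#' Primary-driver shares among genuine changes
#'
#' Counts genuine changes of one direction in one interval by driver group
#' and expresses each as an integer percentage of the interval-direction
#' total (half away from zero). Counts sum exactly to the total; the
#' percentages sum to 100 up to integer rounding.
#'
#' @param changes change-record data frame from [derive_changes()].
#' @param epoch_from start year of the interval.
#' @param direction `"deterioration"` or `"improvement"`.
#' @return data frame `driver_group`, `n`, `percent`, plus attribute
#'   `total`.
#' @export
driver_shares <- function(changes, epoch_from,
                          direction = c("deterioration", "improvement")) {
  direction <- match.arg(direction)
  sel <- isTRUE_v(changes$genuine) & changes$epoch_from == epoch_from &
    changes$direction == direction
  g <- changes[sel, , drop = FALSE]
  total <- nrow(g)
  if (!total)
    return(structure(data.frame(driver_group = character(), n = integer(),
                                percent = numeric()), total = 0L))
  grp <- ifelse(is.na(g$driver_group), "undetermined", g$driver_group)
  tab <- sort(table(grp), decreasing = TRUE)
  res <- data.frame(driver_group = names(tab), n = as.integer(tab),
                    percent = round_half_up(100 * as.integer(tab) / total),
                    stringsAsFactors = FALSE)
  structure(res, total = total)
}

#' Split improvements into conservation-driven and unaided
#'
#' @param changes change-record data frame from [derive_changes()].
#' @return named integer vector `conservation_driven`, `unaided` (summing
#'   to the number of genuine improvements).
#' @export
improvement_breakdown <- function(changes) {
  imp <- isTRUE_v(changes$genuine) & changes$direction == "improvement"
  cons <- sum(imp & isTRUE_v(changes$conservation_driven))
  c(conservation_driven = cons, unaided = sum(imp) - cons)
}

#' Data Deficient proportion
#'
#' @param counts per-epoch counts from [category_counts()].
#' @param epoch epoch year.
#' @return list: `proportion` (DD/total) and `percent` at one decimal.
#' @export
dd_proportion <- function(counts, epoch) {
  r <- .counts_row(counts, epoch)
  if (r$total <= 0) stop("degenerate-counts: zero total", call. = FALSE)
  p <- r$DD / r$total
  list(proportion = p, percent = round_half_up(100 * p, 1))
}
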