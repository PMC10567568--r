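#' Map an IUCN threat-classification code to an analysis group
#'
#' Groups dotted hierarchical threat codes from the IUCN threat
#' classification scheme into the comparison groups used for tallying
#' threats to threatened species:
#'
#' * `2.*` agriculture; `5.2`, `5.3` timber_plant_harvesting;
#'   `1.*`, `4.*` infrastructure; `9.*` pollution; `3.*` mining_energy;
#'   `7.2` water_management; `6.*` human_disturbance; `10.*` geological;
#'   `5.1`, `5.4` over_exploitation; `11.*` climate_change; `7.1` fire
#'   (these all cause habitat loss and degradation except over-exploitation
#'   and climate change);
#' * `8.1.2` and `8.4.2` carry a named problematic species: records naming
#'   Batrachochytrium dendrobatidis map to `Bd`, B. salamandrivorans to
#'   `Bsal` (case-insensitive, tolerant of genus abbreviation);
#' * remaining `8.1`, `8.3`, `8.4`, `8.5`, `8.6` codes map to
#'   `invasive_species` and `8.2` to `native_species`.
#'
#' Codes outside the scheme (including `7.3`, which the grouping does not
#' cover) raise an `"unmapped-code"` error.
#'
#' @param code character vector of dotted codes (e.g. `"2.1"`, `"8.1.2"`).
#' @param named_agent optional character vector of problematic-species names
#'   for `8.1.2`/`8.4.2` records.
#' @return character vector of group labels.
#' @export
group_threat <- function(code, named_agent = NA_character_) {
  code <- trimws(as.character(code))
  named_agent <- rep_len(as.character(named_agent), length(code))
  if (!all(grepl("^[0-9]+(\\.[0-9]+)*$", code)))
    stop("unmapped-code: malformed threat code(s): ",
         paste(unique(code[!grepl("^[0-9]+(\\.[0-9]+)*$", code)]),
               collapse = ", "), call. = FALSE)
  parts <- strsplit(code, ".", fixed = TRUE)
  top <- vapply(parts, `[`, "", 1L)
  two <- vapply(parts, function(p) paste(p[seq_len(min(2L, length(p)))],
                                         collapse = "."), "")
  out <- rep(NA_character_, length(code))
  out[top == "2"] <- "agriculture"
  out[two %in% c("5.2", "5.3")] <- "timber_plant_harvesting"
  out[top %in% c("1", "4")] <- "infrastructure"
  out[top == "9"] <- "pollution"
  out[top == "3"] <- "mining_energy"
  out[two == "7.2"] <- "water_management"
  out[top == "6"] <- "human_disturbance"
  out[top == "10"] <- "geological"
  out[two %in% c("5.1", "5.4")] <- "over_exploitation"
  out[top == "11"] <- "climate_change"
  out[two == "7.1"] <- "fire"
  is8 <- top == "8"
  out[is8 & two %in% c("8.1", "8.3", "8.4", "8.5", "8.6")] <- "invasive_species"
  out[is8 & two == "8.2"] <- "native_species"
  named <- code %in% c("8.1.2", "8.4.2")
  out[named & .is_agent(named_agent, "dendrobatidis")] <- "Bd"
  out[named & .is_agent(named_agent, "salamandrivorans")] <- "Bsal"
  if (anyNA(out))
    stop("unmapped-code: no group for code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

# matches "Batrachochytrium dendrobatidis", "B. dendrobatidis", any case
.is_agent <- function(agent, epithet) {
  a <- tolower(ifelse(is.na(agent), "", agent))
  grepl(paste0("\\bb(atrachochytrium)?\\.?\\s+", epithet), a)
}

#' Threat-group labels in display order
#' @export
rl_threat_groups <- c("agriculture", "timber_plant_harvesting",
                      "infrastructure", "pollution", "mining_energy",
                      "water_management", "human_disturbance", "geological",
                      "over_exploitation", "climate_change", "fire",
                      "Bd", "Bsal", "invasive_species", "native_species")

#' Tally threats to threatened species
#'
#' Counts, per threat group, the threatened species affected by at least
#' one ongoing or future major threat in that group, with a separate count
#' of species for which every threat in the group is only a future threat
#' (the hatched portion of the classic bar chart). Threatened species are
#' those in VU, EN or CR (including CR(PE)) at the chosen epoch; EW can be
#' added via `include_ew` but is excluded by default since species extinct
#' in the wild face no ongoing wild threats. Past-only threats never count.
#' A species counts at most once per group regardless of how many of its
#' codes fall in it.
#'
#' @param assessments backcast assessment data frame.
#' @param threats threat table: `species_id`, `code`, `timing`
#'   (`past`/`ongoing`/`future`), optional `named_agent`, optional `major`
#'   (when absent all ongoing/future threats are treated as major).
#' @param epoch epoch year defining the threatened set.
#' @param include_ew also treat EW species as threatened.
#' @return data frame `group`, `n_species`, `n_future_only`, all groups in
#'   [rl_threat_groups] order (zero rows included).
#' @export
tally_threats <- function(assessments, threats, epoch = NULL,
                          include_ew = FALSE) {
  if (is.null(epoch)) {
    ep_cols <- grep("^cat_[0-9]+$", names(assessments), value = TRUE)
    epoch <- max(as.integer(sub("cat_", "", ep_cols)))
  }
  col <- paste0("cat_", epoch)
  tok <- parse_category(assessments[[col]])
  threat_cats <- c("VU", "EN", "CR", "CR(PE)", if (include_ew) "EW")
  threatened <- assessments$species_id[tok %in% threat_cats]

  timing <- tolower(trimws(threats$timing))
  stopifnot(all(timing %in% c("past", "ongoing", "future")))
  major <- if ("major" %in% names(threats))
    threats$major %in% c(TRUE, 1, "1", "yes", "TRUE") else TRUE
  keep <- threats$species_id %in% threatened & timing != "past" & major
  t_ <- threats[keep, , drop = FALSE]
  timing <- timing[keep]
  agent <- if ("named_agent" %in% names(t_)) t_$named_agent else
    rep(NA_character_, nrow(t_))
  grp <- if (nrow(t_)) group_threat(t_$code, agent) else character()

  res <- data.frame(group = rl_threat_groups, n_species = 0L,
                    n_future_only = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(rl_threat_groups)) {
    g <- rl_threat_groups[i]
    in_g <- grp == g
    sp <- unique(t_$species_id[in_g])
    res$n_species[i] <- length(sp)
    if (length(sp)) {
      fut <- tapply(timing[in_g] == "future", t_$species_id[in_g], all)
      res$n_future_only[i] <- sum(fut)
    }
  }
  structure(res, epoch = epoch, n_threatened = length(threatened))
}
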