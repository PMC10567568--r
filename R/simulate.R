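#' Scenario configuration for the synthetic-assessment generator
#'
#' Bundles every knob of [generate_scenario()] with defaults emulating the
#' conditions of the 2022 Global Amphibian Assessment: 8,011 species over
#' epochs 1980/2004/2022, the published per-epoch category mix, genuine
#' deteriorations of 482 (1980-2004) and 306 (2004-2022) with the published
#' driver composition, 120 improvements of which 63 conservation-driven,
#' multi-realm occupancy of 264 species, breeding-strategy totals
#' 5,320/2,452/61/178 and threat prevalences led by agriculture (77% of
#' threatened species). Two modes: `"scripted"` draws the configured counts
#' exactly (used wherever exact arithmetic must be reproduced) and
#' `"stochastic"` treats deterioration/improvement rates as per-species
#' Bernoulli hazards.
#'
#' @param n_species number of species.
#' @param epochs ordered assessment years.
#' @param mode `"scripted"` or `"stochastic"`.
#' @param category_dist named probabilities over final-epoch categories
#'   (tokens, `"CR(PE)"` allowed). Defaults to the GAA2 2022 mix.
#' @param deteriorations list named by interval start year: named vectors
#'   of deterioration counts (scripted) per driver group.
#' @param det_hazards like `deteriorations` but per-species probabilities
#'   (stochastic mode).
#' @param improvements list named by interval start year:
#'   `c(conservation = , unaided = )` counts (scripted).
#' @param imp_hazard per-species improvement probability per interval
#'   (stochastic), with `conservation_share` of improvements flagged.
#' @param conservation_share fraction of improvements that are
#'   conservation-driven.
#' @param step_size rank steps per deterioration/improvement.
#' @param realm_weights named sampling weights over realm codes.
#' @param p_multi_realm probability a species occupies a second realm.
#' @param order_dist named probabilities over taxonomic orders.
#' @param breeding_dist named probabilities over breeding strategies
#'   (`larval`, `direct`, `live_birth`, `unknown`).
#' @param threat_rates named per-group probability that a threatened
#'   species carries a threat of that group.
#' @param future_share named per-group share of those threats whose timing
#'   is future (others ongoing); groups absent default to 0.
#' @param cells_per_species mean range size in cells.
#' @param grid_dim `c(ncols, nrows)` of the abstract incidence grid.
#' @param clustering probability a species' range centers on one of a few
#'   shared hotspots rather than uniformly.
#' @param seed integer seed; fully determines the output.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(
    n_species = 8011,
    epochs = rl_epochs_default,
    mode = c("scripted", "stochastic"),
    category_dist = c(LC = 3192, NT = 1000, VU = 1037, EN = 1036, CR = 613,
                      `CR(PE)` = 185, EW = 2, EX = 37, DD = 909) / 8011,
    deteriorations = list(
      `1980` = c(disease = 281, habitat_loss_degradation = 156,
                 over_exploitation = 31, climate_change = 6,
                 undetermined = 4, numerous = 4),
      `2004` = c(disease = 69, habitat_loss_degradation = 112,
                 over_exploitation = 4, climate_change = 119,
                 undetermined = 1, numerous = 1)),
    det_hazards = NULL,
    improvements = list(`1980` = c(conservation = 30, unaided = 28),
                        `2004` = c(conservation = 33, unaided = 29)),
    imp_hazard = NULL,
    conservation_share = 63 / 120,
    step_size = 1L,
    realm_weights = c(Neotropical = 0.48, Afrotropical = 0.13,
                      Indomalayan = 0.13, Australasian = 0.09,
                      Nearctic = 0.07, Palaearctic = 0.09, Oceanian = 0.01),
    p_multi_realm = 264 / 8011,
    order_dist = c(Anura = 0.875, Caudata = 0.099, Gymnophiona = 0.026),
    breeding_dist = c(larval = 5320, direct = 2452, live_birth = 61,
                      unknown = 178) / 8011,
    threat_rates = c(agriculture = 0.77, timber_plant_harvesting = 0.53,
                     infrastructure = 0.40, climate_change = 0.29,
                     Bd = 0.29, pollution = 0.20, over_exploitation = 0.10,
                     invasive_species = 0.14, Bsal = 0.02),
    future_share = c(climate_change = 0.35, Bd = 0.15, Bsal = 0.8),
    cells_per_species = 6,
    grid_dim = c(40L, 20L),
    clustering = 0.5,
    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_species >= 1, length(epochs) >= 2, !is.unsorted(epochs),
            abs(sum(category_dist) - 1) < 1e-8,
            all(category_dist >= 0), step_size >= 1,
            clustering >= 0, clustering <= 1,
            all(unlist(deteriorations) >= 0),
            all(unlist(improvements) >= 0),
            all(threat_rates >= 0 & threat_rates <= 1))
  if (!is.null(det_hazards))
    stopifnot(all(unlist(det_hazards) >= 0), all(unlist(det_hazards) <= 1))
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a synthetic assessment dataset
#'
#' Draws an assessment table, genuine-change ledger, threat table and
#' species-by-cell incidence from a [scenario_config()]. The output is
#' fully determined by the config's seed; Data Deficient species never
#' receive genuine changes; scripted deteriorations and improvements hit
#' the configured counts exactly, stochastic ones follow the configured
#' hazards. Emitted tables round-trip losslessly through the CSV
#' readers/writers and pass [validate_assessments()] cleanly.
#'
#' @param config a [scenario_config()].
#' @return list `assessments`, `ledger`, `threats`, `incidence`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  set.seed(cf$seed)
  n <- as.integer(cf$n_species)
  k <- length(cf$epochs)
  ids <- sprintf("sp%05d", seq_len(n))

  # --- final-epoch categories: deterministic counts in scripted mode
  cats <- names(cf$category_dist)
  final <- if (cf$mode == "scripted")
    sample(rep(cats, .apportion(cf$category_dist, n)))
  else sample(cats, n, replace = TRUE, prob = cf$category_dist)
  final <- parse_category(final)

  # --- taxonomy, realms, breeding
  ord <- sample(names(cf$order_dist), n, TRUE, cf$order_dist)
  realm1 <- sample(names(cf$realm_weights), n, TRUE, cf$realm_weights)
  second <- stats::runif(n) < cf$p_multi_realm
  realm2 <- vapply(seq_len(n), function(i)
    if (second[i]) sample(setdiff(names(cf$realm_weights), realm1[i]), 1L)
    else NA_character_, "")
  realms <- ifelse(second, paste(realm1, realm2, sep = ";"), realm1)
  strat <- if (cf$mode == "scripted")
    sample(rep(names(cf$breeding_dist), .apportion(cf$breeding_dist, n)))
  else sample(names(cf$breeding_dist), n, TRUE, cf$breeding_dist)
  br <- .breeding_codes(strat)

  assessments <- data.frame(
    species_id = ids,
    binomial = paste("Genus", sprintf("species%05d", seq_len(n))),
    order = ord, realms = realms,
    lays_eggs = br$lays_eggs, live_young = br$live_young,
    parthenogenesis = "no", free_living_larva = br$free_living_larva,
    water_breeding = ifelse(br$free_living_larva == "yes", "yes", "no"),
    unmapped = 0L, stringsAsFactors = FALSE)
  assessments[[paste0("cat_", cf$epochs[k])]] <- final

  # --- genuine-change ledger, built backward from the final epoch
  state_at <- final                     # state at the interval's end epoch
  ledger <- empty_ledger()
  used <- rep(FALSE, n)                 # one change per species by default
  for (j in rev(seq_len(k - 1L))) {
    yr <- as.character(cf$epochs[j])
    det <- if (cf$mode == "scripted") cf$deteriorations[[yr]] else
      .draw_hazard_counts(cf$det_hazards[[yr]], state_at, used)
    imp <- if (cf$mode == "scripted") cf$improvements[[yr]] else
      .draw_imp_counts(cf$imp_hazard, cf$conservation_share, state_at, used)
    step <- as.integer(cf$step_size)

    # deteriorations: end-state rank must leave room to have been lower
    ladder <- c("LC", "NT", "VU", "EN", "CR", "CR(PE)")
    pos <- match(state_at, ladder)              # NA for EW/EX/DD: ineligible
    elig_d <- which(!used & !is.na(pos) & pos - 1L >= step)
    n_det <- sum(det %||% 0)
    if (n_det > length(elig_d))
      stop("infeasible-scenario: ", n_det, " deteriorations requested in ",
           yr, " but only ", length(elig_d), " eligible species", call. = FALSE)
    pick_d <- if (n_det) sample(elig_d, n_det) else integer()
    drv <- rep(names(det), det)
    # improvements: end state must be below the top of the ladder
    elig_i <- setdiff(which(!used & !is.na(pos) &
                              pos + step <= length(ladder)), pick_d)
    n_imp <- sum(imp %||% 0)
    if (n_imp > length(elig_i))
      stop("infeasible-scenario: ", n_imp, " improvements requested in ",
           yr, " but only ", length(elig_i), " eligible species",
           call. = FALSE)
    pick_i <- if (n_imp) sample(elig_i, n_imp) else integer()

    if (n_det) {
      from_d <- .shift_rank(state_at[pick_d], -step)
      ledger <- rbind(ledger, data.frame(
        species_id = ids[pick_d], epoch_from = cf$epochs[j],
        epoch_to = cf$epochs[j + 1L], state_at_from = from_d,
        primary_driver = .raw_driver(drv), codriver_count =
          ifelse(drv == "numerous", 2L, 1L),
        conservation_driven = FALSE, stringsAsFactors = FALSE))
      state_at[pick_d] <- from_d
      used[pick_d] <- TRUE
    }
    if (n_imp) {
      from_i <- .shift_rank(state_at[pick_i], +step)
      cons <- rep(c(TRUE, FALSE), c(imp["conservation"], imp["unaided"]))
      ledger <- rbind(ledger, data.frame(
        species_id = ids[pick_i], epoch_from = cf$epochs[j],
        epoch_to = cf$epochs[j + 1L], state_at_from = from_i,
        primary_driver = "disease", codriver_count = 1L,
        conservation_driven = cons, stringsAsFactors = FALSE))
      state_at[pick_i] <- from_i
      used[pick_i] <- TRUE
    }
  }
  rownames(ledger) <- NULL
  assessments <- apply_backcast(assessments, ledger, cf$epochs)

  threats <- .sample_threats(assessments, cf)
  incidence <- .sample_incidence(ids, cf)
  list(assessments = assessments, ledger = ledger, threats = threats,
       incidence = incidence)
}

# largest-remainder apportionment of n among probabilities p
.apportion <- function(p, n) {
  raw <- p / sum(p) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# move along the LC..CR(PE) rank ladder (never creates EW/EX/DD)
.shift_rank <- function(state, by) {
  ladder <- c("LC", "NT", "VU", "EN", "CR", "CR(PE)")
  i <- match(state, ladder) + by
  if (any(is.na(i) | i < 1L | i > length(ladder)))
    stop("infeasible-scenario: rank shift leaves the category ladder",
         call. = FALSE)
  ladder[i]
}

# a representative raw driver for each group (inverse of grouping)
.raw_driver <- function(group) {
  map <- c(disease = "disease", habitat_loss_degradation = "agriculture",
           over_exploitation = "over-exploitation",
           climate_change = "climate change effects",
           undetermined = "undetermined", numerous = "agriculture")
  bad <- !group %in% names(map)
  if (any(bad))
    stop("unknown driver group(s) in scenario: ",
         paste(unique(group[bad]), collapse = ", "), call. = FALSE)
  unname(map[group])
}

.breeding_codes <- function(strategy) {
  n <- length(strategy)
  out <- data.frame(lays_eggs = rep("yes", n), live_young = rep("no", n),
                    free_living_larva = rep("yes", n),
                    stringsAsFactors = FALSE)
  out$free_living_larva[strategy == "direct"] <- "no"
  out$live_young[strategy == "live_birth"] <- "yes"
  out$lays_eggs[strategy == "live_birth"] <- "no"
  out[strategy == "unknown", ] <- "unknown"
  out
}

.draw_hazard_counts <- function(hazards, state_at, used) {
  if (is.null(hazards)) return(NULL)
  elig <- sum(!used & state_at %in% c("NT", "VU", "EN", "CR", "CR(PE)"))
  drawn <- stats::rbinom(length(hazards), elig, hazards)
  names(drawn) <- names(hazards)
  drawn
}

.draw_imp_counts <- function(hazard, cons_share, state_at, used) {
  if (is.null(hazard)) return(NULL)
  elig <- sum(!used & state_at %in% c("LC", "NT", "VU", "EN", "CR"))
  m <- stats::rbinom(1L, elig, hazard)
  cons <- stats::rbinom(1L, m, cons_share)
  c(conservation = cons, unaided = m - cons)
}

.threat_code_of <- c(
  agriculture = "2.1", timber_plant_harvesting = "5.3",
  infrastructure = "1.1", pollution = "9.1", mining_energy = "3.2",
  water_management = "7.2", human_disturbance = "6.1", geological = "10.1",
  over_exploitation = "5.1", climate_change = "11.1", fire = "7.1",
  Bd = "8.1.2", Bsal = "8.1.2", invasive_species = "8.1.1",
  native_species = "8.2.1")

.sample_threats <- function(assessments, cf) {
  last <- paste0("cat_", cf$epochs[length(cf$epochs)])
  tok <- assessments[[last]]
  thr <- assessments$species_id[tok %in% c("VU", "EN", "CR", "CR(PE)")]
  recs <- list()
  for (g in names(cf$threat_rates)) {
    hit <- thr[stats::runif(length(thr)) < cf$threat_rates[[g]]]
    if (!length(hit)) next
    fs <- if (g %in% names(cf$future_share)) cf$future_share[[g]] else 0
    recs[[g]] <- data.frame(
      species_id = hit, code = .threat_code_of[[g]],
      timing = ifelse(stats::runif(length(hit)) < fs, "future", "ongoing"),
      named_agent = switch(g, Bd = "Batrachochytrium dendrobatidis",
                           Bsal = "Batrachochytrium salamandrivorans",
                           NA_character_),
      major = 1L, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(species_id = character(), code = character(),
                      timing = character(), named_agent = character(),
                      major = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# contiguous blocks of cells around a centroid; a few shared hotspots
.sample_incidence <- function(ids, cf) {
  W <- cf$grid_dim[1]; H <- cf$grid_dim[2]
  n <- length(ids)
  nhot <- 5L
  hot <- cbind(sample(W, nhot, TRUE), sample(H, nhot, TRUE))
  at_hot <- stats::runif(n) < cf$clustering
  hi <- sample(nhot, n, TRUE)
  cx <- ifelse(at_hot, pmin(pmax(hot[hi, 1] + sample(-2:2, n, TRUE), 1), W),
               sample(W, n, TRUE))
  cy <- ifelse(at_hot, pmin(pmax(hot[hi, 2] + sample(-2:2, n, TRUE), 1), H),
               sample(H, n, TRUE))
  sizes <- pmax(1L, stats::rpois(n, cf$cells_per_species))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sizes[i]
    side <- ceiling(sqrt(m))
    xs <- rep(cx[i] + seq_len(side) - 1L, each = side)[seq_len(m)]
    ys <- rep(cy[i] + seq_len(side) - 1L, times = side)[seq_len(m)]
    keep <- xs <= W & ys <= H
    recs[[i]] <- data.frame(species_id = ids[i],
                            cell_id = paste0(xs[keep], "_", ys[keep]),
                            stringsAsFactors = FALSE)
  }
  out <- unique(do.call(rbind, recs))
  rownames(out) <- NULL
  class(out) <- c("grid_incidence", "data.frame")
  out
}
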