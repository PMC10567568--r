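# small in-code builders shared across test files

make_assessments <- function(cat_2022,
                             ids = sprintf("s%03d", seq_along(cat_2022)),
                             order = "Anura", realms = "Neotropical") {
  data.frame(species_id = ids,
             binomial = paste("Genus", ids),
             order = rep_len(order, length(ids)),
             realms = rep_len(realms, length(ids)),
             lays_eggs = "yes", live_young = "no", parthenogenesis = "no",
             free_living_larva = "yes", water_breeding = "yes",
             unmapped = 0L, cat_2022 = cat_2022,
             stringsAsFactors = FALSE)
}

make_decl <- function(species_id, epoch_from, state_at_from,
                      primary_driver = "disease", codriver_count = 1L,
                      conservation_driven = FALSE) {
  data.frame(species_id = species_id, epoch_from = epoch_from,
             epoch_to = ifelse(epoch_from == 1980L, 2004L, 2022L),
             state_at_from = state_at_from, primary_driver = primary_driver,
             codriver_count = codriver_count,
             conservation_driven = conservation_driven,
             stringsAsFactors = FALSE)
}

# independent brute-force RLI oracle: per-species weight lookup and
# explicit running sum, no shared code with compute_rli()
oracle_rli <- function(states, ew_weight = 5) {
  w <- list(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, "CR(PE)" = 5,
            EW = ew_weight, EX = 5)
  total <- 0; n <- 0
  for (s in states) {
    if (s == "DD") next
    total <- total + w[[s]]
    n <- n + 1
  }
  1 - total / (5 * n)
}

# sort-and-slice quantile-class oracle: cut the sorted cells into k
# rank-contiguous chunks, then give every distinct richness value the
# lowest chunk index any of its cells lands in
oracle_quantile_class <- function(richness, k) {
  n <- length(richness)
  ord <- order(richness)
  chunk <- floor((seq_len(n) - 1) * k / n) + 1   # chunk of each sorted rank
  by_val <- tapply(chunk, richness[ord], min)
  as.integer(by_val[as.character(richness)])
}
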