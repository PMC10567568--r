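test_that("pair-mode incidence deduplicates and preserves the counting identity", {
  pairs <- data.frame(
    species_id = c("a", "a", "a", "b", "b", "c"),
    cell_id = c("1_1", "1_1", "2_1", "2_1", "3_1", "9_9"))
  inc <- build_incidence(pairs)
  expect_equal(nrow(inc), 5L)                 # duplicate dropped
  r <- cell_richness(inc)
  expect_equal(r$richness[r$cell_id == "2_1"], 2L)
  # sum over cells of richness == sum over species of cells occupied
  expect_equal(sum(r$richness),
               sum(tapply(inc$cell_id, inc$species_id, length)))
})

test_that("a stacked fixture attains the configured maximum richness", {
  pairs <- data.frame(species_id = sprintf("sp%02d", 1:61), cell_id = "5_5")
  r <- cell_richness(build_incidence(pairs))
  expect_equal(max(r$richness), 61L)
})

test_that("quantile classes match the sort-and-slice oracle", {
  # uniform case: 100 distinct richness values, 10 classes of 10 ranks
  r <- data.frame(cell_id = as.character(1:100), richness = sample(100))
  q <- richness_quantiles(r, k = 10)
  expect_equal(q$class, ceiling(rank(q$richness) / 10))
  # degenerate: all equal -> a single class
  req <- data.frame(cell_id = as.character(1:7), richness = 5)
  expect_message(qe <- richness_quantiles(req, k = 10), "fewer distinct")
  expect_true(all(qe$class == 1L))
  expect_equal(attr(qe, "n_classes_used"), 1L)
  # ties share the lower class; verified against the oracle
  fib <- data.frame(cell_id = as.character(1:10),
                    richness = c(1, 1, 2, 3, 5, 8, 13, 21, 34, 55))
  q5 <- richness_quantiles(fib, k = 5)
  expect_equal(q5$class, oracle_quantile_class(fib$richness, 5))
  expect_equal(q5$class, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  # random property: oracle equivalence and order-isomorphism
  set.seed(12)
  for (i in 1:50) {
    n <- sample(5:120, 1)
    rr <- data.frame(cell_id = as.character(seq_len(n)),
                     richness = sample(1:25, n, replace = TRUE))
    k <- sample(2:10, 1)
    qq <- suppressMessages(richness_quantiles(rr, k))
    expect_equal(qq$class, oracle_quantile_class(rr$richness, k))
    ord <- order(qq$richness)
    expect_true(!is.unsorted(qq$class[ord]))
  }
})

test_that("dominant driver applies argmax, two-way tie and star rules", {
  inc <- build_incidence(data.frame(
    species_id = c("d1", "d2", "d3", "c1",      # cell A: 3 disease 1 climate
                   "d4", "d5", "c2", "c3",      # cell B: 2 v 2 tie
                   "u1"),                        # cell C: undetermined only
    cell_id = c(rep("A", 4), rep("B", 4), "C")))
  ch <- data.frame(
    species_id = c(paste0("d", 1:5), paste0("c", 1:3), "u1"),
    epoch_from = 2004L, epoch_to = 2022L, from_state = "LC",
    to_state = "EN", genuine = TRUE, direction = "deterioration",
    became_extinct = FALSE,
    driver_group = c(rep("disease", 5), rep("climate_change", 3),
                     "undetermined"),
    conservation_driven = FALSE, stringsAsFactors = FALSE)
  dom <- dominant_driver(inc, ch, 2004L)
  A <- dom[dom$cell_id == "A", ]
  expect_equal(A$driver, "disease")
  expect_false(A$tie_flag); expect_false(A$star_flag)
  B <- dom[dom$cell_id == "B", ]
  expect_true(B$tie_flag)
  expect_equal(B$driver, "climate_change+disease")
  C <- dom[dom$cell_id == "C", ]
  expect_true(C$star_flag)
  # permutation invariance in species order
  perm <- sample(nrow(inc))
  dom2 <- dominant_driver(inc[perm, ], ch[sample(nrow(ch)), ], 2004L)
  expect_identical(dom[order(dom$cell_id), ], dom2[order(dom2$cell_id), ])
})

test_that("three-way ties and numerous-dominant cells are starred", {
  inc <- build_incidence(data.frame(
    species_id = c("x1", "x2", "x3", "n1", "n2"),
    cell_id = c("T", "T", "T", "N", "N")))
  ch <- data.frame(
    species_id = c("x1", "x2", "x3", "n1", "n2"),
    epoch_from = 1980L, epoch_to = 2004L, from_state = "LC",
    to_state = "VU", genuine = TRUE, direction = "deterioration",
    became_extinct = FALSE,
    driver_group = c("disease", "climate_change", "habitat_loss_degradation",
                     "numerous", "numerous"),
    conservation_driven = FALSE, stringsAsFactors = FALSE)
  dom <- dominant_driver(inc, ch, 1980L)
  expect_true(dom$star_flag[dom$cell_id == "T"])
  expect_true(dom$star_flag[dom$cell_id == "N"])
  expect_false(dom$tie_flag[dom$cell_id == "N"])
})

test_that("GeoJSON polygon ranges rasterize onto the equal-area grid", {
  g <- grid_spec(7775)
  # a polygon roughly 3 cells wide at the equator
  side_deg <- g$side_km / (111.32 * g$cosphi1)   # degrees lon per cell
  poly <- function(id, lon0, lat0, w, h) list(
    type = "Feature",
    properties = list(species_id = id),
    geometry = list(type = "Polygon", coordinates = list(list(
      list(lon0, lat0), list(lon0 + w, lat0), list(lon0 + w, lat0 + h),
      list(lon0, lat0 + h), list(lon0, lat0)))))
  gj <- list(type = "FeatureCollection",
             features = list(poly("p1", 0, 0, 3 * side_deg, 0.2),
                             poly("p2", 40, 10, 0.1, 0.1)))
  inc <- build_incidence(gj, g)
  expect_gte(length(unique(inc$cell_id[inc$species_id == "p1"])), 3L)
  expect_gte(nrow(inc[inc$species_id == "p2", ]), 1L)
  # disjoint single-cell ranges (tiny boxes centered on cell centers)
  # give two cells of richness 1
  center_lonlat <- function(col, row) {
    x <- (col + 0.5) * g$side_km - g$width / 2
    y <- (row + 0.5) * g$side_km - g$height / 2
    c(lon = x / (g$R * g$cosphi1) * 180 / pi,
      lat = asin(y * g$cosphi1 / g$R) * 180 / pi)
  }
  c1 <- center_lonlat(100, 50)
  c2 <- center_lonlat(300, 90)
  eps <- 0.01
  gj2 <- list(type = "FeatureCollection",
              features = list(
                poly("q1", c1["lon"] - eps, c1["lat"] - eps, 2 * eps, 2 * eps),
                poly("q2", c2["lon"] - eps, c2["lat"] - eps, 2 * eps, 2 * eps)))
  r <- cell_richness(build_incidence(gj2, g))
  expect_equal(nrow(r), 2L)
  expect_true(all(r$richness == 1L))
})

test_that("invalid features are skipped with a warning and counted", {
  bad <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(species_id = "ok"),
         geometry = list(type = "Polygon", coordinates = list(list(
           list(0, 0), list(1, 0), list(1, 1), list(0, 1), list(0, 0))))),
    list(type = "Feature", properties = list(),
         geometry = list(type = "Polygon", coordinates = list(list())))))
  expect_warning(inc <- build_incidence(bad, grid_spec(7775)),
                 "skipping invalid feature")
  expect_equal(attr(inc, "n_skipped"), 1L)
  expect_true(all(inc$species_id == "ok"))
})

test_that("grid presets have positive cell counts covering the world", {
  for (area in c(865, 7775)) {
    g <- grid_spec(area)
    expect_gt(g$ncol, 0); expect_gt(g$nrow, 0)
    expect_equal(g$side_km^2, area)
  }
})
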