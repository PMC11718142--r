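test_that("leaching index matches the hand sum and its edge cases", {
  s <- src_row(urine = 10, dung = 5, fert = 20, bg = 5)
  expect_equal(leaching_index(s, 0.1), 4.0) # 0.1 x 40
  expect_equal(leaching_index(s, 0), 0)
  expect_equal(leaching_index(src_row(), 0.7), 0)
  # effluent and cultivation mineralization count toward leaching
  expect_equal(leaching_index(src_row(effluent = 3, cult = 7), 0.5), 5)
  # aboveground residues and erosion do not
  expect_equal(leaching_index(src_row(ag = 100, erosion = 50), 1), 0)
  expect_error(leaching_index(s, 1.2), "leach_risk")
  expect_error(leaching_index(src_row(urine = -1), 0.5), ">= 0")
})

test_that("runoff index excludes urine and matches the hand sum", {
  expect_equal(runoff_index(src_row(urine = 100), 1), 0)
  s <- src_row(erosion = 10, dung = 5, fert = 5)
  expect_equal(runoff_index(s, 0.2), 4.0)
  expect_equal(runoff_index(src_row(dung = 7), 1), 7) # identity transport
  # belowground residues and cultivation are leaching-only
  expect_equal(runoff_index(src_row(bg = 50, cult = 20), 1), 0)
})

test_that("literal printed-equation mode weights non-erosion terms by leach risk", {
  s <- src_row(erosion = 10, dung = 6, fert = 4, ag = 2)
  lit <- runoff_index(s, runoff_risk = 0.5, leach_risk = 0.25,
                      literal_eq2 = TRUE)
  expect_equal(lit, 0.5 * 10 + 0.25 * (6 + 4 + 2))
  expect_equal(runoff_index(s, 0.5), 0.5 * 22)
  expect_error(runoff_index(s, 0.5, literal_eq2 = TRUE), "leach_risk")
})

test_that("indices are exactly linear in source vectors", {
  set.seed(33)
  for (i in 1:50) {
    a <- src_row(runif(1, 0, 50), runif(1, 0, 20), runif(1, 0, 10),
                 runif(1, 0, 80), runif(1, 0, 30), runif(1, 0, 30),
                 runif(1, 0, 40), runif(1, 0, 15))
    b <- src_row(runif(1, 0, 50), runif(1, 0, 20), runif(1, 0, 10),
                 runif(1, 0, 80), runif(1, 0, 30), runif(1, 0, 30),
                 runif(1, 0, 40), runif(1, 0, 15))
    lr <- runif(1); rr <- runif(1)
    ab <- a; ab[, -1] <- a[, -1] + b[, -1]
    expect_equal(leaching_index(ab, lr),
                 leaching_index(a, lr) + leaching_index(b, lr),
                 tolerance = 1e-12)
    expect_equal(runoff_index(ab, rr),
                 runoff_index(a, rr) + runoff_index(b, rr),
                 tolerance = 1e-12)
  }
})

test_that("increasing any in-scope source never decreases its index", {
  s <- src_row(urine = 5, dung = 5, effluent = 5, fert = 5, ag = 5, bg = 5,
               cult = 5, erosion = 5)
  for (col in c("urine_n", "dung_n", "effluent_n", "fert_n", "residue_bg_n",
                "cultivation_n")) {
    s2 <- s; s2[[col]] <- s2[[col]] + 10
    expect_gte(leaching_index(s2, 0.5), leaching_index(s, 0.5))
  }
  for (col in c("erosion_n", "dung_n", "fert_n", "residue_ag_n")) {
    s2 <- s; s2[[col]] <- s2[[col]] + 10
    expect_gte(runoff_index(s2, 0.5), runoff_index(s, 0.5))
  }
})

make_scores <- function() {
  transport <- data.frame(location_id = "loc1", soil_id = "s", slope = "flat",
                          irrigated = FALSE, month = 1:12,
                          leach_risk = 0.3, runoff_risk = 0.1)
  blocks <- data.frame(block_id = c("b1", "b2"), area_ha = c(10, 10),
                       land_use = "dairy", location_id = "loc1")
  s1 <- monthly_sources(); s1$urine_n <- 10; s1$erosion_n <- 5
  s2 <- monthly_sources(); s2$urine_n <- 30; s2$erosion_n <- 15
  risk_scores(blocks, list(b1 = s1, b2 = s2), transport)
}

test_that("risk_scores joins transport to sources; total is exact", {
  sc <- make_scores()
  expect_equal(nrow(sc), 24)
  expect_equal(sc$total, sc$leach_index + sc$runoff_index)
  expect_equal(sc$leach_index[sc$block_id == "b1"], rep(3, 12))
  expect_equal(sc$runoff_index[sc$block_id == "b1"], rep(0.5, 12))
  expect_error(risk_scores(data.frame(block_id = "bX", area_ha = 1,
                                      land_use = "dairy",
                                      location_id = "loc1"),
                           list(), data.frame()), "bX")
})

test_that("aggregation: annual sums, area weighting, pathway shares", {
  sc <- make_scores()
  ann <- aggregate_risk(sc, "annual")
  expect_equal(ann$total[ann$block_id == "b1"], 12 * 3.5)
  # two equal-area blocks: farm mean of 42 and 126 is 84
  farm <- aggregate_risk(sc, "farm",
                         blocks = data.frame(block_id = c("b1", "b2"),
                                             area_ha = c(10, 10)))
  expect_equal(farm$total, (42 + 126) / 2)
  # unequal areas weight accordingly
  farm2 <- aggregate_risk(sc, "farm",
                          blocks = data.frame(block_id = c("b1", "b2"),
                                              area_ha = c(30, 10)))
  expect_equal(farm2$total, (42 * 30 + 126 * 10) / 40)
  sh <- aggregate_risk(sc, "pathway_shares")
  expect_equal(sh$leach_share + sh$runoff_share, 1)
  expect_equal(sh$leach_share, sum(sc$leach_index) / sum(sc$total))
  # single block-month aggregate equals the input
  one <- sc[1, ]
  expect_equal(aggregate_risk(one, "annual")$total, one$total)
  expect_error(aggregate_risk(sc[0, ], "annual"), "non-empty")
})

test_that("multi-year linearity: mean of yearly risks = risk of mean sources", {
  transport <- data.frame(month = 1:12, leach_risk = 0.25, runoff_risk = 0.05)
  set.seed(44)
  y1 <- monthly_sources(); y1$fert_n <- runif(12, 0, 60)
  y2 <- monthly_sources(); y2$fert_n <- runif(12, 0, 60)
  li1 <- leaching_index(y1, transport$leach_risk)
  li2 <- leaching_index(y2, transport$leach_risk)
  avg <- y1; avg$fert_n <- (y1$fert_n + y2$fert_n) / 2
  expect_equal((li1 + li2) / 2, leaching_index(avg, transport$leach_risk),
               tolerance = 1e-12)
})

test_that("hydrological year basis regroups September-December", {
  sc <- rbind(
    data.frame(block_id = "b", month = 1:12, leach_index = 1,
               runoff_index = 0, total = 1, year = 2001),
    data.frame(block_id = "b", month = 1:12, leach_index = 2,
               runoff_index = 0, total = 2, year = 2002)
  )
  cal <- aggregate_risk(sc, "annual", year_basis = "calendar")
  expect_equal(cal$total, c(12, 24))
  hyd <- aggregate_risk(sc, "annual", year_basis = "hydrological")
  # hydrological 2002 = Sep-Dec 2001 (4 months at 1) + Jan-Aug 2002 (8 at 2)
  expect_equal(hyd$total[hyd$year == 2002], 4 * 1 + 8 * 2)
})
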