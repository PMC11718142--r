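rates <- data.frame(stock_class = c("sheep_ewe", "dairy_milking"),
                    age_class = "adult", region = "default",
                    urine_n_kg_head = c(1.0, 8.0),
                    dung_n_kg_head = c(0.3, 3.0))

test_that("excreta N follows hand multiplication and per-hectare scaling", {
  stock <- data.frame(month = 1, stock_class = "sheep_ewe",
                      age_class = "adult", region = "default", head = 100)
  ex <- excreta_n(stock, rates, area_ha = 50)
  # 100 head x 1.0 / 50 ha = 2.0; dung 100 x 0.3 / 50 = 0.6
  expect_equal(ex$urine_n[1], 2.0)
  expect_equal(ex$dung_n[1], 0.6)
  expect_equal(ex$effluent_n[1], 0)
  expect_true(all(ex$urine_n[-1] == 0))
  # doubled area halves everything
  ex2 <- excreta_n(stock, rates, area_ha = 100)
  expect_equal(ex2$urine_n[1], 1.0)
  expect_equal(ex2$dung_n[1], 0.3)
  # zero animals
  ex0 <- excreta_n(stock[0, ], rates, area_ha = 50)
  expect_true(all(ex0$urine_n == 0 & ex0$dung_n == 0 & ex0$effluent_n == 0))
})

test_that("excreta N is linear in head counts and effluent follows milking cows", {
  mk <- function(head) {
    excreta_n(data.frame(month = 3, stock_class = "dairy_milking",
                         age_class = "adult", region = "default",
                         head = head),
              rates, area_ha = 20,
              effluent = list(milking_class = "dairy_milking",
                              n_kg_head_month = 0.9))
  }
  one <- mk(10)
  three <- mk(30)
  expect_equal(three$urine_n, 3 * one$urine_n)
  expect_equal(three$dung_n, 3 * one$dung_n)
  expect_equal(one$effluent_n[3], 10 * 0.9 / 20)
  # unknown stock key errors and names the key
  bad <- data.frame(month = 1, stock_class = "llama", age_class = "adult",
                    region = "default", head = 5)
  expect_error(excreta_n(bad, rates, 10), "llama")
})

test_that("fertilizer N is mass x fraction, bucketed by month", {
  products <- data.frame(product_id = c("urea", "dap"),
                         n_fraction = c(0.46, 0.18))
  f <- fertilizer_n(data.frame(product_id = "urea", mass_kg_ha = 100,
                               month = 9), products)
  expect_equal(f[9], 46)
  expect_equal(sum(f[-9]), 0)
  # same-month applications sum; different months do not
  f2 <- fertilizer_n(data.frame(product_id = c("urea", "urea", "dap"),
                                mass_kg_ha = c(100, 50, 100),
                                month = c(9, 9, 10)), products)
  expect_equal(f2[9], 69)
  expect_equal(f2[10], 18)
  expect_equal(fertilizer_n(data.frame(product_id = character(0),
                                       mass_kg_ha = numeric(0),
                                       month = integer(0)), products),
               numeric(12))
  expect_error(
    fertilizer_n(data.frame(product_id = "guano", mass_kg_ha = 1, month = 1),
                 products), "guano")
})

test_that("residue N honours the C:N threshold and rooting adjustments", {
  base <- list(yield_t_ha = 10, residue_fraction = 1, n_conc_ag = 0,
               n_conc_bg = 1, cn_ratio = 20, rooting = "shallow")
  # 10 t x 1 kg N/t = 10 kg bg N; shallow x1.4 = 14, over months 7,8,9
  r <- residue_n(base, harvest_month = 6)
  expect_equal(sum(r$residue_bg_n), 14)
  expect_equal(r$residue_bg_n[7:9], rep(14 / 3, 3))
  expect_equal(sum(r$residue_bg_n[-(7:9)]), 0)
  # deep x0.7 = 7
  deep <- base; deep$rooting <- "deep"
  expect_equal(sum(residue_n(deep, 6)$residue_bg_n), 7)
  # intermediate x1.0
  mid <- base; mid$rooting <- "intermediate"
  expect_equal(sum(residue_n(mid, 6)$residue_bg_n), 10)
  # C:N at or above 25: immobilized, zero release
  hi <- base; hi$cn_ratio <- 30
  expect_true(all(residue_n(hi, 6)$residue_bg_n == 0))
  at <- base; at$cn_ratio <- 25
  expect_true(all(residue_n(at, 6)$residue_bg_n == 0))
  # zero yield
  zy <- base; zy$yield_t_ha <- 0
  expect_true(all(residue_n(zy, 6)$residue_bg_n == 0))
  # release wraps the calendar for late harvests
  wrap <- residue_n(base, harvest_month = 11)
  expect_equal(which(wrap$residue_bg_n > 0), c(1, 2, 12))
})

test_that("residue release sums to the adjusted total to high precision", {
  set.seed(11)
  for (i in 1:20) {
    crop <- list(yield_t_ha = runif(1, 0, 60),
                 residue_fraction = runif(1),
                 n_conc_ag = runif(1, 0, 10), n_conc_bg = runif(1, 0, 5),
                 cn_ratio = runif(1, 5, 24.9),
                 rooting = sample(c("shallow", "deep", "intermediate"), 1))
    h <- sample(1:12, 1)
    r <- residue_n(crop, h)
    mult <- c(shallow = 1.4, deep = 0.7, intermediate = 1.0)[[crop$rooting]]
    expect_equal(sum(r$residue_ag_n),
                 crop$yield_t_ha * crop$residue_fraction * crop$n_conc_ag,
                 tolerance = 1e-9)
    expect_equal(sum(r$residue_bg_n),
                 crop$yield_t_ha * crop$residue_fraction * crop$n_conc_bg * mult,
                 tolerance = 1e-9)
  }
})

test_that("cultivation mineralization releases the pool, long >= short", {
  long <- cultivation_n("long", "dairy", cultivation_month = 9)
  short <- cultivation_n("short", "dairy", cultivation_month = 9)
  expect_gte(sum(long$cultivation_n), sum(short$cultivation_n))
  # released total equals the pool within 1 %
  expect_equal(sum(long$cultivation_n), 300, tolerance = 0.01)
  expect_equal(sum(short$cultivation_n), 150, tolerance = 0.01)
  # releases decline month over month (first-order)
  rel <- cultivation_n("long", "dairy", cultivation_month = 1)$cultivation_n[1:6]
  expect_true(all(diff(rel) < 0))
  # fallow stretches the horizon: first-month release is smaller
  fal <- cultivation_n("long", "dairy", cultivation_month = 1,
                       fallow_months = 3)
  expect_lt(fal$cultivation_n[1], rel[1])
  expect_equal(sum(fal$cultivation_n), 300, tolerance = 0.01)
})

test_that("erosion N evaluates the sediment calibration line", {
  # estimated 20 t/ha -> 0.92 x 20 - 15.7 = 2.7 t/ha; x 1000 x 0.003 = 8.1
  e <- erosion_n(cover_factor = 0.04, multiplier = 500,
                 soil_n_fraction = 0.003)
  expect_equal(e$estimated_t_ha, 20)
  expect_equal(e$calibrated_t_ha, 2.7, tolerance = 1e-12)
  expect_equal(e$erosion_n_kg_ha, 8.1, tolerance = 1e-12)
  expect_equal(e$monthly_n_kg_ha, 2.7, tolerance = 1e-12)
  # below the calibration floor: negative -> 0
  expect_equal(erosion_n(0.02, 500, 0.003)$erosion_n_kg_ha, 0)
  # zero cover factor -> 0
  expect_equal(erosion_n(0, 500, 0.003)$erosion_n_kg_ha, 0)
})

test_that("erosion N is non-decreasing in cover, multiplier and N fraction", {
  set.seed(12)
  for (i in 1:20) {
    cf <- runif(1, 0, 0.2); mu <- runif(1, 70, 800); nf <- runif(1, 0, 0.01)
    base <- erosion_n(cf, mu, nf)$erosion_n_kg_ha
    expect_gte(erosion_n(cf * 1.3, mu, nf)$erosion_n_kg_ha, base)
    expect_gte(erosion_n(cf, mu * 1.3, nf)$erosion_n_kg_ha, base)
    expect_gte(erosion_n(cf, mu, nf * 1.3)$erosion_n_kg_ha, base)
  }
})

test_that("assembled sources equal independent per-category recomputation", {
  tables <- list(excreta_rates = rates,
                 fertilizer_products = data.frame(product_id = "urea",
                                                  n_fraction = 0.46))
  crop <- data.frame(crop_id = "onions", yield_t_ha = 40,
                     residue_fraction = 0.2, n_conc_ag = 2.4, n_conc_bg = 0.8,
                     cn_ratio = 15, rooting = "shallow", harvest_month = 2)
  cal <- list(
    area_ha = 25, land_use = "cropping", tables = tables,
    stock = data.frame(month = c(5, 6), stock_class = "sheep_ewe",
                       age_class = "adult", region = "default", head = 200),
    fertilizer = data.frame(product_id = "urea", mass_kg_ha = 80, month = 10),
    crops = crop,
    cultivation = data.frame(age_class = "short", enterprise = "sheep-and-beef",
                             cultivation_month = 9, fallow_months = 0),
    erosion = data.frame(season = "winter", cover_factor = 0.05,
                         multiplier = 600)
  )
  out <- assemble_monthly_sources(cal, soil_n_fraction = 0.004)
  ex <- excreta_n(cal$stock, rates, 25)
  expect_equal(out$urine_n, ex$urine_n)
  expect_equal(out$dung_n, ex$dung_n)
  expect_equal(out$fert_n, fertilizer_n(cal$fertilizer,
                                        tables$fertilizer_products))
  res <- residue_n(crop, 2)
  expect_equal(out$residue_ag_n, res$residue_ag_n)
  expect_equal(out$residue_bg_n, res$residue_bg_n)
  cn <- cultivation_n("short", "sheep-and-beef", cultivation_month = 9)
  expect_equal(out$cultivation_n, cn$cultivation_n)
  en <- erosion_n(0.05, 600, 0.004)
  expect_equal(out$erosion_n[6:8], rep(en$monthly_n_kg_ha, 3))
  expect_true(all(out$erosion_n[-(6:8)] == 0))
  expect_true(all(as.matrix(out[, -1]) >= 0))
})

test_that("empty calendar gives all-zero sources; fertilizer-only is isolated", {
  tables <- list(excreta_rates = rates,
                 fertilizer_products = data.frame(product_id = "urea",
                                                  n_fraction = 0.46))
  empty <- assemble_monthly_sources(list(area_ha = 10, land_use = "dairy",
                                         tables = tables))
  expect_true(all(as.matrix(empty[, -1]) == 0))
  fert_only <- assemble_monthly_sources(list(
    area_ha = 10, land_use = "dairy", tables = tables,
    fertilizer = data.frame(product_id = "urea", mass_kg_ha = 50, month = 4)))
  expect_equal(fert_only$fert_n[4], 23)
  cols <- setdiff(names(fert_only), c("month", "fert_n"))
  expect_true(all(as.matrix(fert_only[, cols]) == 0))
})
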