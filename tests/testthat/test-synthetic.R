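test_that("simulation is fully deterministic under (config, seed)", {
  a <- simulate_dataset(sim_config(seed = 3))
  b <- simulate_dataset(sim_config(seed = 3))
  expect_identical(a$reserves, b$reserves)
  expect_identical(a$pool, b$pool)
  expect_identical(a$occurrences, b$occurrences)
  c <- simulate_dataset(sim_config(seed = 4))
  expect_false(identical(a$occurrences, c$occurrences))
})

test_that("zero covariate noise collapses climate onto the declared gradients", {
  cfg <- sim_config(seed = 2, noise = 0)
  res <- simulate_reserves(cfg)
  expect_equal(res$MTCM, cfg$mtcm_c0 - cfg$mtcm_c1 * res$lat)
  expect_equal(res$LGM_MTCM,
               res$MTCM - (4 + 0.15 * (res$lat - cfg$lat_range[1])))
  expect_equal(res$PET2, res$PET^2)
})

test_that("winter coldness tracks latitude tightly under defaults", {
  res <- simulate_reserves(sim_config(seed = 1))
  expect_lt(cor(res$MTCM, res$lat), -0.9)
  expect_lt(cor(res$LGM_MTCM, res$lat), -0.9)
  expect_true(all(res$lat >= 19.1 & res$lat <= 51.5))
  expect_true(all(res$TR >= 1))
  expect_true(all(res$MAP >= 0))
})

test_that("pool tolerances follow the affinity targets and RD coupling", {
  cfg <- sim_config(seed = 5)
  pool <- simulate_pool(cfg)
  expect_equal(nrow(pool), sum(cfg$pool_sizes))
  expect_true(all(table(pool$affinity)[names(cfg$pool_sizes)] ==
                  cfg$pool_sizes))
  expect_true(all(pool$warm_limit >= pool$cold_limit))

  # affinity means within 2 sd of targets (moment check on the draws)
  for (aff in names(cfg$cold_limit)) {
    i <- pool$affinity == aff
    mu <- cfg$cold_limit[[aff]][["mean"]]
    sd <- cfg$cold_limit[[aff]][["sd"]]
    # remove the RD shift before comparing against the affinity mean
    shift <- ifelse(classify_thermal_origin(pool$order[i]) %in%
                      names(cfg$cold_shift),
                    cfg$cold_shift[classify_thermal_origin(pool$order[i])],
                    0) * (pool$rd[i] - cfg$rd_ref)
    centred <- pool$cold_limit[i] + shift
    expect_lt(abs(mean(centred) - mu), 2 * sd / sqrt(sum(i)) * 3)
  }

  # derived orders are more cold-tolerant: negative rank correlation between
  # order RD and mean cold limit
  ord_means <- aggregate(cold_limit ~ order, pool, mean)
  ord_rd <- cfg$rd_table[ord_means$order]
  expect_lt(cor(ord_rd, ord_means$cold_limit, method = "spearman"), 0)
})

test_that("degenerate unlimited tolerances admit every species everywhere", {
  cfg <- sim_config(seed = 6,
                    cold_limit = list(Oriental = c(mean = -1e6, sd = 0),
                                      Palearctic = c(mean = -1e6, sd = 0),
                                      widespread = c(mean = -1e6, sd = 0)),
                    warm_limit = list(Oriental = c(mean = 1e6, sd = 0),
                                      Palearctic = c(mean = 1e6, sd = 0),
                                      widespread = c(mean = 1e6, sd = 0)))
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$occurrences))
  # saturated occupancy means constant richness, hence non-significant patterns
  ep <- expected_patterns(ds)
  expect_true(all(ep$p_value[1:3] >= 0.05))
})

test_that("the occupancy filter is the stated interval rule", {
  cfg <- sim_config(seed = 8)
  ds <- simulate_dataset(cfg)
  res <- ds$reserves
  pool <- ds$pool
  # brute-force double loop over species x reserves
  for (r in sample(nrow(res), 15)) {
    for (s in sample(nrow(pool), 25)) {
      expected <- res$LGM_MTCM[r] >= pool$cold_limit[s] &&
        res$LGM_MTCM[r] <= pool$warm_limit[s]
      expect_identical(unname(ds$occurrences[r, s]), expected)
    }
  }
})

test_that("interval membership fixtures behave at the boundaries", {
  cfg <- sim_config(seed = 9)
  pool <- data.frame(species = "sp1", affinity = "widespread",
                     order = "Coleoptera", rd = 7,
                     cold_limit = -5, warm_limit = 5)
  mk_res <- function(lgm) data.frame(reserve_id = "R1", LGM_MTCM = lgm)
  expect_true(assemble(pool, mk_res(0), cfg)[1, 1])
  expect_false(assemble(pool, mk_res(-10), cfg)[1, 1])
  expect_true(assemble(pool, mk_res(-5), cfg)[1, 1])   # closed at the limits
  expect_true(assemble(pool, mk_res(5), cfg)[1, 1])
  expect_false(assemble(pool, mk_res(5.001), cfg)[1, 1])
})

test_that("per-reserve richness identities hold", {
  ds <- simulate_dataset(sim_config(seed = 10))
  sm <- dataset_summaries(ds)
  expect_equal(sm$richness, sm$oriental + sm$palearctic + sm$widespread)
  expect_true(all(sm$warm_richness + sm$cold_richness <= sm$richness))
})

test_that("default simulations show the built-in geographic patterns", {
  ds <- simulate_dataset(sim_config(seed = 7))
  ep <- expected_patterns(ds)
  expect_true(all(ep$pass))
  # the total-richness peak falls inside the declared overlap band, widened
  # by the niche sds
  sm <- dataset_summaries(ds)
  quad <- fit_latitudinal(sm$richness, sm$lat, "quadratic", log_y = TRUE)
  pk <- peak_latitude(quad)
  band <- ds$truth$expected_peak_band
  expect_gt(pk$peak, band[1] - 5)
  expect_lt(pk$peak, band[2] + 5)
})

test_that("random occupancy erases the geographic patterns", {
  ds <- simulate_dataset(sim_config(seed = 12, occupancy = "random"))
  ep <- expected_patterns(ds)
  expect_true(all(!ep$pass))
})

test_that("narrower widespread niches sharpen the midlatitude peak", {
  peak_height <- function(breadth, seed = 30) {
    cfg <- sim_config(
      seed = seed,
      cold_limit = list(Oriental = c(mean = -2, sd = 4),
                        Palearctic = c(mean = -35, sd = 5),
                        widespread = c(mean = -20, sd = breadth)),
      warm_limit = list(Oriental = c(mean = 40, sd = 3),
                        Palearctic = c(mean = -8, sd = 5),
                        widespread = c(mean = 8, sd = breadth)))
    ds <- simulate_dataset(cfg)
    sm <- dataset_summaries(ds)
    band <- ds$truth$expected_peak_band
    centre <- mean(band)
    mid <- sm$widespread[abs(sm$lat - centre) < 4]
    edge <- sm$widespread[sm$lat > band[2] + 5]
    mean(mid) / max(1, mean(edge))
  }
  ratios <- vapply(c(8, 4, 2), peak_height, numeric(1L))
  expect_true(all(diff(ratios) > 0))  # shrinking breadth concentrates the band
})
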