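test_that("the response statistic is the background double subtraction", {
  expect_equal(compute_response(8e5, 1e5, 2e5, 1e5), 6e5)
  expect_equal(compute_response(5e5, 5e5, 5e5, 5e5), 0)
  expect_equal(compute_response(1e5, 2e5, 3e5, 1e5), -3e5)
  # a missing condition propagates, never silently zero
  expect_true(is.na(compute_response(NA, 1e5, 2e5, 1e5)))
})

test_that("plate-wide additive offsets cancel exactly", {
  withr::with_seed(88, {
    for (i in 1:100) {
      f <- runif(4, 0, 1e6)
      off <- runif(1, -1e6, 1e6)
      expect_identical(compute_response(f[1] + off, f[2] + off,
                                        f[3] + off, f[4] + off),
                       compute_response(f[1], f[2], f[3], f[4]))
    }
  })
})

test_that("hit calls use a strict threshold", {
  expect_false(call_hit(3.0e5))
  expect_true(call_hit(3.1e5))
  expect_false(call_hit(-5e5))
  expect_error(call_hit(1e5, threshold = 0), "positive")
})

test_that("raising the OR+odorant signal never unmakes a hit", {
  withr::with_seed(12, {
    for (i in 1:100) {
      f <- runif(4, 0, 1e6)
      r0 <- compute_response(f[1], f[2], f[3], f[4])
      r1 <- compute_response(f[1] + runif(1, 0, 5e5), f[2], f[3], f[4])
      expect_true(!call_hit(r0) || call_hit(r1))
    }
  })
})

test_that("replicate aggregation returns mean, sem and n", {
  a <- aggregate_replicates(c(4, 6))
  expect_equal(a$mean, 5)
  expect_equal(a$sem, 1)
  expect_equal(a$n, 2L)
  b <- aggregate_replicates(5)
  expect_equal(b$mean, 5)
  expect_true(is.na(b$sem))
  expect_error(aggregate_replicates(numeric(0)), "at least one")
  # law of large numbers sanity at scale
  withr::with_seed(4, {
    x <- rnorm(10000, mean = 5, sd = 1)
    ag <- aggregate_replicates(x)
    expect_lt(abs(ag$mean - 5), 3 / sqrt(10000))
  })
})

test_that("percent-of-maximum normalization keeps signs and refuses", {
  expect_equal(normalize_profile(c(2e5, 6e5, 3e5)),
               c(100 / 3, 100, 50), tolerance = 1e-10)
  expect_equal(normalize_profile(7), 100)
  expect_equal(normalize_profile(c(-1e5, 4e5)), c(-25, 100))
  expect_error(normalize_profile(c(-2, 0)), "refused")
})

test_that("lowest effective concentration maps to potency classes", {
  h <- c(`10` = TRUE, `100` = TRUE, `1000` = TRUE)
  r <- lowest_effective_concentration(h)
  expect_equal(r$lowest_effective_uM, 10)
  expect_equal(r$potency_class, "high")
  r2 <- lowest_effective_concentration(c(`10` = FALSE, `100` = FALSE,
                                         `1000` = TRUE))
  expect_equal(r2$lowest_effective_uM, 1000)
  expect_equal(r2$potency_class, "low")
  r3 <- lowest_effective_concentration(c(`10` = FALSE, `100` = FALSE,
                                         `1000` = FALSE))
  expect_true(is.na(r3$lowest_effective_uM))
  expect_equal(r3$potency_class, "none")
  expect_error(lowest_effective_concentration(logical(0)), "no concentration")
})

test_that("plate QC passes at exactly the 0.70 boundary", {
  expect_true(qc_plate(0.70)$pass)
  expect_false(qc_plate(0.69)$pass)
  expect_true(qc_plate(1.0)$pass)
  expect_error(qc_plate(1.2), "\\[0, 1\\]")
})

test_that("noiseless simulated screens are quantified exactly", {
  ors <- sprintf("OR%d", 1:4)
  ods <- sprintf("od%02d", 1:6)
  ag <- data.frame(or_name = c("OR1", "OR2"), odorant = c("od01", "od02"),
                   potency = c("potent", "weak"), effect_AU = 6e5)
  sim <- simulate_plate_dataset(ors, ods, ag, noise_sd_AU = 0, seed = 61)
  q <- quantify_plate_dataset(sim$wells, qc = sim$qc)
  expect_true(all(q$responses$evaluable))
  # agonist responses recover effect x saturation exactly; nulls are 0
  r11 <- q$responses[q$responses$or_name == "OR1" &
                       q$responses$odorant == "od01", ]
  expect_equal(r11$R_AU[order(r11$concentration_uM)],
               6e5 * c(0.6, 0.9, 1.0))
  nulls <- q$responses[!(paste(q$responses$or_name,
                               q$responses$odorant) %in%
                           paste(ag$or_name, ag$odorant)), ]
  expect_true(all(nulls$R_AU == 0))
  # potency matrix equals the generator truth
  h <- hit_table(q$responses)
  merged <- merge(h, sim$truth, by = c("or_name", "odorant"))
  expect_equal(merged$potency_class, merged$true_potency_class)
})

test_that("failing plates are excluded by QC with a logged reason", {
  ors <- "OR1"; ods <- c("odA", "odB")
  sim <- simulate_plate_dataset(ors, ods, noise_sd_AU = 0, seed = 62)
  qc <- sim$qc
  qc$gfp_fraction[qc$plate_id == "plate_odA"] <- 0.5
  q <- quantify_plate_dataset(sim$wells, qc = qc)
  expect_equal(q$excluded_plates, "plate_odA")
  expect_false(any(q$responses$odorant == "odA"))
  expect_false(q$qc_log$pass[q$qc_log$plate_id == "plate_odA"])
})

test_that("missing conditions are reported not-evaluable, never zero", {
  sim <- simulate_plate_dataset("OR1", "odA", noise_sd_AU = 0, seed = 63)
  wells <- sim$wells
  # drop the empty-vector + odorant wells at 100 uM
  drop <- wells$construct == "empty_vector" & !is.na(wells$odorant) &
    wells$concentration_uM == 100
  q <- quantify_plate_dataset(wells[!drop, ])
  bad <- q$responses[q$responses$concentration_uM == 100, ]
  expect_false(bad$evaluable)
  expect_true(is.na(bad$R_AU))
})

test_that("untagged and Rho-tagged constructs are never pooled", {
  sim <- simulate_plate_dataset("OR1", "odA", rho_tagged = c(FALSE, TRUE),
                                noise_sd_AU = 0, seed = 64)
  wells <- sim$wells
  # give the tagged construct an extra response by hand
  bump <- wells$construct == "OR" & wells$rho_tagged &
    !is.na(wells$odorant) & wells$concentration_uM == 10
  wells$fluorescence_AU[bump] <- wells$fluorescence_AU[bump] + 5e5
  q <- quantify_plate_dataset(wells)
  r <- q$responses[q$responses$concentration_uM == 10, ]
  expect_equal(nrow(r), 2L)
  expect_equal(r$R_AU[r$rho_tagged], 5e5)
  expect_equal(r$R_AU[!r$rho_tagged], 0)
})

test_that("screen summaries count odorants, receptors and tuning breadth", {
  ors <- sprintf("OR%d", 1:3)
  ods <- sprintf("od%d", 1:5)
  ag <- data.frame(or_name = c("OR1", "OR1", "OR2"),
                   odorant = c("od1", "od2", "od1"),
                   potency = c("potent", "weak", "potent"),
                   effect_AU = 6e5)
  sim <- simulate_plate_dataset(ors, ods, ag, noise_sd_AU = 0, seed = 65)
  q <- quantify_plate_dataset(sim$wells)
  s <- summarize_screen(hit_table(q$responses))
  expect_equal(s$n_odorants_responding, 2L)
  expect_equal(s$n_odorants_hit_at_10uM, 1L)
  expect_equal(s$n_ors_hit_at_10uM, 2L)
  breadth <- setNames(s$tuning_breadth$n_odorants,
                      s$tuning_breadth$or_name)
  expect_equal(breadth[["OR1"]], 2L)
  expect_equal(breadth[["OR2"]], 1L)
  expect_equal(breadth[["OR3"]], 0L)
})
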