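test_that("reaction tolerance caps at the default accommodation bound", {
  expect_equal(reaction_tolerance(0.2), 0.2)
  expect_equal(reaction_tolerance(1.0), 0.4)
  expect_equal(reaction_tolerance(NA_real_), 0.4)
  expect_equal(reaction_tolerance(c(0.2, 1.0, NA)), c(0.2, 0.4, 0.4))
  expect_equal(reaction_tolerance(0.3, default_tol = 0.25), 0.25)
  expect_error(reaction_tolerance(-0.1), class = "buildplanr_value_error")
})

test_that("identical annealing optima give a flat plan with zero deviation", {
  rx <- tibble::tibble(id = 1:5, ta_opt = rep(60, 5), delta = NA_real_)
  plan <- plan_gradient(rx)
  expect_equal(plan$t_low, plan$t_high)
  expect_equal(plan$assignments$deviation, rep(0, 5))
  prog <- build_pcr_program(plan, ext_s = 30)
  expect_equal(prog$steps$temp_low_c[3], prog$steps$temp_high_c[3])
})

test_that("a spread set is accommodated with the hottest reaction hottest", {
  rx <- tibble::tibble(id = 1:5, ta_opt = c(58, 58.4, 59.1, 60.2, 64.5),
                       delta = NA_real_)
  plan <- plan_gradient(rx)
  a <- plan$assignments
  expect_true(all(a$deviation <= a$tolerance + 1e-12))
  expect_equal(a$zone[which.max(a$ta_opt)], max(a$zone))
  # numeric optimum agrees with exhaustive brute force
  bf <- bf_gradient(rx$ta_opt, rep(0.4, 5))
  expect_equal(plan$t_low, bf$t_low)
  expect_equal(plan$t_high, bf$t_high)
  expect_equal(max(pmax(a$deviation - a$tolerance, 0)), bf$excess)
})

test_that("planner matches the brute-force endpoint oracle across seeds", {
  set.seed(202)
  for (rep in 1:12) {
    n <- sample(2:8, 1)
    ta <- round(runif(n, 58, 66) * 10) / 10
    delta <- sample(c(0.2, 1.0, NA), n, replace = TRUE)
    rx <- tibble::tibble(id = seq_len(n), ta_opt = ta, delta = delta)
    tol <- reaction_tolerance(delta)
    plan <- tryCatch(plan_gradient(rx),
                     buildplanr_gradient_infeasible = function(e) NULL)
    bf <- bf_gradient(ta, tol)
    if (is.null(plan)) {
      expect_gt(bf$excess, 0)
    } else {
      a <- plan$assignments
      expect_equal(max(pmax(a$deviation - a$tolerance, 0)), bf$excess,
                   tolerance = 1e-9)
      expect_equal(plan$t_low, bf$t_low)
      expect_equal(plan$t_high, bf$t_high)
    }
  }
})

test_that("spans beyond the block gradient range are infeasible", {
  rx <- tibble::tibble(id = 1:2, ta_opt = c(55, 72.5), delta = NA_real_)
  plan <- plan_gradient(rx, gradient_geometry(max_span_c = 24))
  expect_equal(sort(unique(plan$assignments$zone)), c(1L, 12L))
  err <- expect_error(
    plan_gradient(rx, gradient_geometry(max_span_c = 15)),
    class = "buildplanr_gradient_infeasible")
  expect_match(conditionMessage(err), "split run")
})

test_that("a spread within two-thirds of the zone spacing budget stays under 0.4 degC", {
  # 12 zones over <= 8 degC: spacing <= 8/11, half-spacing <= 0.364
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    ta <- round(runif(n, 58, 66) * 10) / 10
    plan <- plan_gradient(tibble::tibble(id = seq_len(n), ta_opt = ta,
                                         delta = NA_real_))
    expect_lt(max(plan$assignments$deviation), 0.4)
  }
})

test_that("zone temperatures are equally spaced and id-relabel invariant", {
  rx <- tibble::tibble(id = 1:6, ta_opt = c(58.2, 59, 60.1, 61.7, 62, 63.3),
                       delta = NA_real_)
  plan <- plan_gradient(rx)
  expect_equal(diff(plan$zone_temps),
               rep(diff(plan$zone_temps)[1], 11), tolerance = 1e-9)
  # relabeling ids permutes rows but never changes the gradient
  rx2 <- rx[c(3, 1, 6, 2, 5, 4), ]
  rx2$id <- 11:16
  plan2 <- plan_gradient(rx2)
  expect_equal(plan2$zone_temps, plan$zone_temps)
  expect_equal(sort(plan2$assignments$zone), sort(plan$assignments$zone))
})

test_that("tubes fill rows top-down within a zone in id order", {
  rx <- tibble::tibble(id = 1:2, ta_opt = c(60, 60.05), delta = NA_real_)
  geom <- gradient_geometry()
  plan <- plan_gradient(rx, geom)
  # both reactions land in the same zone; force it to zone 6 to check naming
  plan$assignments$zone <- c(6L, 6L)
  plan <- assign_tubes(plan, geom)
  expect_equal(plan$assignments$position, c("A6", "B6"))

  single <- plan_gradient(tibble::tibble(id = 1, ta_opt = 60,
                                         delta = NA_real_))
  expect_equal(single$assignments$position, "A1")

  crowded <- plan_gradient(tibble::tibble(id = 1:9, ta_opt = rep(60, 9),
                                          delta = NA_real_))
  crowded$assignments$zone <- rep(1L, 9)
  expect_error(assign_tubes(crowded, geom),
               class = "buildplanr_layout_error")
})

test_that("extension time covers the longest product, rounded up", {
  expect_equal(extension_time(1000), 30)
  expect_equal(extension_time(c(800, 2400, 3200)), 100)
  expect_equal(extension_time(150), 10)
  expect_equal(extension_time(c(1000), rate_s_per_kb = 60), 60)
  expect_error(extension_time(numeric(0)), class = "buildplanr_value_error")
  expect_error(extension_time(c(1000, -5)), class = "buildplanr_value_error")
})

test_that("the amplification program has the published shape", {
  rx <- tibble::tibble(id = 1:3, ta_opt = c(59, 60, 62), delta = NA_real_)
  plan <- plan_gradient(rx)
  prog <- build_pcr_program(plan, ext_s = 45)
  expect_equal(nrow(prog$steps), 5)
  expect_equal(prog$steps$temp_low_c[1], 98)
  expect_equal(prog$steps$duration_s[1], 30)
  expect_equal(prog$steps$duration_s[2], 10)
  expect_equal(prog$steps$temp_low_c[3], plan$t_low)
  expect_equal(prog$steps$temp_high_c[3], plan$t_high)
  # final extension: 5 minutes at 72 degC
  expect_equal(prog$steps$temp_low_c[5], 72)
  expect_equal(prog$steps$duration_s[5], 300)
  expect_equal(prog$cycled, c(2L, 4L, 34L))
  expect_equal(program_duration(prog),
               30 + 34 * (10 + 30 + 45) + 300)
})

test_that("the digestion program is 30 min at 37 then 20 min at 65", {
  prog <- build_dpn1_program()
  expect_equal(prog$steps$temp_low_c, c(37, 65))
  expect_equal(prog$steps$duration_s, c(1800, 1200))
  expect_null(prog$cycled)
  expect_equal(program_duration(prog), 3000)
})

test_that("the restriction-ligation program cycles 37/16 then holds and kills", {
  prog <- build_goldengate_program()
  expect_equal(prog$cycled, c(1L, 2L, 30L))
  expect_equal(prog$steps$temp_low_c, c(37, 16, 50, 80))
  single <- build_goldengate_program(n_cycles = 1)
  expect_null(single$cycled)
  expect_equal(nrow(single$steps), 4)
  expect_equal(prog$steps$temp_low_c[nrow(prog$steps)], 80)
  expect_equal(program_duration(prog), 30 * 600 + 300 + 600)
})
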