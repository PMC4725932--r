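test_that("schedules from hand-countable cohorts match direct counts", {
  ## one individual, dies at age 2, reproduces on its last day
  co1 <- makeCohort(list(makeIndividual(2, c(0, 0, 3), adultAge = 2)))
  s1 <- buildSchedules(co1)
  expect_equal(survivalSchedule(s1), c(1, 1, 1))
  expect_equal(fecunditySchedule(s1), c(0, 0, 3))

  ## A dies age 1 (offspring 0,2), B dies age 3 (offspring 0,0,4,0)
  co2 <- makeCohort(list(
    makeIndividual(1, c(0, 2), adultAge = 1),
    makeIndividual(3, c(0, 0, 4, 0), adultAge = 2)))
  s2 <- buildSchedules(co2)
  expect_equal(survivalSchedule(s2), c(1, 1, 0.5, 0.5))
  expect_equal(fecunditySchedule(s2), c(0, 1, 4, 0))
  ## age-stage occupancy sums back to l_x
  expect_equal(rowSums(stageOccupancy(s2)), survivalSchedule(s2))
})

test_that("sum l_x m_x conserves mean lifetime offspring on random cohorts", {
  for (seed in 1:5) {
    sim <- simulateCohort(cohortSimSpec(n = 40), seed = seed)
    s <- buildSchedules(sim$cohort)
    total <- sum(vapply(sim$cohort@offspring, sum, numeric(1)))
    expect_equal(sum(survivalSchedule(s) * fecunditySchedule(s)),
                 total / nIndividuals(sim$cohort))
    expect_equal(netReproductiveRate(s), total / nIndividuals(sim$cohort))
  }
})

test_that("R0 equals the hand values of the worked examples", {
  expect_equal(netReproductiveRate(makeSched(1, 0)), 0)
  expect_equal(netReproductiveRate(makeSched(c(1, 1, 0.5, 0.5),
                                             c(0, 1, 4, 0))), 3)
  ## two individuals with 3 and 5 offspring -> mean 4
  co <- makeCohort(list(makeIndividual(1, c(0, 3), adultAge = 1),
                        makeIndividual(1, c(0, 5), adultAge = 1)))
  expect_equal(netReproductiveRate(buildSchedules(co)), 4)
})

test_that("Euler-Lotka solver hits closed forms and the grid oracle", {
  ## point mass: l_0 = 1, m_0 = e -> exp(-r) * e = 1 -> r = 1
  expect_equal(solveIntrinsicRate(makeSched(1, exp(1))), 1,
               tolerance = 1e-10)
  ## point mass at age a with fecundity f: r = log(f) / (a + 1)
  for (case in list(c(a = 3, f = 20), c(a = 7, f = 55), c(a = 0, f = 2))) {
    lx <- rep(1, case[["a"]] + 1)
    mx <- c(rep(0, case[["a"]]), case[["f"]])
    expect_equal(solveIntrinsicRate(makeSched(lx, mx)),
                 log(case[["f"]]) / (case[["a"]] + 1), tolerance = 1e-10)
  }
  ## replacement fertility: R0 = 1 -> r = 0
  expect_equal(solveIntrinsicRate(makeSched(1, 1)), 0, tolerance = 1e-10)
  ## against the independent dense-grid + bisection oracle
  lx <- c(1, 1, 1); mx <- c(0, 2, 4)
  expect_equal(solveIntrinsicRate(makeSched(lx, mx)),
               oracleEulerLotka(lx, mx), tolerance = 1e-9)
  ## zero fecundity errors
  expect_error(solveIntrinsicRate(makeSched(c(1, 1), c(0, 0))),
               "no reproduction")
})

test_that("Euler-Lotka residual is < 1e-10 on random schedules", {
  set.seed(401)
  for (i in 1:50) {
    len <- sample(3:40, 1)
    lx <- cumprod(c(1, runif(len - 1, 0.8, 1)))
    mx <- c(0, rpois(len - 1, 2)) * runif(len, 0, 2)
    if (sum(lx * mx) == 0) next
    sched <- makeSched(lx, mx)
    r <- solveIntrinsicRate(sched)
    expect_lt(abs(eulerLotkaResidual(r, sched)), 1e-10)
  }
})

test_that("r increases when any m_x is increased", {
  set.seed(402)
  lx <- cumprod(c(1, runif(9, 0.85, 1)))
  mx <- c(0, 0, runif(8, 0, 3))
  r0 <- solveIntrinsicRate(makeSched(lx, mx))
  for (i in 1:10) {
    mx2 <- mx
    j <- sample(2:10, 1)
    mx2[j] <- mx2[j] + runif(1, 0.1, 2)
    expect_gt(solveIntrinsicRate(makeSched(lx, mx2)), r0)
  }
})

test_that("the exponent convention switch changes r as expected", {
  lx <- c(1, 1, 0.8); mx <- c(0, 2, 3)
  sched <- makeSched(lx, mx)
  rx1 <- solveIntrinsicRate(sched, convention = "x+1")
  rx <- solveIntrinsicRate(sched, convention = "x")
  ## exponent x discounts one day less, so the same schedule implies
  ## faster growth
  expect_gt(rx, rx1)
  expect_lt(abs(eulerLotkaResidual(rx, sched, convention = "x")), 1e-10)
  expect_lt(abs(eulerLotkaResidual(rx1, sched, convention = "x+1")), 1e-10)
})

test_that("finite rate and generation time follow their definitions", {
  expect_equal(finiteRate(0), 1)
  expect_equal(meanGenerationTime(exp(1), 1), 1)
  expect_equal(meanGenerationTime(exp(2), 0.5), 4)
  expect_error(meanGenerationTime(3, 0), "undefined at replacement")
  ## composition: T = ln(R0)/r with r from the solver
  lx <- c(1, 1, 0.5, 0.5); mx <- c(0, 1, 4, 0)
  r <- oracleEulerLotka(lx, mx)
  expect_equal(meanGenerationTime(3, r), log(3) / r, tolerance = 1e-9)
})

test_that("stage periods follow the day-counting convention", {
  ## adult entry age 7, death age 24: nymph 7, adult 18, longevity 25
  co <- makeCohort(list(makeIndividual(24, c(rep(0, 8), rep(2, 17)),
                                       adultAge = 7)))
  st <- stagePeriodStats(co)
  expect_equal(st$mean[st$parameter == "nymphPeriod"], 7)
  expect_equal(st$mean[st$parameter == "adultPeriod"], 18)
  expect_equal(st$mean[st$parameter == "totalLongevity"], 25)

  ## a nymph dying at age 3 is excluded from nymph/adult periods
  nymph <- list(stageEntry = c(N1 = 0L, N2 = 2L), deathAge = 3L,
                offspring = c(0L, 0L, 0L, 0L))
  co2 <- makeCohort(list(nymph))
  st2 <- stagePeriodStats(co2)
  expect_true(is.na(st2$mean[st2$parameter == "nymphPeriod"]))
  expect_equal(st2$n[st2$parameter == "nymphPeriod"], 0)
  expect_equal(st2$mean[st2$parameter == "totalLongevity"], 4)
})

test_that("bootstrap is deterministic under seed and degenerate on clones", {
  sim <- simulateCohort(cohortSimSpec(n = 25), seed = 31)
  p1 <- bootstrapPopulationParameters(sim$cohort, B = 100, seed = 5)
  p2 <- bootstrapPopulationParameters(sim$cohort, B = 100, seed = 5)
  expect_identical(estimates(p1), estimates(p2))
  expect_identical(standardErrors(p1), standardErrors(p2))

  ## a cohort of identical individuals has zero bootstrap SE everywhere
  ind <- makeIndividual(10, c(rep(0, 5), rep(3, 6)), adultAge = 4)
  clones <- makeCohort(rep(list(ind), 6))
  pc <- bootstrapPopulationParameters(clones, B = 50, seed = 1)
  expect_true(all(standardErrors(pc) == 0))
  ## and the point estimates respect the analytic identities
  est <- estimates(pc)
  expect_equal(est[["lambda"]], exp(est[["r"]]))
  expect_equal(est[["T"]], log(est[["R0"]]) / est[["r"]])
})

test_that("bootstrap drops zero-offspring resamples and counts them", {
  ## one reproducing adult among non-reproducers: some resamples miss it
  inds <- c(list(makeIndividual(5, c(0, 0, 0, 0, 10, 10), adultAge = 3)),
            rep(list(makeIndividual(2, c(0, 0, 0))), 4))
  co <- makeCohort(inds)
  pp <- bootstrapPopulationParameters(co, B = 200, seed = 9)
  expect_gt(pp@nDegenerate, 0)
  expect_lt(pp@nDegenerate, 200)
  expect_true(all(is.finite(standardErrors(pp)[c("R0", "r", "lambda")])))
})

test_that("bootstrap SE stabilizes at large B", {
  sim <- simulateCohort(cohortSimSpec(n = 25), seed = 77)
  a <- bootstrapPopulationParameters(sim$cohort, B = 1e4, seed = 101)
  b <- bootstrapPopulationParameters(sim$cohort, B = 1e4, seed = 202)
  seA <- standardErrors(a)[["r"]]; seB <- standardErrors(b)[["r"]]
  expect_lt(abs(seA - seB) / seA, 0.10)
})

test_that("life-table report formats, preserves identities and round-trips", {
  sim <- simulateCohort(cohortSimSpec(n = 30), seed = 12)
  pp <- bootstrapPopulationParameters(sim$cohort, B = 50, seed = 3)
  rep1 <- lifeTableReport(pp)
  expect_equal(unique(rep1$host), "synthetic")
  expect_equal(rep1$parameter[1:4], c("R0", "r", "lambda", "T"))
  ## lambda cell equals exp(r cell) before rounding
  expect_equal(rep1$estimate[rep1$parameter == "lambda"],
               exp(rep1$estimate[rep1$parameter == "r"]))
  path <- tempfile(fileext = ".tsv")
  writeLifeTableReport(rep1, path)
  back <- readLifeTableReport(path)
  expect_equal(back$estimate, rep1$estimate)
  expect_equal(back$se, rep1$se)
})
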