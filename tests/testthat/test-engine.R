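test_that("validation passes well-formed models and reports violations", {
  fix <- two_state_chain(0.5)
  expect_true(validate_model(fix$model)$ok)

  P <- rbind(Alive = c(0.49, 0.5), Dead = c(0, 1))
  colnames(P) <- c("Alive", "Dead")
  bad <- transition_model(c("Alive", "Dead"), P, 3, absorbing = "Dead")
  rep <- validate_model(bad)
  expect_false(rep$ok)
  expect_true(any(rep$violations$type == "row-sum" &
                    rep$violations$state == "Alive"))

  P2 <- rbind(Alive = c(0.99, 0.01), Dead = c(0.01, 0.99))
  colnames(P2) <- c("Alive", "Dead")
  leaky <- transition_model(c("Alive", "Dead"), P2, 3,
                            absorbing = "Dead")
  rep2 <- validate_model(leaky)
  expect_false(rep2$ok)
  expect_true(any(rep2$violations$type == "absorbing" &
                    rep2$violations$state == "Dead"))

  expect_error(transition_model(c("A", "A"), diag(2), 2), "unique")
})

test_that("unreachable states are flagged when an initial distribution is given", {
  states <- c("A", "B", "C")
  P <- rbind(A = c(1, 0, 0), B = c(0.5, 0.5, 0), C = c(0, 0, 1))
  colnames(P) <- states
  m <- transition_model(states, P, 3, absorbing = c("A", "C"))
  rep <- validate_model(m, initial = c(A = 0, B = 1, C = 0))
  expect_true(any(rep$violations$type == "unreachable" &
                    rep$violations$state == "C"))
})

test_that("cohort life expectancy matches the geometric closed form", {
  # single absorbing live state: identity case
  m1 <- transition_model("Alive", matrix(1, 1, 1), 5,
                         absorbing = "Alive")
  R <- reward_array("Alive", "utility", 1)
  R[1, 1, 1] <- 1
  tr <- run_cohort(m1, reward_schedule(R, death_states = character()),
                   initial = 1)
  expect_equal(unname(tr$per_person[["utility"]]), 5.0)

  # Alive/Dead with p = 0.01 and end-of-cycle survival rewards
  fix <- two_state_chain(0.01, 5)
  tr2 <- run_cohort(fix$model, fix$rewards, fix$initial)
  expect_equal(unname(tr2$per_person[["survival"]]),
               sum(0.99^(1:5)), tolerance = 1e-12)
})

test_that("occupancy rows conserve mass and nonnegative channels accumulate", {
  fix <- three_state_chain(6)
  tr <- run_cohort(fix$model, fix$rewards, fix$initial)
  expect_equal(rowSums(tr$occupancy), rep(1, 7), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(tr$cumulative[, "cost"]) >= 0))
  expect_true(all(diff(tr$cumulative[, "utility"]) >= 0))
})

test_that("channels are independent and linear in their rewards", {
  fix <- three_state_chain(4)
  tr <- run_cohort(fix$model, fix$rewards, fix$initial)

  doubled <- fix$rewards
  doubled$state_rewards[, "cost", ] <-
    2 * doubled$state_rewards[, "cost", ]
  doubled$transition_rewards <- lapply(
    doubled$transition_rewards,
    function(x) list(cost = 2 * x$cost))
  tr2 <- run_cohort(fix$model, doubled, fix$initial)
  expect_equal(tr2$per_person[["cost"]], 2 * tr$per_person[["cost"]])
  expect_equal(tr2$per_person[["utility"]], tr$per_person[["utility"]])
})

test_that("transition rewards credit expected one-off event values", {
  # hand expectation: flow A->B in cycle 1 is 0.6 * 0.25; in cycle 2 it
  # is occ_A(1) * 0.25, with occ_A(1) = 0.6*0.7 + 0.4*0.1
  fix <- three_state_chain(2)
  tr <- run_cohort(fix$model, fix$rewards, fix$initial)
  occ_a1 <- 0.6 * 0.7 + 0.4 * 0.1
  expected_event <- 40 * 0.25 * (0.6 + occ_a1)
  base <- fix$rewards
  base$transition_rewards <- NULL
  tr0 <- run_cohort(fix$model, base, fix$initial)
  expect_equal(tr$per_person[["cost"]] - tr0$per_person[["cost"]],
               expected_event, tolerance = 1e-12)
})

test_that("the cycle of death accrues the configured utility fraction", {
  # 1 cycle, p_die = 0.5, utility 1, fraction 0.5:
  # survivors contribute 0.5 * 1, the dying contribute 0.5 * 0.5
  P <- rbind(Alive = c(0.5, 0.5), Dead = c(0, 1))
  colnames(P) <- c("Alive", "Dead")
  m <- transition_model(c("Alive", "Dead"), P, 1, absorbing = "Dead")
  R <- reward_array(c("Alive", "Dead"), "utility", 1)
  R["Alive", 1, 1] <- 1
  rw <- reward_schedule(R, death_cycle_fraction = 0.5,
                        death_credit_channels = "utility")
  tr <- run_cohort(m, rw, c(Alive = 1, Dead = 0))
  expect_equal(unname(tr$per_person[["utility"]]), 0.75)
})

test_that("invalid inputs raise informative errors", {
  fix <- two_state_chain(0.01)
  expect_error(run_cohort(fix$model, fix$rewards, c(0.5, 0.4)),
               "initial")
  P <- rbind(Alive = c(0.49, 0.5), Dead = c(0, 1))
  colnames(P) <- c("Alive", "Dead")
  bad <- transition_model(c("Alive", "Dead"), P, 3, absorbing = "Dead")
  expect_error(run_cohort(bad, fix$rewards, fix$initial), "row")
  expect_error(run_microsim(fix$model, fix$rewards, fix$initial,
                            0, seed = 1), "n_individuals")
})

test_that("microsim is deterministic given a seed and exact for deterministic chains", {
  fix <- three_state_chain(4)
  s1 <- run_microsim(fix$model, fix$rewards, fix$initial, 500, seed = 7)
  s2 <- run_microsim(fix$model, fix$rewards, fix$initial, 500, seed = 7)
  expect_identical(s1$mean, s2$mean)
  expect_identical(s1$terminal, s2$terminal)

  # all transition probabilities 0/1: sample mean equals expectation
  P <- rbind(A = c(0, 1, 0), B = c(0, 0, 1), Dead = c(0, 0, 1))
  colnames(P) <- c("A", "B", "Dead")
  m <- transition_model(c("A", "B", "Dead"), P, 3, absorbing = "Dead")
  R <- reward_array(c("A", "B", "Dead"), "utility", 1)
  R["A", 1, 1] <- 0.9; R["B", 1, 1] <- 0.6
  rw <- reward_schedule(R, death_cycle_fraction = 0)
  tr <- run_cohort(m, rw, c(A = 1, B = 0, Dead = 0))
  sim <- run_microsim(m, rw, c(A = 1, B = 0, Dead = 0), 50, seed = 1)
  expect_equal(sim$mean[["utility"]], tr$per_person[["utility"]])
  expect_equal(unname(sim$se[["utility"]]), 0)
})

test_that("microsim means agree with closed form and cohort within 3 SE", {
  fix <- two_state_chain(0.01, 5)
  sim <- run_microsim(fix$model, fix$rewards, fix$initial, 100000,
                      seed = 11)
  expect_lt(abs(sim$mean[["survival"]] - sum(0.99^(1:5))),
            3 * sim$se[["survival"]])

  fix3 <- three_state_chain(4)
  tr <- run_cohort(fix3$model, fix3$rewards, fix3$initial)
  sim3 <- run_microsim(fix3$model, fix3$rewards, fix3$initial, 200000,
                       seed = 12)
  for (ch in names(sim3$mean)) {
    expect_lt(abs(sim3$mean[[ch]] - tr$per_person[[ch]]),
              3 * sim3$se[[ch]])
  }
})

test_that("cohort traces serialise to CSV round-trip", {
  fix <- three_state_chain(3)
  tr <- run_cohort(fix$model, fix$rewards, fix$initial)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(back), 4)
  expect_equal(back$A, unname(tr$occupancy[, "A"]), tolerance = 1e-12)
})
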