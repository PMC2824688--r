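test_that("degenerate single-year traces match hand-computed outcomes", {
  person <- list(id = "T01", sex = "male", age = 57, state = "NO_HISTORY")

  null_tab <- uniform_risk_table(2001, rep(0, 5))
  out <- simulate_person_year(person, 2001, null_tab, u = c(0.5, 0.5, 0.5))
  expect_identical(out$events, character(0))
  expect_identical(out$end_state, "NO_HISTORY")
  expect_false(out$died)
  expect_identical(out$age, 58L)

  death_tab <- uniform_risk_table(2001, c(0, 0, 0, 0, 1))
  out2 <- simulate_person_year(person, 2001, death_tab, u = c(0.5, 0.5, 0.5))
  expect_identical(out2$events, "NON_CHD_DEATH")
  expect_true(out2$died)
  expect_false(out2$aged_out)

  # certain PCI from NO_HISTORY, then the follow-on uses the *updated*
  # PCI_NO_CABG state's risks, where CABG is certain: [PCI, CABG]
  probs <- list(
    NO_HISTORY = c(CHD_ADMISSION_NO_CARP = 0, CABG = 0, PCI = 1,
                   CHD_DEATH = 0, NON_CHD_DEATH = 0),
    PCI_NO_CABG = c(CHD_ADMISSION_NO_CARP = 0, CABG = 1, PCI = 0,
                    CHD_DEATH = 0, NON_CHD_DEATH = 0),
    CHD_NO_CARP = rep(0, 5),
    CABG_HISTORY = rep(0, 5))
  probs$CHD_NO_CARP <- stats::setNames(probs$CHD_NO_CARP, event_types())
  probs$CABG_HISTORY <- stats::setNames(probs$CABG_HISTORY, event_types())
  carp_tab <- state_risk_table(2001, probs)
  out3 <- simulate_person_year(person, 2001, carp_tab, u = c(0.5, 0.5, 0.5))
  expect_identical(out3$events, c("PCI", "CABG"))
  expect_identical(out3$end_state, "CABG_HISTORY")
  expect_false(out3$died)
})

test_that("the vectorized cohort engine agrees with the scalar rule draw-for-draw", {
  cfg <- synthetic_config(n_persons = 60)
  coh <- generate_cohort(cfg, seed = 5)
  # inflate risks so the follow-on stages are exercised often
  tab <- generate_risk_history(synthetic_config(
    risk_intercepts = c(CHD_ADMISSION_NO_CARP = -2.2, CABG = -2.5, PCI = -2.5,
                        CHD_DEATH = -3.5, NON_CHD_DEATH = -3.5),
    age_slope = 0.02, male_effect = 0.2,
    state_effects = c(NO_HISTORY = 0, CHD_NO_CARP = 0.2, PCI_NO_CABG = 0.2,
                      CABG_HISTORY = 0.2),
    noise_sd = 0), years = 2001:2003)

  seed <- 909
  vec <- simulate_cohort(coh, tab, 2001, 2003, seed = seed)

  # replay with the scalar reference implementation under the same stream
  set.seed(seed)
  p <- coh$persons
  n <- nrow(p)
  status <- rep("alive", n)
  age <- p$age
  state <- p$state
  counts <- matrix(0, 3, 5, dimnames = list(2001:2003, event_types()))
  for (t in 1:3) {
    u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
    for (i in seq_len(n)) {
      if (status[i] != "alive") next
      out <- simulate_person_year(list(id = p$id[i], sex = p$sex[i],
                                       age = age[i], state = state[i]),
                                  2000 + t, tab, u = c(u1[i], u2[i], u3[i]))
      for (ev in out$events) counts[t, ev] <- counts[t, ev] + 1
      state[i] <- out$end_state
      age[i] <- out$age
      if (out$died) status[i] <- "died"
      else if (out$aged_out) status[i] <- "aged_out"
    }
  }
  vec_counts <- matrix(vec$counts$count, nrow = 3,
                       dimnames = list(2001:2003, NULL))
  expect_identical(unname(vec_counts), unname(counts))
  expect_identical(vec$final$state, state)
  alive_scalar <- status == "alive"
  expect_identical(vec$final$status == "alive", alive_scalar)
})

test_that("cohort boundaries: null risks, age cap and absorbing death", {
  null_tab <- uniform_risk_table(2001:2010, rep(0, 5))
  coh <- tiny_cohort(ages = rep(50, 100), states = "NO_HISTORY")
  rep1 <- simulate_cohort(coh, null_tab, 2001, 2010, seed = 1)
  expect_true(all(rep1$counts$count == 0))
  expect_true(all(rep1$final$status == "alive"))

  old <- tiny_cohort(ages = 79, states = "NO_HISTORY")
  rep2 <- simulate_cohort(old, null_tab, 2001, 2010, seed = 1)
  expect_identical(rep2$final$status, "aged_out")
  expect_identical(rep2$final$age, 80L)

  chd_death <- uniform_risk_table(2001:2010, c(0, 0, 0, 1, 0))
  rep3 <- simulate_cohort(tiny_cohort(50, "NO_HISTORY"), chd_death,
                          2001, 2010, seed = 1)
  deaths <- rep3$counts[rep3$counts$event == "CHD_DEATH", ]
  expect_identical(deaths$count[deaths$year == 2001], 1)
  expect_true(all(deaths$count[deaths$year > 2001] == 0))
  expect_true(all(rep3$counts$count[rep3$counts$event != "CHD_DEATH"] == 0))
})

test_that("run_replicates is bit-reproducible and averages correctly", {
  cfg <- synthetic_config(n_persons = 300)
  coh <- generate_cohort(cfg, seed = 2)
  tab <- project_risks(fit_trends(generate_risk_history(cfg, 1998:2000,
                                                        seed = 2)),
                       years = 2001:2004)
  a <- run_replicates(coh, tab, 2001, 2004, n_replicates = 5, master_seed = 42)
  b <- run_replicates(coh, tab, 2001, 2004, n_replicates = 5, master_seed = 42)
  expect_identical(a, b)

  one <- run_replicates(coh, tab, 2001, 2004, n_replicates = 1,
                        master_seed = 42)
  merged <- merge(one$averaged, one$counts, by = c("year", "event"))
  expect_equal(merged$mean_count, merged$count)

  # averaged really is the replicate mean
  key <- paste(a$counts$year, a$counts$event)
  manual <- tapply(a$counts$count, key, mean)
  expect_equal(as.numeric(manual[paste(a$averaged$year, a$averaged$event)]),
               a$averaged$mean_count)
})

test_that("single-year PCI counts agree with the binomial expectation", {
  # 10,000 no-history persons, Pr(PCI) = 0.05, follow-on CARP risks zero:
  # PCI count per replicate ~ Binomial(10000, 0.05); the 100-replicate mean
  # has SE sqrt(10000 * 0.05 * 0.95 / 100) ~ 2.18
  probs <- list(
    NO_HISTORY = stats::setNames(c(0, 0, 0.05, 0, 0), event_types()),
    PCI_NO_CABG = stats::setNames(rep(0, 5), event_types()),
    CHD_NO_CARP = stats::setNames(rep(0, 5), event_types()),
    CABG_HISTORY = stats::setNames(rep(0, 5), event_types()))
  tab <- state_risk_table(2001, probs)
  coh <- tiny_cohort(ages = rep(50, 10000), states = "NO_HISTORY")
  res <- run_replicates(coh, tab, 2001, 2001, n_replicates = 100,
                        master_seed = 99)
  pci_mean <- res$averaged$mean_count[res$averaged$event == "PCI"]
  expect_lt(abs(pci_mean - 500), 4 * sqrt(10000 * 0.05 * 0.95 / 100))
  expect_true(all(res$averaged$mean_count[res$averaged$event != "PCI"] == 0))
})

test_that("conservation and state monotonicity hold in every replicate", {
  cfg <- synthetic_config(n_persons = 400)
  coh <- generate_cohort(cfg, seed = 8)
  tab <- project_risks(fit_trends(generate_risk_history(cfg, 1998:2000,
                                                        seed = 8)),
                       years = 2001:2010)
  seeds <- 101:110
  rank0 <- match(coh$persons$state, history_states())
  for (s in seeds) {
    rep_s <- simulate_cohort(coh, tab, 2001, 2010, seed = s)
    stat <- table(factor(rep_s$final$status,
                         levels = c("alive", "died_chd", "died_nonchd",
                                    "aged_out")))
    expect_identical(sum(stat), 400L)
    # history state never moves down the dominance order
    rank1 <- match(rep_s$final$state, history_states())
    expect_true(all(rank1 >= rank0))
    # nobody simulated past the cap
    expect_true(all(rep_s$final$age <= 80L))
  }
})

test_that("simulation aborts on a missing risk cell, naming it", {
  partial <- risk_table(data.frame(year = 2001, sex = "male",
                                   age_band = "50-54", state = "NO_HISTORY",
                                   event = "PCI", probability = 0.01))
  coh <- tiny_cohort(ages = 52, states = "NO_HISTORY")
  expect_error(simulate_cohort(coh, partial, 2001, 2001, seed = 1),
               "incomplete risk table: missing cell \\(2001, male, 50-54")
})
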