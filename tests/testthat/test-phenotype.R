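test_that("daily state rule reproduces the worked-example patient", {
  p <- fig2_patient()
  r <- fig2_relapses()
  # relapsing at diagnosis because the pre-diagnosis relapse is in the window
  expect_equal(state_at(p, r, 0), "rSPMS")
  expect_equal(state_at(p, r, 629), "rSPMS")
  # first non-relapsing day is 630
  expect_equal(state_at(p, r, 630), "nrSPMS")
  # relapsing again from the day of the later relapse
  expect_equal(state_at(p, r, 6546), "nrSPMS")
  expect_equal(state_at(p, r, 6547), "rSPMS")
  expect_equal(state_at(p, r, 6721), "rSPMS")

  tl <- classify_timeline(p, r)
  expect_equal(tl$intervals,
               data.frame(state = c("rSPMS", "nrSPMS", "rSPMS"),
                          start_day = c(0L, 630L, 6547L),
                          end_day = c(629L, 6546L, 6721L)))
  expect_equal(transition_pattern(tl), "rSPMS→nrSPMS→rSPMS")
})

test_that("state rule edge cases", {
  # no SPMS diagnosis: always RRMS
  p <- make_patient(spms_dx_day = NA)
  expect_equal(state_at(p, c(5, 50), 100), "RRMS")
  expect_equal(classify_timeline(p, c(5, 50))$intervals$state, "RRMS")
  expect_error(transition_pattern(classify_timeline(p, integer(0))),
               "no SPMS")
  # SPMS diagnosis with no relapses ever: non-relapsing from day one
  p <- make_patient(spms_dx_day = 0, rrms_dx_day = 0)
  expect_equal(state_at(p, integer(0), 0), "nrSPMS")
  # assessment outside follow-up errors
  expect_error(state_at(p, integer(0), 1e6), "follow-up")
})

test_that("event-driven timeline equals the brute-force day-by-day oracle", {
  set.seed(421)
  for (rep in 1:50) {
    end <- sample(800:4000, 1)
    spms <- if (runif(1) < 0.8) sample(0:(end - 1), 1) else NA
    n_rel <- rpois(1, 4)
    rel <- sort(sample(-500:end, n_rel))
    p <- make_patient(patient_id = paste0("r", rep), onset_day = -600,
                      rrms_dx_day = 0, spms_dx_day = spms, end_day = end)
    tl <- classify_timeline(p, rel)
    iv <- tl$intervals
    # partition of follow-up with no gaps/overlaps, maximal runs
    expect_equal(iv$start_day[1], 0L)
    expect_equal(iv$end_day[nrow(iv)], end)
    if (nrow(iv) > 1) {
      expect_equal(iv$start_day[-1], iv$end_day[-nrow(iv)] + 1L)
      expect_true(all(iv$state[-1] != iv$state[-nrow(iv)]))
    }
    days <- 0:end
    expect_equal(timeline_state_at(tl, days), state_at(p, rel, days))
  }
})

test_that("adding a relapse flips a window toward rSPMS and changes nothing earlier", {
  set.seed(99)
  for (rep in 1:20) {
    end <- 3000
    p <- make_patient(spms_dx_day = 0, rrms_dx_day = 0, end_day = end)
    rel <- sort(sample(0:end, rpois(1, 3)))
    tl0 <- classify_timeline(p, rel)
    candidates <- which(timeline_state_at(tl0, 0:end) == "nrSPMS") - 1L
    if (!length(candidates)) next
    r_new <- sample(candidates, 1)
    tl1 <- classify_timeline(p, c(rel, r_new))
    days <- 0:end
    s0 <- timeline_state_at(tl0, days)
    s1 <- timeline_state_at(tl1, days)
    before <- days < r_new
    expect_equal(s1[before], s0[before])
    flipped <- days >= r_new & days < r_new + 730 & days <= end
    expect_true(all(s1[flipped] == "rSPMS"))
    expect_equal(s1[!before & !flipped], s0[!before & !flipped])
  }
})

test_that("panel observations carry the right states and covariates", {
  p <- make_patient("pp", sex = "female", onset_day = -365, rrms_dx_day = 0,
                    spms_dx_day = 1000, end_day = 2000,
                    end_reason = "death", age_at_onset = 30)
  rel <- c(-200L, 100L, 300L, 500L, 1500L)
  eds <- data.frame(patient_id = "pp", obs_day = c(100L, 900L),
                    edss = c(2, 4.5))
  eps <- data.frame(patient_id = "pp", drug_name = "fingolimod",
                    start_day = 0L, stop_day = 365L)
  pan <- build_panel(p, rel, eds, eps, schedule = c(0L, 600L, 1200L))

  # states: RRMS before diagnosis, then relapsing SPMS (relapse at 500 in
  # window at 1200), plus the exact death record
  expect_equal(pan$state, c("RRMS", "RRMS", "rSPMS", "Death"))
  expect_equal(pan$obs_type, c("panel", "panel", "panel", "exact_death"))
  expect_equal(pan$obs_day[4], 2000L)

  # pre-diagnosis relapse does not count toward cumulative relapses
  expect_equal(pan$cum_relapses, c(0, 3, 3, 4))
  # EDSS: look-ahead fallback before the first visit, then carried forward
  expect_equal(pan$edss, c(2, 2, 4.5, 4.5))
  # ages anchored at onset
  expect_equal(pan$age, 30 + (c(0, 600, 1200, 2000) + 365) / 365.25)
  # treatment exposure caps when the episode ends
  expect_equal(pan$hedmt_years, c(0, 365, 365, 365) / 365.25)
  expect_equal(pan$medmt_years, rep(0, 4))
  expect_equal(pan$disease_duration, rep(365 / 365.25, 4))
  # cumulative covariates are non-decreasing in time
  expect_true(all(diff(pan$cum_relapses) >= 0))
  expect_true(all(diff(pan$hedmt_years) >= 0))

  expect_error(build_panel(p, rel, eds, eps, schedule = integer(0)),
               "empty")
})
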