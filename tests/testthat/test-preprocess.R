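test_that("spike tables round-trip through parsing, sorting and validation", {
  df <- data.frame(unit_id = c("u1", "u2", "u1", "u2", "u1"),
                   time_s = c(2.5, 0.7, 1.2, 3.3, 0.1))
  s <- load_spike_table(write_spike_csv(df), trial_span = c(0, 5))
  expect_s3_class(s, "spike_train_set")
  expect_length(s$units, 2L)
  expect_equal(sum(lengths(s$units)), 5L)
  # input order is irrelevant; output matches a sort oracle
  expect_equal(s$units$u1, sort(df$time_s[df$unit_id == "u1"]))
  expect_equal(s$units$u2, sort(df$time_s[df$unit_id == "u2"]))

  # empty table with declared units: units present, zero spikes
  empty <- load_spike_table(write_spike_csv(df[0, ]), trial_span = c(0, 5),
                            units = c("a", "b"))
  expect_equal(lengths(empty$units), c(a = 0L, b = 0L))

  # descriptive errors
  expect_error(load_spike_table(write_spike_csv(data.frame(x = 1)),
                                c(0, 5)), "missing column")
  bad <- data.frame(unit_id = "u1", time_s = 99)
  expect_error(load_spike_table(write_spike_csv(bad), c(0, 5)),
               "outside trial span.*line")
})

test_that("unit QC removes short-ISI spikes, duplicates and silent units", {
  # second spike of a <=10 ms pair is dropped
  s <- spike_train_set(list(u1 = c(1.000, 1.005, 1.100)), c(0, 2))
  out <- qc_filter_units(s)
  expect_equal(out$spikes$units$u1, c(1.000, 1.100))
  expect_equal(unname(out$report$removed_isi_spikes["u1"]), 1L)

  # identical trains: the (tied) lower-rate unit is removed as a duplicate
  tt <- sort(runif(50, 0, 10))
  s2 <- spike_train_set(list(a = tt, b = tt), c(0, 10))
  out2 <- qc_filter_units(s2, isi_floor = 0)
  expect_length(out2$spikes$units, 1L)
  expect_equal(nrow(out2$report$removed_duplicate_units), 1L)
  expect_gt(out2$report$removed_duplicate_units$correlation, 0.9)

  # mean rates 10, 5, 0.1 spikes/s: 0.1/10 = 0.01 < 0.02 excluded
  set.seed(7)
  mk <- function(rate) sort(runif(rate * 10, 0, 10))
  s3 <- spike_train_set(list(hi = mk(10), mid = mk(5), lo = mk(0.1)),
                        c(0, 10))
  out3 <- qc_filter_units(s3, isi_floor = 0)
  expect_setequal(names(out3$spikes$units), c("hi", "mid"))
  expect_equal(out3$report$removed_low_rate_units$unit_id, "lo")
  expect_lt(out3$report$removed_low_rate_units$rate_ratio, 0.02)

  expect_error(qc_filter_units(
    spike_train_set(list(u1 = c(1, 1.005)), c(0, 2), "t"),
    low_rate_frac = 2), "no responsive units")
})

test_that("spike counts are conserved through QC", {
  set.seed(3)
  units <- lapply(1:5, function(i) sort(runif(rpois(1, 40), 0, 20)))
  names(units) <- paste0("u", 1:5)
  s <- spike_train_set(units, c(0, 20))
  out <- qc_filter_units(s)
  kept <- sum(lengths(out$spikes$units))
  removed_isi <- sum(out$report$removed_isi_spikes)
  # spikes inside dropped units (duplicate/low-rate) counted via originals
  # net of their own ISI removals
  dropped_units <- c(out$report$removed_duplicate_units$dropped,
                     out$report$removed_low_rate_units$unit_id)
  # recompute ISI-filtered lengths for dropped units
  isi_len <- function(tt) {
    if (length(tt) < 2) return(length(tt))
    keep <- 1L; last <- tt[1]
    for (i in 2:length(tt)) if (tt[i] - last > 0.010) {
      keep <- keep + 1L; last <- tt[i]
    }
    keep
  }
  dropped_spikes <- sum(vapply(units[dropped_units], isi_len, numeric(1)))
  expect_equal(kept + removed_isi + dropped_spikes,
               sum(lengths(units)))
})

test_that("rate estimation matches a quadrature oracle and is linear", {
  # one spike at t = 1.0, sigma = 0.05, Delta = 0.2: bin value equals the
  # mean of the unit-area Gaussian over the bin
  s <- spike_train_set(list(u1 = 1.0), c(0.1, 2.1))
  r <- estimate_rates(s, sigma = 0.05, bin_width = 0.2)
  # bin 5 covers [0.9, 1.1)
  oracle <- integrate(function(t) dnorm(t, 1.0, 0.05), 0.9, 1.1)$value / 0.2
  expect_equal(unname(r$values[5, "u1"]), oracle, tolerance = 1e-8)
  expect_equal(nrow(r$values), 10L)   # floor(2 / 0.2)

  # no spikes: all-zero row
  s0 <- spike_train_set(list(u1 = 1.0, u2 = numeric(0)), c(0, 2))
  r0 <- estimate_rates(s0)
  expect_true(all(r0$values[, "u2"] == 0))

  # linearity: density of a merged train equals the sum of densities
  set.seed(5)
  t1 <- sort(runif(30, 0, 10)); t2 <- sort(runif(20, 0, 10))
  ra <- estimate_rates(spike_train_set(list(u = t1), c(0, 10)))
  rb <- estimate_rates(spike_train_set(list(u = t2), c(0, 10)))
  rm <- estimate_rates(spike_train_set(list(u = sort(c(t1, t2))), c(0, 10)))
  expect_equal(rm$values, ra$values + rb$values, tolerance = 1e-10)

  # integral of unnormalized density ~ spike count (sigma << trial length)
  expect_equal(sum(ra$values) * 0.2, 30, tolerance = 30 * 0.005)

  # trial normalization yields unit mass per unit
  rn <- estimate_rates(spike_train_set(list(u = t1), c(0, 10)),
                       normalize_to_trial = TRUE)
  expect_equal(sum(rn$values) * 0.2, 1, tolerance = 0.005)

  expect_error(estimate_rates(s, sigma = 0), "sigma")
  expect_error(estimate_rates(s, bin_width = -1), "bin_width")
})

test_that("epoch timelines derive windows from events and label by majority", {
  r <- mk_rates(matrix(0, 150, 2), bin_width = 0.2)
  # food-cup point event at 10.0 s -> reward window [9.8, 10.8)
  ev <- data.frame(trial_id = "trial1",
                   label_or_event = c("train_reward", "train_choice",
                                      "delay"),
                   start_s = c(10.0, 20.0, 22.0),
                   end_s = c(NA, NA, 28.0))
  tl <- build_epoch_timeline(ev, r)
  w <- tl$event_windows
  expect_equal(w$start_s[w$label == "train_reward"], 9.8)
  expect_equal(w$end_s[w$label == "train_reward"], 10.8)
  # choice at 20.0 with no later reward: [18.5, 20.5)
  expect_equal(w$start_s[w$label == "train_choice"], 18.5)
  expect_equal(w$end_s[w$label == "train_choice"], 20.5)
  # labels cover the windows
  expect_equal(tl$labels[50], "train_reward")        # bin [9.8, 10.0)
  expect_equal(tl$labels[95], "train_choice")        # bin [18.8, 19.0)
  expect_equal(tl$labels[115], "delay")              # bin [22.8, 23.0)
  expect_equal(tl$labels[1], "unlabeled")

  # arm choice truncated by the next reward: choice at 20.0, reward 20.3
  ev2 <- data.frame(trial_id = "trial1",
                    label_or_event = c("test_choice", "test_reward"),
                    start_s = c(20.0, 20.3), end_s = NA)
  w2 <- build_epoch_timeline(ev2, r)$event_windows
  expect_equal(w2$end_s[w2$label == "test_choice"], 20.1)  # 20.3 - 0.2

  # no events: all bins unlabeled
  tl0 <- build_epoch_timeline(ev[0, ], r)
  expect_true(all(tl0$labels == "unlabeled"))

  # row order of the event table is irrelevant
  tl_rev <- build_epoch_timeline(ev[3:1, ], r)
  expect_identical(tl$labels, tl_rev$labels)

  # overlapping windows of different kinds: reward wins, warning logged
  ev3 <- data.frame(trial_id = "trial1",
                    label_or_event = c("delay", "test_reward"),
                    start_s = c(5, 6), end_s = c(9, 7))
  expect_warning(tl3 <- build_epoch_timeline(ev3, r), "precedence")
  expect_equal(tl3$labels[32], "test_reward")        # bin [6.2, 6.4)
})
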