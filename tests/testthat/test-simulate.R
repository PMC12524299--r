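test_that("a default session has the full study layout and is seed-deterministic", {
  trials <- default_trials()
  expect_length(trials, 16 * 8 * 2 * 3)
  log <- as_event_log(trials)
  per_panelist <- tapply(
    paste(log$condition_id, log$task, log$repetition),
    log$panelist_id,
    function(k) length(unique(k))
  )
  expect_true(all(per_panelist == 48))

  again <- as_event_log(simulate_panel(study_design(), seed = 42))
  expect_identical(log, again)
  other <- as_event_log(simulate_panel(study_design(), seed = 43))
  expect_false(identical(log, other))
})

test_that("an empty panel yields an empty session and bad configs are caught", {
  expect_length(simulate_panel(study_design(n_panelists = 0), seed = 1), 0)
  prof <- default_profiles()
  prof$plain_strawberry <- NULL
  expect_error(simulate_panel(study_design(), prof, seed = 1),
               "plain_strawberry")
})

test_that("generated trials satisfy the trial-record invariants", {
  design <- study_design(n_panelists = 3)
  trials <- simulate_panel(design, seed = 11)
  for (tr in trials) {
    expect_s3_class(tr, "trial_record")
    expect_gt(tr$duration_s, 0)
    if (nrow(tr$events)) {
      expect_true(all(diff(tr$events$time_s) > 0))
      expect_gt(tr$events$time_s[1], 0)
      expect_lte(max(tr$events$time_s), tr$duration_s)
      if (tr$task == "TDS") {
        expect_true(all(tr$events$payload %in% design$attributes))
      } else {
        expect_true(all(as.integer(tr$events$payload) %in% 1:9))
      }
    }
  }
})

test_that("a degenerate single-attribute phase emits only that attribute", {
  prof <- degenerate_profile("sweet")
  for (s in 1:20) {
    tr <- sample_tds_trial(prof, duration_s = 10, seed = s)
    expect_true(all(tr$events$payload == "sweet"))
  }
  expect_error(sample_tds_trial(prof, duration_s = Inf, seed = 1),
               "finite")
})

test_that("dwell times at the trial scale give one to two episodes on average", {
  # renewal-process oracle: with exponential dwells of mean equal to the
  # trial duration and a short initial delay, the expected episode count
  # is 1 + (remaining time) / (mean dwell), i.e. just under 2
  prof <- degenerate_profile("sweet", dwell_mean_s = 10)
  counts <- vapply(1:1000,
                   function(s) nrow(sample_tds_trial(prof, 10, s)$events),
                   1L)
  expect_gte(min(counts), 1L)
  expect_gt(mean(counts), 1.5)
  expect_lt(mean(counts), 2.5)
})

test_that("marginal selection frequencies match a single-phase probability vector", {
  prof <- cracker_like_profile(dwell_mean_s = 2)
  payloads <- unlist(lapply(1:1000, function(s) {
    sample_tds_trial(prof, 20, seed = s)$events$payload
  }))
  p <- prof$phases[[1]]$probs
  freq <- table(factor(payloads, levels = names(p))) / length(payloads)
  err <- abs(as.numeric(freq) - as.numeric(p))
  tol <- 4 * sqrt(pmax(p * (1 - p), 1e-4) / length(payloads))
  expect_true(all(err < pmax(tol, 0.01)))
})

test_that("noise-free liking equals the dominant attribute's rounded, clipped weight", {
  prof <- degenerate_profile("sweet", weight = 5, noise_sd = 0)
  tds <- sample_tds_trial(prof, 10, seed = 1)
  tl <- sample_tl_trial(prof, tds, 10, seed = 2)
  after_first <- tl$events$time_s / 10 >= tds$events$time_s[1] / 10
  expect_true(all(tl$events$payload[after_first] == "5"))

  prof12 <- degenerate_profile("sweet", weight = 12, noise_sd = 0)
  tds12 <- sample_tds_trial(prof12, 10, seed = 1)
  tl12 <- sample_tl_trial(prof12, tds12, 10, seed = 2)
  expect_true(all(tl12$events$payload[
    tl12$events$time_s / 10 >= tds12$events$time_s[1] / 10] == "9"))

  expect_error(sample_tl_trial(prof, tl, 10, seed = 3), "TDS")
})

test_that("liking scores reproduce the round-and-clip normal distribution", {
  # Monte-Carlo histogram oracle: weight 5, unit noise, so scores follow
  # round(Normal(5, 1)) clipped to 1..9
  prof <- degenerate_profile("sweet", weight = 5, noise_sd = 1,
                             press_rate = 60)
  scores <- unlist(lapply(1:100, function(s) {
    tds <- sample_tds_trial(degenerate_profile("sweet"), 10, seed = s)
    tl <- sample_tl_trial(prof, tds, 10, seed = 10000 + s)
    u <- tl$events$time_s / 10
    as.integer(tl$events$payload[u >= tds$events$time_s[1] / 10])
  }))
  expect_gt(length(scores), 5000)
  breaks <- c(-Inf, 1:8 + 0.5, Inf)
  expected <- diff(pnorm(breaks, mean = 5, sd = 1))
  observed <- as.numeric(table(factor(scores, levels = 1:9))) /
    length(scores)
  expect_lt(max(abs(observed - expected)), 0.02)
})
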