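test_that("a single pass chain ending in a loss is one play with two passes", {
  ev <- ev_bind(
    ev_row(1, 0, "A", 1, "pass", 2),
    ev_row(1, 4, "A", 2, "pass", 3),
    ev_row(1, 8, "A", 3, "loss"))
  log <- match_log("m1", c("A", "B"), c(2700, 2700), ev)
  plays <- segment_possessions(log)
  expect_length(plays, 1L)
  expect_equal(plays[[1]]$n_passes, 2L)
  expect_equal(plays[[1]]$terminal, "loss")
  expect_equal(nrow(plays[[1]]$events), 3L)
})

test_that("alternating team chains yield plays in order", {
  ev <- ev_bind(
    ev_row(1,  0, "A", 1, "pass", 2), ev_row(1,  3, "A", 2, "loss"),
    ev_row(1, 10, "B", 4, "pass", 5), ev_row(1, 13, "B", 5, "loss"),
    ev_row(1, 20, "A", 6, "pass", 7), ev_row(1, 23, "A", 7, "loss"))
  log <- match_log("m1", c("A", "B"), c(2700, 2700), ev)
  plays <- segment_possessions(log)
  expect_length(plays, 3L)
  expect_equal(vapply(plays, function(p) p$team, character(1)),
               c("A", "B", "A"))
})

test_that("runs without a completed pass produce no play; empty log is empty", {
  ev <- ev_bind(
    ev_row(1, 0, "A", 1, "pass", NA, completed = FALSE),
    ev_row(1, 9, "B", 2, "contact"),
    ev_row(1, 12, "B", 2, "loss"))
  log <- match_log("m1", c("A", "B"), c(2700, 2700), ev)
  expect_length(segment_possessions(log), 0L)
  empty <- match_log("m1", c("A", "B"), c(2700, 2700), empty_events())
  expect_length(segment_possessions(empty), 0L)
})

test_that("plays are categorized by shot, finishing-zone entry and restarts", {
  # shot at goal -> SOP
  sop_shot <- ev_bind(ev_row(1, 0, "A", 1, "pass", 2, zone = 3),
                      ev_row(1, 5, "A", 2, "shot", zone = 4))
  # possession held in zone 4 (completed pass there) then lost -> SOP
  sop_zone <- ev_bind(ev_row(1, 0, "A", 1, "pass", 2, zone = 3),
                      ev_row(1, 4, "A", 2, "pass", 3, zone = 4),
                      ev_row(1, 8, "A", 3, "loss", zone = 4))
  # open play lost in zone 2 -> UOP
  uop <- ev_bind(ev_row(1, 0, "A", 1, "pass", 2, zone = 2),
                 ev_row(1, 4, "A", 2, "loss", zone = 2))
  # corner start, retained a while, never zone 4, no shot -> neutral
  corner <- ev_bind(ev_row(1, 0, "A", 1, "pass", 2, zone = 3,
                           restart = "corner"),
                    ev_row(1, 4, "A", 2, "pass", 3, zone = 3),
                    ev_row(1, 8, "A", 3, "loss", zone = 3))
  # free kick delivered directly into zone 4, lost there -> neutral
  fk <- ev_bind(ev_row(1, 0, "A", 1, "pass", 2, zone = 3,
                       restart = "free_kick"),
                ev_row(1, 4, "A", 2, "contact", zone = 4),
                ev_row(1, 7, "A", 2, "loss", zone = 3))
  # a loss in zone 4 alone does not count as entering with possession
  loss_z4 <- ev_bind(ev_row(1, 0, "A", 1, "pass", 2, zone = 3),
                     ev_row(1, 4, "A", 2, "loss", zone = 4))

  cases <- list(sop_shot = c("SOP"), sop_zone = c("SOP"), uop = c("UOP"),
                corner = c("neutral"), fk = c("neutral"),
                loss_z4 = c("UOP"))
  evs <- list(sop_shot = sop_shot, sop_zone = sop_zone, uop = uop,
              corner = corner, fk = fk, loss_z4 = loss_z4)
  for (nm in names(cases)) {
    log <- match_log("m1", c("A", "B"), c(2700, 2700), evs[[nm]])
    plays <- lapply(segment_possessions(log), categorize_play)
    expect_equal(plays[[1]]$category, cases[[nm]], label = nm)
  }
})

test_that("a play truncated by half-time with possession retained is neutral", {
  ev <- ev_bind(ev_row(1, 2690, "A", 1, "pass", 2, zone = 2),
                ev_row(1, 2696, "A", 2, "pass", 3, zone = 2))
  log <- match_log("m1", c("A", "B"), c(2700, 2700), ev)
  play <- categorize_play(segment_possessions(log)[[1]])
  expect_equal(play$terminal, "retained")
  expect_equal(play$category, "neutral")
})

test_that("SOP, UOP and neutral partition the plays", {
  study <- demo_study()
  for (log in study$logs[1:3]) {
    plays <- segment_plays(log)
    cats <- vapply(plays, function(p) p$category, character(1))
    expect_true(all(cats %in% c("SOP", "UOP", "neutral")))
    parts <- filter_plays(plays)
    expect_equal(length(parts$SOP) + length(parts$UOP) + sum(cats == "neutral"),
                 length(plays))
  }
})

test_that("filter_plays drops neutral plays and splits the rest", {
  mk <- function(cat) structure(list(category = cat), class = "offensive_play")
  plays <- lapply(c(rep("SOP", 3), rep("UOP", 4), rep("neutral", 2)), mk)
  parts <- filter_plays(plays)
  expect_length(parts$SOP, 3L)
  expect_length(parts$UOP, 4L)
  parts <- filter_plays(lapply(rep("neutral", 5), mk))
  expect_length(parts$SOP, 0L)
  expect_length(parts$UOP, 0L)
})

test_that("period assignment follows thirds of each half with half-open bounds", {
  mk_play <- function(half, t) structure(
    list(half = as.integer(half), start_t = t, category = NA, period = NA),
    class = "offensive_play")
  durs <- c(2820, 2880)
  expect_equal(assign_period(mk_play(1, 0), durs)$period, 1L)
  expect_equal(assign_period(mk_play(1, 939), durs)$period, 1L)
  expect_equal(assign_period(mk_play(1, 940), durs)$period, 2L)
  expect_equal(assign_period(mk_play(2, 1000), durs)$period, 5L)
  expect_equal(assign_period(mk_play(2, 960), durs)$period, 5L)  # boundary
  expect_equal(assign_period(mk_play(2, 2880), durs)$period, 6L) # closed end
  expect_error(assign_period(mk_play(1, 2821), durs), "exceeds")
})

test_that("period assignment is invariant to uniform time rescaling", {
  set.seed(1)
  for (i in 1:50) {
    half <- sample(1:2, 1)
    durs <- c(runif(1, 2700, 3000), runif(1, 2700, 3000))
    t <- runif(1, 0, durs[half])
    k <- runif(1, 0.5, 3)
    expect_equal(match_period(half, t, durs),
                 match_period(half, k * t, k * durs))
  }
})

test_that("segmentation recovers simulator ground truth exactly on every seed", {
  for (seed in c(3, 71, 905)) {
    sim <- simulate_match(sim_params(seed = seed), 1)
    pt <- plays_table(segment_plays(sim$log))
    tr <- sim$truth$plays
    expect_equal(nrow(pt), nrow(tr))
    expect_equal(pt$team, tr$team)
    expect_equal(pt$start_t, tr$start_t)
    expect_equal(pt$category, tr$category)
    expect_equal(pt$n_passes, tr$n_passes)
    expect_equal(pt$period, tr$period)
  }
})
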