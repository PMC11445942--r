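test_that("component scores match the rubric-lookup oracle on randomized grids", {
  set.seed(42)
  for (i in 1:200) {
    pf <- sample(c(NA, runif(1, 20, 600)), 1)
    plt <- sample(c(NA, runif(1, 1, 400)), 1)
    bili <- sample(c(NA, runif(1, 0.1, 20)), 1)
    map <- sample(c(NA, runif(1, 40, 120)), 1)
    gcs <- sample(c(NA, sample(3:15, 1)), 1)
    cr <- sample(c(NA, runif(1, 0.2, 8)), 1)
    dopa <- sample(c(0, runif(1, 0, 20)), 1)
    norepi <- sample(c(0, runif(1, 0, 0.3)), 1)
    vent <- sample(c(TRUE, FALSE), 1)
    got <- score_sofa(
      c(pf_ratio = pf, platelets = plt, bilirubin_total = bili,
        map = map, gcs_total = gcs, creatinine = cr),
      vasopressors = c(dopamine = dopa, norepinephrine = norepi),
      ventilated = vent
    )
    want <- oracle_sofa(pf, plt, bili, map, gcs, cr, dopa, norepi, vent = vent)
    expect_equal(unlist(got[names(want)[1:6]]), want[1:6],
                 ignore_attr = TRUE)
    expect_equal(got$total, unname(want["total"]))
  }
})

test_that("hand-verified single scores", {
  s <- score_sofa(c(platelets = 90))
  expect_equal(s$coagulation, 2L)
  expect_equal(s$total, 2L)
  healthy <- score_sofa(c(pf_ratio = 450, platelets = 250,
                          bilirubin_total = 0.5, map = 85, gcs_total = 15,
                          creatinine = 0.8))
  expect_equal(healthy$total, 0L)
  s3 <- score_sofa(c(pf_ratio = 123, bilirubin_total = 1.0, map = 85,
                     gcs_total = 15, creatinine = 0.8, platelets = 200),
                   ventilated = TRUE)
  expect_equal(s3$respiration, 3L)
  expect_equal(s3$total, 3L)
  expect_error(score_sofa(c(creatinine = -1)), "negative")
})

test_that("worsening one lab never decreases its component", {
  grids <- list(
    list(var = "creatinine", comp = "renal", vals = c(0.5, 1.5, 2.5, 4, 6)),
    list(var = "platelets", comp = "coagulation", vals = c(300, 120, 70, 30, 10)),
    list(var = "bilirubin_total", comp = "hepatic", vals = c(0.5, 1.5, 3, 8, 15)),
    list(var = "gcs_total", comp = "cns", vals = c(15, 14, 11, 8, 4))
  )
  for (g in grids) {
    sc <- vapply(g$vals, function(v) {
      obs <- stats::setNames(v, g$var)
      score_sofa(obs)[[g$comp]]
    }, integer(1))
    expect_true(all(diff(sc) >= 0), info = g$var)
  }
})

test_that("sofa_track carries observations forward and aggregates by max", {
  ev <- data.frame(
    encounter_id = "E1", patient_id = "P1",
    time_hours = c(0, 6, 12, 18, 24),
    variable = "creatinine", value = c(0.8, 0.8, 3.6, 3.6, 3.6),
    stringsAsFactors = FALSE
  )
  st <- toy_stream(events = ev)
  trk <- sofa_track(st, "E1")
  expect_equal(trk$renal[trk$time == 0], 0)
  expect_equal(trk$renal[trk$time == 12], 3)
  agg <- sofa_window_max(trk, 0, 24)
  expect_equal(agg$renal, 3)

  # constant observations -> constant track equal to its windowed max
  ev2 <- ev; ev2$value <- 2.5
  trk2 <- sofa_track(toy_stream(events = ev2), "E1")
  expect_true(all(trk2$renal == 2))
  expect_equal(sofa_window_max(trk2, 0, 24)$renal, 2)

  # no scoreable observations -> empty track
  ev3 <- ev[0, ]
  expect_equal(nrow(sofa_track(toy_stream(events = ev3), "E1")), 0)
})

test_that("staleness horizon expires carried-forward values", {
  ev <- data.frame(encounter_id = "E1", patient_id = "P1", time_hours = 0,
                   variable = "creatinine", value = 3.6,
                   stringsAsFactors = FALSE)
  ev <- rbind(ev, data.frame(encounter_id = "E1", patient_id = "P1",
                             time_hours = c(0, 40), variable = "map",
                             value = c(80, 80), stringsAsFactors = FALSE))
  trk <- sofa_track(toy_stream(events = ev), "E1")
  expect_equal(trk$renal[trk$time == 20], 3)   # within 24 h lab horizon
  expect_equal(trk$renal[trk$time == 30], 0)   # expired
})

test_that("suspicion pairing follows the two window rules", {
  s <- find_suspicion(10, 12)
  expect_equal(s$time, 10)
  expect_equal(s$trigger, "abx_then_culture")
  expect_null(find_suspicion(10, 40))            # gap 30 h > 24 h
  expect_null(find_suspicion(10, numeric(0)))
  s2 <- find_suspicion(60, 20)                   # culture first, abx within 72 h
  expect_equal(s2$time, 20)
  expect_equal(s2$trigger, "culture_then_abx")
  expect_null(find_suspicion(100, 20))           # 80 h > 72 h
  # earliest qualifying pair wins
  s3 <- find_suspicion(c(30, 10), c(31, 11))
  expect_equal(s3$time, 10)
})

test_that("sepsis-3 onset detection traces the window rule", {
  mk_track <- function(times, totals) {
    data.frame(time = times, respiration = 0L, coagulation = 0L,
               hepatic = 0L, cardiovascular = 0L, cns = 0L, renal = 0L,
               total = totals)
  }
  susp <- list(time = 50, trigger = "abx_then_culture")
  # flat low total -> no onset
  flat <- mk_track(0:80, rep(1L, 81))
  det <- detect_sepsis3(flat, susp)
  expect_true(is.na(det$onset_time))
  expect_lt(det$delta_sofa, 2)
  # baseline 0 (no data before window), jump to 2 at suspicion + 5 h
  tr <- mk_track(2:80, ifelse(2:80 >= 55, 2L, 0L))
  det2 <- detect_sepsis3(tr, susp)
  expect_equal(det2$onset_time, 55)
  expect_equal(det2$delta_sofa, 2L)
  # jump at suspicion + 30 h is outside the +24 h bound
  tr3 <- mk_track(2:120, ifelse(2:120 >= 80, 2L, 0L))
  det3 <- detect_sepsis3(tr3, susp)
  expect_true(is.na(det3$onset_time))
  # unordered track errors
  expect_error(detect_sepsis3(tr[c(2, 1, 3:nrow(tr)), ], susp), "ordered")
})

test_that("onset decision ignores observations outside search and baseline windows", {
  susp <- list(time = 100, trigger = "abx_then_culture")
  base <- data.frame(time = seq(30, 124, by = 1))
  base$total <- ifelse(base$time >= 110, 3L, 1L)
  for (c6 in c("respiration", "coagulation", "hepatic", "cardiovascular", "cns", "renal"))
    base[[c6]] <- 0L
  d1 <- detect_sepsis3(base, susp)
  # add early and late observations strictly outside [28, 124]
  extra <- base[c(1, 1), ]
  extra$time <- c(5, 160); extra$total <- c(24L, 24L)
  aug <- rbind(extra[1, ], base, extra[2, ])
  d2 <- detect_sepsis3(aug, susp)
  expect_equal(d1$onset_time, d2$onset_time)
  expect_equal(d1$delta_sofa, d2$delta_sofa)
})
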