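test_that("inhibition percent follows the OD formula and is not clamped", {
  expect_equal(inhibition_percent(0.05, 0.05, 0.05, 0.50), 100)
  expect_equal(inhibition_percent(0.05, 0.50, 0.05, 0.50), 0)
  expect_equal(inhibition_percent(0.05, 0.275, 0.05, 0.50), 50)
  # lysis below starting OD exceeds 100; growth promotion is negative
  expect_gt(inhibition_percent(0.10, 0.05, 0.05, 0.50), 100)
  expect_lt(inhibition_percent(0.05, 0.70, 0.05, 0.50), 0)
  expect_error(inhibition_percent(0.05, 0.1, 0.5, 0.4), "control growth")
})

test_that("inhibition percent is invariant under affine OD rescaling", {
  set.seed(51)
  for (i in 1:20) {
    t0 <- runif(1, 0, 0.2); t24 <- t0 + runif(1, -0.05, 0.5)
    c0 <- runif(1, 0, 0.2); c24 <- c0 + runif(1, 0.1, 0.6)
    gain <- runif(1, 0.5, 3); offset <- runif(1, -0.02, 0.1)
    expect_equal(
      inhibition_percent(t0, t24, c0, c24),
      inhibition_percent(gain * t0 + offset, gain * t24 + offset,
                         gain * c0 + offset, gain * c24 + offset),
      tolerance = 1e-9
    )
  }
})

test_that("plate layout covers 96 wells with the documented roles", {
  lay <- plate_layout()
  expect_equal(nrow(lay), 96)
  expect_equal(sum(lay$role == "sterility"), 4)
  expect_equal(sum(lay$role == "positive"), 4)
  expect_equal(sum(lay$role == "test"), 80)
  expect_equal(sum(lay$role == "negative"), 8)
  expect_true(all(lay$row[lay$role %in% c("sterility", "positive")] == 1))
  expect_true(all(lay$row[lay$role == "negative"] == 12))
})

test_that("plate validation flags contamination and assay failure", {
  set.seed(52)
  pl <- simulate_plate(data.frame(strain = "s1", medium = "FM1",
                                  pathogen = "Sa", effect = 0.5),
                       n_replicates = 1)
  r <- pl$readings
  expect_true(validate_plate(r)$valid)
  # a grown sterility well
  bad <- r
  i <- which(bad$row == 1 & bad$col == 1)
  bad$od_t24[i] <- bad$od_t0[i] + 0.3
  v <- validate_plate(bad)
  expect_false(v$valid)
  expect_true("contamination" %in% v$reasons)
  # dead positive control (wells grow like the negative control)
  bad2 <- r
  pos <- bad2$row == 1 & bad2$col >= 5
  bad2$od_t24[pos] <- bad2$od_t0[pos] + 0.45
  v2 <- validate_plate(bad2)
  expect_false(v2$valid)
  expect_true("assay failure" %in% v2$reasons)
  # missing wells are named
  expect_error(validate_plate(r[-1, ]), "missing wells: R01C1")
})

test_that("activity calls average replicates and use a strict threshold", {
  lay <- plate_layout()
  samples <- data.frame(row = 2, col = 1, strain = "s1", medium = "FM1",
                        pathogen = "Sa", stringsAsFactors = FALSE)
  # build three replicate plates by hand with control delta 0.5 per plate
  mk_rep <- function(rep_id, test_delta) {
    r <- lay
    r$replicate <- rep_id
    r$od_t0 <- 0.25
    delta <- ifelse(r$role == "negative", 0.5,
                    ifelse(r$role == "sterility", 0,
                           ifelse(r$role == "positive", 0.01, 0.5)))
    delta[r$row == 2 & r$col == 1] <- test_delta
    r$od_t24 <- r$od_t0 + delta
    r[, c("replicate", "row", "col", "od_t0", "od_t24")]
  }
  # inhibitions 70, 65, 72 -> mean 69, active
  readings <- rbind(mk_rep(1, 0.5 * 0.30), mk_rep(2, 0.5 * 0.35),
                    mk_rep(3, 0.5 * 0.28))
  calls <- call_activity(readings, samples)
  expect_equal(calls$inhibition_pct, 69, tolerance = 1e-9)
  expect_true(calls$active)
  expect_equal(calls$n_replicates, 3)
  # inhibition exactly at the boundary is NOT active (strict "above"):
  # delta ratio 1/2 is exactly representable, so inhibition is exactly 50
  boundary <- rbind(mk_rep(1, 0.25), mk_rep(2, 0.25), mk_rep(3, 0.25))
  calls50 <- call_activity(boundary, samples, threshold = 50)
  expect_identical(calls50$inhibition_pct, 50)
  expect_false(calls50$active)
  # 59.999... at the default 60 threshold is inactive too
  just_under <- rbind(mk_rep(1, 0.2), mk_rep(2, 0.2), mk_rep(3, 0.2))
  expect_false(call_activity(just_under, samples)$active)
})

test_that("simulated screens are classified with high sensitivity/specificity", {
  set.seed(53)
  n_per_plate <- 50
  n_plates <- 10  # 500 wells total, half with effect 0.8
  truth_all <- list(); calls_all <- list()
  for (p in seq_len(n_plates)) {
    eff <- data.frame(
      strain = sprintf("p%d_s%d", p, seq_len(n_per_plate)),
      medium = "FM1", pathogen = "Sa",
      effect = rep(c(0, 0.8), length.out = n_per_plate)
    )
    pl <- simulate_plate(eff)
    calls <- call_activity(pl$readings, pl$samples)
    m <- match(calls$strain, eff$strain)
    truth_all[[p]] <- eff$effect[m] > 0
    calls_all[[p]] <- calls$active
  }
  truth <- unlist(truth_all); called <- unlist(calls_all)
  sens <- sum(called & truth) / sum(truth)
  spec <- sum(!called & !truth) / sum(!truth)
  expect_gte(sens, 0.99)
  expect_gte(spec, 0.99)
})

test_that("screen summaries count strains per pathogen and medium", {
  calls <- data.frame(
    strain = c("s1", "s1", "s2"),
    medium = c("FM1", "FM4", "FM4"),
    pathogen = c("Sa", "Sa", "Ec"),
    inhibition_pct = c(80, 75, 20),
    n_replicates = 3,
    active = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  sm <- summarize_screen(calls)
  expect_equal(sm$per_pathogen$n_active_strains[sm$per_pathogen$pathogen == "Sa"], 1)
  expect_equal(sm$per_medium$n_active_strains, c(1, 1))  # FM1 and FM4
  expect_true(sm$per_strain$any_active[sm$per_strain$strain == "s1"])
  expect_false(sm$per_strain$any_active[sm$per_strain$strain == "s2"])
  # a strain active in several media still counts once per medium:
  expect_gte(sum(sm$per_medium$n_active_strains),
             sum(sm$per_strain$any_active))
  # empty input gives empty tables
  sm0 <- summarize_screen(calls[0, ])
  expect_equal(nrow(sm0$per_pathogen), 0)
})

test_that("long-format plate CSV round trips including letter orientation", {
  set.seed(54)
  pl <- simulate_plate(data.frame(strain = "s", medium = "m", pathogen = "p",
                                  effect = 0.4), n_replicates = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(pl$readings, path)
  back <- read_plate_csv(path)
  merged <- merge(pl$readings, back, by = c("replicate", "row", "col"))
  expect_equal(nrow(merged), nrow(pl$readings))
  expect_equal(merged$od_t24.x, merged$od_t24.y, tolerance = 1e-9)
  # standard A-H x 1-12 orientation transposes into rows 1-12 x cols 1-8
  long <- data.frame(replicate = 1, row = c("A", "B"), col = c(5, 12),
                     timepoint = rep(c("t0", "t24"), each = 2),
                     od600 = c(0.05, 0.05, 0.5, 0.4))
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rbind(long[c(1, 3), ], long[c(2, 4), ]), p2,
                   row.names = FALSE)
  w <- read_plate_csv(p2)
  expect_setequal(w$row, c(5L, 12L))
  expect_setequal(w$col, c(1L, 2L))
})
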