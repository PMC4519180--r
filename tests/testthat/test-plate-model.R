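test_that("replicate FP reads average to the per-well value", {
  w <- well_record("P1", "A1", "compound", c(100, 102, 104), compound_id = "X")
  expect_equal(average_reads(w), 102.0)
  expect_equal(average_reads(well_record("P1", "A2", "pos_control", 50)), 50.0)
  expect_equal(average_reads(c(0, 0, 0)), 0.0)
  expect_error(average_reads(numeric()), class = "fpscreen_value_error")
})

test_that("well records enforce role/compound invariants", {
  expect_error(well_record("P1", "A1", "compound", 100),
               class = "fpscreen_integrity_error")
  expect_error(well_record("P1", "A1", "pos_control", 100, compound_id = "X"),
               class = "fpscreen_integrity_error")
  expect_error(well_record("P1", "A1", "compound", c(100, NaN), compound_id = "X"),
               class = "fpscreen_value_error")
  expect_error(
    screen_plate("P1", list(well_record("P1", "A1", "pos_control", 100),
                            well_record("P1", "A1", "neg_control", 50))),
    class = "fpscreen_integrity_error")
})

test_that("plate summary computes per-role means and sample SDs", {
  pl <- toy_plate(pos = c(100, 100), neg = c(200, 200))
  ps <- summarize_plate(pl)
  expect_equal(ps$mean_pos, 100)
  expect_equal(ps$sd_pos, 0)
  expect_equal(ps$mean_neg, 200)
  expect_equal(ps$sd_neg, 0)

  ps2 <- summarize_plate(toy_plate(pos = c(90, 110), neg = c(195, 205)))
  expect_equal(ps2$mean_pos, 100)
  expect_equal(ps2$sd_pos, sqrt(200))  # n-1 denominator: sd({90,110}) = 14.142...

  expect_error(summarize_plate(toy_plate(pos = 100, neg = c(200, 200))),
               class = "fpscreen_insufficient_controls_error")
})

test_that("plate summary is invariant under permutation of wells", {
  set.seed(5)
  cmp <- stats::setNames(round(stats::rnorm(10, 150, 10), 2), sprintf("C%02d", 1:10))
  pl <- toy_plate(pos = c(90, 110, 95), neg = c(190, 210), compounds = cmp)
  perm <- pl
  perm$wells <- perm$wells[sample(length(perm$wells))]
  a <- summarize_plate(pl); b <- summarize_plate(perm)
  expect_equal(a[names(a) != "plate_id"], b[names(b) != "plate_id"])
})

test_that("plate tables parse, group reads per well, and reject duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plate_id,well,role,compound_id,read_index,fp_mP,intensity_rfu",
    "P1,A1,compound,X,1,100,900",
    "P1,A1,compound,X,2,102,905",
    "P1,A1,compound,X,3,104,910"), path)
  plates <- read_plate_table(path)
  expect_length(plates, 1L)
  expect_length(plates[[1]]$wells, 1L)
  expect_equal(plates[[1]]$wells[[1]]$fp_reads, c(100, 102, 104))
  expect_equal(plates[[1]]$wells[[1]]$intensity_reads, c(900, 905, 910))

  # two plates, 4 wells each
  path2 <- withr::local_tempfile(fileext = ".csv")
  hdr <- "plate_id,well,role,compound_id,read_index,fp_mP,intensity_rfu"
  rows <- unlist(lapply(c("P1", "P2"), function(p) {
    sprintf("%s,%s,compound,%s,1,%d,", p, c("A1", "A2", "B1", "B2"),
            paste0(p, 1:4), 100 + 1:4)
  }))
  writeLines(c(hdr, rows), path2)
  plates2 <- read_plate_table(path2)
  expect_length(plates2, 2L)
  expect_equal(vapply(plates2, function(p) length(p$wells), integer(1)), c(4L, 4L))

  # duplicate coordinate
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "P1,A1,compound,X,1,100,", "P1,A1,compound,X,1,101,"), path3)
  expect_error(read_plate_table(path3), class = "fpscreen_integrity_error")

  # missing column named in the error
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,well,role,compound_id,read_index,fp_mP",
               "P1,A1,compound,X,1,100"), path4)
  expect_error(read_plate_table(path4), "intensity_rfu",
               class = "fpscreen_format_error")
})

test_that("write then read round-trips all numeric well fields", {
  cfg <- sim_config(seed = 3, screen = list(
    n_plates = 2L, compounds_per_plate = 20L,
    hits = data.frame(position = c(3L, 25L), fraction = c(0.8, 0.9),
                      retest_fraction = c(0.8, 0.9), quencher = c(FALSE, TRUE))))
  plates <- generate_screen(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(plates, path)
  back <- read_plate_table(path)
  expect_length(back, length(plates))
  for (i in seq_along(plates)) {
    for (j in seq_along(plates[[i]]$wells)) {
      w0 <- plates[[i]]$wells[[j]]; w1 <- back[[i]]$wells[[j]]
      expect_identical(w1$well, w0$well)
      expect_identical(w1$role, w0$role)
      expect_identical(w1$fp_reads, w0$fp_reads)
      expect_identical(w1$intensity_reads, w0$intensity_reads)
    }
  }
})
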