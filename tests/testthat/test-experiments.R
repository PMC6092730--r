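# accuracy studies, distance table statistics, reports

test_that("reference distance table reproduces the published summary", {
  tab <- reference_bar_distances()
  expect_equal(nrow(tab), 10)
  # each row's absolute difference is consistent
  expect_equal(tab$abs_diff_mm, abs(tab$real_mm - tab$virtual_mm),
               tolerance = 1e-9)
  st <- distance_table_stats(tab)
  expect_equal(st$mean_mm, 1.96)
  expect_equal(round(st$mean_mm, 1), 2.0)
  # the published 1.5 mm SD does not match the printed column (population
  # SD ~ 0.66 mm); it is deliberately not asserted
  expect_lt(st$sd_mm, 0.7)
})

test_that("distance table statistics handle degenerate inputs", {
  const <- data.frame(abs_diff_mm = rep(2, 6))
  st <- distance_table_stats(const)
  expect_equal(st$mean_mm, 2)
  expect_equal(st$sd_mm, 0)
  one <- data.frame(abs_diff_mm = 3.2)
  expect_equal(distance_table_stats(one)$sd_mm, 0)   # population convention
  expect_error(distance_table_stats(data.frame(abs_diff_mm = numeric(0))),
               "empty")
})

test_that("accuracy reports keep mean/SD/pass consistent", {
  r <- accuracy_report(c(3, 4, 5), threshold = 5)
  expect_equal(r$mean, 4)
  expect_equal(r$sd, sqrt(mean((c(3, 4, 5) - 4)^2)))
  expect_true(r$pass)
  expect_false(accuracy_report(c(5, 5.5), threshold = 5)$pass)
  expect_equal(accuracy_report(7)$sd, 0)
  expect_equal(r$sd_convention, "population")
})

test_that("the anthropomorphic study is exact without noise", {
  ps <- cached_pscene("anthro")
  res <- run_anthropomorphic(n_trials = 1, seed = 1, noise = zero_noise(),
                             pscene = ps)
  expect_equal(nrow(res$table), 10)           # C(5,2) pairs
  expect_true(all(res$table$abs_diff_mm < 0.1))
  expect_equal(res$table$abs_diff_mm,
               abs(res$table$real_mm - res$table$virtual_mm),
               tolerance = 1e-9)
})

test_that("the anthropomorphic study stays within threshold under noise", {
  ps <- cached_pscene("anthro")
  res <- run_anthropomorphic(n_trials = 10, seed = 2, pscene = ps)
  expect_equal(nrow(res$table), 10)
  expect_lt(res$stats$mean_mm, 5)
  expect_true(res$report$pass)
  expect_equal(res$n_trials_used, 30)         # 10 trials x 3 camera distances
})

test_that("experiment runs are reproducible byte-for-byte", {
  ps <- cached_pscene("anthro")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_accuracy_report(
    run_anthropomorphic(n_trials = 2, seed = 5, pscene = ps)$report, p1)
  write_accuracy_report(
    run_anthropomorphic(n_trials = 2, seed = 5, pscene = ps)$report, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("porcine study aggregates per-target insertions", {
  ps <- cached_pscene("porcine")
  rep_g <- run_porcine(gated = TRUE, n_reps = 3, seed = 11, pscene = ps)
  expect_length(rep_g$errors, 9)
  pt <- attr(rep_g, "per_target")
  expect_named(pt, c("kidney", "liver1", "liver2"))
  expect_equal(unname(vapply(pt, function(r) length(r$errors), numeric(1))),
               rep(3, 3))
  expect_equal(mean(rep_g$errors), rep_g$mean)
})

test_that("cadaver study reports lesion diameters and zero-noise hits", {
  ps <- cached_pscene("cadaver")
  rep_c <- run_cadaver(n_reps = 2, seed = 3, noise = zero_noise(),
                       pscene = ps)
  pt <- attr(rep_c, "per_target")
  expect_equal(unname(vapply(pt, attr, numeric(1), "diameter_mm")),
               c(18, 30))
  # noiseless gated insertion always ends inside the lesion sphere
  expect_equal(unname(vapply(pt, attr, numeric(1), "hit_rate")), c(1, 1))
  expect_true(rep_c$pass)
})

test_that("accuracy report JSON carries the per-target structure", {
  ps <- cached_pscene("cadaver")
  rep_c <- run_cadaver(n_reps = 2, seed = 3, noise = zero_noise(),
                       pscene = ps)
  p <- withr::local_tempfile(fileext = ".json")
  write_accuracy_report(rep_c, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$sd_convention, "population")
  expect_equal(j$per_target$met1$diameter_mm, 18)
  expect_equal(j$per_target$met2$diameter_mm, 30)
  expect_equal(length(j$errors_mm), 4)
})

test_that("the CLI computes table statistics and synthesises volumes", {
  out <- withr::local_tempfile(fileext = ".txt")
  ref <- system.file("extdata", "anthro_reference_distances.csv",
                     package = "endoguide")
  expect_invisible(endoguide_main(c("table", "--in", ref)))
  vol_out <- withr::local_tempfile(fileext = ".nii")
  suppressMessages(endoguide_main(c("synth", "--scenario", "porcine",
                                    "--seed", "2", "--spacing", "2",
                                    "--out", vol_out)))
  expect_true(file.exists(vol_out))
  back <- read_nifti(vol_out)
  expect_equal(back$spacing, rep(2, 3))
  fid_csv <- sub("\\.nii$", "_fiducials.csv", vol_out)
  expect_true(file.exists(fid_csv))
  expect_equal(nrow(read_fiducials(fid_csv)$points), 12)
})
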