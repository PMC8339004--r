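lesions_2case <- function() {
  list(cases = tibble::tibble(case_id = c("a", "b"),
                              n_lesions = c(1L, 0L)),
       lesions = tibble::tibble(case_id = "a", lesion_id = 1L,
                                com_x = 100, com_y = 100, weight = 1))
}

test_that("the 30-pixel rule is strict at the boundary", {
  man <- lesions_2case()
  near <- tibble::tibble(case_id = "a", x = 100 + 29.9, y = 100, score = 0.8)
  at <- tibble::tibble(case_id = "a", x = 100 + 30.0, y = 100, score = 0.8)
  r_near <- match_marks(near, man, radius_px = 30)
  expect_equal(r_near$lesion_ratings$rating, 0.8)
  expect_equal(nrow(r_near$nl), 0)
  r_at <- match_marks(at, man, radius_px = 30)
  expect_equal(r_at$lesion_ratings$rating, -Inf)
  expect_equal(nrow(r_at$nl), 1)
  # the boundary comparison is config-exposed
  r_incl <- match_marks(at, man, radius_px = 30, radius_inclusive = TRUE)
  expect_equal(r_incl$lesion_ratings$rating, 0.8)
})

test_that("greedy matching prefers higher scores, then closer marks", {
  man <- lesions_2case()
  # two equal-score marks: the nearer one localises the lesion
  marks <- tibble::tibble(case_id = "a", x = c(105, 110), y = 100,
                          score = 0.5)
  r <- match_marks(marks, man)
  expect_equal(r$lesion_ratings$rating, 0.5)
  expect_equal(nrow(r$nl), 1)
  # brute force over both assignment orders: matching the farther mark
  # first would strand the nearer as FP; the rule picks the nearer
  d <- abs(marks$x - 100)
  expect_equal(d[which.min(d)], 5)

  # higher score wins even when farther
  marks2 <- tibble::tibble(case_id = "a", x = c(105, 120), y = 100,
                           score = c(0.4, 0.9))
  r2 <- match_marks(marks2, man)
  expect_equal(r2$lesion_ratings$rating, 0.9)
  expect_equal(r2$nl$score, 0.4)

  # one-to-one: every input mark is LL or NL exactly once
  marks3 <- tibble::tibble(case_id = "a", x = c(101, 102, 260), y = 100,
                           score = c(0.3, 0.2, 0.7))
  r3 <- match_marks(marks3, man)
  n_ll <- sum(is.finite(r3$lesion_ratings$rating))
  expect_equal(n_ll + nrow(r3$nl), nrow(marks3))
})

test_that("marks are validated, deduplicated and thresholded", {
  man <- lesions_2case()
  expect_error(match_marks(tibble::tibble(case_id = "zz", x = 1, y = 1,
                                          score = 1), man),
               class = "cxrsim_validation_error")
  dup <- tibble::tibble(case_id = "a", x = c(10, 10), y = 10, score = 0.5)
  expect_warning(r <- match_marks(dup, man),
                 class = "cxrsim_duplicate_marks_warning")
  expect_equal(nrow(r$nl), 1)
  # marks below zeta are discarded before matching
  marks <- tibble::tibble(case_id = "a", x = c(101, 240), y = 100,
                          score = c(0.2, 0.9))
  r2 <- match_marks(marks, man, score_threshold = 0.5)
  expect_equal(r2$lesion_ratings$rating, -Inf)
  expect_equal(nrow(r2$nl), 1)
})

test_that("lesion weights are equal and sum to one", {
  expect_equal(lesion_weights(4), rep(0.25, 4))
  expect_equal(lesion_weights(1), 1)
  expect_lt(abs(sum(lesion_weights(3)) - 1), 1e-12)
  expect_error(lesion_weights(0), class = "cxrsim_validation_error")
})

test_that("FROC points follow the counting definitions", {
  # perfect detector
  perfect <- ratings_fixture(list(c(1, 1)), normal_fp = -Inf)
  fr <- compute_froc(perfect)
  expect_equal(fr$llf[fr$zeta == 1], 1)
  expect_equal(fr$nlf[fr$zeta == 1], 0)

  # no marks at all: single point (0, 0)
  none <- ratings_fixture(list(c(-Inf, -Inf)), normal_fp = -Inf)
  fr0 <- compute_froc(none)
  expect_equal(nrow(fr0), 1)
  expect_equal(fr0$llf, 0)
  expect_equal(fr0$nlf, 0)

  # two cases: lesions at 0.9/0.4, one nodule-free case with FP 0.6
  inst <- ratings_fixture(list(c(0.9, 0.4)), normal_fp = 0.6)
  fr2 <- compute_froc(inst)
  # at zeta = 0.6: one of two lesions localised, one FP over two cases
  expect_equal(fr2$llf[fr2$zeta == 0.6], 0.5)
  expect_equal(fr2$nlf[fr2$zeta == 0.6], 0.5)
  expect_true(all(diff(fr2$llf) >= 0))   # zeta descending: LLF grows
  expect_true(all(diff(fr2$nlf) >= 0))

  expect_error(compute_froc(ratings_fixture(list(), normal_fp = 1)),
               class = "cxrsim_validation_error")
})

test_that("wAFROC endpoints behave: perfect = 1, all-tied = 1/2", {
  perfect <- ratings_fixture(list(c(5, 5), 4), normal_fp = c(1, -Inf))
  expect_equal(compute_wafroc(perfect)$fom, 1)
  silent <- ratings_fixture(list(c(-Inf, -Inf), -Inf),
                            normal_fp = c(-Inf, -Inf))
  expect_equal(compute_wafroc(silent)$fom, 0.5)
  # K_F = 0 is rejected
  expect_error(compute_wafroc(ratings_fixture(list(1))),
               class = "cxrsim_validation_error")
})

test_that("the psi-kernel FOM equals the trapezoidal curve area", {
  set.seed(7)
  for (i in 1:120) {
    r <- random_ratings()
    wa <- compute_wafroc(r)
    expect_lt(abs(wa$fom - wafroc_curve_area(wa)), 1e-12)
    expect_gte(wa$fom, 0)
    expect_lte(wa$fom, 1)
    expect_true(all(diff(wa$curve$fpf) >= 0))
    expect_true(all(diff(wa$curve$wllf) >= 0))
  }
})

test_that("FOM and curve orderings are invariant to monotone rescoring", {
  set.seed(13)
  for (i in 1:20) {
    r <- random_ratings()
    wa <- compute_wafroc(r)
    fr <- compute_froc(r)
    # strictly increasing transform of every score
    tr <- function(x) ifelse(is.finite(x), exp(0.7 * x) + 2, x)
    r2 <- r
    r2$lesion_ratings$rating <- tr(r2$lesion_ratings$rating)
    r2$nl$score <- tr(r2$nl$score)
    wa2 <- compute_wafroc(r2)
    fr2 <- compute_froc(r2)
    expect_equal(wa2$fom, wa$fom, tolerance = 1e-12)
    expect_equal(wa2$curve$fpf, wa$curve$fpf)
    expect_equal(wa2$curve$wllf, wa$curve$wllf)
    expect_equal(fr2$llf, fr$llf)
    expect_equal(fr2$nlf, fr$nlf)
  }
})

test_that("wLLF equals LLF when all cases have equal lesion counts", {
  set.seed(5)
  for (i in 1:10) {
    diseased <- lapply(1:3, function(j)
      ifelse(runif(2) < 0.4, -Inf, sample(1:4, 2, replace = TRUE)))
    r <- ratings_fixture(diseased, normal_fp = sample(c(-Inf, 1:4), 2))
    wa <- compute_wafroc(r)
    fr <- compute_froc(r)
    common <- intersect(wa$curve$zeta, fr$zeta)
    for (z in common)
      expect_equal(wa$curve$wllf[wa$curve$zeta == z],
                   fr$llf[fr$zeta == z])
  }
})

test_that("wLLF interpolates along the empirical curve", {
  # cases: d1 lesions 0.9/0.3, d2 lesion 0.5; f1 FP 0.4, f2 silent
  inst <- ratings_fixture(list(c(0.9, 0.3), 0.5), normal_fp = c(0.4, -Inf))
  wa <- compute_wafroc(inst)
  # hand-traced operating points: (0,.25), (0,.75), (.5,.75), (.5,1)
  expect_equal(wa$curve$fpf, c(0, 0, 0.5, 0.5))
  expect_equal(wa$curve$wllf, c(0.25, 0.75, 0.75, 1))
  expect_equal(wa$fom, 0.875)               # hand-computed kernel value
  expect_equal(wllf_at(wa, 0.2), 0.75)      # flat segment
  expect_equal(wllf_at(wa, 0.5), 1)         # exact observed point (upper)
  expect_equal(wllf_at(wa, 0.75), 1)        # on the (1,1) extension
  # an instance with no observed point at FPF = 0 starts at the origin
  allfp <- ratings_fixture(list(0.9), normal_fp = c(5, 5))
  expect_equal(wllf_at(compute_wafroc(allfp), 0), 0)
})

test_that("count summaries partition the lesions", {
  inst <- ratings_fixture(list(c(0.9, 0.5), c(0.5, -Inf)),
                          normal_fp = 0.5,
                          extra_nl = tibble::tibble(case_id = "d01",
                                                    score = 0.3))
  for (z in c(0.2, 0.5, 0.8)) {
    cnt <- summarize_counts(inst, z)
    expect_equal(cnt[["tp"]] + cnt[["fn"]], 4)
  }
  # >= vs > at the threshold
  lax <- summarize_counts(inst, 0.5)
  strict <- summarize_counts(inst, 0.5, strict = TRUE)
  expect_equal(lax[["tp"]], 3); expect_equal(strict[["tp"]], 1)
  expect_equal(lax[["fp"]], 1); expect_equal(strict[["fp"]], 0)
})

test_that("box detections are verified by segmentation marks", {
  boxes <- tibble::tibble(case_id = c("a", "a", "b"),
                          x0 = c(0, 50, 0), y0 = c(0, 50, 0),
                          x1 = c(10, 60, 10), y1 = c(10, 60, 10),
                          score = c(0.9, 0.8, 0.7))
  segs <- tibble::tibble(case_id = c("a", "b"), x = c(5, 10), y = c(5, 0),
                         score = 1)
  out <- combine_detections(boxes, segs)
  # centre hit, edge hit (inclusive); the unsupported box drops out
  expect_equal(nrow(out), 2)
  expect_equal(out$score, c(0.9, 0.7))
  expect_equal(out$x, c(5, 5))
  expect_equal(combine_detections(boxes,
                                  segs[0, ])$case_id, character(0))
  bad <- boxes; bad$x1[1] <- bad$x0[1]
  expect_error(combine_detections(bad, segs),
               class = "cxrsim_validation_error")
})

test_that("segmentation masks become component-wise marks", {
  mask <- matrix(0, 20, 20)
  mask[2:4, 2:4] <- 1                       # blob A
  mask[10:12, 15] <- 1                      # blob B
  mask[5, 5] <- 1                           # diagonal touch: joins blob A (8-conn)
  score <- matrix(0, 20, 20); score[3, 3] <- 0.4; score[11, 15] <- 0.9
  marks <- marks_from_segmentation(mask, score)
  expect_equal(nrow(marks), 2)
  expect_setequal(round(marks$score, 2), c(0.4, 0.9))
  # L-shaped blob COM against brute-force pixel averaging
  L <- matrix(0, 10, 10)
  L[2:6, 2] <- 1; L[6, 2:5] <- 1
  mk <- marks_from_segmentation(L)
  idx <- which(L == 1, arr.ind = TRUE)
  expect_equal(mk$y, mean(idx[, 1]) - 1)
  expect_equal(mk$x, mean(idx[, 2]) - 1)
  expect_equal(nrow(marks_from_segmentation(matrix(0, 5, 5))), 0)
})

rating_table_fixture <- function() {
  list(truth = data.frame(CaseID = c("d1", "d1", "d2", "f1", "f2"),
                          LesionID = c(1, 2, 1, 0, 0),
                          Weight = c(0.5, 0.5, 1, 0, 0)),
       nl = data.frame(ReaderID = "r1", ModalityID = "m1",
                       CaseID = "f1", NL_Rating = 0.4),
       ll = data.frame(ReaderID = "r1", ModalityID = "m1",
                       CaseID = c("d1", "d1", "d2"),
                       LesionID = c(1, 2, 1),
                       LL_Rating = c(0.9, 0.3, 0.5)))
}

test_that("rating tables round-trip and reproduce the hand-computed FOM", {
  dir <- tempfile()
  write_rating_table(rating_table_fixture(), dir)
  tbl <- load_rating_table(dir)
  expect_s3_class(tbl, "rating_table")
  r <- ratings_from_table(tbl, "r1", "m1")
  expect_equal(r$K_N, 2); expect_equal(r$K_F, 2)
  wa <- compute_wafroc(r)
  expect_equal(wa$fom, 0.875)               # same instance as above
  expect_equal(wllf_at(wa, 0.2), 0.75)
  # round trip again
  dir2 <- tempfile()
  write_rating_table(tbl, dir2)
  expect_equal(load_rating_table(dir2)$truth, tbl$truth)
})

test_that("malformed rating tables are rejected", {
  bad <- rating_table_fixture()
  bad$truth$Weight[1] <- 0.4               # weights sum to 0.9
  dir <- tempfile(); write_rating_table(bad, dir)
  expect_error(load_rating_table(dir), class = "cxrsim_validation_error")

  bad2 <- rating_table_fixture()
  bad2$ll$LesionID[3] <- 9                  # unknown lesion
  dir2 <- tempfile(); write_rating_table(bad2, dir2)
  expect_error(load_rating_table(dir2), class = "cxrsim_validation_error")
})

test_that("tidiers and plots expose the curves", {
  inst <- ratings_fixture(list(c(0.9, 0.3), 0.5), normal_fp = c(0.4, -Inf))
  wa <- compute_wafroc(inst)
  td <- tidy(wa)
  expect_true(all(c("zeta", "fpf", "wllf") %in% names(td)))
  gl <- glance(wa)
  expect_equal(gl$fom, gl$curve_area, tolerance = 1e-12)
  p1 <- ggplot2::ggplot_build(autoplot(wa))
  p2 <- ggplot2::ggplot_build(autoplot(compute_froc(inst)))
  expect_gt(length(p1$data), 0)
  expect_gt(length(p2$data), 0)
})
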