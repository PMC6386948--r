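feat <- function(n, s) list(n_peaks = n, sharpness = s)

test_that("enrollment fits the shared regression exactly where it must", {
  db <- profile_db()
  db <- enroll(db, "A", "s1", feat(1, 2))
  db <- enroll(db, "A", "s2", feat(3, 6))
  expect_equal(unname(coef(db)), c(0, 2))         # line through both points
  expect_equal(residuals(db), c(0, 0), tolerance = 1e-12)

  db <- enroll(db, "B", "s1", feat(5, 10))        # still collinear
  expect_equal(residuals(db), rep(0, 3), tolerance = 1e-12)

  expect_error(enroll(db, "A", "s1", feat(2, 2)), "already enrolled")
})

test_that("query residuals measure vertical deviation from the line", {
  db <- profile_db()
  db <- enroll(db, "A", "s1", feat(1, 2))
  db <- enroll(db, "A", "s2", feat(3, 6))
  expect_equal(unname(feature_residual(db, feat(2, 4))), 0)
  expect_equal(unname(feature_residual(db, feat(2, 5))), 1)

  single <- enroll(profile_db(), "A", "s1", feat(2, 3))
  expect_error(feature_residual(single, feat(2, 3)), "undefined")
})

test_that("identification ranks by distance with deterministic tie-breaks", {
  db <- profile_db()
  db <- enroll(db, "A", "s1", feat(1, 2))
  db <- enroll(db, "B", "s1", feat(4, 3))
  db <- enroll(db, "C", "s1", feat(8, 9))
  hit <- predict(db, feat(4, 3))
  expect_equal(hit$subject, "B")
  expect_equal(hit$distance, 0)

  ranked <- predict(db, feat(4, 3), k = 3)
  expect_equal(nrow(ranked), 3L)
  expect_true(all(diff(ranked$distance) >= 0))

  # one enrolled subject is always returned, even with degenerate scaling
  solo <- enroll(profile_db(), "Z", "s1", feat(2, 3))
  expect_equal(predict(solo, feat(7, 1))$subject, "Z")

  # exact ties resolve in lexical order
  db2 <- profile_db()
  db2 <- enroll(db2, "B", "s1", feat(2, 2))
  db2 <- enroll(db2, "A", "s1", feat(2, 2))
  db2 <- enroll(db2, "C", "s1", feat(4, 4))
  expect_equal(predict(db2, feat(2, 2))$subject, "A")
  expect_error(predict(profile_db(), feat(1, 1)), "empty")
})

test_that("identification is invariant to relabeling subjects", {
  set.seed(21)
  pts <- data.frame(subject = rep(c("A", "B", "C"), each = 2),
                    session = rep(c("s1", "s2"), 3),
                    n_peaks = c(1, 1.5, 4, 4.5, 7, 7.5),
                    sharpness = c(2, 2.2, 5, 5.5, 9, 8.6))
  db <- profile_db(pts)
  relab <- pts; relab$subject <- c(A = "X", B = "Y", C = "Z")[pts$subject]
  db2 <- profile_db(relab)
  q <- feat(4.2, 5.1)
  r1 <- predict(db, q, k = 3)
  r2 <- predict(db2, q, k = 3)
  expect_equal(c(A = "X", B = "Y", C = "Z")[r1$subject], r2$subject,
               ignore_attr = TRUE)
  expect_equal(r1$distance, r2$distance, tolerance = 1e-12)
})

test_that("cross-validation separates separable clouds and not identical ones", {
  # identical feature clouds cannot beat chance
  same <- data.frame(subject = rep(c("A", "B"), each = 2),
                     session = rep(c("s1", "s2"), 2),
                     n_peaks = rep(c(2, 3), 2), sharpness = rep(c(3, 4), 2))
  cv_same <- cross_validate(profile_db(same))
  expect_lte(cv_same$accuracy, 0.5)

  # widely separated clouds are perfectly recovered
  apart <- data.frame(subject = rep(c("A", "B"), each = 3),
                      session = rep(c("s1", "s2", "s3"), 2),
                      n_peaks = c(1, 1.05, 0.95, 9, 9.05, 8.95),
                      sharpness = c(2, 2.02, 1.98, 14, 14.05, 13.95))
  cv_apart <- cross_validate(profile_db(apart))
  expect_equal(cv_apart$accuracy, 1.0)
  expect_lt(cv_apart$median_intra, cv_apart$median_inter)

  short <- enroll(profile_db(same), "C", "s1", feat(5, 5))
  expect_error(cross_validate(short), ">= 2 sessions")
})

test_that("each held-out fold refits from scratch without the held-out session", {
  set.seed(22)
  tab <- data.frame(subject = rep(c("A", "B", "C"), each = 3),
                    session = rep(c("s1", "s2", "s3"), 3),
                    n_peaks = runif(9, 1, 8), sharpness = runif(9, 1, 10))
  db <- profile_db(tab)
  cv <- cross_validate(db)
  i <- 5L  # reproduce fold i by hand
  rest <- profile_db(tab[-i, ])
  ranked <- predict(rest, feat(tab$n_peaks[i], tab$sharpness[i]), k = 3)
  expect_equal(cv$details$predicted[i], ranked$subject[1])
  expect_equal(cv$details$distance[i], ranked$distance[1], tolerance = 1e-12)
})

test_that("profile databases round-trip through JSON", {
  db <- profile_db()
  db <- enroll(db, "M05", "d1", feat(2.5, 0.3076923076923077))
  db <- enroll(db, "M05", "d2", feat(3, 0.41))
  db <- enroll(db, "F01", "d1", feat(6, 1.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_db(db, path)
  back <- read_profile_db(path)
  tab_a <- db$sessions[order(db$sessions$subject, db$sessions$session), ]
  tab_b <- back$sessions[order(back$sessions$subject, back$sessions$session), ]
  expect_equal(tab_b$n_peaks, tab_a$n_peaks, tolerance = 1e-12)
  expect_equal(tab_b$sharpness, tab_a$sharpness, tolerance = 1e-12)
  expect_equal(coef(back), coef(db), tolerance = 1e-12)
})
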