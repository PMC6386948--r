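#' Enrollment database of subject feature profiles
#'
#' The identification model of this package. Each enrolled session
#' contributes one (n_peaks, sharpness) point. Because sharpness divides
#' the summed peak areas by the peak count, the two raw features are
#' strongly correlated by construction; the discriminative content is the
#' deviation of sharpness from the regression line fitted over all enrolled
#' sessions. Identification therefore operates in the
#' (n_peaks, residual) plane, z-scored per dimension over the enrollment
#' population, with one centroid per subject.
#'
#' `profile_db()` creates an empty database; [enroll()] adds sessions and
#' refits the regression and scaler. The fitted object supports
#' [coef()], [residuals()], [predict()][predict.profile_db],
#' [summary()][summary.profile_db] and [plot()][plot.profile_db].
#'
#' @param features optional data frame (`subject`, `session`, `n_peaks`,
#'   `sharpness`) to enroll immediately, e.g. from [read_features()].
#' @return An object of class `profile_db`.
#' @export
profile_db <- function(features = NULL) {
  db <- structure(list(
    sessions = data.frame(subject = character(0), session = character(0),
                          n_peaks = numeric(0), sharpness = numeric(0),
                          stringsAsFactors = FALSE),
    fit = NULL), class = "profile_db")
  if (!is.null(features)) {
    for (i in seq_len(nrow(features)))
      db <- enroll(db, features$subject[i], features$session[i],
                   list(n_peaks = features$n_peaks[i],
                        sharpness = features$sharpness[i]))
  }
  db
}

#' Enroll one subject session
#'
#' Appends a session's features and refits the shared regression of
#' sharpness on peak count (ordinary least squares over all enrolled
#' sessions) and the per-dimension scaler of the (n_peaks, residual) plane.
#'
#' @param db a [profile_db()].
#' @param subject_id,session_id labels; the pair must be new.
#' @param features a `peak_features` object (or any list with `n_peaks` and
#'   `sharpness`).
#' @return The updated `profile_db`.
#' @export
enroll <- function(db, subject_id, session_id, features) {
  stopifnot(inherits(db, "profile_db"))
  subject_id <- as.character(subject_id)
  session_id <- as.character(session_id)
  if (!nzchar(subject_id) || !nzchar(session_id))
    stop("enroll: empty subject or session id")
  dup <- db$sessions$subject == subject_id & db$sessions$session == session_id
  if (any(dup))
    stop("enroll: (", subject_id, ", ", session_id, ") already enrolled")
  db$sessions <- rbind(db$sessions, data.frame(
    subject = subject_id, session = session_id,
    n_peaks = features$n_peaks, sharpness = features$sharpness,
    stringsAsFactors = FALSE))
  db$fit <- fit_profile_db(db$sessions)
  db
}

# Refit regression + scaler from the session table.
fit_profile_db <- function(sessions) {
  n <- nrow(sessions)
  if (n == 0L) return(NULL)
  distinct_x <- length(unique(sessions$n_peaks)) >= 2L
  if (distinct_x) {
    ols <- stats::lm.fit(cbind(1, sessions$n_peaks), sessions$sharpness)
    coefs <- c(intercept = unname(ols$coefficients[1]),
               slope = unname(ols$coefficients[2]))
    resid <- unname(ols$residuals)
  } else {
    coefs <- NULL
    resid <- rep(NA_real_, n)
  }
  scaler <- list(
    mean = c(n_peaks = mean(sessions$n_peaks),
             residual = if (distinct_x) mean(resid) else NA_real_),
    sd = c(n_peaks = if (n >= 2L) stats::sd(sessions$n_peaks) else NA_real_,
           residual = if (distinct_x && n >= 2L) stats::sd(resid) else NA_real_))
  list(coefficients = coefs, residuals = resid, scaler = scaler)
}

#' @export
print.profile_db <- function(x, ...) {
  ns <- length(unique(x$sessions$subject))
  cat(sprintf("<profile_db> %d subject(s), %d session(s)\n",
              ns, nrow(x$sessions)))
  if (!is.null(x$fit$coefficients))
    cat(sprintf("  regression: sharpness = %.4g + %.4g * n_peaks\n",
                x$fit$coefficients["intercept"], x$fit$coefficients["slope"]))
  invisible(x)
}

#' @export
coef.profile_db <- function(object, ...) {
  if (is.null(object$fit$coefficients))
    stop("coef: regression undefined (need >= 2 distinct n_peaks values)")
  object$fit$coefficients
}

#' Regression residual of a feature point
#'
#' Returns `sharpness - (intercept + slope * n_peaks)` for a query point
#' under the database's fitted regression. Called without `features`,
#' [residuals()] returns the residuals of the enrolled sessions.
#'
#' @param db a fitted [profile_db()] with at least two distinct enrolled
#'   `n_peaks` values.
#' @param features a `peak_features` object or list with `n_peaks`,
#'   `sharpness`.
#' @return A single residual value.
#' @export
feature_residual <- function(db, features) {
  cf <- coef.profile_db(db)
  features$sharpness - (cf["intercept"] + cf["slope"] * features$n_peaks)
}

#' @export
residuals.profile_db <- function(object, ...) {
  if (is.null(object$fit)) stop("residuals: empty database")
  object$fit$residuals
}

# Map feature points to the z-scored (n_peaks, residual) plane.
# Degenerate dimensions (undefined or zero spread) are dropped.
db_embed <- function(db, n_peaks, sharpness) {
  fit <- db$fit
  has_reg <- !is.null(fit$coefficients)
  res <- if (has_reg)
    sharpness - (fit$coefficients["intercept"] +
                 fit$coefficients["slope"] * n_peaks)
  else rep(0, length(n_peaks))
  z <- cbind(n_peaks = n_peaks, residual = unname(res))
  keep <- logical(2)
  for (d in 1:2) {
    s <- fit$scaler$sd[d]; m <- fit$scaler$mean[d]
    ok <- is.finite(s) && s > 0 && (d == 1L || has_reg)
    if (ok) z[, d] <- (z[, d] - m) / s
    keep[d] <- ok
  }
  z[, keep, drop = FALSE]
}

#' Identify the subject of a query feature point
#'
#' The query is mapped to the z-scored (n_peaks, residual) plane and ranked
#' by Euclidean distance to each enrolled subject's centroid, ascending;
#' ties are broken by lexical subject order.
#'
#' @param object a non-empty [profile_db()].
#' @param features a `peak_features` object or list with `n_peaks`,
#'   `sharpness`.
#' @param k number of candidates to return (default 1).
#' @param ... unused.
#' @return A data frame with columns `subject` and `distance`, `k` rows,
#'   best match first.
#' @export
predict.profile_db <- function(object, features, k = 1L, ...) {
  if (nrow(object$sessions) == 0L) stop("predict: empty database")
  emb <- db_embed(object, object$sessions$n_peaks, object$sessions$sharpness)
  q <- db_embed(object, features$n_peaks, features$sharpness)
  subjects <- sort(unique(object$sessions$subject))
  dist <- vapply(subjects, function(s) {
    cen <- colMeans(emb[object$sessions$subject == s, , drop = FALSE])
    if (length(cen) == 0L) 0 else sqrt(sum((q[1, ] - cen)^2))
  }, numeric(1))
  ord <- order(dist, subjects)  # lexical tie-break
  k <- min(k, length(subjects))
  data.frame(subject = subjects[ord][seq_len(k)],
             distance = unname(dist[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' @rdname predict.profile_db
#' @param db a [profile_db()].
#' @export
identify_subject <- function(db, features, k = 1L) {
  predict.profile_db(db, features, k = k)
}

#' Leave-one-session-out cross-validation of an enrollment database
#'
#' Each enrolled session is removed in turn, the regression and scaler are
#' refitted from scratch on the remainder, and the held-out session is
#' identified against it. Reports top-1 accuracy, the confusion table, and
#' the median intra-subject (query to true-subject centroid) versus
#' inter-subject (query to other centroids) distance.
#'
#' @param db a [profile_db()] in which every subject has >= 2 sessions.
#' @return An object of class `piezoid_cv`: list with `accuracy`,
#'   `confusion`, `median_intra`, `median_inter`, `details` (per-held-out
#'   -session data frame).
#' @export
cross_validate <- function(db) {
  stopifnot(inherits(db, "profile_db"))
  tab <- db$sessions
  counts <- table(tab$subject)
  if (any(counts < 2L))
    stop("cross_validate: every subject needs >= 2 sessions (",
         paste(names(counts)[counts < 2L], collapse = ", "), ")")
  subjects <- sort(unique(tab$subject))
  intra <- inter <- numeric(0)
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    rest <- structure(list(sessions = tab[-i, , drop = FALSE], fit = NULL),
                      class = "profile_db")
    rest$fit <- fit_profile_db(rest$sessions)
    ranked <- predict.profile_db(
      rest, list(n_peaks = tab$n_peaks[i], sharpness = tab$sharpness[i]),
      k = length(subjects))
    truth <- tab$subject[i]
    intra <- c(intra, ranked$distance[ranked$subject == truth])
    inter <- c(inter, ranked$distance[ranked$subject != truth])
    rows[[i]] <- data.frame(subject = truth, session = tab$session[i],
                            predicted = ranked$subject[1],
                            distance = ranked$distance[1],
                            correct = ranked$subject[1] == truth,
                            stringsAsFactors = FALSE)
  }
  details <- do.call(rbind, rows)
  confusion <- table(truth = factor(details$subject, subjects),
                     predicted = factor(details$predicted, subjects))
  structure(list(accuracy = mean(details$correct),
                 confusion = confusion,
                 median_intra = stats::median(intra),
                 median_inter = stats::median(inter),
                 details = details),
            class = "piezoid_cv")
}

#' @export
print.piezoid_cv <- function(x, ...) {
  cat(sprintf("<piezoid_cv> leave-one-session-out top-1 accuracy: %.3f (%d/%d)\n",
              x$accuracy, sum(x$details$correct), nrow(x$details)))
  cat(sprintf("  median distance: intra-subject %.3g, inter-subject %.3g\n",
              x$median_intra, x$median_inter))
  invisible(x)
}

#' @export
summary.profile_db <- function(object, ...) {
  print(object)
  if (nrow(object$sessions)) {
    agg <- stats::aggregate(cbind(n_peaks, sharpness) ~ subject,
                            object$sessions, mean)
    cat("  per-subject mean features:\n")
    print(agg, row.names = FALSE)
  }
  invisible(object)
}

#' Feature-plane scatter of an enrollment database
#'
#' Plots sharpness against the number of peak shapes for every enrolled
#' session, one color per subject, with the shared regression line.
#'
#' @param x a [profile_db()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.profile_db <- function(x, ...) {
  tab <- x$sessions
  if (nrow(tab) == 0L) stop("plot: empty database")
  subjects <- sort(unique(tab$subject))
  cols <- grDevices::hcl.colors(max(3L, length(subjects)), "Dark 3")
  graphics::plot(tab$n_peaks, tab$sharpness,
                 col = cols[match(tab$subject, subjects)], pch = 19,
                 xlab = "number of peak shapes", ylab = "sharpness", ...)
  if (!is.null(x$fit$coefficients))
    graphics::abline(x$fit$coefficients["intercept"],
                     x$fit$coefficients["slope"], lty = 2)
  graphics::legend("topright", legend = subjects, col = cols[seq_along(subjects)],
                   pch = 19, cex = 0.8, bty = "n")
  invisible(x)
}

#' Save / load a profile database as JSON
#'
#' Schema: `{subjects: {id: {sessions: {sid: {n_peaks, sharpness}}}},
#' fitted: {slope, intercept, means, stds}}`. The regression and scaler are
#' refitted on load, so the stored `fitted` block is informative only.
#'
#' @param db a [profile_db()].
#' @param path JSON file path.
#' @return `write_profile_db`: `path` invisibly; `read_profile_db`: a
#'   `profile_db`.
#' @export
write_profile_db <- function(db, path) {
  stopifnot(inherits(db, "profile_db"))
  subjects <- list()
  for (i in seq_len(nrow(db$sessions))) {
    s <- db$sessions$subject[i]
    subjects[[s]]$sessions[[db$sessions$session[i]]] <-
      list(n_peaks = db$sessions$n_peaks[i],
           sharpness = db$sessions$sharpness[i])
  }
  fitted <- if (is.null(db$fit$coefficients)) NULL else list(
    slope = unname(db$fit$coefficients["slope"]),
    intercept = unname(db$fit$coefficients["intercept"]),
    means = as.list(db$fit$scaler$mean),
    stds = as.list(db$fit$scaler$sd))
  jsonlite::write_json(list(subjects = subjects, fitted = fitted), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_profile_db
#' @export
read_profile_db <- function(path) {
  doc <- jsonlite::read_json(path)
  db <- profile_db()
  for (s in names(doc$subjects))
    for (sid in names(doc$subjects[[s]]$sessions)) {
      f <- doc$subjects[[s]]$sessions[[sid]]
      db <- enroll(db, s, sid, list(n_peaks = f$n_peaks,
                                    sharpness = f$sharpness))
    }
  db
}
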