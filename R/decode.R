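# Stepping-direction decoding from the estimated GRF: the centre-of-mass
# motion is initiated by the GRF change, so the early phase of the
# estimated horizontal force already carries the step direction.

#' Detect step onsets in a wrench stream
#'
#' An onset is declared where the horizontal force magnitude
#' `sqrt(Fx^2 + Fy^2)` crosses a threshold (a fraction of body weight,
#' default 5%) after having stayed below it for at least `quiet_s`
#' seconds, with a refractory period between detections.
#'
#' @param wrench Tibble with `time`, `Fx`, `Fy` (and `Fz`) at a uniform
#'   rate, typically an estimated wrench at 74.074 Hz.
#' @param body_weight_n Body weight in N used to scale the threshold;
#'   defaults to the median `Fz` of the stream.
#' @param threshold_frac Threshold as a fraction of body weight
#'   (default 0.05; must be > 0).
#' @param quiet_s Minimum sub-threshold time before an onset (default 0.5).
#' @param refractory_s Dead time after each onset (default 1).
#' @return Numeric vector of onset times (s).
#' @export
detect_step_onsets <- function(wrench, body_weight_n = NULL,
                               threshold_frac = 0.05, quiet_s = 0.5,
                               refractory_s = 1) {
  if (threshold_frac <= 0) {
    abort("threshold_frac must be positive (a zero threshold is degenerate).")
  }
  if (is.null(body_weight_n)) body_weight_n <- median(wrench$Fz)
  if (!is.finite(body_weight_n) || body_weight_n <= 0) {
    abort("Could not determine a positive body weight for the onset threshold.")
  }
  fs <- 1 / median(diff(wrench$time))
  mag <- sqrt(wrench$Fx^2 + wrench$Fy^2)
  thr <- threshold_frac * body_weight_n
  below <- mag < thr
  need_quiet <- round(quiet_s * fs)
  refractory <- round(refractory_s * fs)
  onsets <- numeric(0)
  quiet_run <- 0
  i <- 1
  n <- length(mag)
  while (i <= n) {
    if (below[i]) {
      quiet_run <- quiet_run + 1
    } else {
      if (quiet_run >= need_quiet) {
        onsets <- c(onsets, wrench$time[i])
        i <- i + refractory
        quiet_run <- 0
        next
      }
      quiet_run <- 0
    }
    i <- i + 1
  }
  onsets
}

#' Feature vector for a step episode
#'
#' Summarizes the first `window_s` seconds of the estimated GRF after an
#' onset: for each of Fx, Fy, Fz, the mean and slope over the early and
#' late halves of the window (3 channels x 2 statistics x 2 half-windows
#' = 12 features).
#'
#' @param wrench Wrench tibble (`time`, `Fx`, `Fy`, `Fz`).
#' @param onsets Onset times from [detect_step_onsets()].
#' @param window_s Early-phase window length in seconds (default 0.2).
#' @return Tibble with `onset` and 12 feature columns; episodes whose
#'   window exceeds the stream are skipped with a warning.
#' @export
featurize_episodes <- function(wrench, onsets, window_s = 0.2) {
  fs <- 1 / median(diff(wrench$time))
  half <- max(round(window_s * fs / 2), 2)
  slope <- function(y) {
    tt <- seq_along(y) / fs
    unname(coef(stats::lm.fit(cbind(1, tt), y))[2])
  }
  rows <- purrr::map(onsets, function(on) {
    i0 <- which.min(abs(wrench$time - on))
    idx <- i0:(i0 + 2 * half - 1)
    if (max(idx) > nrow(wrench)) {
      warn(sprintf("Skipping episode at %.2f s: window truncated.", on))
      return(NULL)
    }
    feats <- unlist(lapply(c("Fx", "Fy", "Fz"), function(ch) {
      y <- wrench[[ch]][idx] - wrench[[ch]][i0]
      e <- y[seq_len(half)]
      l <- y[(half + 1):(2 * half)]
      stats::setNames(
        c(mean(e), slope(e), mean(l), slope(l)),
        paste0(ch, c("_mean_early", "_slope_early", "_mean_late",
                     "_slope_late"))
      )
    }))
    dplyr::bind_cols(tibble::tibble(onset = on), tibble::as_tibble(as.list(feats)))
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Match detected onsets to ground-truth step events
#'
#' @param onsets Onset times.
#' @param step_events Ground-truth tibble (`time`, `direction`).
#' @param tol_s Matching tolerance (default 0.3 s).
#' @return Character vector of directions (NA where unmatched).
#' @export
label_episodes <- function(onsets, step_events, tol_s = 0.3) {
  vapply(onsets, function(on) {
    d <- abs(step_events$time - on)
    if (length(d) == 0 || min(d) > tol_s) NA_character_
    else step_events$direction[which.min(d)]
  }, character(1))
}

#' Fit the stepping-direction decoder
#'
#' A linear maximum-margin classifier (support vector machine) in
#' one-vs-rest configuration over standardized episode features. Simple
#' by design: the decision is a linear function of the early-phase force
#' summary.
#'
#' @param features Feature tibble from [featurize_episodes()] (the
#'   `onset` column, if present, is dropped).
#' @param labels Character/factor vector: `"left"`, `"right"`,
#'   `"forward"`.
#' @param cost SVM cost parameter (default 10).
#' @return A `grf_decoder`.
#' @export
fit_decoder <- function(features, labels, cost = 10) {
  X <- as.matrix(features[, setdiff(names(features), "onset"), drop = FALSE])
  labels <- as.character(labels)
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort("Need at least two classes to fit the direction decoder.")
  }
  if (any(table(labels) < 3)) {
    warn("Fewer than 3 episodes in some class; decoder may be unstable.")
  }
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  machines <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, cl, "rest"), levels = c(cl, "rest"))
    e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE,
               probability = FALSE)
  })
  names(machines) <- classes
  structure(
    list(machines = machines, classes = classes, mu = mu, sg = sg,
         feature_names = colnames(X), cost = cost),
    class = "grf_decoder"
  )
}

#' Predict step directions from episode features
#'
#' One-vs-rest decision: each class's machine scores the episode and the
#' class with the largest signed margin wins. Deterministic given the
#' fitted model.
#'
#' @param object A `grf_decoder`.
#' @param features Feature tibble or matrix (same columns as at fit
#'   time).
#' @param ... Unused.
#' @return Character vector of predicted directions.
#' @export
predict.grf_decoder <- function(object, features, ...) {
  X <- as.matrix(features[, object$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sg, "/")
  scores <- vapply(object$classes, function(cl) {
    dv <- attr(predict(object$machines[[cl]], Xs, decision.values = TRUE),
               "decision.values")
    s <- dv[, 1]
    # e1071 orients the decision value toward the first factor level
    # (the class itself), but verify via the column name
    if (!grepl(paste0("^", cl, "/"), colnames(dv)[1])) s <- -s
    s
  }, numeric(nrow(Xs)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Decode step directions from an estimated wrench
#'
#' Convenience wrapper: detect onsets, featurize the early windows and
#' predict each episode's direction.
#'
#' @param wrench Estimated wrench tibble.
#' @param decoder A fitted `grf_decoder`.
#' @param window_s Early-phase window (default 0.2 s).
#' @param ... Passed to [detect_step_onsets()].
#' @return Tibble with `onset` and predicted `direction`.
#' @export
decode_directions <- function(wrench, decoder, window_s = 0.2, ...) {
  onsets <- detect_step_onsets(wrench, ...)
  feats <- featurize_episodes(wrench, onsets, window_s = window_s)
  if (nrow(feats) == 0) {
    return(tibble::tibble(onset = numeric(0), direction = character(0)))
  }
  tibble::tibble(onset = feats$onset,
                 direction = predict(decoder, feats))
}
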