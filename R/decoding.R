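#' Define a binary condition contrast
#'
#' A contrast names the two condition cells to discriminate, e.g. -90 deg
#' versus 0 deg at 58 dB.  `NULL` fields match any value, so intensity
#' contrasts fix the location and leave `location_deg = NULL` per class
#' unused.
#'
#' @param location_a,location_b sound-source azimuth of each class
#'   (degrees) or `NULL` for any.
#' @param intensity_a,intensity_b level of each class (dB SPL) or `NULL`.
#' @param label optional printable name.
#' @return Object of class `contrast_spec`.
#' @examples
#' contrast_spec(-90, 0, 58, 58)        # lateral vs front at high level
#' contrast_spec(-90, -90, 48, 58)      # sound level at -90 deg
#' @export
contrast_spec <- function(location_a = NULL, location_b = NULL,
                          intensity_a = NULL, intensity_b = NULL,
                          label = NULL) {
  if (is.null(label)) {
    fmt <- function(l, i) paste0(if (is.null(l)) "any" else l, "deg@",
                                 if (is.null(i)) "any" else i, "dB")
    label <- paste(fmt(location_a, intensity_a), "vs",
                   fmt(location_b, intensity_b))
  }
  structure(list(location_a = location_a, location_b = location_b,
                 intensity_a = intensity_a, intensity_b = intensity_b,
                 label = label),
            class = "contrast_spec")
}

match_class <- function(labels, location, intensity) {
  ok <- rep(TRUE, nrow(labels))
  if (!is.null(location)) ok <- ok & labels$location_deg == location
  if (!is.null(intensity)) ok <- ok & labels$intensity_db == intensity
  ok
}

contrast_classes <- function(labels, contrast) {
  a <- match_class(labels, contrast$location_a, contrast$intensity_a)
  b <- match_class(labels, contrast$location_b, contrast$intensity_b)
  if (any(a & b)) stop("contrast classes must be disjoint")
  if (!any(a) || !any(b)) {
    stop("contrast '", contrast$label, "' selects an empty class")
  }
  if (sum(a) != sum(b)) {
    warning("contrast '", contrast$label, "' is imbalanced (",
            sum(a), " vs ", sum(b), " trials)")
  }
  list(a = which(a), b = which(b))
}

#' Fisher scores for binary class separability
#'
#' For each feature k, `FS_k = (mu1 - mu2)^2 / (var1 + var2)` with
#' class-wise means and within-class sample variances.  A feature whose
#' class variances are both zero scores `+Inf` when the means differ (a
#' perfectly separating feature outranks all others) and `0` when they do
#' not.
#'
#' @param values trials x features numeric matrix.
#' @param classes two-level factor (or vector coercible to one) with one
#'   entry per trial.
#' @return Numeric vector of non-negative scores, one per feature.
#' @export
fisher_scores <- function(values, classes) {
  classes <- factor(classes)
  if (nlevels(classes) != 2L) {
    stop("fisher_scores needs exactly two classes, got ", nlevels(classes))
  }
  g1 <- classes == levels(classes)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 1L || n2 < 1L) stop("both classes must be non-empty")
  x1 <- values[g1, , drop = FALSE]
  x2 <- values[!g1, , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  v1 <- if (n1 > 1L) colSums(sweep(x1, 2L, mu1)^2) / (n1 - 1L) else 0 * mu1
  v2 <- if (n2 > 1L) colSums(sweep(x2, 2L, mu2)^2) / (n2 - 1L) else 0 * mu2
  num <- (mu1 - mu2)^2
  den <- v1 + v2
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
}

#' Select the top-scoring features
#'
#' Returns the indices of the `dim` highest Fisher scores; ties are broken
#' by feature (descriptor) order for determinism.
#'
#' @param scores numeric score vector.
#' @param dim number of features to keep (1 to `length(scores)`).
#' @return Integer indices, highest score first.
#' @export
select_top <- function(scores, dim) {
  if (length(dim) != 1L || is.na(dim) || dim < 1L) {
    stop("dim must be a positive integer")
  }
  if (dim > length(scores)) {
    stop("dim (", dim, ") exceeds the number of features (",
         length(scores), ")")
  }
  order(-scores, seq_along(scores))[seq_len(dim)]
}

#' Leave-one-out linear-SVM decoding over feature-set dimensions
#'
#' The decoding engine: for every left-out observation, Fisher scores and
#' standardization statistics are computed on the remaining observations
#' only (no information leakage), the top-`dim` features are selected and
#' a linear maximum-margin classifier (cost `C`) predicts the held-out
#' trial.  Accuracy per dimension is the fraction of correct predictions
#' over all folds — necessarily a multiple of 1/n.  The best dimension
#' maximizes accuracy, smallest dimension on ties.
#'
#' `selection = "global"` reproduces the literal alternative in which the
#' ranking is computed once on all observations; it is optimistically
#' biased and provided for comparison only.
#'
#' @param ft a `nirs_features` (already restricted to the contrast's
#'   trials; see [decode_contrast()]).
#' @param classes two-level factor, one entry per trial.
#' @param dims candidate feature-set sizes (default 1:20).
#' @param C regularization parameter of the linear SVM (default 1).
#' @param selection `"per_fold"` (default) or `"global"`.
#' @return Object of class `decoding_result`: `per_dim_accuracy` (named
#'   vector), `best_dim`, `best_accuracy`, `mean_dim_accuracy`,
#'   `selection_counts` (descriptor counts over folds at the best
#'   dimension), `fold_predictions` (n x dims matrix).
#' @export
loocv_svm <- function(ft, classes, dims = 1:20, C = 1,
                      selection = c("per_fold", "global")) {
  stopifnot(inherits(ft, "nirs_features"))
  selection <- match.arg(selection)
  classes <- factor(classes)
  if (nlevels(classes) != 2L) stop("decoding needs exactly two classes")
  if (min(table(classes)) < 2L) {
    stop("each class needs at least 2 observations for LOOCV")
  }
  X <- ft$values
  n <- nrow(X)
  if (length(classes) != n) stop("one class label per trial required")
  dims <- sort(unique(as.integer(dims)))
  maxdim <- min(max(dims), ncol(X))
  dims <- dims[dims <= maxdim]
  global_ord <- if (selection == "global") {
    select_top(fisher_scores(X, classes), maxdim)
  }
  pred <- matrix(NA_character_, nrow = n, ncol = length(dims),
                 dimnames = list(NULL, dims))
  sel_per_fold <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- if (selection == "per_fold") {
      select_top(fisher_scores(X[tr, , drop = FALSE], classes[tr]), maxdim)
    } else {
      global_ord
    }
    mu <- colMeans(X[tr, sel, drop = FALSE])
    sdv <- apply(X[tr, sel, drop = FALSE], 2L, sd)
    scale1 <- function(m) {
      z <- sweep(m, 2L, mu)
      ok <- sdv > 0
      z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, sdv[ok], "/")
      z[, !ok] <- 0
      z
    }
    Xtr <- scale1(X[tr, sel, drop = FALSE])
    Xte <- scale1(X[i, sel, drop = FALSE])
    for (j in seq_along(dims)) {
      d <- dims[j]
      fit <- e1071::svm(Xtr[, seq_len(d), drop = FALSE], classes[tr],
                        kernel = "linear", cost = C, scale = FALSE)
      pred[i, j] <- as.character(predict(fit, Xte[, seq_len(d),
                                                  drop = FALSE]))
    }
    sel_per_fold[[i]] <- sel
  }
  acc <- colMeans(pred == as.character(classes))
  best_j <- which.max(acc)            # first max = smallest dim
  best_dim <- dims[best_j]
  sel_best <- unlist(lapply(sel_per_fold, function(s) s[seq_len(best_dim)]))
  desc <- with(ft$info, paste0("u", unit, ":", start_s, "-", end_s, "s:",
                               stat))
  counts <- sort(table(desc[sel_best]), decreasing = TRUE)
  structure(list(per_dim_accuracy = stats::setNames(acc, dims),
                 best_dim = best_dim,
                 best_accuracy = unname(acc[best_j]),
                 mean_dim_accuracy = mean(acc),
                 selection_counts = counts,
                 fold_predictions = pred,
                 classes = classes,
                 n_obs = n, C = C, selection = selection),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> n=%d, best accuracy %.2f%% at dim %d (selection: %s)\n",
              x$n_obs, 100 * x$best_accuracy, x$best_dim, x$selection))
  cat("  top selected features:",
      paste(utils::head(names(x$selection_counts), 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Decode one condition contrast from a feature table
#'
#' Subsets the trials matched by the contrast predicates and runs
#' [loocv_svm()].
#'
#' @param ft a `nirs_features` for a whole session.
#' @param contrast a [contrast_spec()].
#' @inheritParams loocv_svm
#' @return A `decoding_result` (with the contrast label attached).
#' @export
decode_contrast <- function(ft, contrast, dims = 1:20, C = 1,
                            selection = "per_fold") {
  stopifnot(inherits(contrast, "contrast_spec"))
  cls <- contrast_classes(ft$labels, contrast)
  idx <- c(cls$a, cls$b)
  sub <- subset_features(ft, trials = idx)
  classes <- factor(rep(c("a", "b"), c(length(cls$a), length(cls$b))))
  res <- loocv_svm(sub, classes, dims = dims, C = C, selection = selection)
  res$contrast <- contrast$label
  res
}

#' Reduce symmetric ROI pairs to one hemisphere relative to the source
#'
#' For the interhemispheric analysis of -90 vs +90 deg stimuli the ten
#' ROIs collapse to the five mirror pairs (premotor 1/6, supramarginal
#' 2/7, dlPFC 3/8, STG 4/9, auditory association 5/10); for each trial the
#' member on the requested side relative to the sound source is kept:
#' ipsilateral means the left ROI for -90 deg and the right ROI for
#' +90 deg, contralateral the opposite.
#'
#' @param epochs ROI-level `nirs_epochs` containing only -90/+90 deg
#'   trials.
#' @param side `"ipsi"` or `"contra"`.
#' @return `nirs_epochs` with 5 units (`unit_kind = "roi_pair"`).
#' @export
pair_hemispheres <- function(epochs, side = c("ipsi", "contra")) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  side <- match.arg(side)
  if (epochs$unit_kind != "roi") {
    stop("pair_hemispheres expects an ROI-level trial tensor")
  }
  loc <- epochs$labels$location_deg
  if (!all(loc %in% c(-90L, 90L))) {
    stop("interhemispheric pairing is defined for -90/+90 deg trials only")
  }
  pairs <- hemisphere_pairs()
  d <- dim(epochs$data)
  out <- array(NA_real_, dim = c(d[1], nrow(pairs), d[3]))
  for (k in seq_len(d[1])) {
    left_wanted <- (side == "ipsi") == (loc[k] == -90L)
    take <- if (left_wanted) pairs$left_roi else pairs$right_roi
    out[k, , ] <- epochs$data[k, match(take, epochs$unit_ids), ]
  }
  epochs$data <- out
  epochs$unit_kind <- "roi_pair"
  epochs$unit_ids <- pairs$pair
  epochs
}

#' Per-ROI sound-level decoding at a fixed location
#'
#' Decodes 48 vs 58 dB trials of one sound-source location separately for
#' each ROI, using only that ROI's 70 candidate features (14 windows x 5
#' statistics).
#'
#' @param ft ROI-level `nirs_features` for a session containing both
#'   levels at `location`.
#' @param location fixed azimuth in degrees.
#' @inheritParams loocv_svm
#' @return List with `per_roi` (named list of `decoding_result`),
#'   `best_accuracy` (named vector per ROI), `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
sound_level_decoding <- function(ft, location, dims = 1:20, C = 1,
                                 selection = "per_fold") {
  stopifnot(inherits(ft, "nirs_features"))
  if (ft$unit_kind != "roi") {
    stop("sound_level_decoding expects ROI-level features")
  }
  keep <- ft$labels$location_deg == location
  if (!any(keep)) stop("no trials at location ", location)
  sub <- subset_features(ft, trials = which(keep))
  lev <- sub$labels$intensity_db
  if (length(unique(lev)) < 2L) {
    stop("both intensity classes must be present at ", location, " deg")
  }
  rois <- sort(unique(sub$info$unit))
  per_roi <- lapply(rois, function(r) {
    cols <- which(sub$info$unit == r)
    loocv_svm(subset_features(sub, columns = cols), factor(lev),
              dims = dims, C = C, selection = selection)
  })
  names(per_roi) <- paste0("roi", rois)
  best <- vapply(per_roi, `[[`, numeric(1), "best_accuracy")
  list(per_roi = per_roi, best_accuracy = best,
       mean_accuracy = mean(best), sd_accuracy = sd(best))
}

#' Summarize per-subject decoding accuracies against a margin
#'
#' @param accuracies numeric vector of per-subject accuracies, either
#'   proportions in \[0, 1\] or percentages.
#' @param threshold practical-significance margin (default 0.70; the same
#'   scale as `accuracies` is inferred).  Subjects at exactly the margin
#'   count as reaching it.
#' @return List: `mean_pct` (mean accuracy in percent, 2 decimals,
#'   half-up), `n_at_or_above` (count of subjects >= threshold),
#'   `n_total`.
#' @export
summarize_accuracies <- function(accuracies, threshold = 0.70) {
  if (!length(accuracies)) stop("no accuracies supplied")
  pct <- if (max(accuracies) <= 1) 100 * accuracies else accuracies
  thr_pct <- if (threshold <= 1) 100 * threshold else threshold
  list(mean_pct = round_half_up(mean(pct), 2),
       n_at_or_above = sum(pct >= thr_pct - 1e-9),
       n_total = length(pct))
}

#' Compare accuracy distributions between conditions
#'
#' One-way ANOVA across independent groups or a paired two-sided Wilcoxon
#' signed-rank test.  All-zero paired differences return p = 1 by
#' convention (no evidence of any shift).
#'
#' @param acc_a,acc_b numeric vectors (paired and equal length for
#'   `"wilcoxon_signed_rank"`).
#' @param test `"anova_oneway"` or `"wilcoxon_signed_rank"`.
#' @return List with `statistic` and `p_value`.
#' @export
compare_conditions <- function(acc_a, acc_b,
                               test = c("anova_oneway",
                                        "wilcoxon_signed_rank")) {
  test <- match.arg(test)
  if (test == "anova_oneway") {
    x <- c(acc_a, acc_b)
    g <- factor(rep(c("a", "b"), c(length(acc_a), length(acc_b))))
    fit <- oneway.test(x ~ g, var.equal = TRUE)
    list(statistic = unname(fit$statistic), p_value = fit$p.value)
  } else {
    if (length(acc_a) != length(acc_b)) {
      stop("paired test needs vectors of equal length")
    }
    d <- acc_a - acc_b
    if (all(d == 0)) return(list(statistic = 0, p_value = 1))
    fit <- suppressWarnings(wilcox.test(acc_a, acc_b, paired = TRUE,
                                        exact = FALSE))
    list(statistic = unname(fit$statistic), p_value = fit$p.value)
  }
}
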