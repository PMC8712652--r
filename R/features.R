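#' The 14-window analysis grid
#'
#' Candidate feature windows within the 10-s epoch, chosen because
#' task-related hemodynamic responses appear with a 3-8 s delay: seven 2-s
#' windows (2-4 ... 8-10 s), four 3-s windows (4-7 ... 7-10 s) and three
#' 4-s windows (4-8, 5-9, 6-10 s).
#'
#' @return Data frame with columns `start_s`, `end_s` (14 rows).
#' @export
window_grid <- function() {
  data.frame(
    start_s = c(2, 3, 4, 5, 6, 7, 8, 4, 5, 6, 7, 4, 5, 6),
    end_s   = c(4, 5, 6, 7, 8, 9, 10, 7, 8, 9, 10, 8, 9, 10)
  )
}

feature_stats <- c("mean", "variance", "skewness", "kurtosis", "slope")

#' Extract windowed temporal features from a trial tensor
#'
#' For every trial, unit (channel or ROI) and analysis window, computes
#' five temporal statistics of the oxy-Hb segment: arithmetic mean, sample
#' variance (n-1), moment skewness (m3/m2^1.5), excess kurtosis
#' (m4/m2^2 - 3) and the least-squares slope against time in seconds.
#' Zero-variance segments take skewness and kurtosis 0 by convention.
#' Feature columns are ordered deterministically: unit, then window, then
#' statistic.
#'
#' @param epochs a `nirs_epochs` ([segment()] / [roi_average()]).
#' @param grid window table ([window_grid()]); each window must contain at
#'   least 3 samples.
#' @return Object of class `nirs_features`: `values` (trials x features
#'   matrix), `info` (per-feature descriptor: unit, start_s, end_s, stat),
#'   `labels` (per-trial conditions), `unit_kind`.
#' @export
extract_features <- function(epochs, grid = window_grid()) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  d <- dim(epochs$data)
  nt <- d[1]; nu <- d[2]; ns <- d[3]
  fs <- epochs$fs_hz
  nw <- nrow(grid)
  nstat <- length(feature_stats)
  values <- matrix(NA_real_, nrow = nt, ncol = nu * nw * nstat)
  info <- data.frame(unit = rep(epochs$unit_ids, each = nw * nstat),
                     start_s = rep(rep(grid$start_s, each = nstat), nu),
                     end_s = rep(rep(grid$end_s, each = nstat), nu),
                     stat = rep(feature_stats, nu * nw),
                     stringsAsFactors = FALSE)
  for (w in seq_len(nw)) {
    i0 <- sample_index(grid$start_s[w], fs)
    i1 <- sample_index(grid$end_s[w], fs)
    if (i1 > ns) stop("window ", grid$start_s[w], "-", grid$end_s[w],
                      " s exceeds the epoch")
    idx <- (i0 + 1L):i1               # half-open [start, end)
    len <- length(idx)
    if (len < 3L) stop("window with fewer than 3 samples: higher moments undefined")
    slab <- epochs$data[, , idx, drop = FALSE]
    mat <- matrix(slab, nrow = nt * nu, ncol = len)  # trial-fastest rows
    mu <- rowMeans(mat)
    xc <- mat - mu
    m2 <- rowMeans(xc^2)
    m3 <- rowMeans(xc^3)
    m4 <- rowMeans(xc^4)
    vv <- m2 * len / (len - 1)
    sk <- ifelse(m2 > 0, m3 / m2^1.5, 0)
    ku <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
    tsec <- (idx - 1) / fs
    tc <- tsec - mean(tsec)
    sl <- as.numeric(xc %*% tc) / sum(tc^2)
    stat_vals <- cbind(mu, vv, sk, ku, sl)
    for (u in seq_len(nu)) {
      cols <- ((u - 1L) * nw + (w - 1L)) * nstat + seq_len(nstat)
      rows <- (u - 1L) * nt + seq_len(nt)
      values[, cols] <- stat_vals[rows, , drop = FALSE]
    }
  }
  structure(list(values = values, info = info, labels = epochs$labels,
                 unit_kind = epochs$unit_kind),
            class = "nirs_features")
}

#' @export
print.nirs_features <- function(x, ...) {
  cat(sprintf("<nirs_features> %d trials x %d features (%d %ss x %d windows x %d stats)\n",
              nrow(x$values), ncol(x$values), length(unique(x$info$unit)),
              x$unit_kind, nrow(unique(x$info[, c("start_s", "end_s")])),
              length(unique(x$info$stat))))
  invisible(x)
}

#' Standardize features using statistics from a trial subset
#'
#' Centers and scales each feature by the mean and standard deviation
#' computed on `stats_from` only (the training fold in cross-validation),
#' applying them to all trials.  Features with zero variance on the subset
#' are mapped to all-zero columns.
#'
#' @param ft a `nirs_features`.
#' @param stats_from integer indices of the trials supplying mean/sd
#'   (default: all trials).
#' @return The standardized `nirs_features`.
#' @export
standardize <- function(ft, stats_from = seq_len(nrow(ft$values))) {
  stopifnot(inherits(ft, "nirs_features"), length(stats_from) >= 1)
  sub <- ft$values[stats_from, , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2L, sd)
  z <- sweep(ft$values, 2L, mu)
  ok <- sdv > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, sdv[ok], "/")
  z[, !ok] <- 0
  ft$values <- z
  ft
}

subset_features <- function(ft, trials = NULL, columns = NULL) {
  if (!is.null(trials)) {
    ft$values <- ft$values[trials, , drop = FALSE]
    ft$labels <- ft$labels[trials, , drop = FALSE]
    rownames(ft$labels) <- NULL
  }
  if (!is.null(columns)) {
    ft$values <- ft$values[, columns, drop = FALSE]
    ft$info <- ft$info[columns, , drop = FALSE]
    rownames(ft$info) <- NULL
  }
  ft
}
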