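# max |cluster mass| per row of a t matrix given a threshold; clusters
# are runs of contiguous supra-threshold lags of the same sign, mass =
# sum of t inside the run.
row_max_cluster_mass <- function(Tm, thr) {
  apply(Tm, 1, function(tv) {
    lab <- integer(length(tv))
    lab[tv > thr] <- 1L
    lab[tv < -thr] <- -1L
    if (!any(lab != 0L)) return(0)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mx <- 0
    for (i in which(r$values != 0L)) {
      m <- abs(sum(tv[starts[i]:ends[i]]))
      if (m > mx) mx <- m
    }
    mx
  })
}

# clusters of one t vector: data.frame(start, end (indices), mass)
find_clusters <- function(tv, thr) {
  lab <- integer(length(tv))
  lab[tv > thr] <- 1L
  lab[tv < -thr] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(i) sum(tv[starts[i]:ends[i]]),
                           numeric(1)))
}

#' Cluster-based permutation test on response time courses
#'
#' Nonparametric test of a subjects-by-lags matrix against zero
#' (one-sample) or of two such matrices against each other (paired).
#' Per-lag t statistics are thresholded at the two-sided `alpha_cluster`
#' critical value (df = n - 1); contiguous supra-threshold lags of equal
#' sign form clusters whose mass is the summed t. The null distribution
#' of the maximum absolute cluster mass is built from random sign flips
#' of the subject data (equivalently, condition-label swaps in the
#' paired case), and each observed cluster receives
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param data numeric matrix, subjects x lags.
#' @param data2 optional second matrix for a paired test (same shape);
#'   the test is then run on `data - data2` with sign-flip permutations.
#' @param alpha_cluster cluster-forming threshold as a two-sided per-lag
#'   p-value (default 0.05).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; results are reproducible given
#'   `(seed, n_perm)`.
#' @param lags optional lag axis in seconds for reporting.
#' @return an object of class `cluster_result`: data.frame `clusters`
#'   with lag bounds, mass and p-value; plus test metadata.
#' @export
cluster_permutation_test <- function(data, data2 = NULL,
                                     alpha_cluster = 0.05, n_perm = 1000,
                                     seed = 1L, lags = NULL) {
  data <- as.matrix(data)
  test <- "one_sample"
  if (!is.null(data2)) {
    data2 <- as.matrix(data2)
    if (!all(dim(data) == dim(data2)))
      stop("cluster_permutation_test: paired matrices must have equal shape")
    data <- data - data2
    test <- "paired"
  }
  n <- nrow(data); L <- ncol(data)
  if (n < 5) stop("cluster_permutation_test: need at least 5 subjects")
  if (is.null(lags)) lags <- seq_len(L)
  thr <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  eps <- 1e-12

  col_ss <- colSums(data^2)
  t_from_means <- function(M) {
    # M: perms x lags matrix of means of sign-flipped data
    v <- sweep(-M^2, 2, col_ss / n, `+`) * n / (n - 1)  # per-perm column var
    v[v < eps] <- eps
    M / sqrt(v / n)
  }
  t_obs <- drop(t_from_means(matrix(colMeans(data), nrow = 1)))
  cl <- find_clusters(t_obs, thr)

  signs <- with_seed(seed,
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm))
  null_mass <- row_max_cluster_mass(t_from_means((signs %*% data) / n), thr)

  p <- vapply(cl$mass, function(m)
    (1 + sum(null_mass >= abs(m))) / (1 + n_perm), numeric(1))
  clusters <- data.frame(lag_start = lags[cl$start], lag_end = lags[cl$end],
                         mass = cl$mass, p_value = p)
  clusters <- clusters[order(clusters$lag_start), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, t = t_obs, lags = lags,
                 threshold = thr, test = test, n_subjects = n,
                 n_permutations = n_perm, seed = seed,
                 null_max_mass = null_mass),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s test, %d subjects, %d permutations (seed %d)\n",
              x$test, x$n_subjects, x$n_permutations, x$seed))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Median split of event responses by tonic pupil size
#'
#' Partitions events of the types in `split_types` at the median of
#' their tonic values (ties assigned to the low side) and deconvolves
#' each partition separately, keeping the full nuisance design: each
#' side's design contains its half of the split events plus all events
#' of every other type. When all tonic values are equal the split falls
#' back to event-order parity and is flagged degenerate. Window-mean
#' amplitudes of the split types are reported for the caller-supplied
#' lag window.
#'
#' @param phasic [pupil_ts()] at the analysis rate.
#' @param events full [event_table()] (split + nuisance types).
#' @param tonic_values numeric vector of per-event tonic z-scores,
#'   aligned row-by-row with `events[events$type %in% split_types, ]`.
#' @param split_types event types to split (default the sound types).
#' @param window kernel window passed to [build_design_matrix()].
#' @param rate analysis rate in Hz.
#' @param amplitude_window lag window (seconds) over which mean response
#'   amplitudes are computed (default `c(1, 3)`, around the auditory
#'   response peak).
#' @return list with `low` and `high` (`fir_fit` objects, post-processed),
#'   `amplitude` (data.frame: side, type, mean response), `median`,
#'   `degenerate`.
#' @export
median_split_by_tonic <- function(phasic, events, tonic_values,
                                  split_types = c("sound_high", "sound_low"),
                                  window = c(-0.5, 5), rate = 10,
                                  amplitude_window = c(1, 3)) {
  split_ix <- which(events$type %in% split_types)
  stopifnot(length(split_ix) == length(tonic_values))
  if (length(split_ix) < 4)
    stop("median_split_by_tonic: need at least 2 events per side")
  degenerate <- FALSE
  if (stats::sd(tonic_values) == 0) {
    degenerate <- TRUE
    warning("median_split_by_tonic: all tonic values equal; ",
            "falling back to event-order parity split")
    low <- seq_along(tonic_values) %% 2 == 1
  } else {
    med <- stats::median(tonic_values)
    low <- tonic_values <= med              # ties to the low side
  }

  run_side <- function(keep_low) {
    keep <- if (keep_low) low else !low
    ev <- rbind(events[split_ix[keep], , drop = FALSE],
                events[-split_ix, , drop = FALSE])
    ev <- event_table(ev$time, ev$type, ev$duration, ev$amplitude, ev$run_id)
    types <- unique(c(split_types[split_types %in% ev$type],
                      setdiff(unique(events$type), split_types)))
    missing <- setdiff(split_types, ev$type)
    if (length(missing))
      warning("median_split_by_tonic: type(s) ",
              paste(missing, collapse = ", "),
              " empty in one partition; omitted")
    d <- build_design_matrix(ev, n_samples = length(phasic$samples),
                             rate = rate, window = window,
                             event_types = types)
    postprocess_kernels(fir_deconv(d, phasic))
  }
  fit_low <- run_side(TRUE)
  fit_high <- run_side(FALSE)

  amp_of <- function(fit, side) {
    sel <- fit$lags >= amplitude_window[1] & fit$lags < amplitude_window[2]
    tp <- intersect(split_types, colnames(fit$kernels))
    data.frame(side = side, type = tp,
               amplitude = colMeans(fit$kernels[sel, tp, drop = FALSE]),
               row.names = NULL)
  }
  list(low = fit_low, high = fit_high,
       amplitude = rbind(amp_of(fit_low, "low"), amp_of(fit_high, "high")),
       median = if (degenerate) NA_real_ else stats::median(tonic_values),
       degenerate = degenerate)
}
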