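#' Normalize transcription-rate time courses to time zero
#'
#' Each profile is expressed as log2(tr(t)/tr(0)), the scale on which
#' stress repression/induction heat maps are drawn. Profiles with any
#' missing timepoint, or with tr(0) == 0, are flagged incomplete and are
#' excluded from clustering (but retained, as missing, in the output).
#'
#' @param tr matrix genes x timepoints (from \code{\link{read_tr_table}})
#' @return list: \code{log2_ratio} matrix (NA rows for flagged genes),
#'   \code{complete} named logical vector
#' @export
normalize_tr <- function(tr) {
  stopifnot(is.matrix(tr), "0" %in% colnames(tr))
  complete <- apply(tr, 1L, function(x) all(is.finite(x))) & tr[, "0"] > 0
  lr <- log2(sweep(tr, 1L, tr[, "0"], "/"))
  lr[!complete, ] <- NA_real_
  list(log2_ratio = lr, complete = complete)
}

#' K-means clustering of normalized TR profiles
#'
#' Lloyd's algorithm with k-means++ seeding, best-of-restarts by total
#' within-cluster sum of squares (Euclidean distance on the log2-ratio
#' profiles). The run is deterministic for a given seed; a cluster that
#' empties during iteration is re-seeded at the point farthest from its
#' assigned centroid.
#'
#' @param profiles output of \code{\link{normalize_tr}}, or a numeric
#'   matrix of complete profiles
#' @param k number of clusters (3 reproduces the usual grouping of RP
#'   repression kinetics)
#' @param seed integer seed; identical seeds give bit-identical results
#' @param n_restarts independent initializations
#' @param max_iter Lloyd iteration cap per restart
#' @return object of class \code{cluster_result}: k, assignments (named
#'   integer), centroids (k x timepoints), inertia, seed, n_restarts
#' @export
kmeans_cluster <- function(profiles, k = 3L, seed = 1L,
                           n_restarts = 100L, max_iter = 100L) {
  m <- if (is.list(profiles) && !is.null(profiles$log2_ratio)) {
    profiles$log2_ratio[profiles$complete, , drop = FALSE]
  } else as.matrix(profiles)
  if (nrow(m) < k)
    stop("fewer complete profiles (", nrow(m), ") than clusters (", k, ")")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- .lloyd(m, k, max_iter)
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }
  structure(list(k = k,
                 assignments = setNames(best$assign, rownames(m)),
                 centroids = best$centroids, inertia = best$inertia,
                 seed = seed, n_restarts = n_restarts),
            class = "cluster_result")
}

#' @noRd
.kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(m, 2L, m[centers[1L], ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(m, 2L, m[centers[j], ], "-")^2))
  }
  m[centers, , drop = FALSE]
}

#' @noRd
.lloyd <- function(m, k, max_iter) {
  cen <- .kmeanspp_init(m, k)
  assign_prev <- rep(0L, nrow(m))
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j)
      rowSums(sweep(m, 2L, cen[j, ], "-")^2))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
    assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      idx <- which(assign == j)
      if (length(idx) == 0L) {
        # re-seed an empty cluster at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(nrow(m)), assign)])
        assign[far] <- j
        idx <- far
      }
      cen[j, ] <- colMeans(m[idx, , drop = FALSE])
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  d2 <- sapply(seq_len(k), function(j)
    rowSums(sweep(m, 2L, cen[j, ], "-")^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  inertia <- sum(d2[cbind(seq_len(nrow(m)), assign)])
  list(assign = assign, centroids = cen, inertia = inertia)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k=%d, n=%d, inertia=%.4g (seed %d, %d restarts)\n",
              x$k, length(x$assignments), x$inertia, x$seed, x$n_restarts))
  print(table(x$assignments))
  invisible(x)
}

#' Change in transcription rate at a timepoint
#'
#' dTR is defined as the log2 ratio of the transcription rate at time t
#' versus time 0, i.e. the normalized profile evaluated at t (15 min by
#' default). Genes flagged incomplete return NA.
#'
#' @param profiles output of \code{\link{normalize_tr}}
#' @param t timepoint in minutes
#' @return named numeric vector of dTR values
#' @export
delta_tr <- function(profiles, t = 15) {
  lr <- profiles$log2_ratio
  col <- as.character(t)
  if (!col %in% colnames(lr)) stop("timepoint ", t, " not in profiles")
  setNames(lr[, col], rownames(lr))
}

#' Regress PMi on dTR
#'
#' Ordinary least squares of PMi against the transcription-rate change,
#' with the coefficient of determination and a two-sided t-test of the
#' null hypothesis slope = 0 on n - 2 degrees of freedom. Used to ask
#' whether the drop in pre-mRNA levels merely tracks transcriptional
#' repression (a poor fit argues it does not).
#'
#' @param dtr named numeric vector of dTR values
#' @param pmi named numeric vector of PMi values (names matched to dtr)
#' @return object of class \code{pmi_tr_regression}: slope, intercept,
#'   r2, t_stat, p_value, df, n, n_dropped
#' @export
regress_pmi_vs_dtr <- function(dtr, pmi) {
  if (!is.null(names(dtr)) && !is.null(names(pmi))) {
    common <- intersect(names(dtr), names(pmi))
    dtr <- dtr[common]; pmi <- pmi[common]
  }
  stopifnot(length(dtr) == length(pmi))
  ok <- is.finite(dtr) & is.finite(pmi)
  n_dropped <- sum(!ok)
  x <- dtr[ok]; y <- pmi[ok]
  if (length(x) < 3L) stop("need >= 3 complete (dTR, PMi) pairs")
  if (var(x) == 0) stop("zero variance in dTR")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2L])
  df <- length(x) - 2L
  if (sm$sigma == 0) {
    # exact fit: conventionally t undefined; report slope-0 data as t=0,p=1
    t_stat <- if (slope == 0) 0 else Inf
    p <- if (slope == 0) 1 else 0
  } else {
    t_stat <- sm$coefficients[2L, "t value"]
    p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  }
  structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                 r2 = sm$r.squared, t_stat = t_stat, p_value = p,
                 df = df, n = length(x), n_dropped = n_dropped),
            class = "pmi_tr_regression")
}

#' @export
print.pmi_tr_regression <- function(x, ...) {
  cat(sprintf(
    "<pmi_tr_regression> PMi = %.4f * dTR + %.4f (n=%d)\n  r2 = %.4f, t = %.3f, p = %.4g (df %d)\n",
    x$slope, x$intercept, x$n, x$r2, x$t_stat, x$p_value, x$df))
  invisible(x)
}
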