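# Group-level inference across sessions: paired t tests, event-count
# weighted session aggregation, and cluster-based permutation correction
# with sign-flip nulls.

# connected-component labels: runs in 1-D, 4-neighbourhood in 2-D
.labelClusters <- function(mask, dims) {
  if (length(dims) == 1L) {
    lab <- integer(length(mask))
    runs <- .trueRuns(mask)
    for (k in seq_len(nrow(runs))) lab[runs[k, 1]:runs[k, 2]] <- k
    return(lab)
  }
  m <- matrix(mask, dims[1], dims[2])
  lab <- matrix(0L, dims[1], dims[2])
  cur <- 0L
  for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii >= 1 && ii <= dims[1] && jj >= 1 && jj <= dims[2] &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  as.integer(lab)
}

# maximal positive and negative cluster mass of one t map
.maxClusterMass <- function(tvec, tcrit, dims) {
  out <- c(pos = 0, neg = 0)
  posLab <- .labelClusters(tvec > tcrit, dims)
  if (any(posLab > 0L)) {
    out["pos"] <- max(vapply(split(tvec[posLab > 0L], posLab[posLab > 0L]),
                             sum, numeric(1)))
  }
  negLab <- .labelClusters(tvec < -tcrit, dims)
  if (any(negLab > 0L)) {
    out["neg"] <- max(vapply(split(-tvec[negLab > 0L],
                                   negLab[negLab > 0L]),
                             sum, numeric(1)))
  }
  out
}

#' Cluster-based permutation test against zero
#'
#' One-sample t values across sessions per cell; clusters are contiguous
#' supra-threshold cells (lag neighbours in 1-D, 4-neighbourhood in 2-D)
#' with mass = sum of t, separately for positive and negative signs. The
#' null distribution of the maximal cluster mass is built by randomly
#' sign-flipping whole sessions; cluster p values are two-tailed
#' (compared to the maximum of the positive and negative null mass), with
#' minimal attainable p = 1/(nPermutations + 1).
#'
#' @param x sessions x cells matrix (1-D) or sessions x time x frequency
#'   array (2-D).
#' @param nPermutations number of sign-flip permutations.
#' @param clusterAlpha cluster-forming threshold (two-tailed t quantile).
#' @param finalAlpha significance threshold for cluster p values.
#' @param seed optional integer for reproducible permutations.
#' @return a [ClusterResult-class]; `statistic`, `clusterId` and `mask`
#'   have the spatial shape of one session's data.
#' @export
clusterPermutationVsZero <- function(x, nPermutations = 1000,
                                     clusterAlpha = 0.05,
                                     finalAlpha = 0.05, seed = NULL) {
  dims <- if (is.matrix(x)) ncol(x) else dim(x)[-1]
  S <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  if (S < 2) stop("at least 2 sessions required")
  X <- if (is.matrix(x)) x else matrix(x, S, prod(dims))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance cell(s) at index ",
         paste(utils::head(which(sds == 0), 5), collapse = ", "),
         "; exclude undefined cells before testing")
  }
  run <- function() {
    tcrit <- stats::qt(1 - clusterAlpha / 2, df = S - 1)
    mObs <- colMeans(X)
    tObs <- mObs / (sds / sqrt(S))
    posLab <- .labelClusters(tObs > tcrit, dims)
    negLab <- .labelClusters(tObs < -tcrit, dims)
    negLab[negLab > 0L] <- negLab[negLab > 0L] + max(posLab)
    labAll <- posLab + negLab
    ids <- sort(unique(labAll[labAll > 0L]))
    mass <- vapply(ids, function(i) sum(tObs[labAll == i]), numeric(1))

    signs <- matrix(sample(c(-1, 1), nPermutations * S, replace = TRUE),
                    nPermutations, S)
    E2 <- colMeans(X^2)
    M <- (signs %*% X) / S
    V <- sweep(-M^2, 2, E2, "+") * S / (S - 1)
    Tp <- M / sqrt(V / S)
    nullMax <- vapply(seq_len(nPermutations), function(p) {
      max(.maxClusterMass(Tp[p, ], tcrit, dims))
    }, numeric(1))
    pvals <- vapply(mass, function(m) {
      (1 + sum(nullMax >= abs(m))) / (nPermutations + 1)
    }, numeric(1))
    sig <- ids[pvals <= finalAlpha]
    mask <- labAll %in% sig
    shape <- function(v) if (length(dims) == 1L) v
                         else array(v, dims)
    new("ClusterResult", statistic = shape(tObs),
        clusterId = shape(labAll),
        clusterP = if (length(pvals)) stats::setNames(pvals, ids)
                   else numeric(),
        mask = shape(mask), nPermutations = as.integer(nPermutations),
        clusterAlpha = clusterAlpha, finalAlpha = finalAlpha)
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Two-sided paired-samples t test
#'
#' @param x,y paired session values (equal length, >= 2 pairs).
#' @return named numeric: `t`, `p`, `df` (df = n - 1).
#' @examples
#' pairedT(c(2, 3, 5), c(1, 1, 4))
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2) stop("at least 2 pairs required")
  d <- x - y
  if (stats::sd(d) < 1e-10 * (mean(abs(d)) + 1)) {
    stop("zero variance of paired differences; t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  c(t = unname(tt$statistic), p = tt$p.value,
    df = unname(tt$parameter))
}

#' Event-count-weighted session aggregate
#'
#' Averages per-contact values into one session value, weighting each
#' contact by its number of contributing events.
#'
#' @param values per-contact values.
#' @param counts per-contact event counts (>= 0, not all zero).
#' @return weighted mean.
#' @examples
#' aggregateSessions(c(1, 3), c(10, 30))  # 2.5
#' @export
aggregateSessions <- function(values, counts) {
  if (length(values) != length(counts)) {
    stop("values and counts must have equal length")
  }
  if (any(counts < 0)) stop("event counts must be nonnegative")
  if (sum(counts) == 0) stop("all contact weights are zero")
  stats::weighted.mean(values, counts)
}
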