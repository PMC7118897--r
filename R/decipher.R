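## Deciphering: factorize the merged matrix M (features x samples, columns
## summing to 1) as M ~ P E with P >= 0 column-stochastic (signature
## probabilities) and E >= 0 (exposures), by Frobenius-norm NMF with
## multiplicative updates.  The number of signatures k is selected by a
## bootstrap-stability procedure: per-sample multinomial resampling of event
## counts, NMF on each resample, k-medoids clustering of the pooled
## signatures on cosine distance, and the mean silhouette as the stability
## statistic.

#' Non-negative matrix factorization of a feature matrix
#'
#' Factorizes a non-negative matrix \code{M} (features x samples) into
#' \code{P} (features x k, columns summing to 1) and \code{E} (k x samples,
#' non-negative) minimizing the Frobenius reconstruction error with the
#' classic multiplicative update rules.  The objective is non-increasing
#' over iterations; iteration stops when the relative objective change
#' drops below \code{tol} or after \code{maxIter} iterations.  Given the
#' same seed the result is bitwise reproducible.
#'
#' @param M non-negative numeric matrix or [FeatureMatrix-class].
#' @param k number of signatures, \code{1 <= k <= min(dim(M)) - 1} (k equal
#'   to the smaller dimension is allowed for k = 1 edge cases).
#' @param seed integer seed for the random uniform initialization.
#' @param maxIter maximum multiplicative-update iterations.
#' @param tol relative-change convergence threshold on the objective.
#' @param restarts number of random restarts; the fit with the smallest
#'   reconstruction error is kept.
#' @return List with elements \code{P}, \code{E}, \code{error} (relative
#'   Frobenius reconstruction error \eqn{\|M - PE\|_F / \|M\|_F}) and
#'   \code{objectiveTrace} of the best restart.
#' @export
nmfFactorize <- function(M, k, seed = 1L, maxIter = 2000L, tol = 1e-9,
                         restarts = 1L) {
  if (is(M, "FeatureMatrix")) M <- featureValues(M)
  M <- as.matrix(M)
  if (any(!is.finite(M)) || any(M < 0))
    stopf("M must be finite and non-negative")
  if (k < 1L || k > min(dim(M)))
    stopf("k = %d out of range for a %d x %d matrix", k, nrow(M), ncol(M))
  eps <- .Machine$double.eps
  normM <- sqrt(sum(M^2))
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(deriveSeed(seed, paste0("nmf-restart-", r)))
    W <- matrix(runif(nrow(M) * k), nrow(M), k)
    H <- matrix(runif(k * ncol(M)), k, ncol(M))
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(maxIter)) {
      H <- H * (crossprod(W, M) / (crossprod(W, W %*% H) + eps))
      W <- W * (M %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      o <- sqrt(sum((M - W %*% H)^2))
      obj <- c(obj, o)
      if (is.finite(prev) && prev - o < tol * max(prev, eps)) break
      prev <- o
    }
    if (is.null(best) || obj[length(obj)] < best$err) {
      best <- list(W = W, H = H, err = obj[length(obj)], trace = obj)
    }
  }
  ## normalize P columns to probabilities; compensate in E
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  P <- sweep(best$W, 2L, scale, "/")
  E <- sweep(best$H, 1L, scale, "*")
  sigNames <- paste0("Signature.", seq_len(k))
  dimnames(P) <- list(rownames(M), sigNames)
  dimnames(E) <- list(sigNames, colnames(M))
  list(P = P, E = E, error = best$err / max(normM, eps),
       objectiveTrace = best$trace)
}

## per-sample multinomial bootstrap of a merged fraction matrix: within each
## group block, redraw the sample's events from its fraction vector with the
## original per-group totals, renormalize to fractions and reapply the
## group's (possibly renormalized) block weight.
bootstrapMatrix <- function(vals, groupIdx, groupTotals, seed) {
  set.seed(seed)
  out <- vals
  for (s in seq_len(ncol(vals))) {
    for (g in names(groupIdx)) {
      idx <- groupIdx[[g]]
      blockSum <- sum(vals[idx, s])
      tot <- groupTotals[g, s]
      if (blockSum <= 0 || tot <= 0) next
      pr <- vals[idx, s] / blockSum
      draw <- as.numeric(rmultinom(1L, size = round(tot), prob = pr))
      out[idx, s] <- draw / sum(draw) * blockSum
    }
  }
  out
}

cosineDist <- function(X) {
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  Xn <- sweep(X, 2L, nrm, "/")
  d <- 1 - crossprod(Xn)
  d[d < 0] <- 0
  stats::as.dist(d)
}

## Partition pooled bootstrap signatures into k clusters with the
## one-per-replicate constraint: every bootstrap contributes exactly one
## signature to each cluster, assigned greedily by cosine similarity to the
## running cluster centroids (seeded by the first replicate).  Unlike a free
## k-medoids partition, a spurious k-th cluster cannot borrow members from
## stable clusters, so its silhouette collapses when k exceeds the true
## signature count.
matchedClusters <- function(sigPool, k) {
  B <- length(sigPool)
  labels <- integer(B * k)
  centroids <- sigPool[[1]]
  counts <- rep(1, k)
  labels[1:k] <- seq_len(k)
  for (b in seq_len(B)[-1]) {
    P <- sigPool[[b]]
    Pn <- sweep(P, 2L, pmax(sqrt(colSums(P^2)), 1e-12), "/")
    Cn <- sweep(centroids, 2L, pmax(sqrt(colSums(centroids^2)), 1e-12), "/")
    sim <- crossprod(Cn, Pn)  # clusters x signatures
    assign <- integer(k)
    simW <- sim
    for (r in seq_len(k)) {
      ij <- which(simW == max(simW), arr.ind = TRUE)[1, ]
      assign[ij[2]] <- ij[1]
      simW[ij[1], ] <- -Inf
      simW[, ij[2]] <- -Inf
    }
    labels[(b - 1L) * k + seq_len(k)] <- assign
    for (j in seq_len(k)) {
      cl <- assign[j]
      centroids[, cl] <- (centroids[, cl] * counts[cl] + P[, j]) /
        (counts[cl] + 1)
      counts[cl] <- counts[cl] + 1
    }
  }
  labels
}

#' Bootstrap-stability diagnostics over a range of k
#'
#' For each candidate number of signatures k, factorizes
#' \code{bootstrapIterations} multinomial resamples of \code{M}, pools the
#' resulting signature columns, partitions them into k clusters (each
#' bootstrap replicate contributing exactly one signature per cluster,
#' matched by cosine similarity) and reports the mean silhouette width on
#' cosine distance (signature stability, in [-1, 1]) together with the mean
#' relative Frobenius reconstruction error.  The suggested k is the largest k whose
#' stability reaches \code{stabilityFloor}; when no k qualifies the
#' suggestion is absent (NA) and the diagnostics are still returned so the
#' user can override.
#'
#' @param M merged [FeatureMatrix-class] (or plain matrix of column
#'   fractions).
#' @param kRange integer vector of candidate k values (default 2:15,
#'   truncated to \code{min(dim) - 1}).
#' @param bootstrapIterations resamples per k (default 100).
#' @param stabilityFloor minimum mean silhouette for a k to qualify
#'   (default 0.8).
#' @param seed master seed; all resamples and factorizations derive their
#'   seeds from it.
#' @param maxIter,tol NMF controls passed to [nmfFactorize()].
#' @param defaultTotal per-group event total assumed for the multinomial
#'   resampling when \code{M} carries no \code{groupTotals} metadata.
#' @param verbose emit per-k progress logs.
#' @return List with \code{diagnostics} (data.frame k / stability /
#'   reconError) and \code{kSuggested} (integer or NA).
#' @export
selectK <- function(M, kRange = 2:15, bootstrapIterations = 100L,
                    stabilityFloor = 0.8, seed = 1L, maxIter = 500L,
                    tol = 1e-6, defaultTotal = 1000, verbose = FALSE) {
  vals <- if (is(M, "FeatureMatrix")) featureValues(M) else as.matrix(M)
  groupIdx <- matrixGroupIndex(M, vals)
  groupTotals <- matrixGroupTotals(M, vals, groupIdx, defaultTotal)
  kRange <- kRange[kRange >= 1 & kRange < min(dim(vals))]
  if (!length(kRange)) stopf("kRange is empty after bounding by dim(M)")
  diag <- data.frame(k = integer(0), stability = numeric(0),
                     reconError = numeric(0))
  for (k in kRange) {
    sigPool <- vector("list", bootstrapIterations)
    errs <- numeric(bootstrapIterations)
    for (b in seq_len(bootstrapIterations)) {
      Mb <- bootstrapMatrix(vals, groupIdx, groupTotals,
                            deriveSeed(seed, sprintf("boot-%d-%d", k, b)))
      fit <- nmfFactorize(Mb, k, seed = deriveSeed(seed,
                            sprintf("fit-%d-%d", k, b)),
                          maxIter = maxIter, tol = tol)
      sigPool[[b]] <- fit$P
      errs[b] <- fit$error
    }
    pool <- do.call(cbind, sigPool)
    stab <- if (k == 1L) {
      ## a single cluster has no silhouette; use mean pairwise cosine
      ## similarity to the pool centroid as its stability
      ctr <- rowMeans(pool)
      mean(crossprod(pool, ctr) /
             (sqrt(colSums(pool^2)) * sqrt(sum(ctr^2))))
    } else {
      d <- cosineDist(pool)
      labels <- matchedClusters(sigPool, k)
      mean(cluster::silhouette(labels, d)[, "sil_width"])
    }
    diag <- rbind(diag, data.frame(k = k, stability = stab,
                                   reconError = mean(errs)))
    sigLog("selectK", k = k, stability = sprintf("%.3f", stab),
           reconError = sprintf("%.4f", mean(errs)), verbose = verbose)
  }
  pass <- diag$k[diag$stability >= stabilityFloor]
  list(diagnostics = diag,
       kSuggested = if (length(pass)) max(pass) else NA_integer_)
}

matrixGroupIndex <- function(M, vals) {
  if (is(M, "FeatureMatrix")) {
    grp <- SummarizedExperiment::rowData(M)$group
    split(seq_len(nrow(vals)), grp)[unique(grp)]
  } else {
    list(ALL = seq_len(nrow(vals)))
  }
}

matrixGroupTotals <- function(M, vals, groupIdx, defaultTotal) {
  md <- if (is(M, "FeatureMatrix")) S4Vectors::metadata(M) else list()
  if (!is.null(md$groupTotals)) return(md$groupTotals)
  matrix(defaultTotal, length(groupIdx), ncol(vals),
         dimnames = list(names(groupIdx), colnames(vals)))
}

#' Decipher mutational signatures from a merged profile matrix
#'
#' Runs the full deciphering stage: bootstrap-stability selection of the
#' number of signatures over \code{kRange} (see [selectK()]), then a final
#' multi-restart factorization of \code{M} at the selected k.  When no k
#' passes the stability floor, the final factorization uses the k with the
#' highest stability, and \code{selectedK()} on the result is NA to flag
#' that no k qualified.
#'
#' @inheritParams selectK
#' @param restarts random restarts for the final factorization.
#' @param finalMaxIter,finalTol NMF controls for the final factorization.
#' @return A [DecipherResult-class].
#' @export
decipherSignatures <- function(M, kRange = 2:15, bootstrapIterations = 100L,
                               stabilityFloor = 0.8, seed = 1L,
                               maxIter = 500L, tol = 1e-6,
                               defaultTotal = 1000, restarts = 5L,
                               finalMaxIter = 2000L, finalTol = 1e-9,
                               verbose = FALSE) {
  sel <- selectK(M, kRange = kRange,
                 bootstrapIterations = bootstrapIterations,
                 stabilityFloor = stabilityFloor, seed = seed,
                 maxIter = maxIter, tol = tol, defaultTotal = defaultTotal,
                 verbose = verbose)
  kFit <- if (is.na(sel$kSuggested)) {
    sel$diagnostics$k[which.max(sel$diagnostics$stability)]
  } else {
    sel$kSuggested
  }
  fit <- nmfFactorize(M, kFit, seed = deriveSeed(seed, "final-fit"),
                      maxIter = finalMaxIter, tol = finalTol,
                      restarts = restarts)
  sigNames <- paste0("Signature.", LETTERS[seq_len(kFit)])
  colnames(fit$P) <- sigNames
  rownames(fit$E) <- sigNames
  new("DecipherResult", signatures = fit$P, exposures = fit$E,
      kSelected = as.integer(sel$kSuggested),
      diagnostics = sel$diagnostics,
      config = list(kRange = kRange,
                    bootstrapIterations = bootstrapIterations,
                    stabilityFloor = stabilityFloor, seed = seed,
                    restarts = restarts, kFitted = kFit))
}

#' Refit non-negative exposures of one profile against fixed signatures
#'
#' Solves the non-negative least-squares problem
#' \eqn{\min_{e \ge 0} \|m - P e\|_2} for one observed profile vector
#' \code{m} against a fixed column-stochastic signature matrix \code{P}
#' (deciphered, or an external COSMIC/WTSI table).  Used by the reporting
#' stage to reconstruct per-sample profiles.
#'
#' @param P features x k signature matrix, columns summing to 1.
#' @param m observed profile vector (fractions or counts), length
#'   \code{nrow(P)}.
#' @return List with \code{exposures} (raw e), \code{fractions}
#'   (\code{e/sum(e)}; zero vector flagged by \code{allZero = TRUE}),
#'   \code{reconstruction} (\code{P \%*\% e}), \code{residual}
#'   (\code{m - reconstruction}) and \code{residualNorm}.
#' @examples
#' P <- cbind(a = c(1, 0, 0), b = c(0, 0.5, 0.5))
#' refitExposures(P, c(0.5, 0.25, 0.25))$fractions  # 0.5, 0.5
#' @export
refitExposures <- function(P, m) {
  P <- as.matrix(P)
  m <- as.numeric(m)
  if (length(m) != nrow(P))
    stopf("profile length %d does not match %d signature features",
          length(m), nrow(P))
  if (any(m < 0) || any(!is.finite(m)))
    stopf("profile must be finite and non-negative")
  if (all(m == 0)) {
    e <- setNames(numeric(ncol(P)), colnames(P))
    return(list(exposures = e, fractions = e, allZero = TRUE,
                reconstruction = numeric(nrow(P)), residual = m,
                residualNorm = 0))
  }
  e <- pracma::lsqnonneg(P, m)$x
  names(e) <- colnames(P)
  recon <- as.numeric(P %*% e)
  fr <- if (sum(e) > 0) e / sum(e) else e
  list(exposures = e, fractions = fr, allZero = all(e == 0),
       reconstruction = recon, residual = m - recon,
       residualNorm = sqrt(sum((m - recon)^2)))
}
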