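# Cluster-based permutation test for group differences on time-frequency
# maps: pixelwise independent-samples t statistics, suprathreshold clustering
# under 4- or 8-neighbor adjacency (positive and negative clusters
# separately), cluster mass = sum of t, and a Monte Carlo null of the maximum
# absolute cluster mass over whole-subject label permutations.

# stack maps (tfr_map objects or plain matrices) into subjects x pixels,
# restricted to a time window; invalid pixels (any subject) become NA
.stack_maps <- function(maps, time_window) {
  first <- maps[[1]]
  if (inherits(first, "tfr_map")) {
    freqs <- first$frequencies
    times <- first$times
    tsel <- which(times >= time_window[1] & times <= time_window[2])
    valid <- Reduce("&", lapply(maps, function(m) {
      stopifnot(inherits(m, "tfr_map"))
      if (!identical(m$frequencies, freqs) || !identical(m$times, times))
        stop_arg("all maps must share the same frequency/time grids")
      m$valid
    }))[, tsel, drop = FALSE]
    D <- do.call(rbind, lapply(maps, function(m)
      as.vector(m$values[, tsel, drop = FALSE])))
    list(D = D, freqs = freqs, times = times[tsel], valid = valid)
  } else {
    dims <- dim(first)
    for (m in maps) if (!identical(dim(m), dims))
      stop_arg("all maps must share the same grid")
    list(D = do.call(rbind, lapply(maps, as.vector)),
         freqs = seq_len(dims[1]), times = seq_len(dims[2]),
         valid = matrix(TRUE, dims[1], dims[2]))
  }
}

# pooled-variance two-sample t for all permutations at once.
# D: subjects x pixels; Z: subjects x n_perm 0/1 membership of group A.
.perm_t <- function(D, D2, Z, nA, nB) {
  sA <- crossprod(D, Z)                  # pixels x n_perm
  qA <- crossprod(D2, Z)
  S <- colSums(D)
  Q <- colSums(D2)
  sB <- S - sA
  qB <- Q - qA
  mA <- sA / nA
  mB <- sB / nB
  ssA <- qA - sA^2 / nA
  ssB <- qB - sB^2 / nB
  pv <- (ssA + ssB) / (nA + nB - 2)
  pv[pv < 0] <- 0
  den <- sqrt(pv * (1 / nA + 1 / nB))
  tt <- (mA - mB) / den
  tt[den == 0] <- 0
  tt
}

#' Cluster-based permutation test on time-frequency maps
#'
#' Compares two groups of subject-level maps. Pixelwise pooled-variance t
#' statistics are thresholded at the two-sided critical value for
#' `pixel_alpha`; suprathreshold pixels form clusters under the adjacency
#' rule (positive and negative t separately) with mass = sum of t. The null
#' distribution is the maximum absolute cluster mass over `n_perm` random
#' whole-subject label exchanges. A cluster is significant when its absolute
#' mass exceeds the `cluster_percentile` of that null; its Monte Carlo p is
#' `(1 + #null >= mass) / (n_perm + 1)`. Statistics are restricted to the
#' poststimulus window (default 10-500 ms); pixels invalid in any subject's
#' map are excluded.
#'
#' @param maps_a,maps_b Lists of `tfr_map` objects (or plain matrices on a
#'   shared grid), one per subject; >= 2 subjects per group.
#' @param n_perm Number of label permutations (default 1000).
#' @param pixel_alpha Two-sided pixel-level threshold (default 0.05).
#' @param cluster_percentile Percentile of the null defining significance
#'   (default 99). The conventional cluster-alpha 0.05 corresponds to 95.
#' @param adjacency `"4"` (orthogonal, default) or `"8"` (with diagonals).
#' @param time_window Analysis window in ms (default `c(10, 500)`), ignored
#'   for plain matrices.
#' @param seed Optional seed for the permutation draw.
#' @return List of class `cluster_test_result`: `statistic` (t matrix, NA at
#'   excluded pixels), `clusters` (data.frame with sign, size, mass, p,
#'   significant), `mask` (logical matrix of significant clusters),
#'   `null_max_mass`, `threshold` (pixel t threshold), `mass_criterion`,
#'   `freqs`, `times`, `params`.
#' @export
cluster_permutation_test <- function(maps_a, maps_b, n_perm = 1000,
                                     pixel_alpha = 0.05,
                                     cluster_percentile = 99,
                                     adjacency = c("4", "8"),
                                     time_window = c(10, 500), seed = NULL) {
  adjacency <- match.arg(as.character(adjacency), c("4", "8"))
  diagonal <- adjacency == "8"
  nA <- length(maps_a)
  nB <- length(maps_b)
  if (nA < 2 || nB < 2) stop_arg("need >= 2 subjects per group")
  st <- .stack_maps(c(maps_a, maps_b), time_window)
  D <- st$D
  keep <- as.vector(st$valid)
  D[, !keep] <- 0                        # excluded pixels carry no signal
  D2 <- D * D
  nsub <- nA + nB
  tcrit <- stats::qt(1 - pixel_alpha / 2, df = nsub - 2)
  nf <- length(st$freqs)
  nt <- length(st$times)

  as_stat_mat <- function(tvec) {
    m <- matrix(tvec, nf, nt)
    m[!st$valid] <- NA_real_
    m
  }
  Zobs <- matrix(0, nsub, 1)
  Zobs[seq_len(nA), 1] <- 1
  tobs <- as_stat_mat(.perm_t(D, D2, Zobs, nA, nB)[, 1])

  null_max <- with_seed(seed, {
    Z <- matrix(0, nsub, n_perm)
    for (p in seq_len(n_perm)) Z[sample.int(nsub, nA), p] <- 1
    TT <- .perm_t(D, D2, Z, nA, nB)
    vapply(seq_len(n_perm), function(p)
      max_cluster_mass(as_stat_mat(TT[, p]), tcrit, diagonal), numeric(1))
  })
  mass_crit <- stats::quantile(null_max, cluster_percentile / 100, names = FALSE)

  # observed clusters, positive and negative separately
  clusters <- list()
  mask <- matrix(FALSE, nf, nt)
  for (sgn in c(1, -1)) {
    sup <- !is.na(tobs) & (sgn * tobs > tcrit)
    lab <- cc_label(sup, diagonal)
    if (max(lab) == 0) next
    for (id in seq_len(max(lab))) {
      members <- lab == id
      mass <- sum(tobs[members])
      p <- (1 + sum(null_max >= abs(mass))) / (n_perm + 1)
      sig <- abs(mass) > mass_crit
      if (sig) mask[members] <- TRUE
      clusters[[length(clusters) + 1L]] <- data.frame(
        sign = sgn, n_pixels = sum(members), mass = mass, p = p,
        significant = sig)
    }
  }
  clusters <- if (length(clusters)) {
    cl <- do.call(rbind, clusters)
    cl <- cl[order(-abs(cl$mass)), , drop = FALSE]
    cl$id <- seq_len(nrow(cl))
    rownames(cl) <- NULL
    cl[, c("id", "sign", "n_pixels", "mass", "p", "significant")]
  } else data.frame(id = integer(), sign = numeric(), n_pixels = integer(),
                    mass = numeric(), p = numeric(), significant = logical())
  structure(list(statistic = tobs, clusters = clusters, mask = mask,
                 null_max_mass = null_max, threshold = tcrit,
                 mass_criterion = mass_crit, freqs = st$freqs,
                 times = st$times,
                 params = list(n_perm = n_perm, pixel_alpha = pixel_alpha,
                               cluster_percentile = cluster_percentile,
                               adjacency = adjacency,
                               time_window = time_window)),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), %d significant (mass > %.3g, %gth percentile of %d permutations)\n",
              nrow(x$clusters), sum(x$clusters$significant), x$mass_criterion,
              x$params$cluster_percentile, x$params$n_perm))
  invisible(x)
}
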