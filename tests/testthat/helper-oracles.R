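# Independent oracles used by the unit and acceptance tests. Both are
# deliberately naive implementations that share no code with the package
# internals they check.

# Exhaustive-search gated partial matching: maximise the number of matched
# pairs within max_distance, then minimise total matched distance.
oracle_match <- function(from_xy, to_xy, max_distance) {
  n <- nrow(from_xy); m <- nrow(to_xy)
  if (n == 0L) return(list(count = 0L, dist = 0))
  d <- sqrt(outer(from_xy[, 1], to_xy[, 1], "-")^2 +
              outer(from_xy[, 2], to_xy[, 2], "-")^2)
  best <- list(count = -1L, dist = Inf)
  rec <- function(i, used, cnt, tot) {
    if (i > n) {
      if (cnt > best$count ||
          (cnt == best$count && tot < best$dist - 1e-12))
        best <<- list(count = cnt, dist = tot)
      return(invisible())
    }
    rec(i + 1L, used, cnt, tot)
    if (m > 0) for (j in seq_len(m)) {
      if (!used[j] && d[i, j] <= max_distance) {
        used[j] <- TRUE
        rec(i + 1L, used, cnt + 1L, tot + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0L, 0)
  best
}

# package-side matching summarised the same way
package_match <- function(from_xy, to_xy, max_distance) {
  m <- peroxdyn:::match_points(from_xy, to_xy, max_distance)
  matched <- which(!is.na(m))
  dist_tot <- if (length(matched))
    sum(sqrt(rowSums((from_xy[matched, , drop = FALSE] -
                        to_xy[m[matched], , drop = FALSE])^2))) else 0
  list(count = length(matched), dist = dist_tot)
}

# Dense grid-search REML for the random-intercept model: full V matrices,
# generic linear algebra, lambda grid 0-10^3 then local refinement.
reml_grid_oracle <- function(y, X, group) {
  Z <- stats::model.matrix(~ 0 + factor(group))
  n <- length(y); p <- ncol(X)
  crit <- function(lambda) {
    V <- diag(n) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    quad <- drop(t(r) %*% Vi %*% r)
    as.numeric(determinant(V)$modulus) +
      as.numeric(determinant(A)$modulus) + (n - p) * log(quad)
  }
  grid <- c(0, 10^seq(-3, 3, length.out = 181))
  vals <- vapply(grid, crit, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(k - 1L, 1L)]
  hi <- grid[min(k + 1L, length(grid))]
  opt <- stats::optimize(crit, c(lo, max(hi, lo + 1e-8)), tol = 1e-12)
  lambda <- if (crit(0) <= opt$objective) 0 else opt$minimum
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- drop(solve(A, t(X) %*% Vi %*% y))
  r <- y - drop(X %*% beta)
  s2e <- drop(t(r) %*% Vi %*% r) / (n - p)
  list(beta = beta, sigma2_resid = s2e,
       sigma2_subject = lambda * s2e, lambda = lambda)
}

# Frozen 12-observation fixture: 4 subjects x 3 stimulation levels.
lmm_fixture_12 <- function() {
  d <- data.frame(
    subject = rep(c("S1", "S2", "S3", "S4"), each = 3),
    stimulation = rep(c("EGTA", "histamine", "Ca"), 4),
    mean_speed_nm_s = c(383.47, 369.20, 361.64,
                        413.01, 360.48, 295.84,
                        461.57, 373.72, 353.45,
                        339.40, 386.56, 333.29))
  d$stimulation <- factor(d$stimulation,
                          levels = c("EGTA", "histamine", "Ca"))
  d
}

# rasterized disk mask helper for segmentation tests
disk_mask <- function(size, centers, radii) {
  m <- matrix(FALSE, size, size)
  for (i in seq_along(radii))
    for (x in seq_len(size)) for (y in seq_len(size))
      if ((x - centers[i, 1])^2 + (y - centers[i, 2])^2 <= radii[i]^2)
        m[x, y] <- TRUE
  m
}
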