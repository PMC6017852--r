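# Independent oracles, deliberately implemented by a different route than
# the package code they check.

# From-scratch Ward (minimum variance) agglomeration: at every step the
# cost of merging clusters A, B is recomputed from the raw data as
#   2 |A||B| / (|A|+|B|) * ||centroid(A) - centroid(B)||^2
# (no Lance-Williams recurrence), height = sqrt(cost); ties broken like
# the package (smallest first-sample indices). Returns the per-step
# member sets (sorted) and heights.
brute_force_ward <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  sets <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- NULL; best_val <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        ca <- colMeans(X[A, , drop = FALSE])
        cb <- colMeans(X[B, , drop = FALSE])
        v <- 2 * length(A) * length(B) / (length(A) + length(B)) *
          sum((ca - cb)^2)
        tol <- if (is.finite(best_val)) 1e-12 * max(1, best_val) else Inf
        better <- if (is.finite(best_val)) v < best_val - tol else TRUE
        tie <- !better && abs(v - best_val) <= tol &&
          (min(A, B) < min(unlist(clusters[best])) ||
             (min(A, B) == min(unlist(clusters[best])) &&
                sort(c(min(A), min(B)))[2] <
                  sort(vapply(clusters[best], min, numeric(1)))[2]))
        if (better || tie) { best_val <- v; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    sets[[length(sets) + 1]] <- merged
    heights <- c(heights, sqrt(best_val))
    clusters <- c(clusters[-best], list(merged))
  }
  list(sets = sets, heights = heights)
}

# member sets per merge step of an hca_result, for oracle comparison
hca_member_sets <- function(res) {
  n <- length(res$labels)
  out <- vector("list", n - 1)
  get_set <- function(e) if (e < 0) -e else out[[e]]
  for (s in seq_len(n - 1)) {
    out[[s]] <- sort(c(get_set(res$merge[s, 1]), get_set(res$merge[s, 2])))
  }
  out
}

# Cyclic Jacobi rotation eigensolver for symmetric matrices; returns
# eigenvalues sorted descending. Independent of base eigen().
jacobi_eigenvalues <- function(S, tol = 1e-13, max_sweeps = 100) {
  A <- as.matrix(S)
  n <- nrow(A)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(A[upper.tri(A)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        if (abs(A[p, q]) < 1e-300) next
        theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
        t_ <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
        if (theta == 0) t_ <- 1
        c_ <- 1 / sqrt(t_^2 + 1); s_ <- t_ * c_
        J <- diag(n); J[p, p] <- c_; J[q, q] <- c_
        J[p, q] <- s_; J[q, p] <- -s_
        A <- t(J) %*% A %*% J
      }
    }
  }
  sort(diag(A), decreasing = TRUE)
}

# Textbook OLS closed form
ols_oracle <- function(x, y) {
  sxy <- sum(x * y) - length(x) * mean(x) * mean(y)
  sxx <- sum(x^2) - length(x) * mean(x)^2
  a <- sxy / sxx
  c(slope = a, intercept = mean(y) - a * mean(x))
}

# Textbook paired t statistic and two-tailed p
paired_t_oracle <- function(x, y) {
  d <- x - y
  t_ <- mean(d) * sqrt(length(d)) / sd(d)
  c(t = t_, p = 2 * pt(-abs(t_), df = length(d) - 1))
}
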