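# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# least-squares slope via the explicit normal equations
oracle_slope <- function(t, y) {
  n <- length(t)
  (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
}

# K2P distance by an explicit per-site loop over character pairs
oracle_k2p <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  is_ts <- function(x, y) {
    (x == "A" && y == "G") || (x == "G" && y == "A") ||
      (x == "C" && y == "T") || (x == "T" && y == "C")
  }
  nts <- 0L; ntv <- 0L; nv <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% c("A", "C", "G", "T") && b[i] %in% c("A", "C", "G", "T")) {
      nv <- nv + 1L
      if (a[i] != b[i]) {
        if (is_ts(a[i], b[i])) nts <- nts + 1L else ntv <- ntv + 1L
      }
    }
  }
  P <- nts / nv; Q <- ntv / nv
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# partial Procrustes distance by brute-force search over the rotation
# angle (centring and unit scaling done explicitly)
oracle_procrustes_distance <- function(a, b) {
  norm_conf <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  A <- norm_conf(as.matrix(a)); B <- norm_conf(as.matrix(b))
  dist_at <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sqrt(sum((A %*% R - B)^2))
  }
  grid <- seq(0, 2 * pi, length.out = 721)
  best <- grid[which.min(vapply(grid, dist_at, numeric(1)))]
  stats::optimize(dist_at, c(best - 0.02, best + 0.02))$objective
}

# Kasa circle fit through explicit 3x3 normal equations
oracle_circle_radius <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- solve(crossprod(A), crossprod(A, b))
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}

# Duncan letters by exhaustive enumeration: a ranked pair is
# non-significant iff some enclosing ranked span (itself included) fails
# its least-significant-range test; letters then mark the maximal
# non-significant blocks
oracle_duncan <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  g <- length(means)
  ns <- table(groups)[names(means)]
  fit <- stats::aov(values ~ factor(groups))
  mse <- deviance(fit) / fit$df.residual
  nh <- g / sum(1 / as.numeric(ns))
  se <- sqrt(mse / nh)
  lsr <- function(p) {
    stats::qtukey((1 - alpha)^(p - 1), p, fit$df.residual) * se
  }
  nonsig <- matrix(FALSE, g, g)
  for (i in seq_len(g)) nonsig[i, i] <- TRUE
  for (a in seq_len(g - 1)) for (b in (a + 1):g) {
    # enclosing spans [u, v] with u <= a, v >= b
    for (u in seq_len(a)) for (v in b:g) {
      if (means[u] - means[v] <= lsr(v - u + 1)) nonsig[a, b] <- TRUE
    }
  }
  # maximal blocks of mutually non-significant ranked groups
  block_ok <- function(a, b) {
    if (a == b) return(TRUE)
    for (i in a:(b - 1)) for (j in (i + 1):b) {
      if (!nonsig[i, j]) return(FALSE)
    }
    TRUE
  }
  blocks <- list()
  for (a in seq_len(g)) {
    b <- a
    while (b < g && block_ok(a, b + 1)) b <- b + 1
    blocks[[a]] <- c(a, b)
  }
  blocks <- unique(blocks)
  keep <- vapply(seq_along(blocks), function(i) {
    !any(vapply(seq_along(blocks), function(j) {
      j != i && blocks[[j]][1] <= blocks[[i]][1] &&
        blocks[[j]][2] >= blocks[[i]][2]
    }, logical(1)))
  }, logical(1))
  blocks <- blocks[keep]
  blocks <- blocks[order(vapply(blocks, `[`, numeric(1), 1))]
  lab <- vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(blocks, function(bk) {
      bk[1] <= i && i <= bk[2]
    }, logical(1)))], collapse = "")
  }, character(1))
  data.frame(group = names(means), letters = lab,
             stringsAsFactors = FALSE, row.names = NULL)
}

# rigid-motion helper for invariance tests
transform_traj <- function(traj, angle = 0, shift = c(0, 0), scale = 1) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- cbind(traj$x, traj$y) %*% R * scale
  traj$x <- xy[, 1] + shift[1]
  traj$y <- xy[, 2] + shift[2]
  traj
}
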