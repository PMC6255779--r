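# Independent oracles and small fixture builders used across the suite.

# brute-force 26-connected component containing `seed_ijk` (1-based), by
# repeated neighbourhood expansion over an explicit voxel set
brute_component <- function(arr, seed_ijk) {
  d <- dim(arr)
  out <- array(FALSE, d)
  if (!arr[seed_ijk[1], seed_ijk[2], seed_ijk[3]]) return(out)
  frontier <- matrix(seed_ijk, ncol = 3)
  out[seed_ijk[1], seed_ijk[2], seed_ijk[3]] <- TRUE
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (r in seq_len(nrow(frontier))) {
      nb <- sweep(off, 2, frontier[r, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        i <- nb[q, 1]; j <- nb[q, 2]; k <- nb[q, 3]
        if (arr[i, j, k] && !out[i, j, k]) {
          out[i, j, k] <- TRUE
          nxt <- rbind(nxt, nb[q, ])
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else nxt
  }
  out
}

# OLS by explicit normal equations, with classical t-based CIs
ols_oracle <- function(x, y, level = 0.95) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - 2)
  cov <- s2 * solve(t(X) %*% X)
  tq <- qt(1 - (1 - level) / 2, df = n - 2)
  list(intercept = beta[1], slope = beta[2],
       rmse = sqrt(mean(res^2)),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       intercept_ci = beta[1] + c(-1, 1) * tq * sqrt(cov[1, 1]),
       slope_ci = beta[2] + c(-1, 1) * tq * sqrt(cov[2, 2]))
}

# paired t statistic from the defining formula
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Dice from explicit voxel index sets
dice_brute <- function(a, b) {
  ia <- which(a)
  ib <- which(b)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

gauss_mtf <- function(sigma_mm, f_lp_cm) exp(-2 * pi^2 * sigma_mm^2 * (f_lp_cm / 10)^2)

gauss_cutoff_lp_cm <- function(sigma_mm, level) 10 * sqrt(-log(level) / (2 * pi^2 * sigma_mm^2))

# embed a cropped mask back into a full-grid logical array via its origin
embed_mask <- function(mask, grid) {
  g <- ctresolve:::as_grid(grid)
  arr <- array(FALSE, g$shape)
  start <- round((mask$origin - g$origin) / g$spacing) + 1
  d <- dim(mask$values)
  arr[start[1]:(start[1] + d[1] - 1),
      start[2]:(start[2] + d[2] - 1),
      start[3]:(start[3] + d[3] - 1)] <- mask$values
  arr
}

# compact test scene: one 6 mm sphere and one 6 mm spiked nodule
small_scene <- function(noise_free_geometry = TRUE, feeder_radius_mm = 0.35,
                        print_undersize_mm = 0, spacing = c(0.13, 0.13, 0.25)) {
  grid <- list(shape = c(220, 140, 64), spacing = spacing)
  nodules <- list(
    nodule_spec("sphere", 6, c(8, 9, 8)),
    nodule_spec("spiked_sphere", 6, c(20, 9, 8), seed = 4))
  phantom_scene(grid, nodules = nodules, vessel_seed = 11,
                vessel_params = list(depth = 2, root_start_mm = c(0, 3, 8),
                                     root_dir = c(1, 0.2, 0),
                                     root_radius_mm = 0.8),
                feeder_radius_mm = feeder_radius_mm,
                print_undersize_mm = print_undersize_mm)
}
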