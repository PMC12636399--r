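# shared fixture builders; everything is generated in code under fixed seeds

fixed_dist <- function(v) list(type = "fixed", value = v)

# one-class registry with fully pinned parameters
fixed_class <- function(name = "EV", diameter = 100, cargo = 20,
                        axial_ratio = 1, labeling = 1) {
  out <- list(particle_class(name, fixed_dist(diameter),
                             fixed_dist(axial_ratio), fixed_dist(cargo),
                             labeling))
  names(out) <- name
  out
}

# uniform points on a disk of radius r (exact, via sqrt-radius transform)
sample_disk <- function(n, r = 50, cx = 0, cy = 0) {
  rad <- r * sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
  cbind(cx + rad * cos(phi), cy + rad * sin(phi))
}

# well-separated ground truth: particles on a jittered coarse grid
separated_truth <- function(roi, n = 25, diameter = 60, cargo = 10,
                            spacing = 3000, jitter = 500, seed = 1) {
  withr_seed <- seed  # plain set.seed; callers wrap in their own seed scope
  set.seed(withr_seed)
  gp <- expand.grid(x = seq(2000, roi$width_nm - 2000, by = spacing),
                    y = seq(2000, roi$height_nm - 2000, by = spacing))
  pick <- gp[sample(nrow(gp), n), ]
  truth <- data.frame(
    particle_id = seq_len(n) - 1L, class_name = "EV",
    x_nm = pick$x + runif(n, -jitter, jitter),
    y_nm = pick$y + runif(n, -jitter, jitter),
    diameter_nm = diameter, axial_ratio = 1, orientation = 0,
    n_cargo = cargo, reporter_positive = FALSE,
    stringsAsFactors = FALSE)
  truth$cargo <- lapply(seq_len(n), function(k)
    evprofiler:::cargo_in_ellipse(cargo, truth$x_nm[k], truth$y_nm[k],
                                  diameter, 1, 0))
  attr(truth, "roi") <- roi
  class(truth) <- c("particle_truth", "data.frame")
  truth
}

# brute-force connected components at a distance threshold (the clustering
# oracle): breadth-first search over the full distance matrix
oracle_components <- function(x, y, thr = 100) {
  n <- length(x)
  adj <- as.matrix(dist(cbind(x, y))) <= thr
  lab <- rep(NA_integer_, n); cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i])) next
    cur <- cur + 1L
    q <- i
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      if (is.na(lab[v])) {
        lab[v] <- cur
        q <- c(q, which(adj[v, ] & is.na(lab)))
      }
    }
  }
  lab
}

# partitions as canonical sets of sorted index vectors
partition_of <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}

# brute-force clipped Voronoi cell by sequential half-plane clipping
# (independent R oracle for the compiled tessellation)
bf_voronoi_cell <- function(i, x, y, W, H) {
  px <- c(0, W, W, 0); py <- c(0, 0, H, H); gen <- rep(-1L, 4L)
  eps <- 1e-9 * max(W, H)
  for (j in seq_along(x)) {
    if (j == i) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    mx <- (x[j] + x[i]) / 2; my <- (y[j] + y[i]) / 2
    n <- length(px); if (n < 3L) break
    s <- (px - mx) * dx + (py - my) * dy
    if (all(s <= eps)) next
    npx <- npy <- numeric(0); ngen <- integer(0)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      in1 <- s[k] <= eps; in2 <- s[k2] <= eps
      if (in1) {
        npx <- c(npx, px[k]); npy <- c(npy, py[k]); ngen <- c(ngen, gen[k])
      }
      if (xor(in1, in2)) {
        t <- s[k] / (s[k] - s[k2])
        npx <- c(npx, px[k] + t * (px[k2] - px[k]))
        npy <- c(npy, py[k] + t * (py[k2] - py[k]))
        ngen <- c(ngen, if (in1) j else gen[k])
      }
    }
    px <- npx; py <- npy; gen <- ngen
  }
  area <- if (length(px) >= 3L) {
    x2 <- c(px[-1L], px[1L]); y2 <- c(py[-1L], py[1L])
    abs(sum(px * y2 - x2 * py)) / 2
  } else 0
  list(area = area, neighbors = sort(unique(gen[gen > 0L])))
}

# displace a binary mask by whole pixels (content moves +dx columns, +dy rows)
shift_mask <- function(mask, dx = 0L, dy = 0L) {
  m <- unclass(mask); out <- m; out[] <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  src_c <- seq_len(nc) - dx; src_r <- seq_len(nr) - dy
  ok_c <- src_c >= 1L & src_c <= nc; ok_r <- src_r >= 1L & src_r <= nr
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  structure(out, threshold = attr(mask, "threshold"),
            pixel_size_nm = attr(mask, "pixel_size_nm"),
            channel = attr(mask, "channel"), class = class(mask))
}
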