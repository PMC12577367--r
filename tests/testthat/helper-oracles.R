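# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: plain loops and from-scratch formulas.

# --- actin-cluster index: naive per-pixel implementation --------------------
oracle_actin_index <- function(actin, roi, mask, top_fraction = 0.05,
                               com_weighted = TRUE) {
  h <- nrow(actin); w <- ncol(actin)
  cy <- roi$center[["y"]]; cx <- roi$center[["x"]]
  ay <- roi$axis[["y"]]; ax <- roi$axis[["x"]]
  ys <- c(); xs <- c(); vals <- c()
  for (yy in seq_len(h)) {
    for (xx in seq_len(w)) {
      u <- (yy - cy) * ay + (xx - cx) * ax
      v <- -(yy - cy) * ax + (xx - cx) * ay
      if (abs(u) <= roi$height_px / 2 + 1e-12 &&
          abs(v) <= roi$width_px / 2 + 1e-12 && mask[yy, xx]) {
        ys <- c(ys, yy); xs <- c(xs, xx); vals <- c(vals, actin[yy, xx])
      }
    }
  }
  n <- length(vals)
  if (n == 0) return(NULL)
  m <- max(1, ceiling(top_fraction * n))
  # selection sort of indices by (intensity desc, row-major asc)
  key <- order(-vals, (ys - 1) * w + xs)
  top <- key[seq_len(m)]
  int_all <- sum(vals) / n
  int_top <- sum(vals[top]) / m
  wts <- if (com_weighted) vals[top] else rep(1, m)
  com_y <- sum(wts * ys[top]) / sum(wts)
  com_x <- sum(wts * xs[top]) / sum(wts)
  d_all <- mean(sqrt((ys - com_y)^2 + (xs - com_x)^2))
  d_top <- mean(sqrt((ys[top] - com_y)^2 + (xs[top] - com_x)^2))
  enrichment <- (int_top - int_all) / int_all
  clustering <- d_all / d_top
  list(n_positive = n, int_all = int_all, int_top = int_top,
       enrichment = enrichment, com_y = com_y, com_x = com_x,
       d_all = d_all, d_top = d_top, clustering = clustering,
       index = enrichment * clustering)
}

# --- Otsu: exhaustive threshold sweep maximizing between-class variance -----
oracle_otsu_mask <- function(image) {
  vals <- sort(unique(as.vector(image)))
  cands <- (vals[-1] + vals[-length(vals)]) / 2
  best <- -Inf; best_thr <- NA
  for (thr in cands) {
    fg <- image > thr
    w1 <- mean(fg); w0 <- 1 - w1
    if (w1 == 0 || w0 == 0) next
    bcv <- w0 * w1 * (mean(image[fg]) - mean(image[!fg]))^2
    if (bcv > best) {
      best <- bcv
      best_thr <- thr
    }
  }
  image > best_thr
}

# --- Mann-Whitney: full enumeration of group assignments --------------------
oracle_mann_whitney <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pool), nx)
  us <- apply(idx, 2, function(ii) sum(outer(pool[ii], pool[-ii], ">")))
  u_obs <- sum(outer(x, y, ">"))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# --- Fisher: hypergeometric enumeration -------------------------------------
oracle_fisher <- function(tb) {
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  as_ <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(as_, c1, n - c1, r1)
  p_obs <- stats::dhyper(tb[1, 1], c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# --- timing rules: literal definition scans ---------------------------------
# first frame at/after anaphase that is RESOLVED with every later frame
# RESOLVED too
oracle_resolution_frame <- function(frames, status, first_frame) {
  for (i in seq_along(frames)) {
    if (frames[i] < first_frame) next
    if (status[i] == "RESOLVED" &&
        all(status[seq_along(frames) >= i] == "RESOLVED")) {
      return(frames[i])
    }
  }
  NA_integer_
}

# first frame at/after ingression opening a run of k consecutive DOUBLE calls
oracle_abscission_frame <- function(frames, cls, first_frame, k) {
  ok <- which(frames >= first_frame)
  for (i in ok) {
    if (i + k - 1 > length(cls)) break
    if (all(cls[i:(i + k - 1)] == "DOUBLE")) return(frames[i])
  }
  NA_integer_
}

# --- project_five: naive triple loop ----------------------------------------
oracle_project_five <- function(stack, z_center) {
  d <- dim(stack)
  out <- matrix(-Inf, d[1], d[2])
  for (z in max(1, z_center - 2):min(d[3], z_center + 2)) {
    for (yy in seq_len(d[1])) {
      for (xx in seq_len(d[2])) {
        out[yy, xx] <- max(out[yy, xx], stack[yy, xx, z])
      }
    }
  }
  out
}

# --- shared fixtures --------------------------------------------------------
# a deterministic random ROI + actin image pair
random_roi_scene <- function(seed, h = 40, w = 40) {
  set.seed(seed)
  a <- list(centroid_y = runif(1, 8, h - 8), centroid_x = runif(1, 8, w - 8),
            major_axis_px = runif(1, 5, 12))
  repeat {
    b <- list(centroid_y = runif(1, 8, h - 8), centroid_x = runif(1, 8, w - 8),
              major_axis_px = runif(1, 5, 12))
    if ((a$centroid_y - b$centroid_y)^2 + (a$centroid_x - b$centroid_x)^2 > 16) break
  }
  img <- matrix(runif(h * w, 0, 100), h, w)
  mask <- img > 30
  list(roi = build_midzone_roi(a, b), img = img, mask = mask)
}
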