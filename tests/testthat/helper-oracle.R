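# Independent oracles used by the property suites. The superposition
# oracle uses Horn's quaternion method for absolute orientation (a
# different algorithm from the SVD route in the package); the matching
# oracle is a naive exhaustive enumerator with no pruning.

horn_superpose <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  S <- t(xc) %*% yc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  R <- rbind(
    c(q[1]^2 + q[2]^2 - q[3]^2 - q[4]^2, 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), q[1]^2 - q[2]^2 + q[3]^2 - q[4]^2,
      2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2))
  t <- cy - as.vector(R %*% cx)
  moved <- sweep(x %*% t(R), 2, t, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((moved - y)^2))))
}

# exhaustive matching oracle: every injective assignment of points to
# features (optional features may be skipped), both normal signs for
# every directional feature, no distance pruning; returns the minimal
# valid fit RMSD or NULL
naive_match <- function(points, model, heavy_xyz = NULL) {
  feats <- model$features
  nf <- length(feats)
  kinds <- vapply(points, `[[`, character(1), "kind")
  best <- NULL
  cand <- lapply(feats, function(f) {
    ix <- which(kinds %in% f$kinds)
    if (!f$essential) ix <- c(ix, NA_integer_)
    ix
  })
  if (any(vapply(cand, length, integer(1)) == 0)) return(NULL)
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[!is.na(a)]
    if (anyDuplicated(used)) next
    dir_idx <- which(vapply(seq_len(nf), function(k)
      !is.na(a[k]) && !is.null(feats[[k]]$direction) &&
        !is.null(points[[a[k]]]$dir), logical(1)))
    signsets <- if (length(dir_idx))
      expand.grid(rep(list(c(1, -1)), length(dir_idx)))
    else data.frame(row.names = 1)
    for (srow in seq_len(nrow(signsets))) {
      P <- NULL; C <- NULL
      for (k in seq_len(nf)) {
        if (is.na(a[k])) next
        f <- feats[[k]]; pt <- points[[a[k]]]
        P <- rbind(P, pt$pos); C <- rbind(C, f$center)
        if (k %in% dir_idx) {
          s <- signsets[srow, match(k, dir_idx)]
          P <- rbind(P, pt$pos + s * pt$dir)
          C <- rbind(C, f$center + f$direction)
        }
      }
      if (is.null(P) || nrow(P) < 3) next
      tf <- horn_superpose(P, C)
      moved <- sweep(P %*% t(tf$R), 2, tf$t, "+")
      # validity checks
      ok <- TRUE; row <- 1
      for (k in seq_len(nf)) {
        if (is.na(a[k])) next
        f <- feats[[k]]
        if (sqrt(sum((moved[row, ] - f$center)^2)) > f$radius) {
          ok <- FALSE; break
        }
        row <- row + 1
        if (k %in% dir_idx) {
          dv <- moved[row, ] - moved[row - 1, ]
          cs <- sum(dv * f$direction) /
            sqrt(sum(dv^2) * sum(f$direction^2))
          ang <- acos(max(-1, min(1, cs))) * 180 / pi
          ang <- min(ang, 180 - ang)
          if (ang > f$direction_tol) { ok <- FALSE; break }
          row <- row + 1
        }
      }
      if (!ok) next
      if (!is.null(heavy_xyz) && length(model$excluded_volumes)) {
        hx <- sweep(heavy_xyz %*% t(tf$R), 2, tf$t, "+")
        for (v in model$excluded_volumes)
          if (any(rowSums(sweep(hx, 2, v$center)^2) <
                  v$radius^2 - 1e-12)) { ok <- FALSE; break }
      }
      if (!ok) next
      r2 <- sqrt(mean(rowSums((moved - C)^2)))
      if (is.null(best) || r2 < best) best <- r2
    }
  }
  best
}
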