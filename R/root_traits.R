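# Root-length extraction from binary masks and agreement statistics
# against manual line-intersect measurements.

#' Thin a binary mask to a 1-px skeleton (Zhang-Suen)
#'
#' Iterative two-subcycle thinning; each pass is fully vectorised over the
#' image.
#'
#' @param mask Binary matrix (`H x W`) or `(1, H, W)` array.
#' @return Logical `H x W` matrix.
#' @export
skeletonize_mask <- function(mask) {
  m <- spatial_matrix(mask) > 0
  if (!any(m)) return(m)
  H <- nrow(m); W <- ncol(m)
  shift <- function(p, dr, dc) {
    out <- matrix(FALSE, H + 2L, W + 2L)
    out[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)] <- p
    out[2:(H + 1L), 2:(W + 1L)]
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1); p6 <- shift(m, 1, 0); p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (sub == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Skeleton-based root length of a binary mask
#'
#' The mask is thinned to a 1-px skeleton, then length is accumulated over
#' adjacent skeleton pixel steps: orthogonal neighbours contribute 1,
#' diagonal neighbours sqrt(2) (diagonal steps shortcut-suppressed when an
#' orthogonal 2-step path exists).  Thinning shortens every branch by
#' roughly the local half-width, so each skeleton endpoint additionally
#' contributes its distance to the nearest background pixel of the
#' original mask (an endpoint-reconstruction correction; for a straight
#' stroke of length L and width w this recovers ~L).
#'
#' @param mask Binary matrix or `(1, H, W)` array.
#' @param diagonal Use sqrt(2) weighting for diagonal steps (default TRUE;
#'   `FALSE` counts every step as 1).
#' @return Length in pixels (0 for an empty mask).
#' @export
skeleton_length <- function(mask, diagonal = TRUE) {
  m <- spatial_matrix(mask) > 0
  sk <- skeletonize_mask(m)
  if (!any(sk)) return(0)
  H <- nrow(sk); W <- ncol(sk)
  horiz <- sum(sk[, -W] & sk[, -1])
  vert <- sum(sk[-H, ] & sk[-1, ])
  dr <- sk[-H, -W] & sk[-1, -1]
  dl <- sk[-H, -1] & sk[-1, -W]
  dr_skip <- dr & (sk[-H, -1] | sk[-1, -W])
  dl_skip <- dl & (sk[-H, -W] | sk[-1, -1])
  ndiag <- sum(dr & !dr_skip) + sum(dl & !dl_skip)
  w <- if (diagonal) sqrt(2) else 1
  horiz + vert + ndiag * w + sum(endpoint_extents(sk, m))
}

# Distance from each skeleton endpoint (<= 1 neighbour) to the nearest
# background pixel of the original mask; image borders count as background.
endpoint_extents <- function(sk, m) {
  H <- nrow(sk); W <- ncol(sk)
  nb <- conv2_same(sk * 1, matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3))
  eps <- which(sk & nb <= 1, arr.ind = TRUE)
  if (nrow(eps) == 0L) return(0)
  vapply(seq_len(nrow(eps)), function(i) {
    r <- eps[i, 1]; c <- eps[i, 2]
    best <- Inf
    for (rad in 1:32) {
      rr <- max(1L, r - rad):min(H, r + rad)
      cc <- max(1L, c - rad):min(W, c + rad)
      win <- m[rr, cc, drop = FALSE]
      hit_border <- (r - rad < 1L) || (r + rad > H) ||
        (c - rad < 1L) || (c + rad > W)
      bg <- which(!win, arr.ind = TRUE)
      if (nrow(bg)) {
        d <- sqrt((rr[bg[, 1]] - r)^2 + (cc[bg[, 2]] - c)^2)
        best <- min(best, min(d))
      }
      if (hit_border) best <- min(best, rad)
      if (is.finite(best) && best <= rad) break
    }
    if (is.finite(best)) best else 1
  }, numeric(1))
}

# 8-connected component count by BFS over skeleton pixels.
count_components <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  idx <- which(m)
  ncomp <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in idx) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% H + 1L
      c <- (cur - 1L) %/% H + 1L
      rr <- r + offs$dr; cc <- c + offs$dc
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      nb <- (cc[ok] - 1L) * H + rr[ok]
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- ncomp
        queue <- c(queue, nb)
      }
    }
  }
  ncomp
}

#' Pearson agreement between two length measurements
#'
#' `r` from the product-moment formula, two-sided p-value from the exact t
#' distribution with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with non-zero
#'   variance (e.g. manual mm vs segmentation px; `r` is scale-invariant).
#' @param alpha Significance level (default 0.05).
#' @param m_comparisons Number of comparisons for Bonferroni adjustment
#'   (default 1 = none).
#' @return List of class `agreement_result`: `r`, `r_squared`, `p_value`,
#'   `n`, `alpha`, `m_comparisons`, `significant`,
#'   `significant_after_bonferroni`.
#' @export
pearson_agreement <- function(x, y, alpha = 0.05, m_comparisons = 1L) {
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  if (length(x) < 3L) stop_invalid("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_invalid("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, r_squared = r^2, p_value = ct$p.value,
                 n = length(x), alpha = alpha,
                 m_comparisons = as.integer(m_comparisons),
                 significant = ct$p.value < alpha,
                 significant_after_bonferroni =
                   ct$p.value < alpha / m_comparisons),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (r^2 = %.3f), p = %.3g, n = %d\n",
              x$r, x$r_squared, x$p_value, x$n))
  cat(sprintf("significant at alpha = %g: %s; after Bonferroni (m = %d): %s\n",
              x$alpha, x$significant, x$m_comparisons,
              x$significant_after_bonferroni))
  invisible(x)
}

#' Bonferroni significance flags
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise significance level.
#' @return Logical vector: `p_i < alpha / m` with `m = length(p_values)`.
#' @export
bonferroni_correct <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1))
    stop_invalid("p-values must lie in [0, 1]")
  p_values < alpha / length(p_values)
}

#' Read / write a per-image root-length table
#'
#' CSV with header `image,order_1,order_2,order_3,total_length`.
#'
#' @param path CSV file path.
#' @return Data frame with those five columns.
#' @export
read_length_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "order_1", "order_2", "order_3", "total_length")
  if (!all(need %in% names(df)))
    stop_invalid("length table must have columns ", paste(need, collapse = ","))
  df[need]
}

#' @rdname read_length_table
#' @param table Data frame to write.
#' @export
write_length_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Agreement over a pair of length tables
#'
#' Runs [pearson_agreement()] for total length and each root order, with a
#' Bonferroni family of `m = 4` comparisons.
#'
#' @param table_a,table_b Length tables (see [read_length_table()]), rows
#'   matched by position.
#' @param alpha Significance level.
#' @return Named list of `agreement_result`s for `total_length`, `order_1`,
#'   `order_2`, `order_3`.
#' @export
length_table_agreement <- function(table_a, table_b, alpha = 0.05) {
  cols <- c("total_length", "order_1", "order_2", "order_3")
  out <- lapply(cols, function(cl)
    pearson_agreement(table_a[[cl]], table_b[[cl]], alpha = alpha,
                      m_comparisons = length(cols)))
  names(out) <- cols
  out
}
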