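# Neighbour stack in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW).
zs_neighbours <- function(S) {
  lapply(seq_len(8), function(i)
    shift_mat(S, NEIGH8[i, 1], NEIGH8[i, 2], fill = FALSE))
}

# One Guo-Hall subiteration. Neighbours p2..p9 clockwise from north are
# NEIGH8[1..8]; C is the connectivity number, N the endpoint guard.
gh_pass <- function(S, odd) {
  P <- zs_neighbours(S)
  p2 <- P[[1]]; p3 <- P[[2]]; p4 <- P[[3]]; p5 <- P[[4]]
  p6 <- P[[5]]; p7 <- P[[6]]; p8 <- P[[7]]; p9 <- P[[8]]
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
    (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N <- pmin(N1, N2)
  m <- if (odd) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
  S & !(S & C == 1 & N >= 2 & N <= 3 & !m)
}

# Crossing number A (number of 0->1 transitions around the 8-ring) equals
# the number of 8-connected neighbour components, so A == 1 is the exact
# local simplicity test.
crossing_number <- function(S) {
  P <- zs_neighbours(S)
  seqP <- c(P, P[1])
  A <- matrix(0L, nrow(S), ncol(S))
  for (i in seq_len(8)) A <- A + (!seqP[[i]] & seqP[[i + 1]])
  A
}

# Remove residual 2x2 solid blocks. Per block: delete a locally simple
# member (A == 1) when one exists; otherwise a member whose removal keeps
# the global component count; otherwise (degenerate lattice-like masks) the
# last member regardless, so thinness always holds.
zs_deblock <- function(S) {
  repeat {
    blocks <- S & shift_mat(S, 0, -1, FALSE) & shift_mat(S, -1, 0, FALSE) &
      shift_mat(S, -1, -1, FALSE)
    if (!any(blocks)) break
    A <- crossing_number(S)
    tl <- which(blocks)[1]
    r <- ((tl - 1L) %% nrow(S)) + 1L
    c <- ((tl - 1L) %/% nrow(S)) + 1L
    members <- cbind(r = c(r, r, r + 1L, r + 1L),
                     c = c(c, c + 1L, c, c + 1L))
    simple <- members[A[members] == 1, , drop = FALSE]
    if (nrow(simple) > 0) {
      S[simple[1, 1], simple[1, 2]] <- FALSE
      next
    }
    n_comp <- max(label_components(S))
    removed <- FALSE
    for (i in seq_len(4)) {
      Sx <- S
      Sx[members[i, 1], members[i, 2]] <- FALSE
      if (max(label_components(Sx)) == n_comp) {
        S <- Sx
        removed <- TRUE
        break
      }
    }
    if (!removed) S[members[4, 1], members[4, 2]] <- FALSE
  }
  S
}

#' Skeletonize a neurite mask
#'
#' Topology-preserving 2-D thinning (Zhang-Suen two-subiteration scheme with
#' a final clean-up that removes any residual 2x2 block) producing a
#' one-pixel-wide skeleton. Neurite length is defined as the number of true
#' skeleton pixels — the pixel-count convention, with no diagonal-step
#' correction.
#'
#' @param neurite_mask Logical matrix (or `segmentation_masks`, from which
#'   the neurite mask is taken).
#' @return A `neurite_skeleton`: `skeleton` logical matrix, `length_px`,
#'   and `branch_count` (merged junction clusters, see
#'   [count_branch_points()]).
#' @export
skeletonize_neurites <- function(neurite_mask) {
  if (inherits(neurite_mask, "segmentation_masks")) {
    neurite_mask <- neurite_mask$neurite
  }
  S <- as_logical_mask(neurite_mask)
  repeat {
    S1 <- gh_pass(S, odd = TRUE)
    S2 <- gh_pass(S1, odd = FALSE)
    if (identical(S2, S)) break
    S <- S2
  }
  S <- zs_deblock(S)
  skel <- structure(list(skeleton = S, length_px = sum(S),
                         branch_count = NA_integer_),
                    class = "neurite_skeleton")
  skel$branch_count <- count_branch_points(skel)
  skel
}

#' @export
print.neurite_skeleton <- function(x, ...) {
  cat(sprintf("<neurite_skeleton> length %d px, %d branch points\n",
              x$length_px, x$branch_count))
  invisible(x)
}

#' Count neurite branch points
#'
#' A branch point is a skeleton pixel with at least 3 skeleton neighbours
#' (8-connectivity) — a bifurcation or crossover. With `merge = TRUE`
#' (default) adjacent junction pixels within one 8-neighbourhood collapse
#' into a single branch point, so thick crossings are not double-counted;
#' `merge = FALSE` counts raw junction pixels.
#'
#' @param skeleton A `neurite_skeleton` or a logical skeleton matrix.
#' @param merge Merge 8-connected clusters of junction pixels.
#' @return Integer branch-point count.
#' @export
count_branch_points <- function(skeleton, merge = TRUE) {
  S <- if (inherits(skeleton, "neurite_skeleton")) skeleton$skeleton else
    as_logical_mask(skeleton)
  if (!any(S)) return(0L)
  deg <- Reduce(`+`, zs_neighbours(S))
  junction <- S & deg >= 3
  if (!any(junction)) return(0L)
  if (!merge) return(sum(junction))
  max(label_components(junction, connectivity = 8))
}

#' Branch points normalized to neurite length
#'
#' Number of (merged) branch points divided by skeleton length in pixels.
#' Undefined (returned as `NA`) for an empty skeleton rather than 0, so a
#' missing measurement is distinguishable from an unbranched neurite.
#'
#' @param skeleton A `neurite_skeleton` or logical skeleton matrix.
#' @return Branch points per skeleton pixel, in \[0, 1\], or `NA`.
#' @export
normalized_branch_points <- function(skeleton) {
  if (!inherits(skeleton, "neurite_skeleton")) {
    skeleton <- structure(
      list(skeleton = as_logical_mask(skeleton),
           length_px = sum(as_logical_mask(skeleton))),
      class = "neurite_skeleton")
    skeleton$branch_count <- count_branch_points(skeleton)
  }
  if (skeleton$length_px == 0) {
    warning("empty skeleton: normalized branch points undefined")
    return(NA_real_)
  }
  count_branch_points(skeleton) / skeleton$length_px
}
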