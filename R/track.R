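# Block-matching tracking of the periorbital regions.
#
# Conventions: 1-based (row, col) coordinates; a region of interest (ROI)
# is the inclusive pixel rectangle [top, top+height-1] x [left, left+width-1].
# Candidate blocks that would extend past the frame border are excluded
# from candidacy, never clipped.

#' Region of interest
#'
#' @param top,left 1-based position of the upper-left pixel.
#' @param height,width extent in pixels.
#' @return object of class `roi`.
#' @export
roi <- function(top, left, height, width) {
  if (height < 1 || width < 1) pt_stop("roi height and width must be >= 1")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

roi_inside <- function(r, nrow, ncol) {
  r$top >= 1 && r$left >= 1 &&
    r$top + r$height - 1 <= nrow && r$left + r$width - 1 <= ncol
}

block_at <- function(frame, top, left, height, width) {
  frame[top:(top + height - 1), left:(left + width - 1), drop = FALSE]
}

#' Mean-squared-error matching score
#'
#' The matching criterion for block tracking: the mean over pixels of the
#' squared temperature difference between two equally sized blocks. Zero
#' iff the blocks are identical.
#'
#' @param block_a,block_b numeric matrices of identical dimensions (K).
#' @return MSE in K^2.
#' @examples
#' a <- matrix(300, 4, 4)
#' mse_score(a, a + 0.1)  # 0.01
#' @export
mse_score <- function(block_a, block_b) {
  if (!identical(dim(block_a), dim(block_b)))
    pt_stop("mse_score: block dimensions differ")
  mean((block_a - block_b)^2)
}

# internal: pick the best candidate among rows of `d` (displacements) with
# scores `sc`; ties broken by smaller |d_row|+|d_col|, then row-major order
pick_best <- function(d, sc) {
  o <- order(sc, abs(d[, 1]) + abs(d[, 2]), d[, 1], d[, 2])
  o[1]
}

# internal: shared machinery of the two searches. Scores the ref block at
# predicted_pos + d for each displacement; invalid (out-of-frame) candidates
# are dropped. Memoised across stages via an environment.
make_scorer <- function(ref_block, frame, predicted_pos) {
  h <- nrow(ref_block); w <- ncol(ref_block)
  nr <- nrow(frame); nc <- ncol(frame)
  if (h > nr || w > nc) pt_stop("reference block larger than frame")
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(d) {
    top <- predicted_pos[1] + d[1]; left <- predicted_pos[2] + d[2]
    if (top < 1 || left < 1 || top + h - 1 > nr || left + w - 1 > nc)
      return(NA_real_)
    key <- paste(d[1], d[2])
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    v <- mean((ref_block - frame[top:(top + h - 1),
                                 left:(left + w - 1)])^2)
    cache[[key]] <- v
    v
  }
  list(score = score, n_eval = function() n_eval)
}

#' Cross-search block matching
#'
#' Logarithmic block-matching search with the x-shaped candidate pattern:
#' starting from the predicted position with step `max_step`, the centre
#' and the four diagonal neighbours at the current step are scored with
#' [mse_score()]; the search moves to the best candidate, repeating at the
#' same step until the centre wins, then halves the step. At step 1 the
#' full 8-neighbourhood is searched (hill climb) so that displacements of
#' either parity can be resolved exactly. Deterministic: ties are broken by
#' smaller Manhattan displacement, then row-major order, which favours no
#' motion.
#'
#' @param ref_block reference temperature block (matrix, K).
#' @param frame frame to search in (matrix, K).
#' @param predicted_pos predicted `(top, left)` position of the block in
#'   `frame` (1-based).
#' @param max_step initial step size in pixels; a power of two.
#' @return list with `d` (the `(d_row, d_col)` displacement of the best
#'   candidate visited, relative to `predicted_pos`), `mse` (its score),
#'   `n_eval` (blocks scored) and `lost` (`TRUE` when every candidate,
#'   including the predicted position, fell outside the frame — the
#'   tracking-failure signal).
#' @seealso [full_search()] for the exhaustive oracle.
#' @export
cross_search <- function(ref_block, frame, predicted_pos, max_step = 8) {
  if (max_step < 1 || bitwAnd(as.integer(max_step),
                              as.integer(max_step) - 1L) != 0L)
    pt_stop("max_step must be a power of two")
  sc <- make_scorer(ref_block, frame, predicted_pos)
  cur <- c(0L, 0L)
  ok <- FALSE  # have we scored at least one valid candidate?

  run_stage <- function(step, pattern) {
    for (iter in 1:400) {
      cand <- rbind(cur, sweep(pattern * step, 2, cur, "+"))
      scores <- apply(cand, 1, sc$score)
      valid <- !is.na(scores)
      if (!any(valid)) return(FALSE)
      ok <<- TRUE
      cand <- cand[valid, , drop = FALSE]
      best <- pick_best(cand, scores[valid])
      if (all(cand[best, ] == cur)) return(TRUE)
      cur <<- cand[best, ]
    }
    TRUE
  }

  diag_pat <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  full_pat <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  full_pat <- full_pat[!(full_pat[, 1] == 0 & full_pat[, 2] == 0), ]
  step <- max_step
  while (step > 1) {
    run_stage(step, diag_pat)
    step <- step %/% 2
  }
  run_stage(1L, full_pat)

  if (!ok)
    return(list(d = c(NA_integer_, NA_integer_), mse = NA_real_,
                n_eval = sc$n_eval(), lost = TRUE))
  list(d = as.integer(cur), mse = sc$score(cur), n_eval = sc$n_eval(),
       lost = FALSE)
}

#' Exhaustive block-matching search (test oracle)
#'
#' Scans every integer displacement within a square radius of the predicted
#' position and returns the global MSE minimiser, with the same
#' deterministic tie rule as [cross_search()]. Serves as the correctness
#' oracle for the cross search.
#'
#' @inheritParams cross_search
#' @param radius half-width of the square search range, pixels.
#' @return same structure as [cross_search()].
#' @export
full_search <- function(ref_block, frame, predicted_pos, radius = 10) {
  sc <- make_scorer(ref_block, frame, predicted_pos)
  g <- as.matrix(expand.grid(dr = -radius:radius, dc = -radius:radius))
  scores <- apply(g, 1, sc$score)
  valid <- !is.na(scores)
  if (!any(valid))
    return(list(d = c(NA_integer_, NA_integer_), mse = NA_real_,
                n_eval = sc$n_eval(), lost = TRUE))
  g <- g[valid, , drop = FALSE]
  best <- pick_best(g, scores[valid])
  list(d = as.integer(g[best, ]), mse = scores[valid][best],
       n_eval = sc$n_eval(), lost = FALSE)
}

#' Per-region track
#'
#' Container for the result of tracking one periorbital region: per-frame
#' ROI positions and winning match scores, with a failure flag. Exported so
#' that synthetic tracks (e.g. with injected ROI jitter) can be constructed
#' directly.
#'
#' @param pos `n x 2` matrix of `(top, left)` ROI positions (rows `NA`
#'   before `start_frame` / after failure).
#' @param height,width ROI extent, pixels.
#' @param scores per-frame winning MSE (K^2).
#' @param side `"left"` or `"right"`.
#' @param start_frame frame at which tracking began.
#' @param failed,failure_frame failure flag and first failing frame.
#' @return object of class `region_track`.
#' @export
region_track <- function(pos, height, width, scores = NULL, side = "left",
                         start_frame = 1L, failed = FALSE,
                         failure_frame = NA_integer_) {
  structure(list(side = side, start_frame = as.integer(start_frame),
                 pos = pos, height = as.integer(height),
                 width = as.integer(width),
                 scores = if (is.null(scores)) rep(NA_real_, nrow(pos))
                          else scores,
                 failed = failed, failure_frame = failure_frame),
            class = "region_track")
}

#' @export
print.region_track <- function(x, ...) {
  cat(sprintf("<region_track> side %s, %d x %d px, start frame %d%s\n",
              x$side, x$height, x$width, x$start_frame,
              if (x$failed) sprintf(", FAILED at frame %d", x$failure_frame)
              else ""))
  invisible(x)
}

#' Track a region through a frame stack
#'
#' Frame-to-frame cross-search tracking of a reference region. The
#' reference block is fixed: it is cut from `start_frame` at `ref_roi` and
#' never re-templated (avoiding template drift). Each frame's search is
#' centred on the previous frame's position. Tracking fails — and the trial
#' is to be marked unusable — when the region leaves the frame (no valid
#' candidate) or when the winning MSE exceeds `fail_mult` times the median
#' winning MSE of the trial's first `fail_window` frames for at least
#' `fail_k` consecutive frames.
#'
#' @param stack a [thermal_stack()].
#' @param ref_roi reference [roi()], fully inside the frame.
#' @param start_frame frame index providing the reference block.
#' @param side label stored in the track.
#' @param max_step cross-search initial step.
#' @param fail_mult,fail_window,fail_k failure-rule parameters (see above).
#' @return a [region_track()].
#' @export
track_region <- function(stack, ref_roi, start_frame = 1L, side = "left",
                         max_step = 8, fail_mult = 25, fail_window = 15L,
                         fail_k = 5L) {
  n <- n_frames(stack)
  if (n < 1) pt_stop("empty frame stack")
  d <- dim(stack$data)
  if (!roi_inside(ref_roi, d[1], d[2]))
    pt_stop("reference ROI not fully inside the frame")
  ref_block <- block_at(stack$data[, , start_frame], ref_roi$top,
                        ref_roi$left, ref_roi$height, ref_roi$width)
  pos <- matrix(NA_real_, n, 2)
  scores <- rep(NA_real_, n)
  pos[start_frame, ] <- c(ref_roi$top, ref_roi$left)
  scores[start_frame] <- 0
  failed <- FALSE; failure_frame <- NA_integer_
  thr <- NA_real_; consec <- 0L
  if (start_frame < n) for (f in (start_frame + 1):n) {
    res <- cross_search(ref_block, stack$data[, , f], pos[f - 1, ],
                        max_step = max_step)
    if (res$lost) {
      failed <- TRUE; failure_frame <- f
      break
    }
    pos[f, ] <- pos[f - 1, ] + res$d
    scores[f] <- res$mse
    if (is.na(thr) && f - start_frame + 1L >= fail_window)
      thr <- fail_mult *
        median(scores[start_frame:(start_frame + fail_window - 1L)])
    if (!is.na(thr)) {
      if (scores[f] > thr) consec <- consec + 1L else consec <- 0L
      if (consec >= fail_k) {
        failed <- TRUE; failure_frame <- f - fail_k + 1L
        break
      }
    }
  }
  region_track(pos, ref_roi$height, ref_roi$width, scores, side,
               start_frame, failed, failure_frame)
}
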