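#' Stepwise Gram-Schmidt forward channel selection
#'
#' Reduces the feature set to `k` channels by forward orthogonal selection
#' against the kinematic targets. All channels are mean-centered; at each
#' step every unselected channel is residualized against the span of the
#' already-selected channels, and the channel whose residual maximizes the
#' summed squared correlation with the 12 kinematic traces is selected
#' (ties broken by lowest index). Selection stops early, with a warning,
#' when every remaining residual falls below a numerical-rank tolerance.
#'
#' The score of candidate residual \eqn{r} is
#' \deqn{\sum_{d=1}^{12} \mathrm{cor}(r, y_d)^2,}
#' the forward orthogonal-least-squares criterion generalized to multiple
#' targets; it is invariant to positive rescaling of any channel.
#'
#' @param features A `feature_matrix` (or a plain channels x frames matrix).
#' @param kin A `kin_trace` (or a 12 x frames matrix), frame-aligned.
#' @param k Number of channels to retain.
#' @param tol Relative residual-norm tolerance for rank exhaustion.
#' @return An object of class `selection_result`: list with
#'   `selected_indices` (in selection order) and `scores` (per-step score of
#'   the selected channel).
#' @export
gram_schmidt_select <- function(features, kin, k = 48, tol = 1e-10) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  Y <- if (inherits(kin, "kin_trace")) kin$values else as.matrix(kin)
  if (ncol(X) != ncol(Y)) stopf("features and kinematics are not frame-aligned")
  n <- nrow(X)
  if (k > n) stopf("k (%d) exceeds the number of channels (%d)", k, n)
  Tn <- ncol(X)
  R <- X - rowMeans(X)                       # centered candidates -> residuals
  Yc <- Y - rowMeans(Y)
  y_norm <- sqrt(rowSums(Yc^2))
  keep_y <- y_norm > 0                        # DOFs never moved carry no signal
  Yn <- Yc[keep_y, , drop = FALSE] / y_norm[keep_y]
  orig_norm <- sqrt(rowSums(R^2))
  alive <- orig_norm > 0
  selected <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(k)) {
    r_norm <- sqrt(rowSums(R^2))
    alive <- alive & (r_norm > tol * pmax(orig_norm, .Machine$double.eps))
    if (!any(alive)) {
      warning(sprintf("rank exhausted after %d channels (k = %d requested)",
                      length(selected), k))
      break
    }
    cr <- (R %*% t(Yn)) / pmax(r_norm, .Machine$double.eps)  # n x n_dof_active
    sc <- rowSums(cr^2)
    sc[!alive] <- -Inf
    best <- which.max(sc)                    # which.max takes the lowest index
    selected <- c(selected, best)
    scores <- c(scores, sc[best])
    u <- R[best, ] / r_norm[best]
    R <- R - (R %*% u) %*% t(u)
    R[best, ] <- 0
    alive[best] <- FALSE
  }
  structure(list(selected_indices = selected, scores = scores, k = k,
                 n_channels = n),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Gram-Schmidt selection: %d of %d channels retained\n",
              length(x$selected_indices), x$n_channels))
  if (length(x$selected_indices) > 0)
    cat("  first channels:",
        paste(utils::head(x$selected_indices, 8), collapse = ", "),
        if (length(x$selected_indices) > 8) "...", "\n")
  invisible(x)
}
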